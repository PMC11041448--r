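static_csv_columns <- c(
  "patient_id", "outcome", "age", "sex", "bmi", "cause",
  "arrest_pre_ecmo", "shock_pre_ecmo", "reinfusion_site", "drainage_site",
  "reinfusion_size", "drainage_size", "ventilation_type"
)

#' Read a cohort from CSV files
#'
#' Reads one static CSV (one row per patient, columns as in
#' `cevvo:::static_csv_columns`) and one long-format perfusion CSV with
#' columns `patient_id, elapsed_seconds, variable, value`. Perfusion points
#' are sorted by time; every patient in the static table must have at least
#' one perfusion row and vice versa. Missing numeric static values are
#' imputed with the cohort median (with a warning).
#'
#' @param static_path path to the static-variables CSV.
#' @param perfusion_path path to the long-format perfusion CSV.
#' @return A list of [patient_record()] objects, in static-CSV row order.
#' @export
read_cohort <- function(static_path, perfusion_path) {
  static <- utils::read.csv(static_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(static_csv_columns, names(static))
  if (length(missing_cols))
    stop_cevvo("static CSV is missing required column(s): ",
               paste(missing_cols, collapse = ", "),
               class = "cevvo_format_error")
  perf <- utils::read.csv(perfusion_path, stringsAsFactors = FALSE)
  perf_cols <- c("patient_id", "elapsed_seconds", "variable", "value")
  if (!all(perf_cols %in% names(perf)))
    stop_cevvo("perfusion CSV is missing required column(s): ",
               paste(setdiff(perf_cols, names(perf)), collapse = ", "),
               class = "cevvo_format_error")
  perf$patient_id <- as.character(perf$patient_id)
  static$patient_id <- as.character(static$patient_id)

  stray <- setdiff(unique(perf$patient_id), static$patient_id)
  if (length(stray))
    stop_cevvo("perfusion rows reference unknown patient id(s): ",
               paste(stray, collapse = ", "),
               class = "cevvo_validation_error")
  bad_var <- setdiff(unique(perf$variable), perfusion_channels)
  if (length(bad_var))
    stop_cevvo("unknown perfusion variable(s): ",
               paste(bad_var, collapse = ", "),
               class = "cevvo_validation_error")

  # Median-impute missing numeric statics once, over the whole cohort.
  for (col in c("age", "bmi", "reinfusion_size", "drainage_size")) {
    if (anyNA(static[[col]])) {
      med <- stats::median(static[[col]], na.rm = TRUE)
      warning(sprintf("imputing %d missing '%s' value(s) with cohort median %g",
                      sum(is.na(static[[col]])), col, med))
      static[[col]][is.na(static[[col]])] <- med
    }
  }

  perf_by_id <- split(perf, perf$patient_id)
  lapply(seq_len(nrow(static)), function(i) {
    row <- static[i, ]
    p <- perf_by_id[[row$patient_id]]
    if (is.null(p))
      stop_cevvo("patient ", row$patient_id, " has no perfusion rows",
                 class = "cevvo_validation_error")
    channels <- intersect(perfusion_channels, unique(p$variable))
    times <- sort(unique(p$elapsed_seconds))
    series <- matrix(NA_real_, length(times), length(channels),
                     dimnames = list(NULL, channels))
    row_idx <- match(p$elapsed_seconds, times)
    col_idx <- match(p$variable, channels)
    series[cbind(row_idx, col_idx)] <- p$value
    patient_record(
      patient_id = row$patient_id, outcome = row$outcome, age = row$age,
      sex = row$sex, bmi = row$bmi, cause = row$cause,
      arrest_pre_ecmo = row$arrest_pre_ecmo,
      shock_pre_ecmo = row$shock_pre_ecmo,
      reinfusion_site = row$reinfusion_site,
      drainage_site = row$drainage_site,
      reinfusion_size = row$reinfusion_size,
      drainage_size = row$drainage_size,
      ventilation_type = row$ventilation_type,
      time = times, series = series
    )
  })
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: writes the static table and the long-format
#' perfusion table for a list of patient records.
#'
#' @param records list of [patient_record()] objects.
#' @param static_path,perfusion_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(records, static_path, perfusion_path) {
  static <- do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$patient_id, outcome = r$outcome, age = r$age,
               sex = r$sex, bmi = r$bmi, cause = r$cause,
               arrest_pre_ecmo = r$arrest_pre_ecmo,
               shock_pre_ecmo = r$shock_pre_ecmo,
               reinfusion_site = r$reinfusion_site,
               drainage_site = r$drainage_site,
               reinfusion_size = r$reinfusion_size,
               drainage_size = r$drainage_size,
               ventilation_type = r$ventilation_type,
               stringsAsFactors = FALSE)
  }))
  perf <- do.call(rbind, lapply(records, function(r) {
    k <- nrow(r$series)
    v <- ncol(r$series)
    data.frame(patient_id = rep(r$patient_id, k * v),
               elapsed_seconds = rep(r$time, v),
               variable = rep(colnames(r$series), each = k),
               value = as.vector(r$series),
               stringsAsFactors = FALSE)
  }))
  perf <- perf[!is.na(perf$value), ]
  utils::write.csv(static, static_path, row.names = FALSE)
  utils::write.csv(perf, perfusion_path, row.names = FALSE)
  invisible(c(static_path, perfusion_path))
}
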