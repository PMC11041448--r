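#' Perfusion channel names
#'
#' The eight perfusion channels carried by every patient record, in canonical
#' column order. The first six are measured by the device at (by default)
#' 120-second intervals; the last two are derived per-patient ratios added by
#' [derive_ratio_features()].
#'
#' \describe{
#'   \item{dp_membrane}{pressure change across the membrane lung (mmHg)}
#'   \item{venous_pressure}{venous drainage pressure (mmHg)}
#'   \item{flow}{blood flow across the circuit (L/min)}
#'   \item{pump_speed}{pump head rotation speed (RPM)}
#'   \item{sweep}{sweep gas flow through the membrane lung (L/min)}
#'   \item{support_time}{elapsed time on support (hours)}
#'   \item{flow_per_bmi}{circuit flow divided by patient BMI}
#'   \item{sweep_per_flow}{sweep gas flow divided by circuit flow}
#' }
#'
#' @export
perfusion_channels <- c(
  "dp_membrane", "venous_pressure", "flow", "pump_speed", "sweep",
  "support_time", "flow_per_bmi", "sweep_per_flow"
)

raw_perfusion_channels <- perfusion_channels[1:6]

#' Static-variable encoding schema
#'
#' Fixed, documented encoding of the clinical (static) variables into a
#' 32-dimensional numeric vector: four numeric fields passed through, two
#' binary fields, and one-hot blocks for sex and the four multi-level
#' categoricals. The decannulation outcome is never part of the encoding.
#'
#' @return A list with the level sets for each categorical field, the field
#'   order, and the total encoded width (32).
#' @export
static_schema <- function() {
  schema <- list(
    numeric = c("age", "bmi", "reinfusion_size", "drainage_size"),
    binary = c("arrest_pre_ecmo", "shock_pre_ecmo"),
    levels = list(
      sex = c("female", "male"),
      cause = c("covid_ards", "bacterial_pneumonia", "viral_pneumonia",
                "aspiration", "trauma", "asthma", "pulmonary_fibrosis",
                "vaping_injury", "other"),
      reinfusion_site = c("right_ij", "left_ij", "femoral", "subclavian",
                          "dual_lumen"),
      drainage_site = c("femoral", "right_ij", "left_ij", "subclavian",
                        "dual_lumen"),
      ventilation_type = c("conventional", "aprv", "hfov", "nippv", "none")
    )
  )
  schema$width <- length(schema$numeric) + length(schema$binary) +
    sum(lengths(schema$levels))
  schema
}

#' Construct a patient record
#'
#' A patient record bundles the static clinical variables, the binary
#' decannulation outcome, and the raw perfusion time series for one VV-ECMO
#' run.
#'
#' @param patient_id opaque identifier.
#' @param outcome 1 = successful decannulation, 0 = unsuccessful.
#' @param age,bmi numeric; `bmi` must be positive.
#' @param sex,cause,reinfusion_site,drainage_site,ventilation_type categorical
#'   fields; levels must belong to [static_schema()].
#' @param arrest_pre_ecmo,shock_pre_ecmo binary (0/1).
#' @param reinfusion_size,drainage_size cannula sizes (French gauge).
#' @param time numeric vector of elapsed seconds, strictly increasing.
#' @param series numeric matrix with one row per time point and one column per
#'   perfusion channel (6 raw channels, or 8 after
#'   [derive_ratio_features()]); columns must be named.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, outcome, age, sex, bmi, cause,
                           arrest_pre_ecmo, shock_pre_ecmo,
                           reinfusion_site, drainage_site,
                           reinfusion_size, drainage_size,
                           ventilation_type, time, series) {
  series <- as.matrix(series)
  if (length(time) == 0L || nrow(series) == 0L)
    stop_cevvo("patient ", patient_id, ": perfusion series is empty",
               class = "cevvo_validation_error")
  if (nrow(series) != length(time))
    stop_cevvo("patient ", patient_id, ": time/series length mismatch",
               class = "cevvo_validation_error")
  if (any(diff(time) <= 0))
    stop_cevvo("patient ", patient_id,
               ": elapsed_seconds must be strictly increasing",
               class = "cevvo_validation_error")
  if (!outcome %in% c(0, 1))
    stop_cevvo("patient ", patient_id, ": outcome must be 0 or 1",
               class = "cevvo_validation_error")
  if (!is.na(bmi) && bmi <= 0)
    stop_cevvo("patient ", patient_id, ": bmi must be positive",
               class = "cevvo_validation_error")
  schema <- static_schema()
  cats <- list(sex = sex, cause = cause, reinfusion_site = reinfusion_site,
               drainage_site = drainage_site,
               ventilation_type = ventilation_type)
  for (field in names(cats)) {
    if (!cats[[field]] %in% schema$levels[[field]])
      stop_cevvo("patient ", patient_id, ": unknown level '", cats[[field]],
                 "' for field '", field, "'",
                 class = "cevvo_validation_error")
  }
  structure(list(
    patient_id = as.character(patient_id),
    outcome = as.integer(outcome),
    age = age, sex = sex, bmi = bmi, cause = cause,
    arrest_pre_ecmo = as.integer(arrest_pre_ecmo),
    shock_pre_ecmo = as.integer(shock_pre_ecmo),
    reinfusion_site = reinfusion_site, drainage_site = drainage_site,
    reinfusion_size = reinfusion_size, drainage_size = drainage_size,
    ventilation_type = ventilation_type,
    time = as.numeric(time), series = series
  ), class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf(
    "<patient_record %s> outcome=%d, %d time points over %.1f h, %d channels\n",
    x$patient_id, x$outcome, length(x$time), run_hours(x), ncol(x$series)))
  invisible(x)
}

#' Run duration in hours
#'
#' @param record a `patient_record`.
#' @return Elapsed time from cannulation to the last perfusion point, hours.
#' @export
run_hours <- function(record) max(record$time) / 3600
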