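#' Append derived ratio channels
#'
#' Adds the two patient-normalising ratio channels to a record's perfusion
#' series: circuit flow divided by BMI (`flow_per_bmi`) and sweep gas flow
#' divided by circuit flow (`sweep_per_flow`). Where the flow is exactly zero
#' the ratio `sweep_per_flow` is defined as 0 — the circuit is providing no
#' support, so no gas exchange per unit flow is attributed.
#'
#' @param record a [patient_record()] carrying the six raw channels.
#' @return The record with an 8-column series; already-derived records are
#'   returned unchanged.
#' @export
derive_ratio_features <- function(record) {
  s <- record$series
  if (all(c("flow_per_bmi", "sweep_per_flow") %in% colnames(s)))
    return(record)
  if (!all(c("flow", "sweep") %in% colnames(s)))
    stop_cevvo("record needs 'flow' and 'sweep' channels before ratios",
               class = "cevvo_validation_error")
  flow <- s[, "flow"]
  spf <- ifelse(flow == 0, 0, s[, "sweep"] / flow)
  s <- cbind(s, flow_per_bmi = flow / record$bmi, sweep_per_flow = spf)
  record$series <- s[, intersect(perfusion_channels, colnames(s)), drop = FALSE]
  record
}

#' Truncation augmentation
#'
#' Expands each patient run into one sample per requested truncation
#' fraction: the sample at fraction f keeps the first `ceiling(f * K)` of the
#' K raw time points. With the default ten fractions a cohort of N patients
#' yields 10 N samples.
#'
#' @param records list of [patient_record()] objects.
#' @param fractions truncation fractions in (0, 1]; default `seq(0.1, 1, 0.1)`.
#' @return A list of raw samples: each a list with `patient_id`, `fraction`,
#'   `time`, `series`, `label` and `end_day` (days from cannulation to the
#'   last included point).
#' @export
truncate_runs <- function(records, fractions = seq(0.1, 1, by = 0.1)) {
  if (any(fractions <= 0 | fractions > 1))
    stop_cevvo("truncation fractions must lie in (0, 1]",
               class = "cevvo_parameter_error")
  out <- vector("list", length(records) * length(fractions))
  i <- 0L
  for (r in records) {
    k_total <- length(r$time)
    for (f in fractions) {
      keep <- seq_len(ceiling(f * k_total))
      i <- i + 1L
      out[[i]] <- list(
        patient_id = r$patient_id, fraction = f,
        time = r$time[keep],
        series = r$series[keep, , drop = FALSE],
        label = r$outcome,
        end_day = r$time[max(keep)] / 86400
      )
    }
  }
  out
}

#' Standardise a series to a fixed number of time steps
#'
#' Maps a K x V series onto a fixed grid of `n_steps` slots by proportional
#' stretch: raw point k (0-based) lands in slot `floor(k * n_steps / K)`.
#' Slots receiving several points take their mean; empty slots are
#' forward-filled from the previous filled slot; slots before the first
#' filled slot are set to 0. Every input, whatever its raw length, therefore
#' spans the full grid, so a truncated run carries no length cue.
#'
#' @param series numeric matrix (K x V), time-ordered; K = 0 gives an
#'   all-zero matrix.
#' @param n_steps target number of time steps (e.g. 2054 at full scale).
#' @return An `n_steps` x V matrix.
#' @export
standardize_length <- function(series, n_steps) {
  series <- as.matrix(series)
  if (n_steps < 1)
    stop_cevvo("n_steps must be >= 1", class = "cevvo_parameter_error")
  v <- ncol(series)
  k <- nrow(series)
  if (k == 0)
    return(matrix(0, n_steps, v, dimnames = list(NULL, colnames(series))))
  slot <- floor((seq_len(k) - 1) * n_steps / k)  # 0-based slot index
  sums <- rowsum(series, slot, reorder = TRUE)
  counts <- as.vector(table(slot))
  means <- sums / counts
  filled <- as.integer(rownames(sums)) + 1L     # 1-based filled slots
  out <- matrix(NA_real_, n_steps, v, dimnames = list(NULL, colnames(series)))
  out[filled, ] <- means
  # forward fill: index of the most recent filled slot at or before each slot
  last_filled <- cummax(ifelse(seq_len(n_steps) %in% filled,
                               seq_len(n_steps), 0L))
  has_prev <- last_filled > 0L
  out[has_prev, ] <- out[last_filled[has_prev], , drop = FALSE]
  out[!has_prev, ] <- 0
  out
}

#' Encode static clinical variables
#'
#' Deterministically encodes a record's static variables into a fixed-width
#' numeric vector under [static_schema()]: numerics passed through, binaries
#' as 0/1, categoricals one-hot in schema level order. The outcome label is
#' never encoded. Default width is 32.
#'
#' @param record a [patient_record()].
#' @param schema encoding schema, default [static_schema()].
#' @return A named numeric vector of length `schema$width`.
#' @export
encode_static <- function(record, schema = static_schema()) {
  num <- vapply(schema$numeric, function(f) as.numeric(record[[f]]),
                numeric(1))
  bin <- vapply(schema$binary, function(f) as.numeric(record[[f]]),
                numeric(1))
  oh <- unlist(lapply(names(schema$levels), function(f) {
    lv <- schema$levels[[f]]
    if (!record[[f]] %in% lv)
      stop_cevvo("field '", f, "': level '", record[[f]],
                 "' not in schema", class = "cevvo_validation_error")
    stats::setNames(as.numeric(lv == record[[f]]), paste(f, lv, sep = "."))
  }))
  c(num, bin, oh)
}

#' Fit / apply per-feature min-max scaling
#'
#' `fit_scaler()` learns per-feature minima and maxima — one pair per
#' perfusion channel (over all time steps of all training samples) and one
#' per static dimension — from the *training* samples only. `apply_scaler()`
#' maps x to (x - min) / (max - min) for every sample passed to it, without
#' clipping, so values outside the training range may fall outside [0, 1].
#' A feature constant on the training set maps to 0 everywhere.
#'
#' @param train_samples list of samples as produced by [prepare_samples()].
#' @return `fit_scaler()`: an object of class `cevvo_scaler`.
#' @export
fit_scaler <- function(train_samples) {
  stopifnot(length(train_samples) > 0)
  ch_min <- NULL; ch_max <- NULL
  for (s in train_samples) {
    lo <- apply(s$series, 2, min); hi <- apply(s$series, 2, max)
    ch_min <- if (is.null(ch_min)) lo else pmin(ch_min, lo)
    ch_max <- if (is.null(ch_max)) hi else pmax(ch_max, hi)
  }
  st <- do.call(rbind, lapply(train_samples, function(s) s$static))
  structure(list(
    series_min = ch_min, series_max = ch_max,
    static_min = apply(st, 2, min), static_max = apply(st, 2, max),
    fitted_on = attr(train_samples, "split") %||% "training"
  ), class = "cevvo_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `cevvo_scaler`.
#' @param samples samples to transform.
#' @return `apply_scaler()`: the samples with `series` and `static` rescaled.
#' @export
apply_scaler <- function(scaler, samples) {
  if (!inherits(scaler, "cevvo_scaler"))
    stop_cevvo("scaler has not been fitted", class = "cevvo_state_error")
  rng_s <- scaler$series_max - scaler$series_min
  rng_t <- scaler$static_max - scaler$static_min
  scale1 <- function(x, lo, rng) ifelse(rng == 0, 0, (x - lo) / rng)
  lapply(samples, function(s) {
    s$series <- sweep(s$series, 2, scaler$series_min)
    s$series <- sweep(s$series, 2, ifelse(rng_s == 0, 1, rng_s), "/")
    s$series[, rng_s == 0] <- 0
    s$static <- scale1(s$static, scaler$static_min, rng_t)
    s
  })
}

#' Build model-ready samples from raw records
#'
#' Full preprocessing chain: derive ratio channels, apply truncation
#' augmentation, standardise every truncated series to `n_steps` time steps,
#' and attach the encoded static vector and label. Scaling is *not* applied
#' here — fit a scaler on the training split and use [apply_scaler()].
#'
#' @param records list of [patient_record()] objects.
#' @param n_steps standardised series length (2054 at full scale).
#' @param fractions truncation fractions, default `seq(0.1, 1, 0.1)`; use
#'   `1` alone to disable augmentation.
#' @param schema static encoding schema.
#' @return A list of samples; each has `patient_id`, `fraction`, `series`
#'   (`n_steps` x 8), `static`, `label`, `end_day`.
#' @export
prepare_samples <- function(records, n_steps,
                            fractions = seq(0.1, 1, by = 0.1),
                            schema = static_schema()) {
  records <- lapply(records, derive_ratio_features)
  statics <- lapply(records, encode_static, schema = schema)
  names(statics) <- vapply(records, `[[`, character(1), "patient_id")
  raw <- truncate_runs(records, fractions)
  lapply(raw, function(s) {
    list(patient_id = s$patient_id, fraction = s$fraction,
         series = standardize_length(s$series, n_steps),
         static = statics[[s$patient_id]],
         label = s$label, end_day = s$end_day)
  })
}

# Stack a list of samples into arrays for the classifiers:
# X (N x T x V), S (N x d_static), y (N).
samples_to_arrays <- function(samples) {
  n <- length(samples)
  if (n == 0)
    return(list(x = array(0, c(0, 0, 0)), s = matrix(0, 0, 0),
                y = numeric(0), patient_id = character(0),
                fraction = numeric(0), end_day = numeric(0)))
  t_len <- nrow(samples[[1]]$series)
  v <- ncol(samples[[1]]$series)
  x <- array(0, c(n, t_len, v))
  for (i in seq_len(n)) x[i, , ] <- samples[[i]]$series
  list(
    x = x,
    s = do.call(rbind, lapply(samples, function(z) z$static)),
    y = vapply(samples, function(z) z$label, numeric(1)),
    patient_id = vapply(samples, function(z) z$patient_id, character(1)),
    fraction = vapply(samples, function(z) z$fraction, numeric(1)),
    end_day = vapply(samples, function(z) z$end_day, numeric(1))
  )
}
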