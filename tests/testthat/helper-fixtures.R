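# Deterministic toy records and small simulated cohorts used across tests.

toy_record <- function(id = "p1", outcome = 1, k = 20, bmi = 25,
                       flow = 5, sweep = 4, interval = 120) {
  time <- (seq_len(k) - 1) * interval
  series <- cbind(
    dp_membrane = 40 + sin(seq_len(k)),
    venous_pressure = -60 + cos(seq_len(k)),
    flow = rep(flow, k),
    pump_speed = 3000 + 10 * seq_len(k),
    sweep = rep(sweep, k),
    support_time = time / 3600
  )
  patient_record(
    patient_id = id, outcome = outcome, age = 50, sex = "female",
    bmi = bmi, cause = "covid_ards", arrest_pre_ecmo = 0,
    shock_pre_ecmo = 1, reinfusion_site = "right_ij",
    drainage_site = "femoral", reinfusion_size = 23, drainage_size = 25,
    ventilation_type = "conventional", time = time, series = series
  )
}

# small fast cohort: short runs, coarse sampling
tiny_cohort <- function(n_success = 6, n_fail = 5, seed = 42,
                        effect_size = 1.5, run_range = c(5, 15),
                        interval = 600) {
  generate_cohort(cohort_spec(
    n_success = n_success, n_fail = n_fail,
    run_length_range_h = run_range, sample_interval_s = interval,
    effect_size = effect_size, seed = seed))
}

# naive loop-based binning oracle for standardize_length
standardize_oracle <- function(series, n_steps) {
  series <- as.matrix(series)
  k <- nrow(series)
  v <- ncol(series)
  out <- matrix(NA_real_, n_steps, v)
  if (k > 0) {
    for (slot in 0:(n_steps - 1)) {
      hits <- which(floor((seq_len(k) - 1) * n_steps / k) == slot)
      if (length(hits))
        out[slot + 1, ] <- colMeans(series[hits, , drop = FALSE])
    }
  }
  for (j in seq_len(v)) {
    last <- 0
    for (i in seq_len(n_steps)) {
      if (is.na(out[i, j])) out[i, j] <- last else last <- out[i, j]
    }
  }
  out
}

# brute-force pairwise AUROC oracle (ties count one half)
auroc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}
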