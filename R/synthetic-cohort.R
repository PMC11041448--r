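#' Specification of a simulated VV-ECMO cohort
#'
#' Describes the generating law of an ECMO-like cohort: class counts, run
#' lengths, the sampling interval of the perfusion channels, the magnitude of
#' the outcome-dependent weaning signal, and the noise process. The defaults
#' emulate the structure of a single-centre adult VV-ECMO cohort: 90
#' successful and 28 unsuccessful decannulations, runs of 3 to 21 days
#' sampled every 120 s, and jittery, autocorrelated perfusion traces.
#'
#' The outcome-dependent components are purely temporal; static variables
#' are drawn independently of outcome, so any learnable signal lives in the
#' dynamics alone. Over the final quarter of the run, successfully weaned
#' patients show (a) a declining ramp in circuit flow, pump speed and sweep
#' gas flow (support being titrated down) and (b) progressively steadier
#' traces: the autocorrelated noise on those channels is damped by
#' `1 / (1 + effect_size * r)` with `r` rising 0 to 1 across the quartile,
#' reflecting the increasingly stable patient-device interaction of a
#' wean. Unsuccessful patients stay flat and unstable. The ramp rises
#' linearly from 0 to `2 * effect_size * ramp_unit` and is multiplied by a
#' per-patient weaning pace drawn from Gamma(4, 4) (mean 1), so the
#' *expected* between-group difference in the final-quartile mean of each
#' ramped channel is `effect_size * ramp_unit` while individual weans vary.
#'
#' @param n_success,n_fail numbers of successful / unsuccessful patients.
#' @param run_length_range_h run duration range in hours (uniform).
#' @param sample_interval_s sampling interval of the device, seconds.
#' @param effect_size magnitude (>= 0) of the outcome-dependent ramp; 0 gives
#'   identical generating laws for both outcome groups.
#' @param smoothness_h correlation time of the autocorrelated (AR(1) /
#'   Ornstein-Uhlenbeck) noise, hours.
#' @param noise_sd named per-channel stationary noise SDs.
#' @param baseline named per-channel population baselines.
#' @param offset_sd named per-channel SDs of the patient-specific baseline
#'   offset (outcome-independent between-patient variability).
#' @param ramp_unit named per-channel ramp magnitudes per unit effect size.
#' @param seed integer seed for [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_success = 90, n_fail = 28,
                        run_length_range_h = c(72, 504),
                        sample_interval_s = 120,
                        effect_size = 1.5,
                        smoothness_h = 6,
                        noise_sd = c(dp_membrane = 5, venous_pressure = 8,
                                     flow = 0.35, pump_speed = 160,
                                     sweep = 0.9),
                        baseline = c(dp_membrane = 40, venous_pressure = -60,
                                     flow = 4.5, pump_speed = 3000,
                                     sweep = 6),
                        offset_sd = c(dp_membrane = 10, venous_pressure = 12,
                                      flow = 0.8, pump_speed = 400,
                                      sweep = 1.5),
                        ramp_unit = c(flow = 0.4, pump_speed = 200,
                                      sweep = 1.2),
                        seed = 1L) {
  if (n_success < 0 || n_fail < 0)
    stop_cevvo("cohort counts must be non-negative",
               class = "cevvo_parameter_error")
  if (any(run_length_range_h <= 0) || diff(run_length_range_h) < 0)
    stop_cevvo("run_length_range_h must be positive and ordered",
               class = "cevvo_parameter_error")
  if (effect_size < 0)
    stop_cevvo("effect_size must be >= 0", class = "cevvo_parameter_error")
  structure(list(
    n_success = n_success, n_fail = n_fail,
    run_length_range_h = run_length_range_h,
    sample_interval_s = sample_interval_s,
    effect_size = effect_size, smoothness_h = smoothness_h,
    noise_sd = noise_sd, baseline = baseline, offset_sd = offset_sd,
    ramp_unit = ramp_unit, seed = seed
  ), class = "cohort_spec")
}

# Stationary AR(1) (discretised Ornstein-Uhlenbeck) noise of length k.
ou_noise <- function(k, sd, phi) {
  if (sd == 0) return(rep(0, k))
  x1 <- stats::rnorm(1, 0, sd)
  if (k == 1) return(x1)
  innov <- stats::rnorm(k - 1, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(c(x1, innov), phi, method = "recursive"))
}

#' Generate one simulated patient
#'
#' Draws static variables from documented outcome-independent distributions
#' (age ~ Normal(50, 15) clipped to \[18, 80\]; BMI ~ Normal(28, 6) clipped to
#' \[15, 60\]; categoricals uniform over the schema levels) and simulates the
#' six raw perfusion channels as baseline + patient offset + autocorrelated
#' noise + the outcome-dependent final-quartile ramp described in
#' [cohort_spec()]. The two ratio channels are then derived with
#' [derive_ratio_features()].
#'
#' @param outcome 1 = successful decannulation, 0 = unsuccessful.
#' @param spec a [cohort_spec()].
#' @param patient_id identifier for the record.
#' @param seed optional seed; with a fixed seed the record is reproducible.
#' @return A [patient_record()] with the full 8-channel series.
#' @export
generate_patient <- function(outcome, spec, patient_id = "sim",
                             seed = NULL) {
  with_seed(seed, {
    run_h <- stats::runif(1, spec$run_length_range_h[1],
                          spec$run_length_range_h[2])
    # k samples covering [0, run): a 48-h run at 120 s gives 1440 points
    k <- max(2L, round(run_h * 3600 / spec$sample_interval_s))
    time <- (seq_len(k) - 1) * spec$sample_interval_s
    phi <- exp(-spec$sample_interval_s / (spec$smoothness_h * 3600))

    # final-quartile progress r in [0, 1]; ramp 0 -> 2 has quartile mean 1
    frac <- time / max(time)
    r01 <- pmax(0, (frac - 0.75) / 0.25)
    ramp <- 2 * r01

    schema <- static_schema()
    age <- min(max(stats::rnorm(1, 50, 15), 18), 80)
    bmi <- min(max(stats::rnorm(1, 28, 6), 15), 60)
    pick <- function(lv) sample(lv, 1)
    pace <- stats::rgamma(1, shape = 4, rate = 4)  # per-patient weaning pace
    damp <- 1 / (1 + spec$effect_size * r01)       # settling of a real wean

    series <- matrix(0, k, 6,
                     dimnames = list(NULL, raw_perfusion_channels))
    for (ch in setdiff(raw_perfusion_channels, "support_time")) {
      noise <- ou_noise(k, spec$noise_sd[[ch]], phi)
      weaned <- ch %in% names(spec$ramp_unit)
      if (outcome == 1 && weaned) noise <- noise * damp
      x <- spec$baseline[[ch]] +
        stats::rnorm(1, 0, spec$offset_sd[[ch]]) + noise
      if (outcome == 1 && weaned)
        x <- x - spec$effect_size * spec$ramp_unit[[ch]] * pace * ramp
      series[, ch] <- x
    }
    series[, "flow"] <- pmax(series[, "flow"], 0.1)
    series[, "sweep"] <- pmax(series[, "sweep"], 0)
    series[, "pump_speed"] <- pmax(series[, "pump_speed"], 500)
    series[, "support_time"] <- time / 3600

    rec <- patient_record(
      patient_id = patient_id, outcome = outcome, age = age,
      sex = pick(schema$levels$sex), bmi = bmi,
      cause = pick(schema$levels$cause),
      arrest_pre_ecmo = stats::rbinom(1, 1, 0.5),
      shock_pre_ecmo = stats::rbinom(1, 1, 0.5),
      reinfusion_site = pick(schema$levels$reinfusion_site),
      drainage_site = pick(schema$levels$drainage_site),
      reinfusion_size = sample(c(19, 21, 23, 25), 1),
      drainage_size = sample(c(21, 23, 25, 27), 1),
      ventilation_type = pick(schema$levels$ventilation_type),
      time = time, series = series
    )
    derive_ratio_features(rec)
  })
}

#' Generate a full simulated cohort
#'
#' @param spec a [cohort_spec()]; `spec$seed` makes the cohort reproducible.
#' @return A list of `n_success + n_fail` patient records, successful first.
#' @export
generate_cohort <- function(spec) {
  with_seed(spec$seed, {
    succ <- lapply(seq_len(spec$n_success), function(i)
      generate_patient(1, spec, patient_id = sprintf("S%03d", i)))
    fail <- lapply(seq_len(spec$n_fail), function(i)
      generate_patient(0, spec, patient_id = sprintf("F%03d", i)))
    c(succ, fail)
  })
}
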