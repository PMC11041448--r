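#' Platt scaling of raw classifier scores
#'
#' `fit_platt()` fits a logistic regression of the labels on the log-odds of
#' the raw scores (training predictions only); `apply_platt()` maps raw
#' scores through `sigmoid(A * logit(raw) + B)`. The mapping is strictly
#' monotone in the raw score whenever the fitted slope is positive, so the
#' ranking — and hence AUROC — is preserved.
#'
#' @param raw_scores raw sigmoid outputs in (0, 1).
#' @param labels binary labels; both classes must be present.
#' @return `fit_platt()`: an object of class `platt_params` with slope `A`
#'   and intercept `B`.
#' @export
fit_platt <- function(raw_scores, labels) {
  if (length(unique(labels)) < 2)
    stop_cevvo("Platt scaling needs both classes in the labels",
               class = "cevvo_fit_error")
  z <- logit(raw_scores)
  fit <- suppressWarnings(
    stats::glm(labels ~ z, family = stats::binomial()))
  structure(list(A = unname(stats::coef(fit)[2]),
                 B = unname(stats::coef(fit)[1])),
            class = "platt_params")
}

#' @rdname fit_platt
#' @param params a fitted `platt_params`.
#' @return `apply_platt()`: calibrated probabilities in (0, 1).
#' @export
apply_platt <- function(params, raw_scores) {
  stopifnot(inherits(params, "platt_params"))
  sigmoid(params$A * logit(raw_scores) + params$B)
}

#' Reliability (calibration) curve
#'
#' Bins predictions into `n_bins` equal-width bins on \[0, 1\] — half-open
#' `[l, u)`, final bin closed — and reports per bin the mean predicted
#' probability, the observed positive rate, and the count.
#'
#' @param scores predicted probabilities.
#' @param labels binary labels.
#' @param n_bins number of bins (>= 2, default 10).
#' @return A data.frame `bin, mean_score, observed, n`; empty bins carry
#'   `NA` with `n = 0`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10) {
  stopifnot(n_bins >= 2, length(scores) == length(labels))
  bin <- pmin(pmax(floor(scores * n_bins) + 1L, 1L), n_bins)
  do.call(rbind, lapply(seq_len(n_bins), function(b) {
    in_bin <- bin == b
    data.frame(
      bin = b,
      mean_score = if (any(in_bin)) mean(scores[in_bin]) else NA_real_,
      observed = if (any(in_bin)) mean(labels[in_bin]) else NA_real_,
      n = sum(in_bin))
  }))
}

#' Assign calibrated predictions to risk groups
#'
#' Stratifies a calibrated prediction `x` into four groups using the mean
#' `m` and standard deviation `s` of the calibrated training predictions:
#' group 0 (high risk) if `x <= m - s`; group 1 if `m - s < x <= m`;
#' group 2 if `m < x <= m + s`; group 3 (low risk) if `x > m + s`.
#'
#' @param x calibrated score(s).
#' @param m,s mean and SD of the calibrated training-set predictions;
#'   `s >= 0`.
#' @return Integer group(s) in 0-3, non-decreasing in `x`.
#' @export
assign_risk_group <- function(x, m, s) {
  stopifnot(s >= 0)
  ifelse(x <= m - s, 0L,
         ifelse(x <= m, 1L,
                ifelse(x <= m + s, 2L, 3L)))
}

#' Per-patient risk snapshot at a fixed hour
#'
#' For each patient, selects the prediction whose truncated run ends latest
#' at or before `hours` after cannulation (the "nearest value before" the
#' cutoff). Patients whose full run ended before the cutoff — i.e. already
#' decannulated — are excluded, as are patients with no prediction before
#' the cutoff (with a warning).
#'
#' @param predictions data.frame with columns `patient_id`, `end_hours`
#'   (end of the truncated run, hours), `run_hours` (full run length),
#'   `score`, `label`.
#' @param hours snapshot time, e.g. 72 or 96.
#' @param m,s optional risk-grouping parameters; if supplied a `group`
#'   column is added via [assign_risk_group()].
#' @return A data.frame with one row per retained patient.
#' @export
snapshot_at_hours <- function(predictions, hours, m = NULL, s = NULL) {
  keep <- predictions[predictions$run_hours >= hours, , drop = FALSE]
  rows <- lapply(split(keep, keep$patient_id), function(p) {
    p <- p[p$end_hours <= hours, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    p[which.max(p$end_hours), , drop = FALSE]
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%d patient(s) on support at %g h had no prediction before the cutoff",
                    dropped, hours))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  if (!is.null(m) && !is.null(s))
    out$group <- assign_risk_group(out$score, m, s)
  out
}

# One-sided Fisher exact p for a 2x2 table (x0 successes of n0 in arm 0,
# x1 of n1 in arm 1), H1: arm-1 success probability greater. Conditional on
# the observed margin, P(X1 >= x1) is hypergeometric. Vectorised over x0/x1.
fisher_p_greater <- function(x0, n0, x1, n1) {
  m <- x0 + x1
  stats::phyper(x1 - 1, m, n0 + n1 - m, n1, lower.tail = FALSE)
}

#' Boschloo's exact unconditional test for a 2x2 table
#'
#' Compares success proportions between two independent binomial arms.
#' The ordering statistic is Fisher's one-sided exact p-value; the reported
#' p-value is the maximum over a grid of values of the common nuisance
#' success probability of the probability, under independent binomials, of
#' observing a table whose Fisher p is at most the observed one. It is
#' uniformly at least as powerful as Fisher's test (p_Boschloo <= p_Fisher).
#'
#' @param table 2x2 matrix of counts: rows = arms, columns =
#'   (successes, failures). With `alternative = "greater"` the alternative
#'   is that the *second* arm's success probability exceeds the first's.
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`
#'   (twice the smaller one-sided p, capped at 1).
#' @param grid_size number of equispaced nuisance-probability grid points in
#'   (0, 1); default 999.
#' @return A list: `p_value`, `fisher_p`, `alternative`, `grid_size`.
#' @export
boschloo_exact <- function(table, alternative = c("greater", "less",
                                                  "two.sided"),
                           grid_size = 999) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop_cevvo("table must hold non-negative integer counts",
               class = "cevvo_validation_error")
  if (alternative == "two.sided") {
    p_g <- boschloo_exact(table, "greater", grid_size)$p_value
    p_l <- boschloo_exact(table, "less", grid_size)$p_value
    return(list(p_value = min(1, 2 * min(p_g, p_l)), fisher_p = NA_real_,
                alternative = "two.sided", grid_size = grid_size))
  }
  if (alternative == "less") table <- table[2:1, , drop = FALSE]
  n0 <- sum(table[1, ]); n1 <- sum(table[2, ])
  if (n0 < 1 || n1 < 1)
    stop_cevvo("both arms need at least one observation",
               class = "cevvo_validation_error")
  x0_obs <- table[1, 1]; x1_obs <- table[2, 1]

  grid_x0 <- rep(0:n0, times = n1 + 1)
  grid_x1 <- rep(0:n1, each = n0 + 1)
  fp <- fisher_p_greater(grid_x0, n0, grid_x1, n1)
  fp_obs <- fisher_p_greater(x0_obs, n0, x1_obs, n1)
  extreme <- fp <= fp_obs * (1 + 1e-7) + 1e-12

  pis <- seq_len(grid_size) / (grid_size + 1)
  # P_pi(extreme) = sum over extreme tables of Bin(x0;n0,pi) * Bin(x1;n1,pi)
  d0 <- outer(0:n0, pis, function(x, p) stats::dbinom(x, n0, p))
  d1 <- outer(0:n1, pis, function(x, p) stats::dbinom(x, n1, p))
  probs <- vapply(seq_along(pis), function(j) {
    sum(d0[grid_x0 + 1, j] * d1[grid_x1 + 1, j] * extreme)
  }, numeric(1))
  list(p_value = max(probs), fisher_p = fp_obs,
       alternative = alternative, grid_size = grid_size)
}
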