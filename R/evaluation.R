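#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive scores above a randomly chosen negative, with ties counting one
#' half.
#'
#' @param labels binary vector (0/1); both classes must be present.
#' @param scores numeric scores, higher = more positive.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_cevvo("AUROC undefined: only one class present",
               class = "cevvo_metric_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision
#'
#' Step-wise area under the precision-recall curve:
#' `sum_k (R_k - R_{k-1}) P_k` over score thresholds taken at the distinct
#' predicted values in decreasing order (tied scores enter as one threshold).
#'
#' @param labels binary vector (0/1); at least one positive required.
#' @param scores numeric scores.
#' @return Average precision in (0, 1\].
#' @export
average_precision <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  if (n_pos == 0)
    stop_cevvo("AP undefined: no positive labels",
               class = "cevvo_metric_error")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  # evaluate only at the last index of each tied-score block
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

metric_fun <- function(metric) {
  if (is.function(metric)) return(metric)
  switch(match.arg(metric, c("auroc", "ap")),
         auroc = auroc, ap = average_precision)
}

#' Bootstrap confidence interval for a ranking metric
#'
#' Resamples (label, score) pairs jointly with replacement `B` times,
#' recomputes the metric on each resample, and reports the empirical
#' `alpha/2` and `1 - alpha/2` percentiles. Resamples containing a single
#' class (where the metric is undefined) are skipped and counted. Pairs are
#' put into a canonical order before resampling, so with a fixed seed the
#' interval is invariant to the ordering of the inputs.
#'
#' @param labels,scores paired observations.
#' @param metric `"auroc"`, `"ap"`, or a `function(labels, scores)`.
#' @param B number of bootstrap resamples (default 5000).
#' @param alpha two-sided miscoverage level (default 0.05 for a 95% CI).
#' @param seed optional RNG seed.
#' @return An object of class `metric_ci`: point estimate, `lower`, `upper`,
#'   `B`, `alpha`, and `n_skipped` degenerate resamples.
#' @export
bootstrap_ci <- function(labels, scores, metric = "auroc", B = 5000,
                         alpha = 0.05, seed = NULL) {
  f <- metric_fun(metric)
  n <- length(labels)
  stopifnot(n == length(scores), B >= 1)
  point <- f(labels, scores)
  # canonical pair order, so resamples are invariant to input ordering
  ord <- order(scores, labels)
  labels <- labels[ord]
  scores <- scores[ord]
  vals <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    apply(idx, 1, function(i) {
      lab <- labels[i]
      if (length(unique(lab)) < 2) return(NA_real_)
      f(lab, scores[i])
    })
  })
  skipped <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop_cevvo("all bootstrap resamples were degenerate",
               class = "cevvo_numeric_error")
  q <- stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  structure(list(point = point, lower = q[1], upper = q[2], B = B,
                 alpha = alpha, n_skipped = skipped),
            class = "metric_ci")
}

#' @export
print.metric_ci <- function(x, ...) {
  cat(sprintf("%.4f (%.0f%% CI %.4f-%.4f, B=%d%s)\n", x$point,
              100 * (1 - x$alpha), x$lower, x$upper, x$B,
              if (x$n_skipped) sprintf(", %d degenerate resamples skipped",
                                       x$n_skipped) else ""))
  invisible(x)
}

#' Per-day metric table
#'
#' Buckets predictions by the day their (possibly truncated) run ends — a
#' sample ending at `end_day` in `(d - 1, d]` is reported on day `d` — and
#' computes the metric with a bootstrap CI in every bucket. Buckets that are
#' empty or single-class are reported with `NA` metrics.
#'
#' @param labels,scores,end_days aligned vectors; `end_days` in days from
#'   cannulation.
#' @param max_day last day bucket (default 24).
#' @param min_day first day bucket (default 1); use `min_day`/`max_day` to
#'   restrict to a window such as days 3-11.
#' @param metric,B,alpha,seed as in [bootstrap_ci()].
#' @return A data.frame with one row per day: `day`, `n`, `estimate`,
#'   `lower`, `upper`.
#' @export
per_day_metrics <- function(labels, scores, end_days, max_day = 24,
                            min_day = 1, metric = "auroc", B = 1000,
                            alpha = 0.05, seed = NULL) {
  days <- seq.int(min_day, max_day)
  rows <- lapply(days, function(d) {
    in_bucket <- end_days > d - 1 & end_days <= d
    n <- sum(in_bucket)
    if (n == 0 || length(unique(labels[in_bucket])) < 2)
      return(data.frame(day = d, n = n, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    ci <- bootstrap_ci(labels[in_bucket], scores[in_bucket], metric = metric,
                       B = B, alpha = alpha, seed = child_seed(seed, d))
    data.frame(day = d, n = n, estimate = ci$point, lower = ci$lower,
               upper = ci$upper)
  })
  do.call(rbind, rows)
}

#' Paired permutation test between two score vectors
#'
#' Tests whether classifier A and classifier B differ in a ranking metric on
#' the same evaluation samples. The statistic is `metric(A) - metric(B)`;
#' the null distribution is built by independently swapping the pair
#' `(a_i, b_i)` with probability 1/2 for each sample. The two-sided p-value
#' uses the add-one correction `(1 + #{|stat*| >= |stat|}) / (n_perm + 1)`.
#' With `exhaustive = TRUE` (n <= 20) all `2^n` swap patterns are enumerated
#' and the p-value is exact.
#'
#' @param scores_a,scores_b aligned score vectors for the two classifiers.
#' @param labels shared binary labels.
#' @param metric `"auroc"`, `"ap"`, or a function.
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param exhaustive enumerate all swap patterns instead of sampling.
#' @param seed optional RNG seed.
#' @return A list: `statistic`, `p_value`, `n_perm`, `exhaustive`.
#' @export
paired_permutation_test <- function(scores_a, scores_b, labels,
                                    metric = "auroc", n_perm = 10000,
                                    exhaustive = FALSE, seed = NULL) {
  n <- length(labels)
  if (length(scores_a) != n || length(scores_b) != n)
    stop_cevvo("scores_a, scores_b and labels must have equal length",
               class = "cevvo_validation_error")
  f <- metric_fun(metric)
  observed <- f(labels, scores_a) - f(labels, scores_b)
  stat_for <- function(swap) {
    a <- ifelse(swap, scores_b, scores_a)
    b <- ifelse(swap, scores_a, scores_b)
    f(labels, a) - f(labels, b)
  }
  if (exhaustive) {
    if (n > 20)
      stop_cevvo("exhaustive enumeration limited to n <= 20",
                 class = "cevvo_parameter_error")
    pats <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    stats <- apply(pats, 1, stat_for)
    p <- mean(abs(stats) >= abs(observed) - 1e-12)
    return(list(statistic = observed, p_value = p, n_perm = nrow(pats),
                exhaustive = TRUE))
  }
  stats <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) stat_for(stats::runif(n) < 0.5), numeric(1))
  })
  p <- (1 + sum(abs(stats) >= abs(observed) - 1e-12)) / (n_perm + 1)
  list(statistic = observed, p_value = p, n_perm = n_perm,
       exhaustive = FALSE)
}

#' Build repeated patient-level cross-validation folds
#'
#' For each iteration: shuffle the patient ids; form `n_groups` disjoint
#' groups each holding exactly `succ_per_group` successful and
#' `fail_per_group` unsuccessful patients; randomly exclude the surplus
#' patients; then rotate the test group through all `n_groups` positions,
#' with the next group as validation and the rest as training. With a
#' 118-patient cohort (90/28) and the defaults this yields 5 groups of 23
#' patients (18 successful + 5 unsuccessful) and 3 exclusions per iteration.
#'
#' @param ids patient identifiers.
#' @param labels binary outcomes aligned with `ids`.
#' @param n_iter number of independent shuffles (default 12).
#' @param n_groups number of groups (default 5).
#' @param succ_per_group,fail_per_group per-group class quotas; default
#'   `floor(class count / n_groups)`.
#' @param seed optional RNG seed.
#' @return A list of fold plans. Each plan has `iteration`, `groups` (list of
#'   id vectors), `excluded`, and `splits`: one split per rotation with
#'   `train`, `validation`, `test` id vectors.
#' @export
make_real_folds <- function(ids, labels, n_iter = 12, n_groups = 5,
                            succ_per_group = NULL, fail_per_group = NULL,
                            seed = NULL) {
  ids <- as.character(ids)
  stopifnot(length(ids) == length(labels))
  succ <- ids[labels == 1]
  fail <- ids[labels == 0]
  succ_per_group <- succ_per_group %||% floor(length(succ) / n_groups)
  fail_per_group <- fail_per_group %||% floor(length(fail) / n_groups)
  if (succ_per_group < 1 || fail_per_group < 1 ||
      length(succ) < n_groups * succ_per_group ||
      length(fail) < n_groups * fail_per_group)
    stop_cevvo("not enough patients of each class for the per-group quota",
               class = "cevvo_configuration_error")
  with_seed(seed, {
    lapply(seq_len(n_iter), function(it) {
      s <- sample(succ)
      f <- sample(fail)
      groups <- lapply(seq_len(n_groups), function(g) {
        c(s[seq.int((g - 1) * succ_per_group + 1, g * succ_per_group)],
          f[seq.int((g - 1) * fail_per_group + 1, g * fail_per_group)])
      })
      used <- unlist(groups)
      splits <- lapply(seq_len(n_groups), function(g) {
        val <- g %% n_groups + 1
        list(test = groups[[g]], validation = groups[[val]],
             train = unlist(groups[-c(g, val)], use.names = FALSE))
      })
      list(iteration = it, groups = groups,
           excluded = setdiff(ids, used), splits = splits)
    })
  })
}
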