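test_that("AUROC matches the brute-force pairwise oracle, ties included", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(auroc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0.0)
  expect_equal(auroc(c(0, 1), c(0.5, 0.5)), 0.5)
  set.seed(19)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(auroc(labels, scores), auroc_oracle(labels, scores))
  }
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), class = "cevvo_metric_error")
})

test_that("average precision matches a step-wise reference computation", {
  expect_equal(average_precision(c(0, 1, 1), c(0.1, 0.8, 0.9)), 1.0)
  # reference: walk thresholds at distinct scores, accumulate (dR * P)
  ap_oracle <- function(labels, scores) {
    ths <- sort(unique(scores), decreasing = TRUE)
    prev_r <- 0; ap <- 0
    for (th in ths) {
      sel <- scores >= th
      p <- sum(labels[sel]) / sum(sel)
      r <- sum(labels[sel]) / sum(labels)
      ap <- ap + (r - prev_r) * p
      prev_r <- r
    }
    ap
  }
  set.seed(23)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    labels <- c(1, rbinom(n - 1, 1, 0.4))
    scores <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    expect_equal(average_precision(labels, scores),
                 ap_oracle(labels, scores))
  }
  expect_error(average_precision(c(0, 0), c(0.2, 0.3)),
               class = "cevvo_metric_error")
})

test_that("bootstrap CIs are valid, reproducible and order-invariant", {
  lab <- rep(c(1, 0), each = 10)
  sep <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))
  ci <- bootstrap_ci(lab, sep, "auroc", B = 200, seed = 1)
  expect_equal(ci$lower, 1.0)
  expect_equal(ci$upper, 1.0)

  set.seed(4)
  scores <- runif(30); labels <- rbinom(30, 1, 0.5 + scores / 3)
  a <- bootstrap_ci(labels, scores, "auroc", B = 300, seed = 9)
  b <- bootstrap_ci(labels, scores, "auroc", B = 300, seed = 9)
  expect_identical(a, b)
  expect_true(a$lower <= a$point && a$point <= a$upper)
  expect_true(a$lower >= 0 && a$upper <= 1)
  perm <- sample(30)
  c2 <- bootstrap_ci(labels[perm], scores[perm], "auroc", B = 300, seed = 9)
  expect_equal(a$lower, c2$lower)
  expect_equal(a$upper, c2$upper)
})

test_that("per-day buckets follow the (d-1, d] rule and pool consistently", {
  set.seed(12)
  n <- 300
  labels <- rbinom(n, 1, 0.6)
  scores <- runif(n) + 0.3 * labels
  end_days <- runif(n, 0, 6)
  tab <- per_day_metrics(labels, scores, end_days, max_day = 8, B = 100,
                         seed = 1)
  expect_equal(nrow(tab), 8)
  # a sample ending at day 0.5 is reported on day 1
  expect_equal(tab$n[1], sum(end_days > 0 & end_days <= 1))
  expect_equal(tab$n[8], 0)
  expect_true(is.na(tab$estimate[8]))
  expect_equal(sum(tab$n), n)
  # pooling all buckets reproduces the overall metric
  expect_equal(auroc(labels, scores),
               auroc(labels[end_days <= 8], scores[end_days <= 8]))
})

test_that("paired permutation test agrees with exhaustive enumeration", {
  set.seed(31)
  labels <- c(1, 1, 1, 0, 0, 1, 0)
  a <- runif(7); b <- runif(7)
  ex <- paired_permutation_test(a, b, labels, exhaustive = TRUE)
  # independent oracle: loop over all 2^7 masks via bit arithmetic
  f <- function(lab, s) auroc(lab, s)
  obs <- f(labels, a) - f(labels, b)
  count <- 0
  for (mask in 0:(2^7 - 1)) {
    swap <- bitwAnd(bitwShiftR(mask, 0:6), 1L) == 1L
    aa <- ifelse(swap, b, a); bb <- ifelse(swap, a, b)
    if (abs(f(labels, aa) - f(labels, bb)) >= abs(obs) - 1e-12)
      count <- count + 1
  }
  expect_equal(ex$p_value, count / 2^7)
  mc <- paired_permutation_test(a, b, labels, n_perm = 4000, seed = 2)
  expect_lt(abs(mc$p_value - ex$p_value), 0.05)

  # identical scores give p = 1
  same <- paired_permutation_test(a, a, labels, n_perm = 50, seed = 1)
  expect_equal(same$p_value, 1.0)
  expect_error(paired_permutation_test(a, b[1:5], labels),
               class = "cevvo_validation_error")
})

test_that("a strong score difference is detected with high power", {
  set.seed(55)
  labels <- rbinom(200, 1, 0.5)
  good <- 0.8 * labels + 0.2 * runif(200)
  noise <- runif(200)
  res <- paired_permutation_test(good, noise, labels, n_perm = 500,
                                 seed = 3)
  expect_lt(res$p_value, 0.01)
})

test_that("fold construction enforces quotas, exclusions and no leakage", {
  ids <- sprintf("p%03d", 1:118)
  labels <- rep(c(1, 0), c(90, 28))
  plans <- make_real_folds(ids, labels, n_iter = 3, seed = 10)
  for (plan in plans) {
    expect_length(plan$groups, 5)
    expect_true(all(lengths(plan$groups) == 23))
    expect_length(plan$excluded, 3)
    for (g in plan$groups)
      expect_equal(sum(labels[match(g, ids)] == 1), 18)
    for (split in plan$splits) {
      expect_length(intersect(split$train, split$test), 0)
      expect_length(intersect(split$train, split$validation), 0)
      expect_length(intersect(split$validation, split$test), 0)
      expect_length(unique(c(split$train, split$validation, split$test)),
                    115)
    }
    tested <- sort(unlist(lapply(plan$splits, `[[`, "test")))
    expect_equal(tested, sort(unlist(plan$groups)))
  }
  # reshuffled every iteration
  expect_false(identical(plans[[1]]$groups, plans[[2]]$groups))
  expect_error(make_real_folds(ids[1:20], labels[1:20], succ_per_group = 18,
                               fail_per_group = 5),
               class = "cevvo_configuration_error")
})
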