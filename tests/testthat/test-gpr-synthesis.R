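test_that("RBF kernel matches its closed form and a loop oracle", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, 5), 1)
  # squared distance of 2L gives exp(-1)
  xj <- c(1 + sqrt(2 * 5), 2, 3)
  expect_equal(rbf_kernel(x, xj, 5), exp(-1))
  set.seed(3)
  for (i in 1:50) {
    a <- rnorm(4); b <- rnorm(4)
    d2 <- 0
    for (j in 1:4) d2 <- d2 + (a[j] - b[j])^2
    expect_equal(rbf_kernel(a, b, 1), exp(-d2 / 2))
    expect_equal(rbf_kernel(a, b, 1), rbf_kernel(b, a, 1))
    expect_equal(rbf_kernel(a, b, 3, convention = "squared"),
                 exp(-d2 / 18))
  }
  expect_error(rbf_kernel(a, b, 0), class = "cevvo_parameter_error")
})

test_that("kernel Gram matrices are PSD after jitter at L in {1, 100}", {
  set.seed(8)
  for (L in c(1, 100)) {
    x <- cbind(matrix(rnorm(60), 20, 3), step = 0:19)
    k <- cevvo:::rbf_kernel_matrix(x, x, L)
    expect_equal(k, t(k))
    expect_silent(chol(k + diag(1e-6, 20)))
  }
})

test_that("triplet formation sorts, groups by outcome, drops remainders", {
  recs <- tiny_cohort(9, 7, seed = 5)
  trips <- suppressMessages(form_triplets(recs))
  expect_length(trips, 5)  # 3 successful + 2 unsuccessful, 1 dropped
  for (tr in trips) {
    expect_length(tr$member_ids, 3)
    ocs <- vapply(tr$members, `[[`, numeric(1), "outcome")
    expect_true(all(ocs == tr$outcome))
    # consecutive in run length within the sorted outcome group
    rh <- vapply(tr$members, run_hours, numeric(1))
    expect_true(all(diff(rh) >= 0))
  }
  expect_message(form_triplets(recs), "dropping 1 patient")
  expect_warning(form_triplets(tiny_cohort(2, 0, seed = 1)),
                 "no triplets formed")
})

test_that("triplet GPRs interpolate their training data", {
  recs <- tiny_cohort(3, 0, seed = 21)
  trip <- form_triplets(recs)[[1]]
  gpr <- fit_triplet_gprs(trip, length_scale = 1, n_steps = 16)
  expect_equal(ncol(gpr$alpha), 8)  # one posterior per perfusion variable
  # posterior mean at the training covariates reproduces the targets
  for (m in 1:3) {
    post <- cevvo:::gpr_posterior_at_member(gpr, m)
    member <- gpr$members[[m]]
    target <- standardize_length(
      member$series[, perfusion_channels], 16)
    target_std <- sweep(sweep(target, 2, gpr$mu_y), 2, gpr$sd_y, "/")
    expect_lt(max(abs(post$mean_std - target_std)), 0.05)
  }
})

test_that("large length scales produce smoother posterior draws", {
  recs <- tiny_cohort(3, 0, seed = 31)
  trip <- form_triplets(recs)[[1]]
  roughness <- function(L) {
    gpr <- fit_triplet_gprs(trip, length_scale = L, n_steps = 32)
    draws <- sample_synthetic_cohort(list(gpr), draws_success = 20,
                                     draws_fail = 1, seed = 77)
    mean(vapply(draws, function(d)
      mean(abs(diff(d$series[, "flow"]))), numeric(1)))
  }
  expect_lt(suppressWarnings(roughness(100)), roughness(1))
})

test_that("synthetic sampling preserves counts, labels, reproducibility", {
  recs <- tiny_cohort(9, 6, seed = 12)
  gprs <- fit_gpr_synthesis(recs, length_scale = 1, n_steps = 12)
  expect_length(gprs, 5)
  synth <- sample_synthetic_cohort(gprs, draws_success = 3, draws_fail = 18,
                                   seed = 4)
  expect_length(synth, 3 * 3 + 2 * 18)
  # every synthetic label equals its source triplet's label
  by_id <- setNames(vapply(gprs, `[[`, numeric(1), "outcome"),
                    vapply(gprs, `[[`, character(1), "triplet_id"))
  for (s in synth)
    expect_equal(s$outcome, unname(by_id[s$triplet_id]))
  one_each <- sample_synthetic_cohort(gprs, 1, 1, seed = 4)
  expect_length(one_each, 5)
  again <- sample_synthetic_cohort(gprs, 3, 18, seed = 4)
  expect_identical(synth[[1]]$series, again[[1]]$series)
  expect_error(sample_synthetic_cohort(gprs, 0, 1),
               class = "cevvo_parameter_error")
})

test_that("synthetic fold plan has fixed composition and rotates the test group", {
  trips <- c(
    lapply(1:30, function(i) list(triplet_id = sprintf("TS%02d", i),
                                  outcome = 1)),
    lapply(1:8, function(i) list(triplet_id = sprintf("TF%02d", i),
                                 outcome = 0)))
  plan <- split_synthetic_folds(trips, seed = 3)
  expect_length(plan$groups, 5)
  expect_true(all(lengths(plan$groups) == 7))
  expect_length(plan$excluded, 3)
  expect_length(unique(unlist(plan$groups)), 35)
  # each group expands to 6*3 + 1*18 = 36 synthetic patients
  for (g in plan$groups) {
    n_succ <- sum(grepl("^TS", g))
    expect_equal(n_succ, 6)
    expect_equal(n_succ * 3 + (7 - n_succ) * 18, 36)
  }
  tested <- sort(unlist(lapply(plan$splits, `[[`, "test")))
  expect_equal(tested, sort(unlist(plan$groups)))
  expect_identical(plan, split_synthetic_folds(trips, seed = 3))
  expect_error(split_synthetic_folds(trips[1:20], seed = 1),
               class = "cevvo_configuration_error")
})
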