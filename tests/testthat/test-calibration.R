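test_that("Platt scaling recovers identity on already-calibrated scores", {
  set.seed(14)
  raw <- runif(5000, 0.02, 0.98)
  labels <- rbinom(5000, 1, raw)
  params <- fit_platt(raw, labels)
  expect_equal(params$A, 1, tolerance = 0.1)
  expect_equal(params$B, 0, tolerance = 0.1)
  expect_equal(apply_platt(list(A = 1, B = 0) |>
                             structure(class = "platt_params"), 0.5), 0.5)
  expect_error(fit_platt(runif(10), rep(1, 10)), class = "cevvo_fit_error")
})

test_that("calibration preserves ranking and hence AUROC exactly", {
  set.seed(15)
  raw <- runif(200)
  labels <- rbinom(200, 1, pmin(pmax(raw, 0.05), 0.95))
  params <- fit_platt(raw, labels)
  cal <- apply_platt(params, raw)
  expect_true(all(cal > 0 & cal < 1))
  expect_equal(order(cal), order(raw))
  expect_equal(auroc(labels, cal), auroc(labels, raw))
})

test_that("reliability curve bins are half-open with a closed last bin", {
  tab <- calibration_curve(c(0.7, 0.7, 0.7), c(1, 1, 1), n_bins = 10)
  expect_equal(tab$n[8], 3)            # 0.7 falls in [0.7, 0.8)
  expect_equal(tab$observed[8], 1.0)
  expect_equal(sum(tab$n), 3)
  edge <- calibration_curve(c(0.1, 1.0), c(0, 1), n_bins = 10)
  expect_equal(edge$n[10], 1)          # 1.0 belongs to the final bin
  expect_equal(edge$n[2], 1)           # 0.1 opens bin [0.1, 0.2)
  set.seed(16)
  p <- runif(10000)
  lab <- rbinom(10000, 1, p)
  tab <- calibration_curve(p, lab)
  gap <- abs(tab$mean_score - tab$observed)
  expect_lt(max(gap, na.rm = TRUE), 0.05)
})

test_that("risk groups partition the line with the stated boundaries", {
  m <- 0.6; s <- 0.1
  expect_equal(assign_risk_group(m - 2 * s, m, s), 0L)
  expect_equal(assign_risk_group(m - s, m, s), 0L)       # boundary: <=
  expect_equal(assign_risk_group(m, m, s), 1L)           # x = M -> group 1
  expect_equal(assign_risk_group(m + s, m, s), 2L)       # x = M + S -> 2
  expect_equal(assign_risk_group(m + s + 1e-9, m, s), 3L)
  x <- seq(0, 1, by = 0.001)
  g <- assign_risk_group(x, m, s)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g %in% 0:3))
})

test_that("hour snapshots pick the nearest prediction before the cutoff", {
  preds <- data.frame(
    patient_id = rep(c("a", "b"), c(3, 2)),
    end_hours = c(24, 60, 80, 20, 40),
    run_hours = c(80, 80, 80, 50, 50),
    score = c(0.2, 0.5, 0.9, 0.4, 0.6),
    label = c(1, 1, 1, 0, 0))
  snap <- snapshot_at_hours(preds, 72)
  expect_equal(nrow(snap), 1)          # b ran only 50 h: excluded
  expect_equal(snap$score, 0.5)        # 60 h is nearest before 72
  snap48 <- snapshot_at_hours(preds, 48, m = 0.5, s = 0.1)
  expect_equal(snap48$group[snap48$patient_id == "a"], 0L)  # score 0.2
  expect_equal(snap48$group[snap48$patient_id == "b"], 2L)  # score 0.6
  late <- data.frame(patient_id = "c", end_hours = 90, run_hours = 100,
                     score = 0.5, label = 1)
  expect_warning(snapshot_at_hours(late, 72), "no prediction")
})

test_that("risk-group success rates increase on a calibrated cohort", {
  set.seed(17)
  p <- rbeta(600, 4, 1.5)
  labels <- rbinom(600, 1, p)
  m <- mean(p); s <- sd(p)
  g <- assign_risk_group(p, m, s)
  rate <- tapply(labels, g, mean)
  expect_true(all(diff(rate) > 0))
})

test_that("Boschloo's test is exact, one-sided and bounded by Fisher", {
  # no difference in proportions: no evidence either way
  same <- boschloo_exact(rbind(c(5, 5), c(5, 5)))
  expect_gt(same$p_value, 0.45)
  # independent enumeration oracle on random small tables
  boschloo_oracle <- function(x0, n0, x1, n1, grid = 199) {
    fp <- function(a, b)
      phyper(b - 1, a + b, n0 + n1 - a - b, n1, lower.tail = FALSE)
    obs <- fp(x0, x1)
    best <- 0
    for (pi in seq_len(grid) / (grid + 1)) {
      tot <- 0
      for (a in 0:n0) for (b in 0:n1)
        if (fp(a, b) <= obs * (1 + 1e-7) + 1e-12)
          tot <- tot + dbinom(a, n0, pi) * dbinom(b, n1, pi)
      best <- max(best, tot)
    }
    best
  }
  set.seed(18)
  for (i in 1:25) {
    n0 <- sample(3:9, 1); n1 <- sample(3:9, 1)
    x0 <- sample(0:n0, 1); x1 <- sample(0:n1, 1)
    tab <- rbind(c(x0, n0 - x0), c(x1, n1 - x1))
    res <- boschloo_exact(tab, grid_size = 199)
    expect_equal(res$p_value, boschloo_oracle(x0, n0, x1, n1),
                 tolerance = 1e-10)
    expect_lte(res$p_value, res$fisher_p + 1e-12)
  }
  expect_error(boschloo_exact(rbind(c(-1, 2), c(1, 1))),
               class = "cevvo_validation_error")
})

test_that("the printed snapshot tables give two-decimal p-values .04 and .01", {
  p72 <- boschloo_exact(rbind(c(7, 5), c(11, 1)))$p_value
  p96 <- boschloo_exact(rbind(c(6, 5), c(9, 0)))$p_value
  expect_equal(round(p72, 2), 0.04)
  expect_equal(round(p96, 2), 0.01)
  # 'less' mirrors 'greater' with swapped arms
  expect_equal(boschloo_exact(rbind(c(11, 1), c(7, 5)), "less")$p_value, p72)
})
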