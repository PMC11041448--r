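test_that("ratio channels follow their definitions, including flow = 0", {
  r <- toy_record(flow = 5, sweep = 4, bmi = 25)
  r2 <- derive_ratio_features(r)
  expect_equal(unname(r2$series[1, "flow_per_bmi"]), 0.2)
  expect_equal(unname(r2$series[1, "sweep_per_flow"]), 0.8)
  expect_equal(ncol(r2$series), 8)
  expect_equal(r2$series[, 1:6], r$series, ignore_attr = TRUE)

  r0 <- toy_record(flow = 5, sweep = 2)
  r0$series[3, "flow"] <- 0
  r0d <- derive_ratio_features(r0)
  expect_equal(unname(r0d$series[3, "sweep_per_flow"]), 0)
  expect_equal(unname(r0d$series[1, "sweep_per_flow"]), 2 / 5)
})

test_that("truncation yields one sample per (patient, fraction)", {
  recs <- lapply(1:4, function(i) toy_record(paste0("p", i), i %% 2, k = 100))
  samples <- truncate_runs(recs)
  expect_length(samples, 40)
  full <- samples[[10]]  # fraction 1.0 of patient 1
  expect_equal(full$series, recs[[1]]$series, ignore_attr = TRUE)
  tenth <- samples[[1]]  # fraction 0.1
  expect_equal(nrow(tenth$series), 10)
  expect_equal(tenth$series, recs[[1]]$series[1:10, ], ignore_attr = TRUE)
  expect_error(truncate_runs(recs, fractions = c(0, 0.5)),
               class = "cevvo_parameter_error")
  expect_error(truncate_runs(recs, fractions = 1.2),
               class = "cevvo_parameter_error")
})

test_that("end_day is non-decreasing in the truncation fraction", {
  recs <- tiny_cohort(3, 2)
  samples <- truncate_runs(recs)
  for (id in unique(vapply(samples, `[[`, character(1), "patient_id"))) {
    sub <- Filter(function(s) s$patient_id == id, samples)
    fr <- vapply(sub, `[[`, numeric(1), "fraction")
    ed <- vapply(sub, `[[`, numeric(1), "end_day")
    expect_true(all(diff(ed[order(fr)]) >= 0))
  }
})

test_that("length standardisation matches the loop-based binning oracle", {
  # identity when K = T
  m <- matrix(rnorm(40), 20, 2)
  expect_equal(standardize_length(m, 20), m, ignore_attr = TRUE)
  # dense input: adjacent pairs averaged when K = 2T
  v <- matrix(1:20, 20, 1)
  got <- standardize_length(v, 10)
  expect_equal(as.vector(got), seq(1.5, 19.5, by = 2))
  # empty input is all zeros by contract
  expect_equal(standardize_length(matrix(0, 0, 3), 5), matrix(0, 5, 3),
               ignore_attr = TRUE)
  # random K and V against the oracle
  set.seed(11)
  for (i in 1:200) {
    k <- sample(1:60, 1); t_len <- sample(1:40, 1); v <- sample(1:3, 1)
    m <- matrix(rnorm(k * v), k, v)
    expect_equal(standardize_length(m, t_len), standardize_oracle(m, t_len),
                 ignore_attr = TRUE)
  }
})

test_that("sparse inputs are forward-filled and lead-padded with zeros", {
  m <- matrix(c(10, 20), 2, 1)
  got <- standardize_length(m, 6)
  # points land in slots 1 and 4 (1-based); slots 2-3 carry 10, 5-6 carry 20
  expect_equal(as.vector(got), c(10, 10, 10, 20, 20, 20))
})

test_that("static encoding is 32-wide, deterministic, and label-blind", {
  r <- toy_record()
  v <- encode_static(r)
  expect_length(v, 32)
  expect_identical(v, encode_static(toy_record()))
  r_flip <- toy_record(outcome = 0)
  expect_identical(encode_static(r_flip), v)
  r_bad <- r; r_bad$cause <- "not_a_cause"
  expect_error(encode_static(r_bad), class = "cevvo_validation_error")
  # exactly one indicator set per categorical block
  schema <- static_schema()
  expect_equal(sum(v[grepl("^cause\\.", names(v))]), 1)
  expect_equal(schema$width, 32)
})

test_that("encoding composed with reading is row-order invariant", {
  recs <- lapply(1:5, function(i) toy_record(paste0("p", i), i %% 2,
                                             k = 10 + i))
  sp <- tempfile(fileext = ".csv"); pp <- tempfile(fileext = ".csv")
  write_cohort(recs, sp, pp)
  static <- read.csv(sp)
  sp2 <- tempfile(fileext = ".csv")
  write.csv(static[5:1, ], sp2, row.names = FALSE)
  a <- read_cohort(sp, pp)
  b <- read_cohort(sp2, pp)
  enc_a <- lapply(a, encode_static)
  names(enc_a) <- vapply(a, `[[`, character(1), "patient_id")
  enc_b <- lapply(b, encode_static)
  names(enc_b) <- vapply(b, `[[`, character(1), "patient_id")
  expect_identical(enc_a[order(names(enc_a))], enc_b[order(names(enc_b))])
})

test_that("min-max scaling honours its contract", {
  recs <- tiny_cohort(4, 3)
  samples <- prepare_samples(recs, n_steps = 16)
  train <- samples[1:40]
  sc <- fit_scaler(train)
  scaled <- apply_scaler(sc, train)
  lo <- sapply(scaled, function(s) min(s$series))
  hi <- sapply(scaled, function(s) max(s$series))
  expect_gte(min(lo), 0)
  expect_lte(max(hi), 1)
  # round trip: unscaling recovers the original values
  orig <- train[[3]]$series
  rng <- sc$series_max - sc$series_min
  back <- sweep(sweep(scaled[[3]]$series, 2, rng, "*"), 2, sc$series_min, "+")
  nonconst <- rng > 0
  expect_equal(back[, nonconst], orig[, nonconst], tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant training features map to 0, even off the training range
  test_s <- samples[41:70]
  scaled_test <- apply_scaler(sc, test_s)
  if (any(!nonconst))
    expect_true(all(sapply(scaled_test, function(s)
      all(s$series[, !nonconst] == 0))))
  # values beyond the training max may exceed 1: no clipping
  bumped <- train[3]
  bumped[[1]]$series[1, 1] <- sc$series_max[1] + 2 * max(1, rng[1])
  expect_gt(apply_scaler(sc, bumped)[[1]]$series[1, 1], 1)
  expect_error(apply_scaler(list(), train), class = "cevvo_state_error")
})
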