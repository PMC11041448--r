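split_sample_sets <- function(samples, split) {
  by_id <- vapply(samples, function(s) s$patient_id, character(1))
  list(train = samples[by_id %in% split$train],
       validation = samples[by_id %in% split$validation],
       test = samples[by_id %in% split$test])
}

#' Train and evaluate models on one train/validation/test split
#'
#' Fits the min-max scaler on the training samples, transforms all three
#' sets, trains each requested model, and returns the pooled test-set
#' predictions. The fusion network uses the validation set for early
#' stopping; the reference classifiers train on the training set alone.
#'
#' @param train_samples,val_samples,test_samples unscaled sample lists
#'   (patient-disjoint).
#' @param models character vector from `"cevvo"` plus the kinds of
#'   [fit_baseline()].
#' @param config [model_config()] for the fusion network.
#' @param seed seed for model fitting.
#' @param n_ensemble number of independently initialised fusion networks
#'   whose scores are averaged (variance reduction at small sample sizes;
#'   reference models are deterministic given the data and are not
#'   ensembled).
#' @return A data.frame with columns `model`, `patient_id`, `fraction`,
#'   `label`, `score`, `end_day`.
#' @export
evaluate_split <- function(train_samples, val_samples, test_samples,
                           models = c("cevvo", "logistic_regression"),
                           config = model_config(profile = "small",
                                                 seed = 1L),
                           seed = config$seed, n_ensemble = 1) {
  scaler <- fit_scaler(train_samples)
  tr <- samples_to_arrays(apply_scaler(scaler, train_samples))
  va <- samples_to_arrays(apply_scaler(scaler, val_samples))
  te <- samples_to_arrays(apply_scaler(scaler, test_samples))
  base <- data.frame(patient_id = te$patient_id, fraction = te$fraction,
                     label = te$y, end_day = te$end_day,
                     stringsAsFactors = FALSE)
  rows <- lapply(models, function(m) {
    scores <- if (m == "cevvo") {
      runs <- vapply(seq_len(n_ensemble), function(e) {
        cfg <- config
        cfg$seed <- child_seed(seed, 7000 + e) %||% e
        net <- build_model(cfg, n_steps = dim(tr$x)[2],
                           n_channels = dim(tr$x)[3],
                           static_dim = ncol(tr$s))
        net <- train_cevvo(net, tr, va)
        predict(net, te)
      }, numeric(length(te$y)))
      rowMeans(runs)
    } else {
      predict(fit_baseline(m, tr, seed = seed), te)
    }
    cbind(data.frame(model = m, stringsAsFactors = FALSE), base,
          score = scores)
  })
  do.call(rbind, rows)
}

#' Cross-validate models over a cohort of raw records
#'
#' Runs the full protocol on raw patient records: preprocessing with
#' truncation augmentation, repeated group cross-validation from
#' [make_real_folds()], per-split training via [evaluate_split()], and
#' pooling of all test-set predictions.
#'
#' @param records list of patient records.
#' @param n_steps standardised series length.
#' @param fractions truncation fractions (use `1` to disable augmentation).
#' @param plans fold plans from [make_real_folds()]; built with defaults if
#'   omitted.
#' @param models,config as in [evaluate_split()].
#' @param n_iter,seed forwarded to [make_real_folds()] when `plans` is
#'   missing; `seed` also drives per-split model seeds.
#' @return Pooled predictions with `iteration` and `rotation` columns.
#' @export
cross_validate_cohort <- function(records, n_steps,
                                  fractions = seq(0.1, 1, by = 0.1),
                                  plans = NULL,
                                  models = c("cevvo", "logistic_regression"),
                                  config = model_config(profile = "small"),
                                  n_iter = 12, seed = 1L) {
  ids <- vapply(records, `[[`, character(1), "patient_id")
  labels <- vapply(records, `[[`, numeric(1), "outcome")
  plans <- plans %||% make_real_folds(ids, labels, n_iter = n_iter,
                                      seed = seed)
  samples <- prepare_samples(records, n_steps, fractions)
  out <- list()
  for (plan in plans) {
    for (g in seq_along(plan$splits)) {
      sets <- split_sample_sets(samples, plan$splits[[g]])
      preds <- evaluate_split(sets$train, sets$validation, sets$test,
                              models = models, config = config,
                              seed = child_seed(seed,
                                                100 * plan$iteration + g))
      preds$iteration <- plan$iteration
      preds$rotation <- g
      out[[length(out) + 1]] <- preds
    }
  }
  do.call(rbind, out)
}

#' Evaluate models on a GP-synthesised cohort at one length scale
#'
#' Samples a synthetic cohort from fitted triplet GPRs, splits it by
#' triplet with [split_synthetic_folds()], and pools test predictions over
#' the rotations. Synthetic series are already on the model grid, so no
#' truncation augmentation is applied.
#'
#' @param gprs fitted `triplet_gpr` list (one length scale).
#' @param fold_plan triplet-level plan from [split_synthetic_folds()]; keep
#'   it fixed across length scales so predictions pair by patient id.
#' @param draws_success,draws_fail posterior draws per triplet.
#' @param models,config as in [evaluate_split()].
#' @param sample_seed seed for the posterior draws.
#' @param seed seed for model fitting.
#' @param rotations which test rotations to run (default all).
#' @return Pooled test predictions (`model`, `patient_id`, `triplet_id`,
#'   `label`, `score`, `rotation`).
#' @export
evaluate_synthetic_cohort <- function(gprs, fold_plan, draws_success = 3,
                                      draws_fail = 18,
                                      models = c("cevvo",
                                                 "logistic_regression"),
                                      config = model_config(profile =
                                                              "small"),
                                      sample_seed = 1L, seed = 1L,
                                      rotations = NULL, n_ensemble = 1) {
  synth <- sample_synthetic_cohort(gprs, draws_success, draws_fail,
                                   seed = sample_seed)
  trip_of <- vapply(synth, function(r) r$triplet_id, character(1))
  n_steps <- gprs[[1]]$n_steps
  samples <- prepare_samples(synth, n_steps, fractions = 1)
  rotations <- rotations %||% seq_along(fold_plan$splits)
  out <- list()
  for (g in rotations) {
    split <- fold_plan$splits[[g]]
    pid_split <- lapply(split, function(trips) {
      vapply(synth[trip_of %in% trips], `[[`, character(1), "patient_id")
    })
    sets <- split_sample_sets(samples, pid_split)
    preds <- evaluate_split(sets$train, sets$validation, sets$test,
                            models = models, config = config,
                            seed = child_seed(seed, g),
                            n_ensemble = n_ensemble)
    preds$rotation <- g
    preds$triplet_id <- trip_of[match(preds$patient_id, vapply(
      synth, function(r) r$patient_id, character(1)))]
    out[[length(out) + 1]] <- preds
  }
  do.call(rbind, out)
}

#' Length-scale mechanism experiment
#'
#' Quantifies how much of the fusion network's edge comes from temporal
#' dependence: fits triplet GPRs to a source cohort at two RBF length
#' scales (rough, L = 1, preserving local temporal structure; smooth,
#' L = 100, destroying it), synthesises a cohort from each, trains the
#' requested models on both, and compares each model's pooled test AUROC
#' across length scales with a paired permutation test (predictions pair by
#' synthetic patient id).
#'
#' @param records source cohort (e.g. from [generate_cohort()]).
#' @param length_scales two RBF length scales, default `c(1, 100)`.
#' @param n_steps GP / model time grid length (default 128).
#' @param models,config as in [evaluate_split()]; the default trains the
#'   fusion network for a fixed 60-epoch budget because on triplet-level
#'   folds the whole validation negative class is a single triplet, making
#'   validation-based early stopping unreliable.
#' @param seed master seed for sampling, folds and model fits.
#' @param rotations test rotations to run (default all 5).
#' @param n_perm permutations for the paired test.
#' @return A list with `predictions` (per length scale) and `summary`: one
#'   row per model with the two AUROCs, their difference
#'   (rough - smooth), and the permutation p-value.
#' @export
length_scale_experiment <- function(records, length_scales = c(1, 100),
                                    n_steps = 128,
                                    models = c("cevvo",
                                               "logistic_regression"),
                                    config = model_config(
                                      profile = "small",
                                      learning_rate = 3e-3,
                                      max_epochs = 60, patience = 60),
                                    seed = 1L, rotations = NULL,
                                    n_perm = 2000, n_ensemble = 1) {
  stopifnot(length(length_scales) == 2)
  gprs <- lapply(length_scales, function(L)
    fit_gpr_synthesis(records, length_scale = L, n_steps = n_steps))
  plan <- split_synthetic_folds(gprs[[1]], seed = child_seed(seed, 1))
  preds <- lapply(gprs, function(g)
    evaluate_synthetic_cohort(g, plan, models = models, config = config,
                              sample_seed = child_seed(seed, 2),
                              seed = child_seed(seed, 3),
                              rotations = rotations,
                              n_ensemble = n_ensemble))
  names(preds) <- paste0("L", length_scales)
  summary <- do.call(rbind, lapply(models, function(m) {
    a <- preds[[1]][preds[[1]]$model == m, ]
    b <- preds[[2]][preds[[2]]$model == m, ]
    b <- b[match(a$patient_id, b$patient_id), ]
    stopifnot(all(a$label == b$label))
    perm <- paired_permutation_test(a$score, b$score, a$label,
                                    metric = "auroc", n_perm = n_perm,
                                    seed = child_seed(seed, 4))
    data.frame(model = m,
               auroc_rough = auroc(a$label, a$score),
               auroc_smooth = auroc(b$label, b$score),
               difference = perm$statistic, p_value = perm$p_value,
               stringsAsFactors = FALSE)
  }))
  list(predictions = preds, summary = summary)
}
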