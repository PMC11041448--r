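#' Radial basis function kernel, as-printed convention
#'
#' Kernel between covariate vectors: `k(xi, xj) = exp(-d^2 / (2 L))` with
#' `d` the Euclidean distance. Note the denominator `2 L`, not the textbook
#' `2 L^2`; the kernel is implemented in this form by design, and
#' `convention = "squared"` switches to the textbook parameterisation.
#'
#' @param xi,xj numeric covariate vectors of equal length.
#' @param length_scale positive length scale `L`.
#' @param convention `"as_printed"` (denominator `2 L`, default) or
#'   `"squared"` (denominator `2 L^2`).
#' @return Kernel value in (0, 1\]; 1 iff `xi == xj`.
#' @export
rbf_kernel <- function(xi, xj, length_scale,
                       convention = c("as_printed", "squared")) {
  convention <- match.arg(convention)
  if (length_scale <= 0)
    stop_cevvo("length_scale must be positive",
               class = "cevvo_parameter_error")
  denom <- if (convention == "as_printed") 2 * length_scale
           else 2 * length_scale^2
  exp(-sum((xi - xj)^2) / denom)
}

# Kernel Gram matrix between the rows of two covariate matrices.
rbf_kernel_matrix <- function(x1, x2, length_scale,
                              convention = "as_printed") {
  denom <- if (convention == "as_printed") 2 * length_scale
           else 2 * length_scale^2
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  exp(-pmax(d2, 0) / denom)
}

#' Group patients into run-length-matched triplets
#'
#' Splits the cohort by outcome, sorts each group by ECMO run duration, and
#' takes consecutive non-overlapping triples, so each triplet holds three
#' patients with the same outcome and similar run lengths. Remainder
#' patients (group size mod 3) are dropped with a message.
#'
#' @param records list of [patient_record()] objects.
#' @return A list of triplets, each a list with `triplet_id`, `outcome`,
#'   `member_ids`, and `members` (the three records).
#' @export
form_triplets <- function(records) {
  out <- list()
  for (oc in c(1, 0)) {
    grp <- Filter(function(r) r$outcome == oc, records)
    if (length(grp) < 3) {
      if (length(grp) > 0)
        warning(sprintf("outcome %d group has %d patient(s): no triplets formed",
                        oc, length(grp)))
      next
    }
    grp <- grp[order(vapply(grp, run_hours, numeric(1)))]
    n_trip <- length(grp) %/% 3
    dropped <- length(grp) %% 3
    if (dropped > 0)
      message(sprintf("outcome %d: dropping %d patient(s) not filling a triplet",
                      oc, dropped))
    for (j in seq_len(n_trip)) {
      members <- grp[(3 * j - 2):(3 * j)]
      out[[length(out) + 1]] <- list(
        triplet_id = sprintf("T%s%02d", if (oc == 1) "S" else "F", j),
        outcome = oc,
        member_ids = vapply(members, `[[`, character(1), "patient_id"),
        members = members
      )
    }
  }
  out
}

# Cohort-level standardisation statistics for the GPR static covariates
# (age, sex coded 0/1 in schema level order, BMI).
gpr_covariate_stats <- function(records) {
  schema <- static_schema()
  m <- cbind(
    age = vapply(records, `[[`, numeric(1), "age"),
    sex = vapply(records, function(r)
      match(r$sex, schema$levels$sex) - 1, numeric(1)),
    bmi = vapply(records, `[[`, numeric(1), "bmi")
  )
  sds <- apply(m, 2, stats::sd)
  list(mean = colMeans(m), sd = ifelse(sds == 0 | is.na(sds), 1, sds))
}

# Standardised (age, sex, bmi) row for one record.
gpr_static_covariates <- function(record, stats) {
  schema <- static_schema()
  raw <- c(age = record$age,
           sex = match(record$sex, schema$levels$sex) - 1,
           bmi = record$bmi)
  (raw - stats$mean) / stats$sd
}

#' Fit the per-variable Gaussian-process regressors of one triplet
#'
#' Stacks the three members' perfusion runs — each standardised to a uniform
#' grid of `n_steps` steps with unnormalised values — and conditions one GP
#' per perfusion variable (8 in total) on the covariates (standardised age,
#' sex, BMI, and the 0-based time-step index) with an RBF kernel of the
#' given length scale. Targets are internally centred and scaled per
#' variable, so the observation-noise jitter is relative to each target's
#' variance, and a single Cholesky factor is shared by all 8 regressors.
#' If the kernel matrix is numerically singular the jitter is escalated (up
#' to 1e-2, with a warning) before failing.
#'
#' @param triplet one triplet from [form_triplets()].
#' @param length_scale RBF length scale `L` (in time-step units).
#' @param n_steps time grid length (2054 at full scale).
#' @param covar_stats standardisation stats from the full training cohort;
#'   defaults to stats computed from the triplet's own members.
#' @param jitter relative observation-noise jitter (default 1e-6).
#' @param convention kernel convention, see [rbf_kernel()].
#' @return An object of class `triplet_gpr` holding the shared Cholesky
#'   factor and the 8 per-variable posteriors.
#' @export
fit_triplet_gprs <- function(triplet, length_scale, n_steps = 2054,
                             covar_stats = NULL, jitter = 1e-6,
                             convention = "as_printed") {
  if (length_scale <= 0)
    stop_cevvo("length_scale must be positive",
               class = "cevvo_parameter_error")
  covar_stats <- covar_stats %||% gpr_covariate_stats(triplet$members)
  members <- lapply(triplet$members, derive_ratio_features)
  grid <- 0:(n_steps - 1)
  xs <- lapply(members, function(r) {
    cbind(matrix(gpr_static_covariates(r, covar_stats), n_steps, 3,
                 byrow = TRUE), step = grid)
  })
  x <- do.call(rbind, xs)
  y <- do.call(rbind, lapply(members, function(r)
    standardize_length(r$series[, perfusion_channels], n_steps)))

  mu_y <- colMeans(y)
  sd_y <- apply(y, 2, stats::sd)
  sd_y[sd_y == 0] <- 1
  y_std <- sweep(sweep(y, 2, mu_y), 2, sd_y, "/")

  k <- rbf_kernel_matrix(x, x, length_scale, convention)
  chol_k <- NULL
  jit <- jitter
  while (is.null(chol_k) && jit <= 1e-2) {
    chol_k <- tryCatch(chol(k + diag(jit, nrow(k))), error = function(e) NULL)
    if (is.null(chol_k)) jit <- jit * 100
  }
  if (is.null(chol_k))
    stop_cevvo("kernel matrix for triplet ", triplet$triplet_id,
               " is singular even with jitter 1e-2 (L = ", length_scale, ")",
               class = "cevvo_numeric_error")
  if (jit > jitter)
    warning(sprintf("triplet %s: jitter escalated to %g for conditioning",
                    triplet$triplet_id, jit))
  alpha <- backsolve(chol_k, forwardsolve(t(chol_k), y_std))

  structure(list(
    triplet_id = triplet$triplet_id, outcome = triplet$outcome,
    member_ids = triplet$member_ids,
    members = members, covar_stats = covar_stats,
    length_scale = length_scale, convention = convention,
    n_steps = n_steps, jitter_used = jit,
    x = x, chol_k = chol_k, alpha = alpha, mu_y = mu_y, sd_y = sd_y
  ), class = "triplet_gpr")
}

#' Fit all triplet GPRs for a cohort
#'
#' Forms triplets with [form_triplets()], computes cohort-level covariate
#' standardisation, and fits every triplet's 8 regressors.
#'
#' @inheritParams fit_triplet_gprs
#' @param records list of patient records.
#' @return A list of `triplet_gpr` objects.
#' @export
fit_gpr_synthesis <- function(records, length_scale, n_steps = 2054,
                              jitter = 1e-6, convention = "as_printed") {
  stats <- gpr_covariate_stats(records)
  triplets <- form_triplets(records)
  lapply(triplets, fit_triplet_gprs, length_scale = length_scale,
         n_steps = n_steps, covar_stats = stats, jitter = jitter,
         convention = convention)
}

# Posterior mean (n_steps x 8, standardised target space) and covariance
# factor at one member's static covariates over the full time grid.
gpr_posterior_at_member <- function(gpr, member_idx) {
  member <- gpr$members[[member_idx]]
  grid <- 0:(gpr$n_steps - 1)
  x_star <- cbind(matrix(gpr_static_covariates(member, gpr$covar_stats),
                         gpr$n_steps, 3, byrow = TRUE), step = grid)
  k_star <- rbf_kernel_matrix(gpr$x, x_star, gpr$length_scale,
                              gpr$convention)
  mean_std <- crossprod(k_star, gpr$alpha)
  v <- forwardsolve(t(gpr$chol_k), k_star)
  k_ss <- rbf_kernel_matrix(x_star, x_star, gpr$length_scale,
                            gpr$convention)
  post_cov <- k_ss - crossprod(v)
  # clamp tiny negative eigenvalues from cancellation
  eig <- eigen((post_cov + t(post_cov)) / 2, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  list(mean_std = mean_std,
       cov_factor = eig$vectors %*% diag(sqrt(lam), length(lam)),
       member = member)
}

#' Sample a synthetic cohort from fitted triplet GPRs
#'
#' Each draw evaluates the triplet's 8 posteriors over the full time grid at
#' one member's static covariates (members used round-robin across draws)
#' and samples the 8 variables independently from their joint posteriors.
#' The synthetic patient inherits the member's static profile and the
#' triplet's outcome. Successful triplets are sampled `draws_success` times
#' and unsuccessful ones `draws_fail` times; with the defaults (3, 18) and
#' 30 + 8 triplets this gives 90 + 144 = 234 synthetic patients.
#'
#' @param gprs list of `triplet_gpr` objects from [fit_gpr_synthesis()].
#' @param draws_success,draws_fail posterior draws per successful /
#'   unsuccessful triplet.
#' @param seed optional RNG seed; a fixed seed reproduces the cohort.
#' @return A list of [patient_record()] objects; each carries its source
#'   `triplet_id` as an extra field.
#' @export
sample_synthetic_cohort <- function(gprs, draws_success = 3,
                                    draws_fail = 18, seed = NULL) {
  if (draws_success < 1 || draws_fail < 1)
    stop_cevvo("draws per triplet must be >= 1",
               class = "cevvo_parameter_error")
  with_seed(seed, {
    out <- list()
    for (gpr in gprs) {
      n_draws <- if (gpr$outcome == 1) draws_success else draws_fail
      post_cache <- vector("list", 3)
      for (j in seq_len(n_draws)) {
        midx <- (j - 1) %% 3 + 1
        if (is.null(post_cache[[midx]]))
          post_cache[[midx]] <- gpr_posterior_at_member(gpr, midx)
        post <- post_cache[[midx]]
        z <- matrix(stats::rnorm(gpr$n_steps * 8), gpr$n_steps, 8)
        y_std <- post$mean_std + post$cov_factor %*% z
        series <- sweep(sweep(y_std, 2, gpr$sd_y, "*"), 2, gpr$mu_y, "+")
        colnames(series) <- perfusion_channels
        member <- post$member
        dur <- max(member$time)
        rec <- patient_record(
          patient_id = sprintf("%s_d%02d", gpr$triplet_id, j),
          outcome = gpr$outcome, age = member$age, sex = member$sex,
          bmi = member$bmi, cause = member$cause,
          arrest_pre_ecmo = member$arrest_pre_ecmo,
          shock_pre_ecmo = member$shock_pre_ecmo,
          reinfusion_site = member$reinfusion_site,
          drainage_site = member$drainage_site,
          reinfusion_size = member$reinfusion_size,
          drainage_size = member$drainage_size,
          ventilation_type = member$ventilation_type,
          time = seq(0, dur, length.out = gpr$n_steps),
          series = series
        )
        rec$triplet_id <- gpr$triplet_id
        out[[length(out) + 1]] <- rec
      }
    }
    out
  })
}

#' Triplet-level fold plan for the synthetic cohort
#'
#' Randomises the triplets and splits them into `n_groups` groups, each with
#' `succ_per_group` successful and `fail_per_group` unsuccessful triplets;
#' surplus triplets of either outcome are randomly excluded so every group
#' has the same composition (with 30 + 8 triplets and the defaults, 3
#' unsuccessful triplets are excluded). The test group rotates through all
#' positions, the next group serving as validation. With draws of (3, 18)
#' each group expands to 6 x 3 + 1 x 18 = 36 synthetic patients.
#'
#' @param triplets list of triplets or `triplet_gpr` objects (fields
#'   `triplet_id`, `outcome`).
#' @param n_groups number of groups (default 5).
#' @param succ_per_group,fail_per_group per-group triplet quotas
#'   (defaults 6 and 1).
#' @param seed optional RNG seed.
#' @return A fold plan: `groups` (lists of triplet ids), `excluded`, and
#'   `splits` with `train` / `validation` / `test` triplet-id vectors.
#' @export
split_synthetic_folds <- function(triplets, n_groups = 5,
                                  succ_per_group = 6, fail_per_group = 1,
                                  seed = NULL) {
  ids <- vapply(triplets, `[[`, character(1), "triplet_id")
  oc <- vapply(triplets, `[[`, numeric(1), "outcome")
  succ <- ids[oc == 1]
  fail <- ids[oc == 0]
  if (length(succ) < n_groups * succ_per_group ||
      length(fail) < n_groups * fail_per_group)
    stop_cevvo("not enough triplets for the requested group composition",
               class = "cevvo_configuration_error")
  with_seed(seed, {
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
    list(groups = groups, excluded = setdiff(ids, used), splits = splits)
  })
}
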