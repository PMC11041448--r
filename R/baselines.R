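# Reference classifiers trained on the flattened concatenation of the
# temporal block (n_steps x 8 values) and the 32 encoded static features,
# under the same train/test protocol as the fusion network.

flatten_samples <- function(samples) {
  ar <- if (is.list(samples) && !is.null(samples$x))
    samples else samples_to_arrays(samples)
  n <- dim(ar$x)[1]
  cbind(matrix(ar$x, n, dim(ar$x)[2] * dim(ar$x)[3]), ar$s)
}

baseline_kinds <- c("logistic_regression", "naive_bayes", "dense_network",
                    "decision_tree")

#' Fit a reference classifier
#'
#' Fits one of four reference models on the flattened
#' (temporal + static) feature vector:
#' \describe{
#'   \item{logistic_regression}{ridge-penalised logistic regression
#'     (`glmnet`, small fixed penalty — the feature count far exceeds the
#'     sample count, so an unpenalised fit is not identifiable).}
#'   \item{naive_bayes}{Gaussian naive Bayes (`e1071`); zero-variance
#'     features are dropped at fit time.}
#'   \item{dense_network}{a dense network (one tanh hidden layer of 32
#'     units, sigmoid output) trained with Adam on the binary cross-entropy,
#'     early-stopped on a held-out fifth of the training samples.}
#'   \item{decision_tree}{CART classification tree (`rpart`).}
#' }
#'
#' @param kind one of `r paste0('"', paste(cevvo:::baseline_kinds, collapse = '", "'), '"')`.
#' @param train_samples scaled training samples (list or prestacked arrays).
#' @param seed RNG seed (initialisation / internal validation split).
#' @return An object of class `cevvo_baseline`.
#' @export
fit_baseline <- function(kind, train_samples, seed = 1L) {
  if (!kind %in% baseline_kinds)
    stop_cevvo("unknown baseline kind '", kind, "'",
               class = "cevvo_parameter_error")
  ar <- if (is.list(train_samples) && !is.null(train_samples$x))
    train_samples else samples_to_arrays(train_samples)
  x <- flatten_samples(ar)
  y <- ar$y
  fit <- with_seed(seed, switch(
    kind,
    logistic_regression = {
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = 1e-2, standardize = FALSE)
    },
    naive_bayes = {
      keep <- which(apply(x, 2, stats::var) > 0)
      list(model = e1071::naiveBayes(x[, keep, drop = FALSE],
                                     factor(y, levels = c(0, 1))),
           keep = keep)
    },
    dense_network = {
      n <- length(y)
      val_idx <- sample.int(n, max(2, floor(n / 5)))
      tr_idx <- setdiff(seq_len(n), val_idx)
      params <- mlp_init_params(ncol(x), 32)
      grad_fn <- function(p, idx) {
        cache <- mlp_forward(p, x[tr_idx[idx], , drop = FALSE])
        g <- mlp_backward(p, cache, x[tr_idx[idx], , drop = FALSE],
                          y[tr_idx[idx]])
        attr(g, "loss") <- bce_loss(y[tr_idx[idx]], cache$score)
        g
      }
      val_loss_fn <- function(p)
        bce_loss(y[val_idx], mlp_forward(p, x[val_idx, , drop = FALSE])$score)
      train_loop(params, length(tr_idx), grad_fn, val_loss_fn,
                 lr = 1e-2, batch_size = 32, max_epochs = 150,
                 patience = 15)$params
    },
    decision_tree = {
      df <- data.frame(y = factor(y, levels = c(0, 1)), x = I(x))
      rpart::rpart(y ~ x, data = df, method = "class")
    }
  ))
  structure(list(kind = kind, fit = fit, n_features = ncol(x)),
            class = "cevvo_baseline")
}

#' Predict with a reference classifier
#'
#' @param object a fitted `cevvo_baseline`.
#' @param samples scaled samples (list or prestacked arrays).
#' @param ... unused.
#' @return Numeric vector of success probabilities.
#' @export
predict.cevvo_baseline <- function(object, samples, ...) {
  x <- flatten_samples(samples)
  switch(object$kind,
    logistic_regression = as.vector(
      stats::predict(object$fit, newx = x, type = "response")),
    naive_bayes = {
      pr <- stats::predict(object$fit$model,
                           x[, object$fit$keep, drop = FALSE], type = "raw")
      clip_prob(pr[, "1"], 1e-12)
    },
    dense_network = mlp_forward(object$fit, x)$score,
    decision_tree = {
      df <- data.frame(x = I(x))
      stats::predict(object$fit, newdata = df, type = "prob")[, "1"]
    })
}
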