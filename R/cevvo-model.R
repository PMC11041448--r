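#' Configuration of the two-headed classifier
#'
#' Architecture and optimisation settings for the fusion network. The
#' defaults are the full-scale architecture: static encoder of dense layers
#' 32 -> 33 -> 25 (trained with an auxiliary 25 -> 32 reconstruction
#' decoder), a pointwise (1x1) convolution expanding the 8 perfusion
#' channels to 1024 feature maps with tanh activation, an LSTM of 1024
#' units whose final hidden state is concatenated with the 25-dim static
#' encoding into a 1049-wide fusion layer feeding a single sigmoid output.
#' `profile = "small"` keeps the identical code paths at desk scale
#' (32 filters / 32 LSTM units), for use with series standardised to ~128
#' steps.
#'
#' @param static_widths widths of the three static encoder layers.
#' @param temporal_filters 1x1-convolution output channels.
#' @param lstm_units LSTM hidden units.
#' @param recon_loss_weight weight of the auxiliary reconstruction
#'   (mean-squared) loss on the static head (default 0.1).
#' @param learning_rate,batch_size,max_epochs,patience Adam optimiser and
#'   early-stopping settings.
#' @param min_epochs warm-up epochs before early stopping may track or
#'   restore weights; guarantees the returned model is trained even when a
#'   small validation split is misleading at initialisation.
#' @param seed seed controlling initialisation and batch shuffling.
#' @param profile `"full"` (1024/1024) or `"small"` (32/32).
#' @return An object of class `cevvo_config`.
#' @export
model_config <- function(static_widths = c(32, 33, 25),
                         temporal_filters = 1024, lstm_units = 1024,
                         recon_loss_weight = 0.1, learning_rate = 1e-3,
                         batch_size = 32, max_epochs = 100, patience = 10,
                         min_epochs = 10, seed = 1L,
                         profile = c("full", "small")) {
  profile <- match.arg(profile)
  if (profile == "small") {
    # desk-scale profile: identical code paths, smaller widths, and a
    # learning rate suited to the resulting small problem sizes
    if (missing(temporal_filters) && missing(lstm_units)) {
      temporal_filters <- 32
      lstm_units <- 32
    }
    if (missing(learning_rate)) learning_rate <- 1e-2
    if (missing(max_epochs)) max_epochs <- 150
    if (missing(patience)) patience <- 15
  }
  if (any(c(static_widths, temporal_filters, lstm_units) < 1))
    stop_cevvo("all widths must be >= 1", class = "cevvo_parameter_error")
  if (recon_loss_weight < 0)
    stop_cevvo("recon_loss_weight must be >= 0",
               class = "cevvo_parameter_error")
  structure(list(
    static_widths = static_widths, temporal_filters = temporal_filters,
    lstm_units = lstm_units, recon_loss_weight = recon_loss_weight,
    learning_rate = learning_rate, batch_size = batch_size,
    max_epochs = max_epochs, patience = patience,
    min_epochs = min_epochs, seed = seed,
    profile = profile
  ), class = "cevvo_config")
}

#' Build the two-headed classifier
#'
#' Allocates and initialises all weights for a given input geometry. The
#' fusion layer width is `static_widths[3] + lstm_units` (1049 with the
#' full-scale defaults); the flattened temporal input that the LSTM head
#' compresses is `n_steps * n_channels` values (16,432 at full scale,
#' 2054 x 8).
#'
#' @param config a [model_config()].
#' @param n_steps standardised series length the model will consume.
#' @param n_channels perfusion channels (default 8).
#' @param static_dim encoded static width (default 32, see
#'   [static_schema()]).
#' @return An object of class `cevvo_model` (untrained).
#' @export
build_model <- function(config = model_config(), n_steps,
                        n_channels = 8, static_dim = 32) {
  if (n_steps < 1 || n_channels < 1 || static_dim < 1)
    stop_cevvo("invalid input geometry", class = "cevvo_construction_error")
  params <- with_seed(config$seed, cevvo_init_params(
    n_channels, static_dim, config$temporal_filters, config$lstm_units,
    config$static_widths))
  structure(list(
    config = config, params = params, n_steps = n_steps,
    n_channels = n_channels, static_dim = static_dim,
    fusion_width = config$static_widths[3] + config$lstm_units,
    flat_temporal_dim = n_steps * n_channels,
    trained = FALSE, history = NULL
  ), class = "cevvo_model")
}

#' @export
print.cevvo_model <- function(x, ...) {
  cat(sprintf(
    "<cevvo_model> %s profile: conv 1x1 %d->%d (tanh) + LSTM %d; static %s; fusion %d; %strained\n",
    x$config$profile, x$n_channels, x$config$temporal_filters,
    x$config$lstm_units, paste(x$config$static_widths, collapse = "->"),
    x$fusion_width, if (x$trained) "" else "un"))
  invisible(x)
}

#' Train the two-headed classifier
#'
#' Minimises the mean binary cross-entropy plus the weighted static
#' reconstruction loss by mini-batch Adam, with early stopping on the
#' validation loss (the best-validation weights are restored). Train and
#' validation samples must be disjoint at the patient level and already
#' scaled with a scaler fitted on the training split.
#'
#' @param model an untrained or trained `cevvo_model`.
#' @param train_samples,val_samples lists of scaled samples
#'   (see [prepare_samples()], [apply_scaler()]), or prestacked arrays from
#'   `cevvo:::samples_to_arrays()`.
#' @return The model with fitted weights, `trained = TRUE`, and a
#'   per-epoch `history` data.frame.
#' @export
train_cevvo <- function(model, train_samples, val_samples) {
  tr <- if (is.list(train_samples) && !is.null(train_samples$x))
    train_samples else samples_to_arrays(train_samples)
  va <- if (is.list(val_samples) && !is.null(val_samples$x))
    val_samples else samples_to_arrays(val_samples)
  if (length(tr$y) == 0 || length(va$y) == 0)
    stop_cevvo("empty training or validation split",
               class = "cevvo_configuration_error")
  cfg <- model$config
  units <- cfg$lstm_units
  rw <- cfg$recon_loss_weight

  grad_fn <- function(params, idx) {
    x <- tr$x[idx, , , drop = FALSE]
    s <- tr$s[idx, , drop = FALSE]
    y <- tr$y[idx]
    cache <- cevvo_forward(params, x, s, units)
    g <- cevvo_backward(params, cache, x, s, y, units, rw)
    attr(g, "loss") <- bce_loss(y, cache$score) +
      rw * mean((cache$s_hat - s)^2)
    g
  }
  val_loss_fn <- function(params)
    cevvo_loss_value(params, va$x, va$s, va$y, units, rw)

  fit <- with_seed(cfg$seed, train_loop(
    model$params, length(tr$y), grad_fn, val_loss_fn,
    lr = cfg$learning_rate, batch_size = cfg$batch_size,
    max_epochs = cfg$max_epochs, patience = cfg$patience,
    min_epochs = cfg$min_epochs %||% 1))
  model$params <- fit$params
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$trained <- TRUE
  model
}

#' Predict decannulation-success scores
#'
#' Runs the forward pass on scaled samples and returns one sigmoid score in
#' (0, 1) per sample, order-preserving and batch-size invariant. A warning
#' is emitted if the inputs look unscaled (values far outside \[-1, 2\]).
#'
#' @param object a trained `cevvo_model`.
#' @param samples list of scaled samples or prestacked arrays.
#' @param ... unused.
#' @return Numeric vector of scores.
#' @export
predict.cevvo_model <- function(object, samples, ...) {
  ar <- if (is.list(samples) && !is.null(samples$x))
    samples else samples_to_arrays(samples)
  if (max(abs(ar$x)) > 25 || max(abs(ar$s)) > 1e3)
    warning("input values are far outside the scaled range; was the training scaler applied?")
  cache <- cevvo_forward(object$params, ar$x, ar$s, object$config$lstm_units)
  clip_prob(cache$score, 1e-12)
}
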