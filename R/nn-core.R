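# Minimal neural-network core: Glorot initialisation, Adam, and the exact
# forward/backward passes for the two-headed classifier and the dense
# reference network. Written against base R matrix ops; batch-major layouts
# (B x T x V for series, B x d for static features).

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Mean binary cross-entropy
#'
#' `L = -(1/N) sum(y log(p) + (1 - y) log(1 - p))`, with predictions
#' clipped to `[eps, 1 - eps]` before the logs.
#'
#' @param labels binary vector.
#' @param scores predicted probabilities in (0, 1).
#' @param eps clipping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(labels, scores, eps = 1e-7) {
  p <- clip_prob(scores, eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# ---- two-headed classifier -------------------------------------------------

cevvo_init_params <- function(n_channels, static_dim, filters, units,
                              widths) {
  p <- list(
    Wc = glorot(n_channels, filters), bc = numeric(filters),
    Wx = glorot(filters, 4 * units), Wh = glorot(units, 4 * units),
    bl = numeric(4 * units),
    W1 = glorot(static_dim, widths[1]), b1 = numeric(widths[1]),
    W2 = glorot(widths[1], widths[2]), b2 = numeric(widths[2]),
    W3 = glorot(widths[2], widths[3]), b3 = numeric(widths[3]),
    Wd = glorot(widths[3], static_dim), bd = numeric(static_dim),
    Wo = glorot(widths[3] + units, 1), bo = 0
  )
  # positive initial forget-gate bias: standard LSTM conditioning
  p$bl[(units + 1):(2 * units)] <- 1
  p
}

cevvo_forward <- function(params, x, s, units) {
  b <- dim(x)[1]; t_len <- dim(x)[2]; v <- dim(x)[3]
  filters <- ncol(params$Wc)

  # 1x1 convolution over channels, tanh, applied at every time step at once
  conv_list <- vector("list", t_len)
  conv_flat <- tanh(sweep(matrix(x, b * t_len, v) %*% params$Wc, 2,
                          params$bc, "+"))
  for (t in seq_len(t_len))
    conv_list[[t]] <- conv_flat[(t - 1) * b + seq_len(b), , drop = FALSE]

  gi <- vector("list", t_len); gf <- gi; gg <- gi; go <- gi
  cs <- gi; tc <- gi; hs <- gi
  h_prev <- matrix(0, b, units)
  c_prev <- matrix(0, b, units)
  iu <- seq_len(units)
  for (t in seq_len(t_len)) {
    pre <- conv_list[[t]] %*% params$Wx + h_prev %*% params$Wh
    pre <- sweep(pre, 2, params$bl, "+")
    i_g <- sigmoid(pre[, iu, drop = FALSE])
    f_g <- sigmoid(pre[, units + iu, drop = FALSE])
    g_g <- tanh(pre[, 2 * units + iu, drop = FALSE])
    o_g <- sigmoid(pre[, 3 * units + iu, drop = FALSE])
    c_prev <- f_g * c_prev + i_g * g_g
    tc_cur <- tanh(c_prev)
    h_prev <- o_g * tc_cur
    gi[[t]] <- i_g; gf[[t]] <- f_g; gg[[t]] <- g_g; go[[t]] <- o_g
    cs[[t]] <- c_prev; tc[[t]] <- tc_cur; hs[[t]] <- h_prev
  }
  h_last <- h_prev

  z1 <- tanh(sweep(s %*% params$W1, 2, params$b1, "+"))
  z2 <- tanh(sweep(z1 %*% params$W2, 2, params$b2, "+"))
  z3 <- tanh(sweep(z2 %*% params$W3, 2, params$b3, "+"))
  s_hat <- sweep(z3 %*% params$Wd, 2, params$bd, "+")

  fusion <- cbind(z3, h_last)
  score <- sigmoid(as.vector(fusion %*% params$Wo) + params$bo)
  list(score = score, fusion = fusion, z1 = z1, z2 = z2, z3 = z3,
       s_hat = s_hat, conv_list = conv_list, conv_flat = conv_flat,
       gi = gi, gf = gf, gg = gg, go = go, cs = cs, tc = tc, hs = hs)
}

cevvo_backward <- function(params, cache, x, s, y, units, recon_weight) {
  b <- dim(x)[1]; t_len <- dim(x)[2]; v <- dim(x)[3]
  filters <- ncol(params$Wc)
  w3 <- ncol(params$W3)
  g <- lapply(params, function(p) p * 0)

  dlogit <- matrix((cache$score - y) / b, b, 1)
  g$Wo <- crossprod(cache$fusion, dlogit)
  g$bo <- sum(dlogit)
  dfusion <- dlogit %*% t(params$Wo)
  dz3 <- dfusion[, seq_len(w3), drop = FALSE]
  dh <- dfusion[, w3 + seq_len(units), drop = FALSE]

  # reconstruction head
  ds_hat <- 2 * recon_weight * (cache$s_hat - s) / (b * ncol(s))
  g$Wd <- crossprod(cache$z3, ds_hat)
  g$bd <- colSums(ds_hat)
  dz3 <- dz3 + ds_hat %*% t(params$Wd)

  da3 <- dz3 * (1 - cache$z3^2)
  g$W3 <- crossprod(cache$z2, da3); g$b3 <- colSums(da3)
  da2 <- (da3 %*% t(params$W3)) * (1 - cache$z2^2)
  g$W2 <- crossprod(cache$z1, da2); g$b2 <- colSums(da2)
  da1 <- (da2 %*% t(params$W2)) * (1 - cache$z1^2)
  g$W1 <- crossprod(s, da1); g$b1 <- colSums(da1)

  dc <- matrix(0, b, units)
  dpre_all <- matrix(0, b * t_len, filters)
  zero_bu <- matrix(0, b, units)
  tWh <- t(params$Wh)
  tWx <- t(params$Wx)
  for (t in seq.int(t_len, 1)) {
    i_g <- cache$gi[[t]]; f_g <- cache$gf[[t]]
    g_g <- cache$gg[[t]]; o_g <- cache$go[[t]]
    tc_t <- cache$tc[[t]]
    c_prev <- if (t > 1) cache$cs[[t - 1]] else zero_bu
    h_prev <- if (t > 1) cache$hs[[t - 1]] else zero_bu

    do_g <- dh * tc_t
    dc <- dc + dh * o_g * (1 - tc_t^2)
    da <- cbind((dc * g_g) * i_g * (1 - i_g),
                (dc * c_prev) * f_g * (1 - f_g),
                (dc * i_g) * (1 - g_g^2),
                do_g * o_g * (1 - o_g))
    dc <- dc * f_g
    g$Wx <- g$Wx + crossprod(cache$conv_list[[t]], da)
    g$Wh <- g$Wh + crossprod(h_prev, da)
    g$bl <- g$bl + colSums(da)
    dh <- da %*% tWh
    dpre_all[(t - 1) * b + seq_len(b), ] <- da %*% tWx
  }
  dpre_conv <- dpre_all * (1 - cache$conv_flat^2)
  g$Wc <- crossprod(matrix(x, b * t_len, v), dpre_conv)
  g$bc <- colSums(dpre_conv)
  g
}

cevvo_loss_value <- function(params, x, s, y, units, recon_weight,
                             cache = NULL) {
  cache <- cache %||% cevvo_forward(params, x, s, units)
  bce_loss(y, cache$score) +
    recon_weight * mean((cache$s_hat - s)^2)
}

# ---- dense reference network ----------------------------------------------

mlp_init_params <- function(d_in, hidden) {
  list(W1 = glorot(d_in, hidden), b1 = numeric(hidden),
       W2 = glorot(hidden, 1), b2 = 0)
}

mlp_forward <- function(params, x) {
  z1 <- tanh(sweep(x %*% params$W1, 2, params$b1, "+"))
  score <- sigmoid(as.vector(z1 %*% params$W2) + params$b2)
  list(score = score, z1 = z1)
}

mlp_backward <- function(params, cache, x, y) {
  b <- nrow(x)
  dlogit <- matrix((cache$score - y) / b, b, 1)
  g <- list()
  g$W2 <- crossprod(cache$z1, dlogit)
  g$b2 <- sum(dlogit)
  da1 <- (dlogit %*% t(params$W2)) * (1 - cache$z1^2)
  g$W1 <- crossprod(x, da1)
  g$b1 <- colSums(da1)
  g
}

# Generic mini-batch training loop with validation-loss early stopping.
# grad_fn(params, idx) -> grads (with attr "loss"); the best-validation
# parameters are restored on exit.
train_loop <- function(params, n_train, grad_fn, val_loss_fn,
                       lr, batch_size, max_epochs, patience,
                       min_epochs = 1) {
  state <- adam_init(params)
  # best-so-far tracking starts at min_epochs: the restored model is always
  # a trained one, even when a small validation split is misleading early on
  best <- list(params = NULL, val = Inf, epoch = 0)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  wait <- 0
  for (epoch in seq_len(max_epochs)) {
    order_idx <- sample.int(n_train)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / batch_size))
    ep_loss <- 0
    for (bidx in batches) {
      g <- grad_fn(params, bidx)
      ep_loss <- ep_loss + attr(g, "loss") * length(bidx)
      upd <- adam_step(params, g, state, lr)
      params <- upd$params; state <- upd$state
    }
    vl <- val_loss_fn(params)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / n_train, val_loss = vl))
    if (epoch >= min_epochs) {
      if (vl < best$val - 1e-9) {
        best <- list(params = params, val = vl, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
  }
  if (is.null(best$params))
    best <- list(params = params, val = NA_real_, epoch = nrow(history))
  list(params = best$params, history = history, best_epoch = best$epoch)
}
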