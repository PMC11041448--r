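#' @keywords internal
"_PACKAGE"

# Numerically safe sigmoid / logit used throughout the package.
sigmoid <- function(x) 1 / (1 + exp(-x))

# Clip probabilities away from {0, 1} before taking logs / logits.
clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

logit <- function(p, eps = 1e-7) stats::qlogis(clip_prob(p, eps))

# Run `expr` under a temporary RNG seed without disturbing the caller's
# RNG state; with seed = NULL the current stream is used as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed, staying below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cevvo <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "cevvo_error")))
}
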