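# Internal numeric and RNG helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded library calls never disturb
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic stream of sub-seeds below 2^31, one per (seed, k) pair.
# Park-Miller style multiplicative step keeps consecutive epochs decorrelated.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(k) * 104729) %% 2147483647)
}

# round() in R is banker's rounding; splits and improvement rates are
# specified half-up (0.5 always rounds away from zero).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# -log(sigmoid(x)) == softplus(-x), computed without overflow for large |x|.
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Adam optimizer state for a list of weight matrices
#' @noRd
adam_init <- function(weights) {
  list(
    m = lapply(weights, function(w) array(0, dim(w))),
    v = lapply(weights, function(w) array(0, dim(w))),
    t = 0L
  )
}

# One Adam step over a list of matrices; returns list(weights, state).
adam_step <- function(weights, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (l in seq_along(weights)) {
    g <- grads[[l]]
    state$m[[l]] <- beta1 * state$m[[l]] + (1 - beta1) * g
    state$v[[l]] <- beta2 * state$v[[l]] + (1 - beta2) * g^2
    mhat <- state$m[[l]] / (1 - beta1^t)
    vhat <- state$v[[l]] / (1 - beta2^t)
    weights[[l]] <- weights[[l]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

# Stops with a consistent "input error" style message.
input_error <- function(...) stop(sprintf(...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    input_error("`%s` must be a single number in (0, 1), got %s", name,
                paste(format(x), collapse = ", "))
  }
  invisible(x)
}
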