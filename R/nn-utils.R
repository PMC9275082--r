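# Numerical building blocks for the encoder/decoder and its optimizer.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

#' Scaled exponential linear unit
#'
#' `selu(x) = lambda * x` for `x > 0` and `lambda * alpha * (exp(x) - 1)`
#' otherwise, with the standard self-normalizing constants.
#'
#' @param x Numeric vector/matrix.
#' @export
selu <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
}

selu_grad <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Xavier (Glorot) uniform initialization
#'
#' Draws entries uniformly on `+/- sqrt(6 / (fan_in + fan_out))` where fan_in
#' and fan_out are the matrix dimensions.
#'
#' @param nrow,ncol Matrix dimensions.
#' @return `nrow` x `ncol` matrix.
#' @export
xavier_init <- function(nrow, ncol) {
  b <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -b, b), nrow, ncol)
}

#' Triangular cyclic learning rate schedule
#'
#' A triangular wave between `lr_low` and `lr_high`: the rate starts at
#' `lr_low`, rises linearly to `lr_high` at mid-cycle and falls back, with one
#' full cycle every `cycle` steps.
#'
#' @param step 0-based step index.
#' @param lr_low,lr_high Schedule bounds (defaults 0.01 and 0.1).
#' @param cycle Cycle length in steps (default 100).
#' @return Learning rate in `[lr_low, lr_high]`.
#' @export
cyclic_lr <- function(step, lr_low = 0.01, lr_high = 0.1, cycle = 100L) {
  stopifnot(lr_low > 0, lr_low <= lr_high, cycle >= 2)
  pos <- step %% cycle
  half <- cycle / 2
  frac <- ifelse(pos <= half, pos / half, (cycle - pos) / half)
  lr_low + frac * (lr_high - lr_low)
}

# Adam optimizer over a named list of parameter matrices/vectors.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}
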