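# Small numerical helpers shared across modules.

# log(1 - exp(-x)) for x > 0, switching branches at log(2) to avoid
# catastrophic cancellation on either side.
log1mexp <- function(x) {
  out <- numeric(length(x))
  small <- x <= log(2)
  out[small] <- log(-expm1(-x[small]))
  out[!small] <- log1p(-exp(-x[!small]))
  out
}

# Exponent clipping bound: the likelihood is overflow-prone in exp(linear
# predictor); +-50 keeps exp() finite while being far outside any plausible
# fitted range.
EXP_CLIP <- 50

clip_exp <- function(x) exp(pmin(pmax(x, -EXP_CLIP), EXP_CLIP))

# Floor for the conditional hazard scale h = Lambda(U) exp(LP): the
# likelihood is undefined at h = 0 with delta = 1.
H_FLOOR <- 1e-12

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
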