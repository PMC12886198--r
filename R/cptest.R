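# Eigenvalue-thresholded pseudo-inverse of a symmetric PSD matrix:
# directions with near-zero variance are projected out rather than
# erroring.
psd_pinv <- function(m, tol = 1e-8) {
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  keep <- ev$values > tol * max(ev$values, 0)
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  v <- ev$vectors[, keep, drop = FALSE]
  v %*% (t(v) / ev$values[keep])
}

#' Score statistic for one candidate (zeta, direction) pair
#'
#' The quadratic-form statistic `U_n' Sigma_n^- U_n` with
#' `U_n = sum_i 1{E_i > zeta} Q_i (X_i', f(Z_i))'` and
#' `Sigma_n = sum_i 1{E_i > zeta} Q_i^2 (X_i', f(Z_i))'(X_i', f(Z_i))`,
#' where `Q` is evaluated at the restricted (null) fit and the direction
#' function is the indicator `f(Z) = 1{Z_j < z_j}`. An empty indicator set
#' (`zeta >= max(E)`) gives statistic 0.
#'
#' @param data a `cscp_data`.
#' @param null_fit a restricted `cscp_fit` (`deep-null` or `linear-null`).
#' @param zeta candidate threshold.
#' @param j coordinate of Z for the direction function.
#' @param zj cut point of the direction indicator.
#' @param pinv_tol relative eigenvalue cutoff of the pseudo-inverse.
#' @return scalar statistic (nonnegative).
#' @export
score_stat <- function(data, null_fit, zeta, j, zj, pinv_tol = 1e-8) {
  q <- q_weight(null_fit$state, data)
  idx <- data$e > zeta
  if (!any(idx)) return(0)
  v <- cbind(data$x, as.numeric(data$z[, j] < zj))[idx, , drop = FALSE]
  qi <- q[idx]
  u <- drop(crossprod(v, qi))
  sig <- crossprod(v * qi)
  drop(t(u) %*% psd_pinv(sig, pinv_tol) %*% u)
}

# Candidate construction: k thresholds at equally spaced quantiles of E
# between the zeta_range quantiles; per-coordinate direction cut points at
# the z_probs quantiles of each Z column.
sup_candidates <- function(data, k = 5L, zeta_range = c(0.1, 0.9),
                           z_probs = seq(0.1, 0.9, by = 0.1)) {
  zetas <- stats::quantile(data$e, seq(zeta_range[1], zeta_range[2],
                                       length.out = k),
                           names = FALSE, type = 7)
  cuts <- lapply(seq_len(data$r), function(j)
    stats::quantile(data$z[, j], z_probs, names = FALSE, type = 7))
  dir_j <- rep(seq_len(data$r), each = length(z_probs))
  dir_z <- unlist(cuts)
  fmat <- matrix(0, length(data$e), length(dir_j))
  for (d in seq_along(dir_j))
    fmat[, d] <- as.numeric(data$z[, dir_j[d]] < dir_z[d])
  list(zetas = zetas, dir_j = dir_j, dir_z = dir_z, fmat = fmat)
}

# Vectorized SUP over the candidate grid for a given E column (the
# permutation loop swaps `e` only). Tie-breaking: the first candidate in
# (zeta, direction) order is kept.
sup_core <- function(e, x, q, cand, pinv_tol = 1e-8) {
  q2 <- q^2
  best <- -Inf
  arg <- c(NA_integer_, NA_integer_)
  p <- ncol(x)
  for (iz in seq_along(cand$zetas)) {
    mask <- as.numeric(e > cand$zetas[iz])
    if (!any(mask > 0)) next
    qm <- q * mask
    q2m <- q2 * mask
    ux <- drop(crossprod(x, qm))                    # p
    uf <- drop(crossprod(cand$fmat, qm))            # ndir
    a <- crossprod(x * sqrt(q2m))                   # p x p
    bmat <- crossprod(cand$fmat, x * q2m)           # ndir x p
    cvec <- drop(crossprod(cand$fmat, q2m))         # ndir (f^2 = f)
    for (d in seq_along(uf)) {
      u <- c(ux, uf[d])
      sig <- rbind(cbind(a, bmat[d, ]), c(bmat[d, ], cvec[d]))
      s <- drop(t(u) %*% psd_pinv(sig, pinv_tol) %*% u)
      if (s > best + 1e-15) {
        best <- s
        arg <- c(iz, d)
      }
    }
  }
  list(sup = max(best, 0), arg = arg)
}

#' SUP_k statistic over the candidate grid
#'
#' Exhaustive maximum of [score_stat()] over the finite candidate set
#' (k thresholds) x (r coordinates) x (direction cut points), with
#' smallest-index tie-breaking.
#'
#' @inheritParams score_stat
#' @param k number of threshold candidates.
#' @param zeta_range quantile range of E containing the candidates.
#' @param z_probs quantile levels of each Z column used as direction cut
#'   points (default deciles).
#' @return list with `sup` and `argmax` (zeta, coordinate j, cut z_j).
#' @export
sup_statistic <- function(data, null_fit, k = 5L, zeta_range = c(0.1, 0.9),
                          z_probs = seq(0.1, 0.9, by = 0.1),
                          pinv_tol = 1e-8) {
  cand <- sup_candidates(data, k, zeta_range, z_probs)
  q <- q_weight(null_fit$state, data)
  res <- sup_core(data$e, data$x, q, cand, pinv_tol)
  argmax <- if (anyNA(res$arg)) NULL else list(
    zeta = cand$zetas[res$arg[1]],
    j = cand$dir_j[res$arg[2]],
    zj = cand$dir_z[res$arg[2]]
  )
  list(sup = res$sup, argmax = argmax, candidates = cand)
}

#' Permutation test for the existence of a change point
#'
#' Tests H0: `gamma = 0`, `h = 0` (no change-point effect). The
#' restricted model is fitted once — under H0 the model does not involve E
#' at all, so the restricted fit is invariant to any permutation of E and
#' refitting per permutation would reproduce it exactly. The observed
#' SUP_k is compared with its permutation distribution obtained by
#' permuting the E column `B` times; the p-value uses the add-one
#' convention `p = (1 + #\{permuted >= observed\}) / (B + 1)`.
#'
#' @param data a `cscp_data`.
#' @param null_model restricted model kind: `"deep-null"` or the faster
#'   `"linear-null"`.
#' @param k,zeta_range,z_probs,pinv_tol candidate-grid parameters, see
#'   [sup_statistic()].
#' @param B number of permutations (default 1000).
#' @param control a [cscp_control()] for the restricted fit.
#' @param seed integer seed for the permutation draws.
#' @return object of class `cscp_suptest`: observed statistic, `p_value`,
#'   `argmax`, the permutation draws, and the restricted fit.
#' @export
cscp_suptest <- function(data, null_model = c("deep-null", "linear-null"),
                         k = 5L, B = 1000L, zeta_range = c(0.1, 0.9),
                         z_probs = seq(0.1, 0.9, by = 0.1),
                         pinv_tol = 1e-8, control = cscp_control(),
                         seed = NULL) {
  null_model <- match.arg(null_model)
  B <- as.integer(B)
  if (B < 1L) stop("'B' must be >= 1")
  if (k < 1L) stop("'k' must be >= 1")
  null_fit <- cscp_fit(data, model = null_model, control = control)
  cand <- sup_candidates(data, k, zeta_range, z_probs)
  q <- q_weight(null_fit$state, data)
  obs <- sup_core(data$e, data$x, q, cand, pinv_tol)
  if (!is.null(seed)) set.seed(seed)
  perms <- vapply(seq_len(B), function(b) {
    sup_core(sample(data$e), data$x, q, cand, pinv_tol)$sup
  }, numeric(1))
  pval <- (1 + sum(perms >= obs$sup)) / (B + 1)
  argmax <- if (anyNA(obs$arg)) NULL else list(
    zeta = cand$zetas[obs$arg[1]],
    j = cand$dir_j[obs$arg[2]],
    zj = cand$dir_z[obs$arg[2]]
  )
  structure(list(sup = obs$sup, p_value = pval, argmax = argmax,
                 perms = perms, B = B, k = k, null_model = null_model,
                 null_fit = null_fit),
            class = "cscp_suptest")
}

#' @export
print.cscp_suptest <- function(x, ...) {
  cat(sprintf("SUP_%d permutation test for a change point (%s restricted fit)\n",
              x$k, x$null_model))
  cat(sprintf("  observed SUP = %.4f, B = %d permutations, p = %.4g\n",
              x$sup, x$B, x$p_value))
  if (!is.null(x$argmax))
    cat(sprintf("  argmax: zeta = %.4f, direction 1{Z%d < %.4f}\n",
                x$argmax$zeta, x$argmax$j, x$argmax$zj))
  invisible(x)
}
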