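#' Least-favorable projection of the regression score
#'
#' Computes, separately for each coordinate of `Xtilde(zeta_hat)`, the
#' weighted least-squares projection onto `a(U) + b(Z)`, with weights
#' `Q_hat^2` and finite bases: `a` in the span of the cubic B-spline basis
#' on the fitted hazard knots (which contains the constant), `b` in an
#' additive spline basis with `b_df` functions per coordinate of Z,
#' empirically centered (the mean-zero tangent-space constraint on b). A
#' small ridge (1e-8) stabilizes the Gram matrix; if it is effectively
#' singular beyond that rescue the information is degenerate and an error
#' is raised.
#'
#' @param data a `cscp_data`.
#' @param fit a `cscp_fit` with a change-point term.
#' @param b_df basis functions per Z coordinate (default 5).
#' @param ridge ridge added to the Gram diagonal (default 1e-8).
#' @return list with `residuals` (n-by-2p), `coef`, `design`, `q`
#'   (the score weights), class `cscp_projection`.
#' @export
project_scores <- function(data, fit, b_df = 5L, ridge = 1e-8) {
  state <- fit$state
  q <- q_weight(state, data)
  xt <- xtilde(data, state$zeta, state$has_cp)

  haz <- state$hazard
  kv <- hazard_knot_vector(haz)
  uc <- pmin(pmax(data$u, haz$boundary[1]), haz$boundary[2])
  a_basis <- splines::splineDesign(kv, uc, ord = haz$degree + 1L, outer.ok = FALSE)

  b_list <- lapply(seq_len(data$r), function(j) {
    zj <- data$z[, j]
    kn <- stats::quantile(zj, probs = seq_len(b_df - 3L) / (b_df - 2L),
                          names = FALSE, type = 7)
    bb <- splines::splineDesign(
      c(rep(min(zj), 4), kn, rep(max(zj), 4)), zj, ord = 4, outer.ok = TRUE)
    bb <- bb[, -1, drop = FALSE]           # drop one column: constants live in a(U)
    sweep(bb, 2, colMeans(bb), "-")        # mean-zero constraint on b
  })
  design <- cbind(a_basis, do.call(cbind, b_list))

  aq <- abs(q)
  dw <- design * aq
  xw <- xt * aq
  gram <- crossprod(dw)
  diag(gram) <- diag(gram) + ridge * max(diag(gram))
  coefs <- tryCatch(solve(gram, crossprod(dw, xw)),
                    error = function(e) stop("information degenerate", call. = FALSE))
  res <- xt - design %*% coefs
  structure(list(residuals = res, coef = coefs, design = design, q = q),
            class = "cscp_projection")
}

#' Plug-in information matrix and Wald summary
#'
#' Empirical information `I_hat = n^-1 sum_i Q_i^2 R_i R_i'` from the
#' projection residuals, estimated standard errors
#' `ESE_k = sqrt((I_hat^-1)_kk / n)`, normal-reference confidence
#' intervals and p-values for `theta = (beta', gamma')'`. The fitted
#' change point is treated as known (the change-point and regression
#' estimators are asymptotically independent).
#'
#' @param data a `cscp_data`.
#' @param fit a `cscp_fit`.
#' @param proj a `cscp_projection` from [project_scores()].
#' @param level confidence level (default 0.95).
#' @return object of class `cscp_wald`: `info`, `ese`, `table` (estimate,
#'   ESE, CI bounds, two- and one-sided p-values).
#' @export
information_matrix <- function(data, fit, proj, level = 0.95) {
  n <- length(data$delta)
  rq <- proj$residuals * proj$q
  info <- crossprod(rq) / n
  info <- (info + t(info)) / 2
  if (!all(is.finite(info)) || rcond(info) < 1e-10)
    stop("information degenerate", call. = FALSE)
  inv <- tryCatch(solve(info), error = function(e)
    stop("information degenerate", call. = FALSE))
  ese <- sqrt(pmax(diag(inv), 0) / n)
  theta <- fit$theta
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  zstat <- theta / ese
  p <- data$p
  nm <- c(paste0("beta", seq_len(p)), paste0("gamma", seq_len(p)))
  tab <- data.frame(
    parameter = nm[seq_along(theta)],
    estimate = theta,
    ese = ese,
    lower = theta - zcrit * ese,
    upper = theta + zcrit * ese,
    p_two_sided = 2 * stats::pnorm(-abs(zstat)),
    p_one_sided = stats::pnorm(-abs(zstat)),
    row.names = NULL
  )
  structure(list(info = info, ese = ese, table = tab, level = level),
            class = "cscp_wald")
}

#' Wald inference for the regression parameters
#'
#' Convenience wrapper: projection followed by the information matrix.
#'
#' @inheritParams project_scores
#' @param level confidence level.
#' @return a `cscp_wald` object.
#' @export
cscp_wald <- function(fit, data, b_df = 5L, level = 0.95) {
  proj <- project_scores(data, fit, b_df = b_df)
  information_matrix(data, fit, proj, level = level)
}

#' @export
print.cscp_wald <- function(x, ...) {
  cat(sprintf("Wald inference (plug-in efficient information, %.0f%% CI)\n",
              100 * x$level))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-8s %8.4f  SE %7.4f  p %8.2g  [%8.4f, %8.4f]\n",
                tab$parameter[i], tab$estimate[i], tab$ese[i],
                tab$p_two_sided[i], tab$lower[i], tab$upper[i]))
  }
  invisible(x)
}
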