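#' Monotone baseline cumulative hazard via an I-spline basis
#'
#' `build_hazard_knots()` constructs the sieve for the baseline cumulative
#' hazard: boundary knots just outside the observed examination-time range,
#' `m_n` interior knots at empirical quantiles of `u`, and `m_n + degree + 1`
#' basis coefficients initialized to zero. The basis functions are
#' integrated B-splines (I-splines), each nondecreasing, 0 at the left
#' boundary and normalized to 1 at the right boundary, so any nonnegative
#' coefficient vector yields a monotone nondecreasing cumulative hazard.
#'
#' The default number of interior knots is `ceiling(n^(1/3))`, placing the
#' sieve growth rate in the window required for the convergence theory of
#' the smooth (u = 1) baseline class.
#'
#' @param u examination times (at least two distinct values).
#' @param m_n number of interior knots; default `ceiling(length(u)^(1/3))`.
#' @param degree polynomial degree label of the monotone basis (default 3).
#' @return object of class `monotone_hazard` with fields `degree`,
#'   `interior`, `boundary`, `coef` (all zero).
#' @export
build_hazard_knots <- function(u, m_n = NULL, degree = 3L) {
  u <- as.numeric(u)
  if (length(unique(u)) < 2L) stop("'u' needs at least 2 distinct values")
  if (any(u <= 0)) stop("'u' must be positive")
  degree <- as.integer(degree)
  if (degree < 1L) stop("'degree' must be >= 1")
  if (is.null(m_n)) m_n <- ceiling(length(u)^(1 / 3))
  m_n <- as.integer(m_n)
  if (m_n < 0L) stop("'m_n' must be >= 0")
  if (m_n + degree + 1L > length(u))
    stop("over-parameterized sieve: m_n + degree + 1 exceeds the number of observations")
  l_u <- min(u) * (1 - 1e-6)
  r_u <- max(u) * (1 + 1e-6)
  interior <- if (m_n > 0L) {
    q <- stats::quantile(u, probs = seq_len(m_n) / (m_n + 1), names = FALSE, type = 7)
    q <- pmin(pmax(q, l_u + 1e-10), r_u - 1e-10)
    sort(q)
  } else numeric(0)
  structure(list(
    degree = degree, interior = interior, boundary = c(l_u, r_u),
    coef = rep(0, m_n + degree + 1L)
  ), class = "monotone_hazard")
}

# Full (replicated) knot vector for the order-(degree+1) B-splines whose
# normalized integrals form the monotone basis.
hazard_knot_vector <- function(haz) {
  k <- haz$degree + 1L
  c(rep(haz$boundary[1], k), haz$interior, rep(haz$boundary[2], k))
}

# 3-point Gauss-Legendre nodes/weights on [a, b]; exact for polynomials up
# to degree 5, so exact for the piecewise-polynomial B-spline columns.
gl3 <- function(a, b) {
  half <- (b - a) / 2
  mid <- (a + b) / 2
  s <- sqrt(3 / 5)
  list(x = c(mid - half * s, mid, mid + half * s),
       w = half * c(5, 8, 5) / 9)
}

#' Evaluate the monotone (I-spline) basis
#'
#' Returns the matrix of normalized integrated B-spline basis functions at
#' the points `t`. Each column is nondecreasing, equals 0 at the left
#' boundary and 1 at the right boundary; evaluation outside the boundary
#' clamps to the endpoint values. Integrals are computed exactly by
#' per-knot-interval Gauss-Legendre quadrature of the underlying B-spline
#' columns.
#'
#' @param t evaluation points.
#' @param haz a `monotone_hazard` object (see [build_hazard_knots()]).
#' @return numeric matrix, `length(t)` rows and `length(haz$coef)` columns.
#' @export
ispline_basis <- function(t, haz) {
  stopifnot(inherits(haz, "monotone_hazard"))
  k <- haz$degree + 1L
  kv <- hazard_knot_vector(haz)
  nb <- length(kv) - k
  breaks <- c(haz$boundary[1], haz$interior, haz$boundary[2])
  nint <- length(breaks) - 1L

  bdes <- function(x) splines::splineDesign(kv, x, ord = k, outer.ok = FALSE)

  # Exact integral of each B-spline column over every knot interval.
  intmat <- matrix(0, nint, nb)
  for (i in seq_len(nint)) {
    g <- gl3(breaks[i], breaks[i + 1])
    intmat[i, ] <- colSums(bdes(g$x) * g$w)
  }
  cumint <- rbind(0, apply(intmat, 2, cumsum))   # (nint+1) x nb, rows at breaks
  total <- cumint[nint + 1L, ]

  tc <- pmin(pmax(as.numeric(t), haz$boundary[1]), haz$boundary[2])
  idx <- findInterval(tc, breaks, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nint)
  out <- cumint[idx, , drop = FALSE]
  lo <- breaks[idx]
  partial <- tc > lo
  if (any(partial)) {
    ip <- which(partial)
    a <- lo[ip]; b <- tc[ip]
    half <- (b - a) / 2; mid <- (a + b) / 2; s <- sqrt(3 / 5)
    nodes <- c(mid - half * s, mid, mid + half * s)
    bb <- bdes(nodes)
    np <- length(ip)
    w1 <- half * 5 / 9; w2 <- half * 8 / 9
    out[ip, ] <- out[ip, , drop = FALSE] +
      bb[seq_len(np), , drop = FALSE] * w1 +
      bb[np + seq_len(np), , drop = FALSE] * w2 +
      bb[2L * np + seq_len(np), , drop = FALSE] * w1
  }
  sweep(out, 2, total, "/")
}

#' Evaluate the fitted cumulative hazard
#'
#' @param haz a `monotone_hazard` object with nonnegative coefficients.
#' @param t evaluation points (clamped to the boundary interval).
#' @return numeric vector of cumulative hazard values.
#' @export
hazard_eval <- function(haz, t) {
  drop(ispline_basis(t, haz) %*% haz$coef)
}

#' Serialize / restore a monotone hazard
#'
#' Round-trippable plain-list representation (degree, knots, boundary,
#' coefficients), suitable for writing as JSON with jsonlite.
#'
#' @param haz a `monotone_hazard`.
#' @return `hazard_serialize()`: a plain list; `hazard_restore()`: a
#'   `monotone_hazard`.
#' @export
hazard_serialize <- function(haz) {
  list(degree = haz$degree, interior = haz$interior,
       boundary = haz$boundary, coef = haz$coef)
}

#' @rdname hazard_serialize
#' @param obj a list produced by `hazard_serialize()` (e.g. parsed JSON).
#' @export
hazard_restore <- function(obj) {
  structure(list(degree = as.integer(obj$degree),
                 interior = as.numeric(obj$interior),
                 boundary = as.numeric(obj$boundary),
                 coef = as.numeric(obj$coef)),
            class = "monotone_hazard")
}

# Constrained spline coefficient update: maximize the current-status
# log-likelihood over c >= 0 with the regression components held fixed.
# `basis_u` is the I-spline basis at the observed U, `w` the fixed
# multiplicative factor exp(linear predictor) per subject.
spline_step_core <- function(basis_u, delta, w, coef_in, maxit = 200L) {
  negll <- function(cc) {
    h <- pmax(drop(basis_u %*% cc) * w, H_FLOOR)
    -mean(delta * log1mexp(h) - (1 - delta) * h)
  }
  grad <- function(cc) {
    h <- pmax(drop(basis_u %*% cc) * w, H_FLOOR)
    qlam <- w * (delta / expm1(h) - (1 - delta))
    -colMeans(basis_u * qlam)
  }
  ll_in <- -negll(coef_in)
  res <- tryCatch(
    stats::optim(coef_in, negll, grad, method = "L-BFGS-B",
                 lower = rep(0, length(coef_in)),
                 control = list(maxit = maxit)),
    error = function(e) NULL
  )
  if (is.null(res) || -res$value < ll_in - 1e-10) {
    # optimizer failure: preserve the incoming coefficients
    return(list(coef = coef_in, loglik = ll_in, improved = FALSE))
  }
  list(coef = pmax(res$par, 0), loglik = -res$value, improved = TRUE)
}

#' Spline coefficient update step
#'
#' One block update of the profiling algorithm: with the regression
#' parameters, nonparametric effects and change point held fixed at the
#' values in `state`, maximizes the log-likelihood over the nonnegative
#' I-spline coefficients of the baseline cumulative hazard. The returned
#' log-likelihood never falls below the incoming one (on failure the
#' incoming coefficients are preserved).
#'
#' @param data a `cscp_data` object.
#' @param state a model state as held in a [cscp_fit()] result.
#' @param basis_u optional precomputed basis at `data$u`.
#' @return list with `coef` (nonnegative), `loglik`, `improved`.
#' @export
fit_spline_step <- function(data, state, basis_u = NULL) {
  if (is.null(basis_u)) basis_u <- ispline_basis(data$u, state$hazard)
  w <- clip_exp(state_linpred(state, data, include_hazard = FALSE))
  spline_step_core(basis_u, data$delta, w, state$hazard$coef)
}
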