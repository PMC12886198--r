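# Model state: the fitted tuple eta = (Lambda, beta, g, gamma, h, zeta).
# `gh_kind` selects how (g, h) are represented: a two-headed network
# ("deep"), linear forms ("linear": g = varsigma'Z, h = vartheta'Z +
# vartheta0), or identically zero ("none"). `has_cp` marks whether the
# change-point term is active; restricted (null) states have gamma = 0,
# h = 0 and ignore E entirely.
new_cscp_state <- function(hazard, beta, gamma, zeta, gh_kind,
                           net = NULL, lin = NULL, has_cp = TRUE) {
  structure(list(hazard = hazard, beta = beta, gamma = gamma, zeta = zeta,
                 gh_kind = gh_kind, net = net, lin = lin, has_cp = has_cp),
            class = "cscp_state")
}

# (g(Z), h(Z)) as an n-by-2 matrix under the state's representation.
state_gh <- function(state, z) {
  n <- nrow(as.matrix(z))
  switch(state$gh_kind,
    deep = {
      out <- net_forward(state$net, z)
      if (ncol(out) == 1L) cbind(out[, 1], rep(0, n)) else out[, 1:2]
    },
    linear = cbind(drop(as.matrix(z) %*% state$lin$varsigma),
                   if (state$has_cp)
                     drop(as.matrix(z) %*% state$lin$vartheta) + state$lin$vartheta0
                   else rep(0, n)),
    none = matrix(0, n, 2),
    stop("unknown gh_kind")
  )
}

# Linear predictor beta'X + g(Z) + (gamma'X + h(Z)) 1{E > zeta}; with
# include_hazard = TRUE, log Lambda(U) is added (giving log h_eta).
state_linpred <- function(state, data, include_hazard = FALSE) {
  gh <- state_gh(state, data$z)
  lp <- drop(data$x %*% state$beta) + gh[, 1]
  if (isTRUE(state$has_cp)) {
    ind <- as.numeric(data$e > state$zeta)
    lp <- lp + (drop(data$x %*% state$gamma) + gh[, 2]) * ind
  }
  if (!all(is.finite(lp))) {
    stop("non-finite linear predictor; first offending row: ",
         which(!is.finite(lp))[1])
  }
  if (include_hazard) lp + log(pmax(hazard_eval(state$hazard, data$u), 0)) else lp
}

#' Conditional cumulative hazard scale h_eta(V)
#'
#' The per-subject quantity `h_i = Lambda(U_i) * exp{beta'X_i + g(Z_i) +
#' (gamma'X_i + h(Z_i)) 1{E_i > zeta}}` at a model state, floored at 1e-12
#' for numerical safety. The threshold is strict: a subject with
#' `E == zeta` belongs to the no-jump group.
#'
#' @param state a `cscp_state` (e.g. `fit$state` from [cscp_fit()]).
#' @param data a `cscp_data` object.
#' @return positive numeric vector of length n.
#' @export
h_eta <- function(state, data) {
  lam <- hazard_eval(state$hazard, data$u)
  pmax(lam * clip_exp(state_linpred(state, data)), H_FLOOR)
}

#' Current status log-likelihood
#'
#' `l_n = n^-1 sum_i [delta_i log(1 - exp(-h_i)) - (1 - delta_i) h_i]`,
#' computed with a branch-stable `log(1 - exp(-x))`. Rows with
#' `delta = 1` and `h` at the numerical floor contribute through the floor
#' (the likelihood diverges to -Inf there); a warning reports how many
#' such rows were floored.
#'
#' @inheritParams h_eta
#' @return scalar mean log-likelihood.
#' @export
cs_loglik <- function(state, data) {
  mean(cs_loglik_rows(state, data))
}

cs_loglik_rows <- function(state, data) {
  h <- h_eta(state, data)
  nfloor <- sum(data$delta == 1 & h <= H_FLOOR)
  if (nfloor > 0)
    warning(nfloor, " event row(s) hit the hazard floor (likelihood -Inf region)")
  data$delta * log1mexp(h) - (1 - data$delta) * h
}

# Likelihood from precomputed pieces (hot path of the profiling loop):
# lam_u = Lambda(U), lp = full linear predictor.
loglik_from_parts <- function(delta, lam_u, lp) {
  h <- pmax(lam_u * clip_exp(lp), H_FLOOR)
  mean(delta * log1mexp(h) - (1 - delta) * h)
}

#' Score weight Q(Y; xi, zeta)
#'
#' The scalar factor of the score function:
#' `Q_i = h_i * [delta_i exp(-h_i)/(1 - exp(-h_i)) - (1 - delta_i)]`.
#' Event rows contribute positively, censored rows contribute `-h_i`. The
#' score of the regression parameters is `colMeans(Xtilde * Q)`.
#'
#' @inheritParams h_eta
#' @return numeric vector of length n.
#' @export
q_weight <- function(state, data) {
  h <- h_eta(state, data)
  h * (data$delta / expm1(h) - (1 - data$delta))
}

# Xtilde(zeta) = (X', X' 1{E > zeta})' as an n x 2p matrix (n x p when the
# state has no change-point term).
xtilde <- function(data, zeta, has_cp = TRUE) {
  if (!has_cp) return(data$x)
  ind <- as.numeric(data$e > zeta)
  cbind(data$x, data$x * ind)
}

# Analytic score of the regression parameters at a state.
score_theta <- function(state, data) {
  q <- q_weight(state, data)
  colMeans(xtilde(data, state$zeta, state$has_cp) * q)
}
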