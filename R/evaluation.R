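#' Relative error of a nonparametric effect estimate
#'
#' `RE = sqrt( sum_i{(ghat_i - mean(ghat)) - g0_i}^2 / sum_i g0_i^2 )`,
#' evaluated on a test set: the estimate is centered (it is identified
#' only up to an additive constant) while the truth is not. The
#' per-observation prediction errors `ghat_i - g0_i` are returned as an
#' attribute.
#'
#' @param g_hat estimated values on the test set.
#' @param g_true true values on the same test set.
#' @return scalar RE with attribute `errors`.
#' @export
relative_error <- function(g_hat, g_true) {
  if (length(g_hat) != length(g_true) || length(g_true) < 2L)
    stop("'g_hat' and 'g_true' must have equal length >= 2")
  denom <- sum(g_true^2)
  if (denom == 0) stop("relative error undefined: sum(g_true^2) is zero")
  num <- sum(((g_hat - mean(g_hat)) - g_true)^2)
  structure(sqrt(num / denom), errors = g_hat - g_true)
}

#' Empirical 95% interval length of change-point estimates
#'
#' The difference between the 97.5% and 2.5% empirical quantiles (linear
#' interpolation, R's default type-7 convention) of the change-point
#' estimates across replications.
#'
#' @param estimates numeric vector of per-replication estimates (>= 2).
#' @return scalar length.
#' @export
zeta_ci_length <- function(estimates) {
  if (length(estimates) < 2L) stop("need at least 2 estimates")
  qs <- stats::quantile(estimates, c(0.025, 0.975), names = FALSE, type = 7)
  qs[2] - qs[1]
}

#' Replication harness for the simulation designs
#'
#' For `m = 1..M`: simulates a dataset with seed `base_seed + m`, fits the
#' requested model(s), computes Wald standard errors, and evaluates the
#' relative errors of the fitted (g, h) on a fresh covariate test set of
#' size `n_test`. Aggregates per-parameter Bias, SSE (sampling standard
#' deviation), mean ESE and 95% coverage, the RE summaries, and the
#' change-point Bias / 95% interval length / SSE. Replications that fail
#' are recorded and excluded (the summary reports the count).
#'
#' @param case effect case (1, 2 or 3).
#' @param n sample size per replication.
#' @param M number of replications.
#' @param models character vector of model kinds for [cscp_fit()].
#' @param control a [cscp_control()].
#' @param base_seed integer; replication m uses seed `base_seed + m`.
#' @param n_test test-set size for the relative errors (default 200).
#' @param sim_args extra arguments passed to [cscp_sim_config()].
#' @return object of class `cscp_simsummary` with `records` (one row per
#'   replication and model) and `summary` (one row per model).
#' @export
cscp_replicate <- function(case, n, M, models = "deep-cp",
                           control = cscp_control(), base_seed = 1L,
                           n_test = 200L, sim_args = list()) {
  theta0 <- sim_args$theta0 %||% c(-1, 2)
  zeta0 <- sim_args$zeta0 %||% 2
  if (!all(vapply(models, model_has_cp, logical(1))))
    stop("the replication harness summarizes change-point models only")
  recs <- list()
  failures <- 0L
  for (m in seq_len(M)) {
    cfg <- do.call(cscp_sim_config,
                   c(list(n = n, case = case, seed = base_seed + m), sim_args))
    dat <- cscp_simulate(cfg)
    tcfg <- do.call(cscp_sim_config,
                    c(list(n = n_test, case = case, seed = base_seed + 500000L + m),
                      sim_args))
    test_cov <- cscp_sample_covariates(tcfg)
    tr <- cscp_truth(case, center = cfg$center_truth)
    g0t <- tr$g0(test_cov$z)
    h0t <- tr$h0(test_cov$z)
    for (model in models) {
      ctl <- control
      ctl$seed <- base_seed + 900000L + m
      rec <- tryCatch({
        fit <- cscp_fit(dat, model = model, control = ctl)
        wd <- cscp_wald(fit, dat)
        gh <- cscp_predict_gh(fit, test_cov$z)
        re_g <- as.numeric(relative_error(gh[, 1], g0t))
        re_h <- as.numeric(relative_error(gh[, 2], h0t))
        p <- dat$p
        data.frame(
          rep = m, model = model,
          beta = fit$beta[1], gamma = fit$gamma[1],
          ese_beta = wd$ese[1], ese_gamma = wd$ese[p + 1],
          cover_beta = wd$table$lower[1] <= theta0[1] &
            theta0[1] <= wd$table$upper[1],
          cover_gamma = wd$table$lower[p + 1] <= theta0[p + 1] &
            theta0[p + 1] <= wd$table$upper[p + 1],
          zeta = fit$zeta, re_g = re_g, re_h = re_h,
          loglik = fit$loglik, converged = fit$converged,
          ascent_min = min(diff(fit$loglik_path)),
          haz_coef_min = min(fit$state$hazard$coef)
        )
      }, error = function(e) {
        warning(sprintf("replication %d (%s) failed: %s", m, model,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(rec)) failures <- failures + 1L else recs[[length(recs) + 1L]] <- rec
    }
  }
  records <- do.call(rbind, recs)
  summ <- do.call(rbind, lapply(split(records, records$model), function(d) {
    data.frame(
      model = d$model[1], M = nrow(d),
      bias_beta = mean(d$beta) - theta0[1],
      sse_beta = stats::sd(d$beta),
      ese_beta = mean(d$ese_beta),
      cp_beta = mean(d$cover_beta),
      bias_gamma = mean(d$gamma) - theta0[2],
      sse_gamma = stats::sd(d$gamma),
      ese_gamma = mean(d$ese_gamma),
      cp_gamma = mean(d$cover_gamma),
      re_g = mean(d$re_g), sse_re_g = stats::sd(d$re_g),
      re_h = mean(d$re_h), sse_re_h = stats::sd(d$re_h),
      bias_zeta = mean(d$zeta) - zeta0,
      ci_len_zeta = zeta_ci_length(d$zeta),
      sse_zeta = stats::sd(d$zeta)
    )
  }))
  structure(list(records = records, summary = summ, case = case, n = n,
                 M = M, failures = failures, theta0 = theta0, zeta0 = zeta0),
            class = "cscp_simsummary")
}

#' @export
print.cscp_simsummary <- function(x, ...) {
  cat(sprintf("Simulation summary: case %d, n = %d, M = %d (%d failure(s))\n",
              x$case, x$n, x$M, x$failures))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  model %s:\n", s$model[i]))
    cat(sprintf("    beta : Bias %8.4f  SSE %6.4f  ESE %6.4f  CP %5.3f\n",
                s$bias_beta[i], s$sse_beta[i], s$ese_beta[i], s$cp_beta[i]))
    cat(sprintf("    gamma: Bias %8.4f  SSE %6.4f  ESE %6.4f  CP %5.3f\n",
                s$bias_gamma[i], s$sse_gamma[i], s$ese_gamma[i], s$cp_gamma[i]))
    cat(sprintf("    RE(g) %6.4f (SSE %6.4f)   RE(h) %6.4f (SSE %6.4f)\n",
                s$re_g[i], s$sse_re_g[i], s$re_h[i], s$sse_re_h[i]))
    cat(sprintf("    zeta : Bias %8.4f  95%% CI length %6.4f  SSE %6.4f\n",
                s$bias_zeta[i], s$ci_len_zeta[i], s$sse_zeta[i]))
  }
  invisible(x)
}
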