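test_that("initialization follows the recommended starting values", {
  dat <- tiny_cp_data(60, seed = 14)
  ctl <- cscp_control(m_n = 9, net = net_config(seed = 1))
  st <- cscp_initial_state(dat, "deep-cp", ctl)
  expect_identical(st$beta, 0)
  expect_identical(st$gamma, 0)
  expect_equal(st$zeta, mean(dat$e))
  expect_length(st$hazard$coef, 13)
  expect_true(all(st$hazard$coef == 0.1))

  d3 <- dat; d3$e <- rep(c(1, 2, 3), 20)
  expect_equal(cscp_initial_state(d3, "deep-cp", ctl)$zeta, 2)
})

test_that("theta update is a conditional maximizer (dense grid oracle)", {
  dat <- tiny_cp_data(150, seed = 15)
  st <- cscp_initial_state(dat, "linear-cp", cscp_control(m_n = 2))
  st$zeta <- 2
  sp <- fit_spline_step(dat, st)
  st$hazard$coef <- sp$coef
  up <- update_theta(dat, st)
  expect_gte(up$loglik, cs_loglik(st, dat) - 1e-10)

  # two-stage dense grid oracle over (beta, gamma)
  lam_u <- hazard_eval(up$state$hazard, dat$u)
  ind <- as.numeric(dat$e > st$zeta)
  ll_of <- function(b, g) {
    lp <- b * dat$x[, 1] + g * dat$x[, 1] * ind
    h <- pmax(lam_u * exp(lp), 1e-12)
    mean(dat$delta * log(1 - exp(-h)) - (1 - dat$delta) * h)
  }
  coarse <- expand.grid(b = seq(-3, 1, by = 0.05), g = seq(0, 4, by = 0.05))
  vals <- mapply(ll_of, coarse$b, coarse$g)
  best <- coarse[which.max(vals), ]
  fine <- expand.grid(b = seq(best$b - 0.06, best$b + 0.06, by = 0.001),
                      g = seq(best$g - 0.06, best$g + 0.06, by = 0.001))
  vals <- mapply(ll_of, fine$b, fine$g)
  oracle <- unlist(fine[which.max(vals), ])
  expect_equal(unname(up$theta), unname(oracle), tolerance = 2e-3)

  # stationary start: returned unchanged within solver tolerance
  st2 <- up$state
  up2 <- update_theta(dat, st2)
  expect_equal(up2$theta, up$theta, tolerance = 1e-4)
})

test_that("change-point profiling equals exhaustive evaluation and respects ties", {
  dat <- tiny_cp_data(500, seed = 16)
  st <- cscp_initial_state(dat, "linear-cp", cscp_control(m_n = 2))
  st$beta <- -1; st$gamma <- 2
  sp <- fit_spline_step(dat, st)
  st$hazard$coef <- sp$coef
  pz <- profile_zeta(dat, st, gap = 0.01, trim = c(0.05, 0.95))

  # brute force: evaluate the full likelihood at every grid point
  oracle <- vapply(pz$grid, function(zt) {
    s2 <- st; s2$zeta <- zt
    cs_loglik(s2, dat)
  }, numeric(1))
  expect_equal(pz$profile, oracle, tolerance = 1e-12)
  expect_equal(pz$zeta, pz$grid[which.max(oracle)])
  expect_gte(pz$zeta, min(dat$e))
  expect_lte(pz$zeta, max(dat$e))

  # flat profile under the null: smallest grid point returned
  st$gamma <- 0
  pz0 <- profile_zeta(dat, st, gap = 0.01)
  expect_lt(diff(range(pz0$profile)), 1e-12)
  expect_equal(pz0$zeta, pz0$grid[1])
})

test_that("full fit recovers the planted parameters and keeps its invariants", {
  cfg <- cscp_sim_config(n = 1000, case = 1, seed = 20)
  dat <- cscp_simulate(cfg)
  fit <- cscp_fit(dat, "deep-cp", control = harness_control(seed = 20))

  expect_lt(abs(fit$beta - (-1)), 0.6)    # about 3x the sampling SD
  expect_lt(abs(fit$gamma - 2), 0.8)
  expect_true(all(diff(fit$loglik_path) >= -1e-6))
  expect_true(all(fit$state$hazard$coef >= 0))
  expect_true(fit$zeta > min(dat$e) && fit$zeta < max(dat$e))
  # fitted hazard is monotone
  gg <- seq(min(dat$u), max(dat$u), length.out = 200)
  expect_true(all(diff(hazard_eval(fit$state$hazard, gg)) >= -1e-10))

  # the linear benchmark is correctly specified in case 1 and recovers too
  fit_lin <- cscp_fit(dat, "linear-cp", control = cscp_control(max_outer = 15))
  expect_lt(abs(fit_lin$beta - (-1)), 0.6)
  expect_lt(abs(fit_lin$gamma - 2), 0.8)
  expect_lt(abs(fit_lin$zeta - 2), 0.2)
})

test_that("restricted null fit ignores the change-point covariate entirely", {
  dat <- tiny_cp_data(300, gamma0 = 0, seed = 25)
  ctl <- cscp_control(max_outer = 5,
                      net = net_config(depth = 1, width = 4, epochs = 20, seed = 1))
  f1 <- cscp_fit(dat, "deep-null", control = ctl)
  set.seed(31)
  datp <- dat
  datp$e <- sample(dat$e)
  f2 <- cscp_fit(datp, "deep-null", control = ctl)
  expect_equal(f1$beta, f2$beta)
  expect_equal(f1$loglik, f2$loglik)
  expect_null(f1$zeta)
})

test_that("convergence stopping rule fires on stationary theta iterates", {
  dat <- tiny_cp_data(200, seed = 26)
  ctl <- cscp_control(max_outer = 20, tol = 0.5,
                      net = net_config(depth = 1, width = 4, epochs = 10, seed = 2))
  fit <- cscp_fit(dat, "deep-cp", control = ctl)
  # a loose tolerance must stop the loop early with the converged flag set
  expect_true(fit$converged)
  expect_lt(fit$iterations, 20)
})
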