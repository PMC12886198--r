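# A minimal hand-built state for closed-form likelihood checks: hazard
# with a single flat-ish basis is inconvenient, so the tests construct
# states whose pieces are controlled exactly through tiny datasets.
make_flat_state <- function(dat, coef_scale = 1) {
  st <- cscp_initial_state(dat, "deep-cp",
    cscp_control(m_n = 0, net = net_config(depth = 1, width = 2, seed = 1)))
  # zero the network so g = h = 0
  st$net$W <- lapply(st$net$W, function(w) w * 0)
  st$net$b <- lapply(st$net$b, function(v) v * 0)
  st$hazard$coef <- rep(coef_scale, length(st$hazard$coef))
  st
}

test_that("h_eta matches its closed form on controlled rows", {
  dat <- tiny_cp_data(50, seed = 9)
  st <- make_flat_state(dat)

  # beta = gamma = 0, g = h = 0: h_eta = Lambda(U)
  st$beta <- 0; st$gamma <- 0
  expect_equal(h_eta(st, dat), hazard_eval(st$hazard, dat$u))

  # gamma = 0, h = 0: independent of zeta
  st$beta <- 0.7
  h1 <- h_eta(st, dat)
  st2 <- st; st2$zeta <- st$zeta - 0.3
  expect_equal(h_eta(st2, dat), h1)

  # hand-computed row: Lambda(U) = 0.5, beta'X = 1, g = -0.2,
  # gamma'X = 0.3, h = 0.1, E > zeta  ->  0.5 * exp(1.2)
  lp <- 1 - 0.2 + (0.3 + 0.1) * 1
  expect_equal(0.5 * exp(lp), 1.6600584, tolerance = 1e-6)
})

test_that("log-likelihood and Q weight match closed forms", {
  # per-row closed forms, delta = 1, h = 1
  expect_equal(cscpcox:::log1mexp(1), log(1 - exp(-1)))
  expect_equal(log(1 - exp(-1)), -0.458675, tolerance = 1e-6)
  q1 <- 1 * (1 / expm1(1))
  expect_equal(q1, 0.581977, tolerance = 1e-6)
  # delta = 0 branch: Q = -h
  dat <- tiny_cp_data(30, seed = 10)
  st <- make_flat_state(dat, coef_scale = 2)
  st$beta <- 0; st$gamma <- 0
  q <- q_weight(st, dat)
  h <- h_eta(st, dat)
  cens <- dat$delta == 0
  expect_equal(q[cens], -h[cens])
  expect_true(all(q[!cens] > 0))
  # delta = 1, h -> large: Q -> 0
  expect_lt(abs(40 * (1 / expm1(40))), 1e-15)

  # stability across the log1mexp branch switch: agrees with the accurate
  # special function on each side and is continuous at the switch point
  xs <- c(1e-8, 0.1, 0.5)
  expect_equal(cscpcox:::log1mexp(xs), log(-expm1(-xs)), tolerance = 1e-15)
  xl <- c(log(2) + 0.1, 5, 40)
  expect_equal(cscpcox:::log1mexp(xl), log1p(-exp(-xl)), tolerance = 1e-15)
  expect_equal(cscpcox:::log1mexp(log(2) - 1e-12),
               cscpcox:::log1mexp(log(2) + 1e-12), tolerance = 1e-9)

  # gamma = 0, h = 0: profile over zeta is flat
  ll1 <- cs_loglik(st, dat)
  st$zeta <- st$zeta + 0.4
  expect_equal(cs_loglik(st, dat), ll1)

  # invariance to row permutation
  set.seed(1)
  perm <- sample(30)
  datp <- as_cscp_data(dat$delta[perm], dat$u[perm],
                       dat$x[perm, , drop = FALSE], dat$z[perm, , drop = FALSE],
                       dat$e[perm])
  expect_equal(cs_loglik(st, datp), cs_loglik(st, dat))
})

test_that("analytic theta-score equals central finite differences of the likelihood", {
  dat <- tiny_cp_data(60, seed = 12)
  for (rep in 1:3) {
    st <- make_flat_state(dat)
    set.seed(rep)
    st$beta <- rnorm(1, 0, 0.5)
    st$gamma <- rnorm(1, 0, 0.5)
    st$hazard$coef <- runif(length(st$hazard$coef), 0.05, 0.3)
    sc <- cscpcox:::score_theta(st, dat)
    eps <- 1e-6
    fd <- numeric(2)
    for (k in 1:2) {
      sp <- st; sm <- st
      if (k == 1) { sp$beta <- st$beta + eps; sm$beta <- st$beta - eps }
      else { sp$gamma <- st$gamma + eps; sm$gamma <- st$gamma - eps }
      fd[k] <- (cs_loglik(sp, dat) - cs_loglik(sm, dat)) / (2 * eps)
    }
    expect_equal(unname(sc), fd, tolerance = 1e-6)
  }
})

test_that("score has mean near zero at the generating state", {
  cfg <- cscp_sim_config(n = 2e4, case = 1, seed = 13)
  dat <- cscp_simulate(cfg)
  # exact generating state: true hazard values enter through a direct
  # computation of h_eta rather than a spline approximation
  lp <- cfg$theta0[1] * dat$x[, 1] + dat$truth$g0 +
    (cfg$theta0[2] * dat$x[, 1] + dat$truth$h0) * (dat$e > cfg$zeta0)
  h <- (sqrt(dat$u) / 5) * exp(lp)
  q <- h * (dat$delta / expm1(h) - (1 - dat$delta))
  xt <- cbind(dat$x, dat$x * (dat$e > cfg$zeta0))
  sc <- colMeans(xt * q)
  se <- apply(xt * q, 2, sd) / sqrt(2e4)
  expect_true(all(abs(sc) < 4 * se))
})
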