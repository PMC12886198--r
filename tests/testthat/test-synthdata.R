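test_that("covariate sampler matches its laws and is seed-deterministic", {
  cfg <- cscp_sim_config(n = 1e5, case = 1, seed = 101)
  cov <- cscp_sample_covariates(cfg)

  # Bernoulli(0.5) treatments, truncated-normal change variable symmetric
  # about its mean
  expect_true(abs(mean(cov$x) - 0.5) < 3 * 0.5 / sqrt(1e5))
  expect_true(all(cov$x %in% c(0, 1)))
  expect_true(abs(mean(cov$e) - 2) < 3 * sd(cov$e) / sqrt(1e5))
  expect_true(all(cov$e >= 1.5 & cov$e <= 2.5))
  expect_true(all(cov$z >= 0 & cov$z <= 2))

  # bitwise determinism
  cov2 <- cscp_sample_covariates(cfg)
  expect_identical(cov, cov2)

  # pairwise correlations of Z against an independently coded rejection
  # sampler for the truncated t
  set.seed(999)
  r <- 5
  sig <- matrix(0.5, r, r); diag(sig) <- 1
  ch <- chol(sig)
  kept <- matrix(numeric(0), 0, r)
  while (nrow(kept) < 5e4) {
    m <- 5e4
    tt <- (matrix(rnorm(m * r), m, r) %*% ch) / sqrt(rchisq(m, 5) / 5)
    kept <- rbind(kept, tt[apply(tt >= 0 & tt <= 2, 1, all), , drop = FALSE])
  }
  oracle_cor <- cor(kept[seq_len(5e4), ])
  impl_cor <- cor(cov$z)
  expect_lt(max(abs(impl_cor - oracle_cor)), 0.02)
})

test_that("truth functions reproduce the printed constants and the centering property", {
  z0 <- matrix(0, 1, 5)
  raw <- cscp_truth(1, center = FALSE)
  expect_equal(raw$g0(z0), 0.94)
  expect_equal(raw$h0(z0), 0.71)
  raw2 <- cscp_truth(2, center = FALSE)
  expect_equal(raw2$g0(z0), exp(0) / 5 - 1.62)   # = -1.42

  # centered versions have near-zero mean under the covariate law
  cov <- cscp_sample_covariates(cscp_sim_config(n = 1e5, case = 1, seed = 55))
  for (case in 1:3) {
    tr <- cscp_truth(case, center = TRUE)
    # tolerance: MC error of this draw plus the 1e-4 rounding of the
    # frozen offsets
    expect_lt(abs(mean(tr$g0(cov$z))), 0.02)
    expect_lt(abs(mean(tr$h0(cov$z))), 0.02)
  }

  # formulas contain sqrt/log terms defined on [0,2] only
  expect_error(cscp_truth(2)$g0(matrix(-0.5, 1, 5)), "0,2")
  expect_error(cscp_truth(1)$g0(matrix(3, 1, 5)), "0,2")
})

test_that("failure times follow the inverted cumulative hazard model", {
  bl <- cscpcox:::baseline_funs("sqrt")
  # inverse-function identity
  for (y in c(0.1, 1, 3)) expect_equal(bl$Lambda(bl$Lambda_inv(y)), y)

  # with zero linear predictor the median failure time is (5 log 2)^2
  set.seed(42)
  tmed <- median(bl$Lambda_inv(-log(runif(2e5))))
  expect_lt(abs(tmed - (5 * log(2))^2) / (5 * log(2))^2, 0.02)

  cfg <- cscp_sim_config(n = 4000, case = 1, seed = 7)
  dat <- cscp_simulate(cfg)
  # non-degenerate censoring mix under the default examination-time law
  expect_gt(mean(dat$delta), 0.1)
  expect_lt(mean(dat$delta), 0.9)
  # the status indicator is exactly 1{T <= U}
  expect_identical(dat$delta, as.integer(dat$truth$t <= dat$u))

  # identical config => bitwise-identical datasets
  expect_identical(cscp_simulate(cfg), dat)
})

test_that("conditional law of delta given (U, linear predictor) matches the model", {
  cfg <- cscp_sim_config(n = 3e4, case = 1, seed = 31)
  dat <- cscp_simulate(cfg)
  beta0 <- cfg$theta0[1]; gamma0 <- cfg$theta0[2]
  lp <- beta0 * dat$x[, 1] + dat$truth$g0 +
    (gamma0 * dat$x[, 1] + dat$truth$h0) * (dat$e > cfg$zeta0)
  pred <- 1 - exp(-(sqrt(dat$u) / 5) * exp(lp))
  bins <- cut(pred, breaks = quantile(pred, 0:20 / 20), include.lowest = TRUE)
  obs <- tapply(dat$delta, bins, mean)
  exp_p <- tapply(pred, bins, mean)
  nb <- tapply(pred, bins, length)
  se <- sqrt(exp_p * (1 - exp_p) / nb)
  expect_true(all(abs(obs - exp_p) < pmax(4 * se, 0.02)))
})

test_that("dataset validation rejects malformed inputs", {
  expect_error(as_cscp_data(c(0, 2), c(1, 1), matrix(0, 2, 1),
                            matrix(0, 2, 2), c(1, 2)), "row: 2")
  expect_error(as_cscp_data(c(0, 1), c(1, -1), matrix(0, 2, 1),
                            matrix(0, 2, 2), c(1, 2)), "row: 2")
  expect_error(as_cscp_data(c(0, 1), c(1, 1), matrix(c(0, NA), 2, 1),
                            matrix(0, 2, 2), c(1, 2)), "finite")
})
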