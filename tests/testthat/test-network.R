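test_that("network initialization and forward pass honor their contracts", {
  cfg <- net_config(depth = 2, width = 8, seed = 77)
  n1 <- net_init(cfg, 5)
  n2 <- net_init(cfg, 5)
  expect_identical(n1$W, n2$W)

  z <- matrix(runif(40 * 5, 0, 2), 40, 5)
  out <- net_forward(n1, z)
  expect_equal(dim(out), c(40, 2))
  expect_true(all(is.finite(out)))

  # all-zero parameters give identically zero outputs
  n0 <- n1
  n0$W <- lapply(n0$W, function(w) w * 0)
  n0$b <- lapply(n0$b, function(v) v * 0)
  expect_equal(net_forward(n0, z), matrix(0, 40, 2))

  # permutation equivariance over rows
  perm <- sample(40)
  expect_equal(net_forward(n1, z[perm, ]), out[perm, ])

  # output clamp
  cfgb <- net_config(depth = 1, width = 4, output_bound = 0.01, seed = 1)
  nb <- net_init(cfgb, 5)
  expect_true(all(abs(net_forward(nb, z)) <= 0.01))
})

test_that("analytic network gradients match central finite differences", {
  set.seed(7)
  n <- 10; r <- 5
  z <- matrix(runif(n * r, 0, 2), n, r)
  delta <- rbinom(n, 1, 0.5)
  lam_u <- runif(n, 0.1, 1)
  off0 <- rnorm(n, 0, 0.5); off1 <- rnorm(n, 0, 0.5)
  ind <- rbinom(n, 1, 0.5)
  net <- net_init(net_config(depth = 2, width = 4, dropout = 0, seed = 1), r)
  lg <- cscpcox:::net_loss_grad(net, z, delta, lam_u, off0, off1, ind)
  eps <- 1e-5
  for (k in seq_along(net$W)) {
    idx <- seq_len(min(4, length(net$W[[k]])))
    for (i in idx) {
      np <- net; np$W[[k]][i] <- np$W[[k]][i] + eps
      nm <- net; nm$W[[k]][i] <- nm$W[[k]][i] - eps
      fd <- (cscpcox:::net_loss_grad(np, z, delta, lam_u, off0, off1, ind)$loss -
             cscpcox:::net_loss_grad(nm, z, delta, lam_u, off0, off1, ind)$loss) / (2 * eps)
      expect_equal(lg$gW[[k]][i], fd,
                   tolerance = 1e-4 * max(abs(fd), 1e-6))
    }
    bp <- net; bp$b[[k]][1] <- bp$b[[k]][1] + eps
    bm <- net; bm$b[[k]][1] <- bm$b[[k]][1] - eps
    fd <- (cscpcox:::net_loss_grad(bp, z, delta, lam_u, off0, off1, ind)$loss -
           cscpcox:::net_loss_grad(bm, z, delta, lam_u, off0, off1, ind)$loss) / (2 * eps)
    expect_equal(lg$gb[[k]][1], fd, tolerance = 1e-4 * max(abs(fd), 1e-6))
  }
})

test_that("training step is a no-op at zero epochs and never worsens the loss", {
  dat <- tiny_cp_data(100, seed = 2)
  ctl <- cscp_control(net = net_config(depth = 1, width = 4, seed = 3))
  st <- cscp_initial_state(dat, "deep-cp", ctl)
  res0 <- fit_network_step(dat, st, epochs = 0)
  expect_identical(res0$net$W, st$net$W)
  res <- fit_network_step(dat, st, epochs = 30)
  expect_lte(res$loss_end, res$loss_start + 1e-10)
})

test_that("weight clipping keeps every augmented weight matrix in [-1, 1]", {
  dat <- tiny_cp_data(100, seed = 4)
  ctl <- cscp_control(net = net_config(depth = 2, width = 4, lr = 0.05,
                                       weight_clip = TRUE, seed = 5))
  st <- cscp_initial_state(dat, "deep-cp", ctl)
  res <- fit_network_step(dat, st, epochs = 50)
  for (k in seq_along(res$net$W)) {
    expect_lte(max(abs(res$net$W[[k]])), 1)
    expect_lte(max(abs(res$net$b[[k]])), 1)
  }
})

test_that("with other components at truth, training recovers signal (RE < 1)", {
  cfg <- cscp_sim_config(n = 2000, case = 1, seed = 21)
  dat <- cscp_simulate(cfg)
  st <- cscp_initial_state(dat, "deep-cp",
    cscp_control(net = net_config(depth = 2, width = 16, epochs = 400,
                                  lr = 1e-3, dropout = 0.1, seed = 22)))
  st$beta <- cfg$theta0[1]; st$gamma <- cfg$theta0[2]; st$zeta <- cfg$zeta0
  lam_true <- sqrt(dat$u) / 5
  res <- fit_network_step(dat, st, lam_u = lam_true)
  # held-out evaluation against the generating truth
  test_cov <- cscp_sample_covariates(cscp_sim_config(n = 500, case = 1, seed = 23))
  tr <- cscp_truth(1)
  gh <- net_forward(res$net, test_cov$z)
  re_g <- as.numeric(relative_error(gh[, 1], tr$g0(test_cov$z)))
  expect_lt(re_g, 1)  # better than the zero predictor
})
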