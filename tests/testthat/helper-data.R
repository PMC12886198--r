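# Small dataset builders shared across test files.

# Tiny dataset with no nonparametric structure (g = h = 0 in truth):
# T drawn by inversion under Lambda0(t) = sqrt(t)/5 with linear predictor
# beta0*x + gamma0*x*1{e > zeta0}.
tiny_cp_data <- function(n, beta0 = -1, gamma0 = 2, zeta0 = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rbinom(n, 1, 0.5))
  z <- matrix(runif(n * 5, 0, 2), n, 5)
  e <- runif(n, 1.5, 2.5)
  lp <- beta0 * x[, 1] + gamma0 * x[, 1] * (e > zeta0)
  tfail <- 25 * (-log(runif(n)) * exp(-lp))^2
  u <- runif(n, 0.1, 20)
  as_cscp_data(as.integer(tfail <= u), u, x, z, e,
               truth = list(t = tfail, g0 = numeric(n), h0 = numeric(n)))
}

# Default scaled-study fit control used throughout the suite.
harness_control <- function(seed = NULL) {
  cscp_control(net = net_config(depth = 2, width = 16, epochs = 50,
                                lr = 1e-3, dropout = 0.1),
               max_outer = 10L, seed = seed)
}
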