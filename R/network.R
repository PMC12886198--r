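#' Configuration of the two-headed ReLU network
#'
#' The nonparametric effects (g, h) are modeled jointly by one feed-forward
#' ReLU network with a two-dimensional output head, trained by full-batch
#' backpropagation with the Adam optimizer on the negative log-likelihood.
#' Dropout on the hidden layers is the operative regularizer; the
#' theoretical sparsity and sup-norm bounds of the network class can be
#' enforced literally through `weight_clip` (clamps every entry of the
#' augmented weight matrices to \[-1, 1\] after each update) and
#' `output_bound` (clamps the outputs to \[-D, D\] in the forward pass).
#'
#' @param depth number of hidden layers K (default 2).
#' @param width hidden-layer width, scalar or length-`depth` vector
#'   (default 32).
#' @param dropout dropout rate on hidden activations during training,
#'   in \[0, 1) (default 0.1).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs full-batch training epochs per block update (default 200).
#' @param weight_clip logical; enforce the unit sup-norm bound on the
#'   augmented weight matrices (default `FALSE`).
#' @param output_bound optional positive D clamping the outputs.
#' @param seed integer seed for the (reproducible) initialization.
#' @return object of class `cscp_net_config`.
#' @export
net_config <- function(depth = 2L, width = 32L, dropout = 0.1,
                       lr = 1e-3, epochs = 200L,
                       weight_clip = FALSE, output_bound = NULL,
                       seed = NULL) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("'depth' must be >= 1")
  widths <- as.integer(rep(width, length.out = depth))
  if (any(widths < 1L)) stop("widths must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)")
  stopifnot_scalar(lr, "lr", positive = TRUE)
  structure(list(depth = depth, widths = widths, dropout = dropout,
                 lr = lr, epochs = as.integer(epochs),
                 weight_clip = isTRUE(weight_clip),
                 output_bound = output_bound, seed = seed),
            class = "cscp_net_config")
}

#' Initialize a two-headed ReLU network
#'
#' He-scaled Gaussian initialization for the hidden layers and a
#' small-scale Gaussian for the output head (so the initial nonparametric
#' effects are near zero, matching the near-null starting point of the
#' profiling algorithm). Reproducible given `cfg$seed`.
#'
#' @param cfg a [net_config()] object.
#' @param input_dim dimension r of the covariate Z.
#' @param out_dim output head width (2: the (g, h) pair).
#' @return object of class `two_head_net`.
#' @export
net_init <- function(cfg, input_dim, out_dim = 2L) {
  stopifnot(inherits(cfg, "cscp_net_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dims <- c(as.integer(input_dim), cfg$widths, as.integer(out_dim))
  nl <- length(dims) - 1L
  W <- vector("list", nl)
  b <- vector("list", nl)
  for (k in seq_len(nl)) {
    fan_in <- dims[k]
    sdv <- if (k < nl) sqrt(2 / fan_in) else 0.1 / sqrt(fan_in)
    W[[k]] <- matrix(stats::rnorm(dims[k + 1] * dims[k], sd = sdv),
                     dims[k + 1], dims[k])
    b[[k]] <- rep(0, dims[k + 1])
  }
  structure(list(W = W, b = b, dims = dims, cfg = cfg), class = "two_head_net")
}

#' Forward pass of the two-headed network
#'
#' Deterministic evaluation-mode forward pass: no dropout. Returns the
#' n-by-2 matrix of (g, h) values (n-by-`out_dim` in general).
#'
#' @param net a `two_head_net`.
#' @param z n-by-r input matrix.
#' @return numeric matrix of outputs.
#' @export
net_forward <- function(net, z) {
  a <- as.matrix(z)
  nl <- length(net$W)
  for (k in seq_len(nl - 1L)) {
    a <- pmax(sweep(a %*% t(net$W[[k]]), 2, net$b[[k]], "+"), 0)
  }
  out <- sweep(a %*% t(net$W[[nl]]), 2, net$b[[nl]], "+")
  d <- net$cfg$output_bound
  if (!is.null(d)) out <- pmin(pmax(out, -d), d)
  out
}

# Forward pass with caches (and optional dropout masks) for backprop.
net_forward_train <- function(net, z, dropout = 0) {
  nl <- length(net$W)
  h <- vector("list", nl)      # activations entering layer k (h[[1]] = z)
  h[[1]] <- as.matrix(z)
  pre <- vector("list", nl - 1L)
  masks <- vector("list", nl - 1L)
  for (k in seq_len(nl - 1L)) {
    a <- sweep(h[[k]] %*% t(net$W[[k]]), 2, net$b[[k]], "+")
    pre[[k]] <- a
    act <- pmax(a, 0)
    if (dropout > 0) {
      m <- matrix(stats::rbinom(length(act), 1L, 1 - dropout), nrow(act)) / (1 - dropout)
      masks[[k]] <- m
      act <- act * m
    }
    h[[k + 1L]] <- act
  }
  out <- sweep(h[[nl]] %*% t(net$W[[nl]]), 2, net$b[[nl]], "+")
  list(out = out, h = h, pre = pre, masks = masks)
}

# Backprop of dLoss/dout through the network; returns per-layer gradients.
net_backprop <- function(net, cache, gout) {
  nl <- length(net$W)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  g <- gout
  for (k in rev(seq_len(nl))) {
    gW[[k]] <- t(g) %*% cache$h[[k]]
    gb[[k]] <- colSums(g)
    if (k > 1L) {
      g <- g %*% net$W[[k]]
      g <- g * (cache$pre[[k - 1L]] > 0)
      if (!is.null(cache$masks[[k - 1L]])) g <- g * cache$masks[[k - 1L]]
    }
  }
  list(W = gW, b = gb)
}

# Negative log-likelihood pieces for the network step: Lambda(U), the
# fixed linear offsets and the jump indicator are held constant.
net_loss_parts <- function(out, delta, lam_u, off0, off1, ind) {
  g <- out[, 1]
  hfun <- if (ncol(out) >= 2L) out[, 2] else 0
  lp <- off0 + g + (off1 + hfun) * ind
  h <- pmax(lam_u * clip_exp(lp), H_FLOOR)
  qv <- h * (delta / expm1(h) - (1 - delta))
  loss <- -mean(delta * log1mexp(h) - (1 - delta) * h)
  list(loss = loss, q = qv)
}

# Loss and analytic parameter gradients at the current weights (no
# dropout, no update); used for gradient verification.
net_loss_grad <- function(net, z, delta, lam_u, off0, off1, ind) {
  cache <- net_forward_train(net, z, dropout = 0)
  parts <- net_loss_parts(cache$out, delta, lam_u, off0, off1, ind)
  n <- length(delta)
  gout <- -cbind(parts$q, parts$q * ind) / n
  gout <- gout[, seq_len(ncol(cache$out)), drop = FALSE]
  gr <- net_backprop(net, cache, gout)
  list(loss = parts$loss, gW = gr$W, gb = gr$b)
}

#' Network training step of the profiling algorithm
#'
#' Trains the (g, h) heads jointly by full-batch Adam on the negative
#' log-likelihood with the baseline hazard, regression parameters and
#' change point held fixed. If training ends at a worse evaluation-mode
#' loss than it started (possible under dropout noise), the incoming
#' network is returned unchanged, so the block-ascent property of the
#' outer loop is preserved. Training aborts with diagnostics if the loss
#' becomes non-finite.
#'
#' @param data a `cscp_data` object.
#' @param state model state holding the fixed components (`hazard`,
#'   `beta`, `gamma`, `zeta`) and the current network `net`.
#' @param epochs optional override of the configured epoch count.
#' @param lam_u optional precomputed `Lambda(U)` vector.
#' @return list with the updated `net`, the per-epoch training `loss`
#'   history, and evaluation-mode `loss_start` / `loss_end`.
#' @export
fit_network_step <- function(data, state, epochs = NULL, lam_u = NULL) {
  net <- state$net
  cfg <- net$cfg
  epochs <- epochs %||% cfg$epochs
  if (is.null(lam_u)) lam_u <- hazard_eval(state$hazard, data$u)
  off0 <- drop(data$x %*% state$beta)
  if (isTRUE(state$has_cp)) {
    off1 <- drop(data$x %*% state$gamma)
    ind <- as.numeric(data$e > state$zeta)
  } else {
    off1 <- numeric(length(data$delta))
    ind <- numeric(length(data$delta))
  }
  eval_loss <- function(nn) {
    net_loss_parts(net_forward(nn, data$z), data$delta, lam_u, off0, off1, ind)$loss
  }
  loss0 <- eval_loss(net)
  if (epochs <= 0L)
    return(list(net = net, loss = numeric(0), loss_start = loss0, loss_end = loss0))

  n <- length(data$delta)
  nl <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(v) v * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$lr
  hist <- numeric(epochs)
  for (t in seq_len(epochs)) {
    cache <- net_forward_train(net, data$z, dropout = cfg$dropout)
    parts <- net_loss_parts(cache$out, data$delta, lam_u, off0, off1, ind)
    if (!is.finite(parts$loss)) {
      stop(sprintf(paste0("non-finite network training loss at epoch %d ",
                          "(|q| max %.3g, output range [%.3g, %.3g])"),
                   t, max(abs(parts$q)), min(cache$out), max(cache$out)))
    }
    hist[t] <- parts$loss
    gout <- -cbind(parts$q, parts$q * ind) / n
    gout <- gout[, seq_len(ncol(cache$out)), drop = FALSE]
    gr <- net_backprop(net, cache, gout)
    corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
    for (k in seq_len(nl)) {
      mW[[k]] <- b1 * mW[[k]] + (1 - b1) * gr$W[[k]]
      vW[[k]] <- b2 * vW[[k]] + (1 - b2) * gr$W[[k]]^2
      net$W[[k]] <- net$W[[k]] - lr * (mW[[k]] / corr1) / (sqrt(vW[[k]] / corr2) + eps)
      mb[[k]] <- b1 * mb[[k]] + (1 - b1) * gr$b[[k]]
      vb[[k]] <- b2 * vb[[k]] + (1 - b2) * gr$b[[k]]^2
      net$b[[k]] <- net$b[[k]] - lr * (mb[[k]] / corr1) / (sqrt(vb[[k]] / corr2) + eps)
      if (cfg$weight_clip) {
        net$W[[k]] <- pmin(pmax(net$W[[k]], -1), 1)
        net$b[[k]] <- pmin(pmax(net$b[[k]], -1), 1)
      }
    }
  }
  loss1 <- eval_loss(net)
  if (!is.finite(loss1) || loss1 > loss0) {
    # dropout noise left us worse off: keep the incoming network
    return(list(net = state$net, loss = hist, loss_start = loss0, loss_end = loss0))
  }
  list(net = net, loss = hist, loss_start = loss0, loss_end = loss1)
}
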