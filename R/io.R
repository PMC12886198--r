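#' Write a current status dataset to CSV
#'
#' Flat delimited format with header `delta,u,x1..xp,z1..zr,e`; when the
#' dataset carries a latent truth block and `truth = TRUE`, columns
#' `t_true,g0,h0` are appended. Floating point values are written with 17
#' significant digits so a write/read cycle is exact.
#'
#' @param data a `cscp_data`.
#' @param path output file path.
#' @param truth include the truth columns when available?
#' @return `path`, invisibly.
#' @export
write_cscp <- function(data, path, truth = FALSE) {
  stopifnot(inherits(data, "cscp_data"))
  p <- data$p
  r <- data$r
  cols <- list(delta = data$delta, u = data$u)
  for (j in seq_len(p)) cols[[paste0("x", j)]] <- data$x[, j]
  for (j in seq_len(r)) cols[[paste0("z", j)]] <- data$z[, j]
  cols$e <- data$e
  if (truth && !is.null(data$truth)) {
    cols$t_true <- data$truth$t
    cols$g0 <- data$truth$g0
    cols$h0 <- data$truth$h0
  }
  fmt <- function(v) if (is.integer(v)) as.character(v) else sprintf("%.17g", v)
  mat <- do.call(cbind, lapply(cols, fmt))
  lines <- c(paste(names(cols), collapse = ","),
             apply(mat, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a current status dataset from CSV
#'
#' Parses a delimited file into a validated `cscp_data`. Column roles are
#' taken from the header by default (`delta`, `u`, `e`, `x*`-prefixed
#' treatment columns, `z*`-prefixed nonparametric columns) or can be named
#' explicitly, so arbitrary real datasets can be mapped without
#' preprocessing. Validation is strict: `delta` must be exactly 0 or 1,
#' `u` positive, and no missing values are allowed; errors name the first
#' offending row.
#'
#' @param path input file path.
#' @param delta_col,u_col,e_col column names of the status indicator,
#'   examination time and change-point covariate.
#' @param x_cols,z_cols character vectors of treatment / nonparametric
#'   column names; `NULL` selects by `x`/`z` prefix.
#' @return a `cscp_data`.
#' @export
read_cscp <- function(path, delta_col = "delta", u_col = "u", e_col = "e",
                      x_cols = NULL, z_cols = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c(delta_col, u_col, e_col)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  others <- setdiff(names(df), c(need, "t_true", "g0", "h0"))
  if (is.null(x_cols)) x_cols <- others[startsWith(others, "x")]
  if (is.null(z_cols)) z_cols <- others[startsWith(others, "z")]
  if (length(x_cols) < 1L || length(z_cols) < 1L)
    stop("need at least one treatment (x) and one nonparametric (z) column")
  if (anyNA(df[, c(need, x_cols, z_cols)]))
    stop("missing values are not supported; first offending row: ",
         which(rowSums(is.na(df[, c(need, x_cols, z_cols)])) > 0)[1])
  truth <- if (all(c("t_true", "g0", "h0") %in% names(df)))
    list(t = df$t_true, g0 = df$g0, h0 = df$h0) else NULL
  new_cscp_data(df[[delta_col]], df[[u_col]],
                as.matrix(df[, x_cols, drop = FALSE]),
                as.matrix(df[, z_cols, drop = FALSE]),
                df[[e_col]], truth = truth)
}

#' Serialize a fitted model to a plain list / JSON
#'
#' Bundles the spline hazard, regression parameters, change point and the
#' nonparametric-effect representation (network architecture + weights, or
#' linear coefficients) into a plain list that `jsonlite` round-trips.
#'
#' @param fit a `cscp_fit`.
#' @return plain list (use `jsonlite::write_json(..., digits = NA)`).
#' @export
cscp_serialize <- function(fit) {
  st <- fit$state
  out <- list(
    model = fit$model,
    hazard = hazard_serialize(st$hazard),
    beta = st$beta, gamma = st$gamma, zeta = st$zeta,
    gh_kind = st$gh_kind,
    loglik = fit$loglik, converged = fit$converged,
    iterations = fit$iterations
  )
  if (st$gh_kind == "deep") {
    out$net <- list(dims = st$net$dims,
                    W = lapply(st$net$W, function(m) unclass(m)),
                    b = st$net$b,
                    output_bound = st$net$cfg$output_bound)
  } else if (st$gh_kind == "linear") {
    out$lin <- st$lin
  }
  out
}
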