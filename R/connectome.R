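#' Lagged Pearson correlation between two time series
#'
#' Correlation between `x_u` restricted to time steps `1..(T-tau)` and `x_v`
#' restricted to steps `(tau+1)..T`, using the sample means and standard
#' deviations of those windows (divisor `T - tau - 1`). With `tau = 0` this is
#' the ordinary Pearson correlation. The statistic is asymmetric in its
#' arguments for `tau > 0` and is the edge weight of the directed connectome:
#' a large value of `lagged_pcc(x_u, x_v, tau)` means past activity of region
#' `u` resembles future activity of region `v`.
#'
#' @param x_u numeric vector, source series of length `T`.
#' @param x_v numeric vector, target series of the same length.
#' @param tau non-negative integer lag in time steps; must satisfy
#'   `tau < T - 1`.
#' @return a number in `[-1, 1]` (clipped against round-off).
#' @examples
#' lagged_pcc(c(1, 2, 3, 4), c(9, 1, 2, 3), tau = 1) # exact lag-1 copy -> 1
#' @export
lagged_pcc <- function(x_u, x_v, tau = 1L) {
  stopifnot(is.numeric(x_u), is.numeric(x_v), length(x_u) == length(x_v))
  T_len <- length(x_u)
  tau <- as.integer(tau)
  if (tau < 0L) stop("tau must be non-negative")
  if (tau >= T_len - 1L) {
    stop("invalid lag: tau = ", tau, " must be < T - 1 = ", T_len - 1L)
  }
  if (anyNA(x_u) || anyNA(x_v)) stop("missing values in time series")
  a <- x_u[seq_len(T_len - tau)]
  b <- x_v[seq.int(tau + 1L, T_len)]
  n <- T_len - tau
  mu_a <- mean(a)
  mu_b <- mean(b)
  s_a <- stats::sd(a)
  s_b <- stats::sd(b)
  if (s_a == 0 || s_b == 0) {
    stop("degenerate input: zero-variance window (constant series segment)")
  }
  rho <- sum((a - mu_a) * (b - mu_b)) / ((n - 1) * s_a * s_b)
  clip_correlation(rho)
}

# Clip |rho| <= 1 allowing a 1e-12 numerical overshoot; anything larger is an
# error, not data.
clip_correlation <- function(rho, tol = 1e-12) {
  bad <- abs(rho) > 1 + tol
  if (any(bad)) {
    stop("invalid correlation value(s) with |rho| > 1: ",
         paste(format(rho[bad][seq_len(min(3, sum(bad)))]), collapse = ", "))
  }
  pmin(pmax(rho, -1), 1)
}

#' Multivariate ROI time series container
#'
#' @param values numeric matrix, `T` time points by `N` regions.
#' @param region_ids character vector of `N` region labels; defaults to column
#'   names or `R1..RN`.
#' @return an object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, region_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 3L) stop("need at least 3 time points")
  if (anyNA(values)) stop("missing values in time series matrix")
  if (is.null(region_ids)) {
    region_ids <- colnames(values)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(ncol(values)))
  }
  stopifnot(length(region_ids) == ncol(values))
  colnames(values) <- region_ids
  structure(list(values = values, region_ids = as.character(region_ids)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("ROI time series:", nrow(x$values), "time points x",
      ncol(x$values), "regions\n")
  invisible(x)
}

#' Build a directed connectome from regional time series
#'
#' Computes the full `N x N` matrix of lagged Pearson correlations
#' `rho[u, v] = lagged_pcc(x_u, x_v, tau)`. The matrix is generally
#' asymmetric; the diagonal stores the lagged autocorrelation of each region
#' and is excluded from all downstream edge sets (self-distances must be 0 in
#' the quasimetric construction).
#'
#' @param ts an [roi_timeseries], or a numeric `T x N` matrix.
#' @param tau positive integer lag, default 1 (the shortest delay, so the
#'   statistic captures direct rather than indirect interactions).
#' @return an object of class `directed_connectome` with fields `rho`
#'   (`N x N`), `tau` and `region_ids`.
#' @export
build_connectome <- function(ts, tau = 1L) {
  if (!inherits(ts, "roi_timeseries")) ts <- roi_timeseries(ts)
  X <- ts$values
  T_len <- nrow(X)
  tau <- as.integer(tau)
  if (tau < 0L || tau >= T_len - 1L) {
    stop("invalid lag: tau = ", tau, " for T = ", T_len)
  }
  A <- X[seq_len(T_len - tau), , drop = FALSE]
  B <- X[seq.int(tau + 1L, T_len), , drop = FALSE]
  sd_a <- apply(A, 2, stats::sd)
  sd_b <- apply(B, 2, stats::sd)
  degen <- sd_a == 0 | sd_b == 0
  if (any(degen)) {
    stop("degenerate input: zero-variance window for region(s) ",
         paste(ts$region_ids[degen], collapse = ", "))
  }
  n <- nrow(A)
  Za <- scale(A)  # centred, sd divisor n-1
  Zb <- scale(B)
  rho <- crossprod(Za, Zb) / (n - 1)
  rho <- clip_correlation(rho)
  dimnames(rho) <- list(ts$region_ids, ts$region_ids)
  structure(list(rho = rho, tau = tau, region_ids = ts$region_ids),
            class = "directed_connectome")
}

#' @export
print.directed_connectome <- function(x, ...) {
  n <- length(x$region_ids)
  off <- x$rho[row(x$rho) != col(x$rho)]
  cat("Directed connectome:", n, "regions, lag tau =", x$tau, "\n")
  cat(sprintf("  off-diagonal lagged PCC range [%.3f, %.3f], asymmetry mean |rho_uv - rho_vu| = %.4f\n",
              min(off), max(off), mean(abs(x$rho - t(x$rho)))))
  invisible(x)
}

#' Vectorize the off-diagonal entries of a connectome
#'
#' Row-major flattening of the `N x N` lagged-PCC matrix with the diagonal
#' (lagged autocorrelation, never an edge) removed; length `N * (N - 1)`.
#'
#' @param conn a `directed_connectome`.
#' @return numeric vector of length `N * (N - 1)`.
#' @export
vectorize_connectome <- function(conn) {
  stopifnot(inherits(conn, "directed_connectome"))
  m <- conn$rho
  keep <- t(row(m) != col(m))
  as.vector(t(m))[as.vector(keep)]
}
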