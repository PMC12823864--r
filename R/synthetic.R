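# Seeded generators: the worked 5-node example digraph, random quasimetric
# spaces, VAR(1) regional time series with directed lag-1 coupling, and
# labelled two-class cohorts.

#' The worked 5-node example digraph
#'
#' Six directed edges reconstructed from the printed threshold subgraphs of
#' the worked example: `v0->v1`, `v0->v3`, `v2->v3` at weight 0.1;
#' `v1->v2`, `v1->v4` at weight 0.2; `v2->v4` at weight 0.3. Any weights
#' within the same threshold intervals yield identical Betti curves on the
#' example grid; the interval right-endpoints are used for readability.
#'
#' @param weights numeric vector of 6 edge weights, in the order above.
#' @return a [weighted_digraph] with nodes `v0..v4`.
#' @export
example1_graph <- function(weights = c(0.1, 0.1, 0.1, 0.2, 0.2, 0.3)) {
  stopifnot(length(weights) == 6, all(weights > 0))
  edges <- data.frame(
    from = c(1L, 1L, 3L, 2L, 2L, 3L),
    to   = c(2L, 4L, 4L, 3L, 5L, 5L),
    weight = weights
  )
  weighted_digraph(5L, edges)
}

#' Random closed quasimetric space
#'
#' Draws an asymmetric nonnegative matrix with zero diagonal (off-diagonal
#' entries uniform on `[lo, hi]`) and applies [shortest_path_closure()], so
#' the result always satisfies the quasimetric axioms.
#'
#' @param n number of nodes, at least 2.
#' @param seed integer seed.
#' @param lo,hi off-diagonal weight range before closure.
#' @return a closed [quasimetric_space].
#' @export
random_quasimetric <- function(n, seed, lo = 0.05, hi = 1) {
  stopifnot(n >= 2)
  set.seed(as.integer(seed))
  d <- matrix(stats::runif(n * n, lo, hi), n, n)
  diag(d) <- 0
  shortest_path_closure(d)
}

#' VAR(1) specification for synthetic regional time series
#'
#' @param coupling `N x N` matrix; entry `(u, v)` is the lag-1 influence of
#'   region `u` on region `v`. Spectral radius must be below 1 (stationarity).
#' @param T number of retained time points, at least 50.
#' @param noise_sd innovation standard deviation, positive.
#' @param seed integer seed.
#' @param burn_in discarded initial steps, default 100.
#' @return object of class `var_spec`.
#' @export
var_spec <- function(coupling, T = 150L, noise_sd = 1, seed = 1L,
                     burn_in = 100L) {
  coupling <- as.matrix(coupling)
  stopifnot(nrow(coupling) == ncol(coupling), noise_sd > 0, T >= 50L)
  sr <- max(abs(eigen(coupling, only.values = TRUE)$values))
  if (sr >= 1) {
    stop("nonstationary coupling: spectral radius ", format(sr), " >= 1")
  }
  structure(list(coupling = coupling, T = as.integer(T),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 burn_in = as.integer(burn_in)),
            class = "var_spec")
}

#' Simulate VAR(1) regional time series
#'
#' `x_t = t(coupling) %*% x_{t-1} + e_t` with Gaussian innovations, after a
#' burn-in; fully determined by the seed. Directed coupling `u -> v`
#' produces the asymmetric lagged correlations the directed connectome
#' construction is designed to detect.
#'
#' @param spec a [var_spec].
#' @param region_ids optional labels.
#' @return an [roi_timeseries] of dimension `T x N`.
#' @export
var1_timeseries <- function(spec, region_ids = NULL) {
  stopifnot(inherits(spec, "var_spec"))
  n <- nrow(spec$coupling)
  At <- t(spec$coupling)
  set.seed(spec$seed)
  total <- spec$burn_in + spec$T
  X <- matrix(0, total, n)
  x <- stats::rnorm(n, sd = spec$noise_sd)
  for (t in seq_len(total)) {
    x <- as.vector(At %*% x) + stats::rnorm(n, sd = spec$noise_sd)
    X[t, ] <- x
  }
  roi_timeseries(X[(spec$burn_in + 1L):total, , drop = FALSE], region_ids)
}

# Random within-subnetwork coupling matrix: each ordered within-subnetwork
# pair gets a directed edge with probability `density` and weight
# `strength`; rescaled if the spectral radius approaches 1.
random_coupling <- function(partition, density, strength, seed,
                            cross_density = 0.02) {
  regions <- names(partition$mapping)
  n <- length(regions)
  set.seed(as.integer(seed))
  same <- outer(partition$mapping[regions], partition$mapping[regions], "==")
  p <- ifelse(same, density, cross_density)
  diag(p) <- 0
  C <- matrix(stats::runif(n * n) < p, n, n) * strength
  sr <- max(abs(eigen(C, only.values = TRUE)$values))
  if (sr >= 0.95) C <- C * (0.9 / sr)
  dimnames(C) <- list(regions, regions)
  C
}

#' Evenly sized synthetic partition over the nine subnetworks
#'
#' @param regions_per_subnetwork regions assigned to each of the nine
#'   canonical subnetworks, at least 3.
#' @return a [subnetwork_partition] with region labels `R1..RN`.
#' @export
synthetic_partition <- function(regions_per_subnetwork = 4L) {
  stopifnot(regions_per_subnetwork >= 3L)
  n <- 9L * regions_per_subnetwork
  mapping <- rep(SUBNETWORKS, each = regions_per_subnetwork)
  names(mapping) <- paste0("R", seq_len(n))
  subnetwork_partition(mapping)
}

#' Two-class cohort specification
#'
#' Classes share region count and partition and differ in their
#' within-subnetwork directed coupling density (and/or strength); this
#' emulates a case/control contrast in effective connectivity. When
#' `inject_subnetwork` is set, the classes differ only within that
#' subnetwork (signal injection for importance experiments).
#'
#' @param n_per_class integer vector of length 2, subjects per class.
#' @param partition a [subnetwork_partition]; default nine subnetworks of 4
#'   regions.
#' @param density numeric length 2, within-subnetwork coupling density per
#'   class.
#' @param strength coupling weight per present edge.
#' @param T time points per subject.
#' @param noise_sd innovation SD.
#' @param seed cohort seed; per-subject seeds are derived deterministically.
#' @param inject_subnetwork optional subnetwork label carrying the entire
#'   class difference.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(20L, 20L),
                        partition = synthetic_partition(4L),
                        density = c(0.2, 0.6),
                        strength = 0.35,
                        T = 150L,
                        noise_sd = 1,
                        seed = 1L,
                        inject_subnetwork = NULL) {
  stopifnot(length(n_per_class) == 2, all(n_per_class >= 1),
            length(density) == 2)
  if (!is.null(inject_subnetwork)) {
    stopifnot(inject_subnetwork %in% partition$subnetworks)
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 partition = partition, density = density,
                 strength = strength, T = as.integer(T),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 inject_subnetwork = inject_subnetwork),
            class = "cohort_spec")
}

# Class-specific coupling for subject draws. With signal injection, the
# baseline density applies everywhere except the injected subnetwork.
class_coupling <- function(spec, class_idx, subject_seed) {
  dens <- spec$density[class_idx]
  if (is.null(spec$inject_subnetwork)) {
    return(random_coupling(spec$partition, dens, spec$strength, subject_seed))
  }
  base <- random_coupling(spec$partition, spec$density[1], spec$strength,
                          subject_seed)
  inj <- names(spec$partition$mapping)[
    spec$partition$mapping == spec$inject_subnetwork]
  set.seed(subject_seed + 1000003L)
  m <- length(inj)
  mask <- matrix(stats::runif(m * m) < dens, m, m)
  diag(mask) <- FALSE
  base[inj, inj] <- mask * spec$strength
  sr <- max(abs(eigen(base, only.values = TRUE)$values))
  if (sr >= 0.95) base <- base * (0.9 / sr)
  base
}

#' Generate a labelled two-class cohort of time series
#'
#' @param spec a [cohort_spec].
#' @return list with `series` (list of [roi_timeseries]), `labels` (0/1
#'   integer vector) and `partition`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- sum(spec$n_per_class)
  labels <- rep(c(0L, 1L), times = spec$n_per_class)
  series <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    subject_seed <- (spec$seed * 10007L + i * 7919L) %% .Machine$integer.max
    cls <- labels[i] + 1L
    C <- class_coupling(spec, cls, subject_seed)
    vs <- var_spec(C, T = spec$T, noise_sd = spec$noise_sd,
                   seed = (subject_seed + 13L) %% .Machine$integer.max)
    series[[i]] <- var1_timeseries(vs, region_ids = rownames(C))
  }
  list(series = series, labels = labels, partition = spec$partition)
}

#' Feature bundles for every subject of a cohort
#'
#' Runs the full featurization pipeline (lagged-PCC connectome, per-
#' subnetwork quasimetric closure, Betti curves) on each subject.
#'
#' @param cohort output of [make_cohort()].
#' @param T Betti-curve grid size.
#' @param tau lag for the connectome, default 1.
#' @return list of [subnetwork_features()] bundles (same order as
#'   `cohort$series`).
#' @export
cohort_features <- function(cohort, T = 32L, tau = 1L) {
  lapply(cohort$series, function(ts) {
    conn <- build_connectome(ts, tau = tau)
    subnetwork_features(conn, cohort$partition, T = T)
  })
}
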