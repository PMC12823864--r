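# Betti curves over threshold grids and the 18-curve per-subnetwork feature
# representation of a directed connectome.

#' Evenly spaced threshold grid
#'
#' @param d_min,d_max range endpoints, `d_min < d_max`; both included.
#' @param T number of grid points, at least 2.
#' @return object of class `threshold_grid` with field `points`.
#' @export
threshold_grid <- function(d_min, d_max, T = 256L) {
  T <- as.integer(T)
  if (T < 2L) stop("grid needs at least 2 points")
  if (!(d_min < d_max)) stop("d_min must be less than d_max")
  structure(list(d_min = d_min, d_max = d_max, T = T,
                 points = seq(d_min, d_max, length.out = T)),
            class = "threshold_grid")
}

#' Default threshold grids for the two Betti curves
#'
#' The degree-0 curve is evaluated on `[0, 1]` (the range of the
#' correlation-derived distance) and the degree-1 curve on `[0, 2]` (the
#' range of 2-path lengths entering triangle deformations).
#'
#' @param T grid size, default 256.
#' @return list with elements `beta0` and `beta1`, both [threshold_grid]s.
#' @export
default_grids <- function(T = 256L) {
  list(beta0 = threshold_grid(0, 1, T), beta1 = threshold_grid(0, 2, T))
}

as_grid <- function(grid) {
  if (inherits(grid, "threshold_grid")) return(grid)
  if (is.numeric(grid) && length(grid) >= 2L && all(diff(grid) > 0)) {
    return(structure(list(d_min = grid[1], d_max = grid[length(grid)],
                          T = length(grid), points = as.numeric(grid)),
                     class = "threshold_grid"))
  }
  stop("grid must be a threshold_grid or a strictly increasing numeric vector")
}

#' Blurred magnitude Betti curve over a threshold grid
#'
#' Evaluates the degree-`n` blurred magnitude Betti number at every grid
#' point. Chain bases and boundary matrices are enumerated once at the
#' largest threshold and filtered per level (equivalent to, and much cheaper
#' than, per-level recomputation: lower-level bases are exactly the
#' length-filtered rows/columns).
#'
#' @param space a [quasimetric_space], [weighted_digraph] or distance matrix.
#' @param n homology degree, 0 or 1.
#' @param grid a [threshold_grid] or increasing numeric vector of thresholds.
#' @param subnetwork optional label stored with the curve (default "global").
#' @return object of class `betti_curve` with integer `values`, one per grid
#'   point.
#' @export
betti_curve <- function(space, n, grid, subnetwork = "global") {
  n <- as.integer(n)
  if (!n %in% 0:1) stop("unsupported degree n = ", n, " (only 0 and 1)")
  grid <- as_grid(grid)
  if (grid$d_min < 0) stop("thresholds must be nonnegative")
  d_max <- grid$d_max
  b0 <- enumerate_paths(space, 0L, d_max, blurred = TRUE)
  b1 <- enumerate_paths(space, 1L, d_max, blurred = TRUE)
  d1 <- boundary_matrix(b0, b1)
  N <- nrow(b0$tuples)
  L1 <- b1$lengths
  if (n == 1L) {
    b2 <- enumerate_paths(space, 2L, d_max, blurred = TRUE)
    d2 <- boundary_matrix(b1, b2)
    L2 <- b2$lengths
  }
  values <- vapply(grid$points, function(t) {
    eps <- length_tol(t)
    m1 <- L1 <= t + eps
    r1 <- rank_exact(d1[, m1, drop = FALSE])
    if (n == 0L) {
      N - r1
    } else {
      m2 <- L2 <= t + eps
      sum(m1) - r1 - rank_exact(d2[m1, m2, drop = FALSE])
    }
  }, numeric(1))
  structure(list(n = n, grid = grid, values = as.integer(values),
                 subnetwork = subnetwork),
            class = "betti_curve")
}

#' @export
print.betti_curve <- function(x, ...) {
  cat(sprintf("Betti curve (degree %d, subnetwork %s): %d thresholds on [%g, %g]\n",
              x$n, x$subnetwork, x$grid$T, x$grid$d_min, x$grid$d_max))
  show <- min(10L, length(x$values))
  cat("  values:", paste(x$values[seq_len(show)], collapse = " "),
      if (length(x$values) > show) "...\n" else "\n")
  invisible(x)
}

#' @export
plot.betti_curve <- function(x, ...) {
  graphics::plot(x$grid$points, x$values, type = "s",
                 xlab = "length threshold",
                 ylab = sprintf("beta_%d", x$n),
                 main = sprintf("Betti curve (degree %d, %s)", x$n,
                                x$subnetwork), ...)
  invisible(x)
}

#' Canonical functional subnetwork order
#'
#' The nine functional subnetworks, in the fixed canonical order used by
#' every feature bundle: basal ganglia, cerebellar, dorsal attention,
#' default mode, frontoparietal, limbic, sensorimotor, ventral attention,
#' visual.
#'
#' @format A character vector of length 9.
#' @export
SUBNETWORKS <- c("BGN", "CEREN", "DAN", "DMN", "FPN", "LN", "SMN", "VAN", "VN")

#' Region-to-subnetwork partition
#'
#' @param mapping named character vector or two-column data frame
#'   (`region_label`, `subnetwork_label`) assigning every region to exactly
#'   one subnetwork.
#' @return object of class `subnetwork_partition`; `mapping` is a named
#'   character vector, region label -> subnetwork label.
#' @export
subnetwork_partition <- function(mapping) {
  if (is.data.frame(mapping)) {
    m <- as.character(mapping[[2]])
    names(m) <- as.character(mapping[[1]])
    mapping <- m
  }
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  if (anyDuplicated(names(mapping))) stop("region assigned more than once")
  counts <- table(mapping)
  if (any(counts < 3L)) {
    warning("subnetwork(s) with fewer than 3 regions: ",
            paste(names(counts)[counts < 3L], collapse = ", "),
            " (homology will be trivial)")
  }
  structure(list(mapping = mapping,
                 subnetworks = sort(unique(unname(mapping)))),
            class = "subnetwork_partition")
}

#' @export
print.subnetwork_partition <- function(x, ...) {
  cat("Subnetwork partition:", length(x$mapping), "regions in",
      length(x$subnetworks), "subnetworks\n")
  print(table(x$mapping))
  invisible(x)
}

# Ordered subnetwork labels: the canonical nine if the partition uses them,
# otherwise alphabetical.
partition_order <- function(partition) {
  labs <- partition$subnetworks
  if (all(labs %in% SUBNETWORKS)) SUBNETWORKS[SUBNETWORKS %in% labs] else labs
}

#' Per-subnetwork Betti-curve feature bundle of a connectome
#'
#' For each subnetwork in canonical order (BGN, CEREN, DAN, DMN, FPN, LN,
#' SMN, VAN, VN) the connectome is restricted to the subnetwork's regions,
#' transformed with [dissimilarity()] and closed with
#' [shortest_path_closure()] *within* the subnetwork, and the degree-0 and
#' degree-1 blurred magnitude Betti curves are evaluated on the default
#' grids (`[0, 1]` and `[0, 2]`). The joint feature vector concatenates the
#' nine degree-0 curves, then the nine degree-1 curves (length
#' `2 * 9 * T`); the vectorized off-diagonal connectome is carried alongside.
#'
#' @param conn a `directed_connectome`.
#' @param partition a [subnetwork_partition] covering every region of `conn`.
#' @param T grid size per curve, default 256.
#' @return object of class `feature_bundle` with fields `beta0_joint`,
#'   `beta1_joint`, `x_betti`, `x_connectome`, `curves` (named list of
#'   [betti_curve]s) and `subnetworks`.
#' @export
subnetwork_features <- function(conn, partition, T = 256L) {
  stopifnot(inherits(conn, "directed_connectome"),
            inherits(partition, "subnetwork_partition"))
  missing_regions <- setdiff(conn$region_ids, names(partition$mapping))
  if (length(missing_regions)) {
    stop("region(s) not assigned to any subnetwork: ",
         paste(missing_regions, collapse = ", "))
  }
  grids <- default_grids(T)
  order_labs <- partition_order(partition)
  curves <- list()
  b0_parts <- list()
  b1_parts <- list()
  for (lab in order_labs) {
    regions <- names(partition$mapping)[partition$mapping == lab]
    regions <- intersect(conn$region_ids, regions)
    sub_rho <- conn$rho[regions, regions, drop = FALSE]
    space <- connectome_to_quasimetric(sub_rho)
    c0 <- betti_curve(space, 0L, grids$beta0, subnetwork = lab)
    c1 <- betti_curve(space, 1L, grids$beta1, subnetwork = lab)
    curves[[paste0("beta0_", lab)]] <- c0
    curves[[paste0("beta1_", lab)]] <- c1
    b0_parts[[lab]] <- c0$values
    b1_parts[[lab]] <- c1$values
  }
  beta0_joint <- unlist(b0_parts, use.names = FALSE)
  beta1_joint <- unlist(b1_parts, use.names = FALSE)
  structure(list(beta0_joint = beta0_joint,
                 beta1_joint = beta1_joint,
                 x_betti = c(beta0_joint, beta1_joint),
                 x_connectome = vectorize_connectome(conn),
                 curves = curves,
                 subnetworks = order_labs,
                 T = as.integer(T)),
            class = "feature_bundle")
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat("Feature bundle:", length(x$subnetworks), "subnetworks, grid size",
      x$T, "\n")
  cat("  x_betti length:", length(x$x_betti),
      "| x_connectome length:", length(x$x_connectome), "\n")
  invisible(x)
}

# Index of each x_betti position -> subnetwork label, for importance sums.
betti_feature_map <- function(bundle) {
  rep(rep(bundle$subnetworks, each = bundle$T), times = 2L)
}
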