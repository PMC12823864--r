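#' Correlation-to-dissimilarity transform
#'
#' Maps a correlation `rho` in `[-1, 1]` to `sqrt((1 - rho) / 2)` in
#' `[0, 1]`: 0 for perfect positive correlation, 1 for perfect negative
#' correlation. For a symmetric correlation this is the chord distance between
#' standardized series; the same form is applied to the asymmetric lagged
#' correlation, yielding a dissimilarity that is not yet a quasimetric.
#'
#' @param rho numeric vector or matrix of correlations, `|rho| <= 1` (a
#'   1e-12 numerical overshoot is clipped; more is an error).
#' @return values in `[0, 1]`, same shape as `rho`.
#' @export
dissimilarity <- function(rho) {
  rho <- clip_correlation(rho)
  sqrt((1 - rho) / 2)
}

#' Weighted digraph container for toy inputs
#'
#' Positive finite edge weights; an absent ordered pair means infinite weight.
#'
#' @param n_nodes number of nodes.
#' @param edges data frame with columns `from`, `to` (1-based node indices)
#'   and `weight` (> 0, finite); no self-loops, no duplicate pairs.
#' @param node_ids optional character labels, default `v0..v(n-1)`.
#' @return an object of class `weighted_digraph`.
#' @export
weighted_digraph <- function(n_nodes, edges, node_ids = NULL) {
  n_nodes <- as.integer(n_nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (nrow(edges)) {
    stopifnot(all(edges$from >= 1), all(edges$from <= n_nodes),
              all(edges$to >= 1), all(edges$to <= n_nodes))
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    if (anyDuplicated(edges[, c("from", "to")])) stop("duplicate edge")
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
      stop("edge weights must be finite and positive")
    }
  }
  if (is.null(node_ids)) node_ids <- paste0("v", seq_len(n_nodes) - 1L)
  structure(list(n_nodes = n_nodes, edges = edges,
                 node_ids = as.character(node_ids)),
            class = "weighted_digraph")
}

#' @export
print.weighted_digraph <- function(x, ...) {
  cat("Weighted digraph:", x$n_nodes, "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Distance matrix of a weighted digraph
#'
#' Absent ordered pairs get `Inf`; the diagonal is 0.
#' @param g a `weighted_digraph`.
#' @return numeric `n x n` matrix.
#' @export
digraph_distance_matrix <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  n <- g$n_nodes
  d <- matrix(Inf, n, n, dimnames = list(g$node_ids, g$node_ids))
  diag(d) <- 0
  if (nrow(g$edges)) d[cbind(g$edges$from, g$edges$to)] <- g$edges$weight
  d
}

#' Quasimetric space container
#'
#' @param d nonnegative `N x N` matrix with zero diagonal; `Inf` allowed for
#'   unreachable ordered pairs.
#' @param node_ids optional labels.
#' @param is_closed whether shortest-path closure has been applied.
#' @return an object of class `quasimetric_space`.
#' @export
quasimetric_space <- function(d, node_ids = NULL, is_closed = FALSE) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d))
  if (any(d < 0, na.rm = TRUE)) stop("negative distances are not allowed")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  if (is.null(node_ids)) {
    node_ids <- rownames(d)
    if (is.null(node_ids)) node_ids <- paste0("v", seq_len(nrow(d)) - 1L)
  }
  dimnames(d) <- list(node_ids, node_ids)
  structure(list(d = d, node_ids = as.character(node_ids),
                 is_closed = isTRUE(is_closed)),
            class = "quasimetric_space")
}

#' @export
print.quasimetric_space <- function(x, ...) {
  cat("Quasimetric space:", nrow(x$d), "nodes",
      if (x$is_closed) "(shortest-path closed)" else "(not closed)", "\n")
  invisible(x)
}

# Accept a quasimetric_space, weighted_digraph or bare matrix and return the
# distance matrix.
as_distance_matrix <- function(space) {
  if (inherits(space, "quasimetric_space")) return(space$d)
  if (inherits(space, "weighted_digraph")) return(digraph_distance_matrix(space))
  if (is.matrix(space)) return(space)
  stop("cannot interpret object of class ", paste(class(space), collapse = "/"),
       " as a distance matrix")
}

#' Shortest-path closure of a dissimilarity matrix
#'
#' Replaces every entry by the minimum total weight over directed paths,
#' which enforces the triangle inequality by construction (single-source
#' Dijkstra from every node). Entries can only decrease; on digraphs that are
#' not strongly connected, unreachable pairs keep distance `Inf`. Zero
#' off-diagonal dissimilarities (perfectly correlated regions) are preserved
#' and a warning is emitted, since they violate identity of indiscernibles.
#'
#' @param dtilde nonnegative matrix with zero diagonal (`Inf` = absent edge),
#'   or a [weighted_digraph].
#' @return a [quasimetric_space] with `is_closed = TRUE`.
#' @export
shortest_path_closure <- function(dtilde) {
  d0 <- as_distance_matrix(dtilde)
  if (any(d0 < 0)) stop("negative input weight")
  if (any(diag(d0) != 0)) stop("diagonal must be zero")
  n <- nrow(d0)
  ids <- rownames(d0)
  if (is.null(ids)) ids <- paste0("v", seq_len(n) - 1L)
  # build the edge list explicitly so zero-weight edges survive
  idx <- which(is.finite(d0) & row(d0) != col(d0), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    out <- matrix(Inf, n, n); diag(out) <- 0
    dimnames(out) <- list(ids, ids)
    return(quasimetric_space(out, ids, is_closed = TRUE))
  }
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  g <- igraph::add_edges(g, t(idx))
  w <- d0[idx]
  out <- igraph::distances(g, mode = "out", weights = w,
                           algorithm = "dijkstra")
  dimnames(out) <- list(ids, ids)
  if (any(out[row(out) != col(out)] == 0)) {
    warning("zero off-diagonal distance(s) retained: identity of ",
            "indiscernibles is violated (perfectly correlated nodes)")
  }
  quasimetric_space(out, ids, is_closed = TRUE)
}

#' Check quasimetric axioms
#'
#' Enumerates violations of non-negativity, zero diagonal, identity of
#' indiscernibles (off-diagonal zeros) and the triangle inequality
#' `d(u, w) <= d(u, v) + d(v, w)` (exhaustive over all ordered triples).
#' An empty report means the matrix is a quasimetric.
#'
#' @param space a [quasimetric_space], [weighted_digraph] or matrix.
#' @param tol numerical slack for the triangle check.
#' @return an object of class `quasimetric_report`; `is_quasimetric(report)`
#'   or `length(report$violations) == 0` tests emptiness.
#' @export
check_quasimetric <- function(space, tol = 1e-12) {
  d <- as_distance_matrix(space)
  n <- nrow(d)
  viol <- list()
  neg <- which(d < 0, arr.ind = TRUE)
  for (k in seq_len(nrow(neg))) {
    viol[[length(viol) + 1L]] <- list(type = "non-negativity",
                                      u = neg[k, 1], v = neg[k, 2],
                                      value = d[neg[k, 1], neg[k, 2]])
  }
  dg <- which(diag(d) != 0)
  for (u in dg) {
    viol[[length(viol) + 1L]] <- list(type = "nonzero-diagonal", u = u, v = u,
                                      value = d[u, u])
  }
  z <- which(d == 0 & row(d) != col(d), arr.ind = TRUE)
  for (k in seq_len(nrow(z))) {
    viol[[length(viol) + 1L]] <- list(type = "identity-of-indiscernibles",
                                      u = z[k, 1], v = z[k, 2], value = 0)
  }
  # triangle: for each intermediate v, compare d[u, w] with d[u, v] + d[v, w]
  for (v in seq_len(n)) {
    bound <- outer(d[, v], d[v, ], `+`)
    bad <- which(d > bound + tol, arr.ind = TRUE)
    for (k in seq_len(nrow(bad))) {
      u <- bad[k, 1]; w <- bad[k, 2]
      viol[[length(viol) + 1L]] <- list(type = "triangle", u = u, v = v, w = w,
                                        value = d[u, w],
                                        bound = bound[u, w])
    }
  }
  structure(list(n = n, violations = viol), class = "quasimetric_report")
}

#' @rdname check_quasimetric
#' @param report a `quasimetric_report`.
#' @export
is_quasimetric <- function(report) length(report$violations) == 0L

#' @export
print.quasimetric_report <- function(x, ...) {
  if (is_quasimetric(x)) {
    cat("Quasimetric: all axioms hold on", x$n, "nodes\n")
  } else {
    tab <- table(vapply(x$violations, `[[`, "", "type"))
    cat("Axiom violations on", x$n, "nodes:\n")
    for (nm in names(tab)) cat(" ", nm, ":", tab[[nm]], "\n")
  }
  invisible(x)
}

#' Quasimetric space from a directed connectome
#'
#' Applies [dissimilarity()] to the off-diagonal lagged correlations and then
#' [shortest_path_closure()]. The diagonal is set to 0 (self-edges are never
#' used).
#'
#' @param conn a `directed_connectome` or a bare correlation matrix.
#' @return a closed [quasimetric_space].
#' @export
connectome_to_quasimetric <- function(conn) {
  rho <- if (inherits(conn, "directed_connectome")) conn$rho else as.matrix(conn)
  dt <- dissimilarity(rho)
  diag(dt) <- 0
  shortest_path_closure(dt)
}
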