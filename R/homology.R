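# Magnitude and blurred magnitude homology of quasimetric spaces / weighted
# digraphs, degrees 0 and 1, by exact boundary-operator rank computation.
#
# A k-path is an ordered tuple (v0, ..., vk) with consecutive entries
# distinct; its length is the sum of consecutive distances. The strict
# chain space MC_{k,l} is spanned by k-paths of length exactly l, the
# blurred space BMC_{k,l} by k-paths of length at most l. The boundary
# operator drops interior/end nodes with alternating signs; a drop
# contributes only when the resulting tuple is itself a basis member.

# Comparison slack for path-length sums: fixture weights like 0.1 + 0.2 do
# not hit 0.3 exactly in binary floating point.
length_tol <- function(level) 1e-9 * max(1, abs(level))

tuple_keys <- function(tuples) {
  if (nrow(tuples) == 0L) return(character(0))
  apply(tuples, 1L, paste, collapse = ",")
}

new_chain_basis <- function(k, level, blurred, tuples, lengths, n_nodes,
                            node_ids) {
  o <- do.call(order, as.data.frame(tuples))
  tuples <- tuples[o, , drop = FALSE]
  lengths <- lengths[o]
  structure(list(k = as.integer(k), level = level, blurred = blurred,
                 tuples = tuples, lengths = lengths,
                 keys = tuple_keys(tuples), n_nodes = n_nodes,
                 node_ids = node_ids),
            class = "chain_basis")
}

#' @export
print.chain_basis <- function(x, ...) {
  cat(sprintf("%s chain basis: k = %d, level = %g, %d tuple(s)\n",
              if (x$blurred) "Blurred magnitude" else "Magnitude",
              x$k, x$level, nrow(x$tuples)))
  invisible(x)
}

#' Enumerate the chain basis of (blurred) magnitude homology
#'
#' Lists the k-paths generating `MC[k, level]` (strict: length equal to
#' `level`) or `BMC[k, level]` (blurred: length at most `level`), in
#' canonical lexicographic order of node indices. Supported degrees are
#' `k` in 0, 1, 2, which suffice for the zeroth and first Betti numbers.
#'
#' On digraphs with absent (infinite-weight) edges, a 2-path enters the
#' blurred basis only when its endpoints are joined by a finite-distance edge
#' or coincide: otherwise the degree-2 boundary would not land in the cycle
#' space and the chain-complex property would fail. On a shortest-path closed
#' space this condition always holds and the rule is vacuous.
#'
#' @param space a [quasimetric_space], [weighted_digraph] or distance matrix.
#' @param k chain degree, one of 0, 1, 2.
#' @param level nonnegative length threshold.
#' @param blurred if `TRUE` (default) use the length-at-most-level basis.
#' @return a `chain_basis` object with fields `tuples` (matrix of node
#'   indices, one row per tuple) and `lengths`.
#' @export
enumerate_paths <- function(space, k, level, blurred = TRUE) {
  d <- as_distance_matrix(space)
  n <- nrow(d)
  ids <- rownames(d)
  if (level < 0) stop("level must be nonnegative")
  k <- as.integer(k)
  if (!k %in% 0:2) {
    stop("unsupported degree k = ", k,
         " (only k <= 2 is needed for Betti numbers 0 and 1)")
  }
  eps <- length_tol(level)
  keep_len <- function(len) {
    if (blurred) len <= level + eps else abs(len - level) <= eps
  }
  if (k == 0L) {
    tuples <- matrix(seq_len(n), ncol = 1L)
    lengths <- rep(0, n)
    sel <- keep_len(lengths)
    return(new_chain_basis(k, level, blurred, tuples[sel, , drop = FALSE],
                           lengths[sel], n, ids))
  }
  ed <- which(is.finite(d) & row(d) != col(d), arr.ind = TRUE)
  if (k == 1L) {
    lengths <- d[ed]
    sel <- keep_len(lengths)
    return(new_chain_basis(k, level, blurred, unname(ed[sel, , drop = FALSE]),
                           lengths[sel], n, ids))
  }
  # k == 2: compose finite edges (u, v) and (v, w)
  if (nrow(ed) == 0L) {
    return(new_chain_basis(k, level, blurred, matrix(integer(0), 0, 3),
                           numeric(0), n, ids))
  }
  e1 <- data.frame(u = ed[, 1], v = ed[, 2], w1 = d[ed])
  e2 <- data.frame(v = ed[, 1], w = ed[, 2], w2 = d[ed])
  tri <- merge(e1, e2, by = "v")
  if (nrow(tri) == 0L) {
    return(new_chain_basis(k, level, blurred, matrix(integer(0), 0, 3),
                           numeric(0), n, ids))
  }
  len <- tri$w1 + tri$w2
  sel <- keep_len(len)
  if (blurred) {
    shortcut_ok <- tri$u == tri$w | is.finite(d[cbind(tri$u, tri$w)])
    sel <- sel & shortcut_ok
  }
  tuples <- cbind(tri$u, tri$v, tri$w)[sel, , drop = FALSE]
  new_chain_basis(k, level, blurred, tuples, len[sel], n, ids)
}

#' Boundary operator matrix between two chain bases
#'
#' Column for each k-tuple: dropping node `i` contributes `(-1)^i` at the row
#' of the resulting (k-1)-tuple when that tuple is a member of the lower
#' basis (consecutive nodes distinct, hops finite, length within the level
#' constraint); all other drops contribute zero. Entries are integers in
#' `{-1, 0, 1}` except where drops coincide.
#'
#' @param basis_km1,basis_k `chain_basis` objects of degrees `k - 1` and `k`
#'   sharing level and blurred flag.
#' @return a dense integer matrix, rows indexed by `basis_km1`, columns by
#'   `basis_k`.
#' @export
boundary_matrix <- function(basis_km1, basis_k) {
  stopifnot(inherits(basis_km1, "chain_basis"), inherits(basis_k, "chain_basis"))
  if (basis_k$k != basis_km1$k + 1L ||
      basis_k$blurred != basis_km1$blurred ||
      abs(basis_k$level - basis_km1$level) > 1e-15 ||
      basis_k$n_nodes != basis_km1$n_nodes) {
    stop("mismatched bases: degrees must differ by one and share level, ",
         "blurred flag and space")
  }
  nr <- nrow(basis_km1$tuples)
  nc <- nrow(basis_k$tuples)
  M <- matrix(0, nr, nc)
  if (nr == 0L || nc == 0L) return(M)
  row_of <- seq_len(nr)
  names(row_of) <- basis_km1$keys
  k <- basis_k$k
  for (i in 0:k) {
    dropped <- basis_k$tuples[, -(i + 1L), drop = FALSE]
    # degenerate drops (consecutive entries equal after removal) contribute 0
    ok <- rep(TRUE, nc)
    if (ncol(dropped) >= 2L) {
      for (j in seq_len(ncol(dropped) - 1L)) {
        ok <- ok & dropped[, j] != dropped[, j + 1L]
      }
    }
    keys <- rep(NA_character_, nc)
    keys[ok] <- tuple_keys(dropped[ok, , drop = FALSE])
    hit <- !is.na(keys) & keys %in% names(row_of)
    if (any(hit)) {
      rr <- row_of[keys[hit]]
      cc <- which(hit)
      sgn <- (-1)^i
      M[cbind(rr, cc)] <- M[cbind(rr, cc)] + sgn
    }
  }
  M
}

# Greatest common divisor of the absolute values of an integer-valued vector.
vec_gcd <- function(x) {
  x <- abs(x[x != 0])
  if (!length(x)) return(1)
  g <- x[1]
  for (v in x[-1]) {
    while (v != 0) { t <- g %% v; g <- v; v <- t }
    if (g == 1) return(1)
  }
  g
}

#' Exact rank of an integer matrix over the rationals
#'
#' Gaussian elimination with exact integer arithmetic: unit pivots are
#' preferred (boundary matrices are incidence-like, so a +-1 pivot is almost
#' always available and entries stay small); otherwise a fraction-free step
#' with per-row gcd reduction is used. An overflow guard aborts if entries
#' approach the exactly-representable integer range of doubles, so a returned
#' rank is always exact.
#'
#' @param M numeric matrix with integer entries.
#' @return the rank, a nonnegative integer.
#' @export
rank_exact <- function(M) {
  if (is.null(M) || length(M) == 0L || nrow(M) == 0L || ncol(M) == 0L) {
    return(0L)
  }
  A <- unname(as.matrix(M))
  storage.mode(A) <- "double"
  if (any(A != round(A))) stop("rank_exact requires integer entries")
  m <- nrow(A); n <- ncol(A)
  guard <- 2^48
  r <- 0L
  pr <- 1L
  for (cc in seq_len(n)) {
    if (pr > m) break
    col <- A[pr:m, cc]
    nz <- which(col != 0)
    if (!length(nz)) next
    ones <- nz[abs(col[nz]) == 1]
    pick <- if (length(ones)) ones[1L] else nz[which.min(abs(col[nz]))]
    prow <- pr + pick - 1L
    if (prow != pr) {
      tmp <- A[pr, ]; A[pr, ] <- A[prow, ]; A[prow, ] <- tmp
    }
    piv <- A[pr, cc]
    if (pr < m) {
      below <- (pr + 1L):m
      f <- A[below, cc]
      upd <- below[f != 0]
      if (length(upd)) {
        if (abs(piv) == 1) {
          A[upd, ] <- A[upd, , drop = FALSE] -
            outer(A[upd, cc] * piv, A[pr, ])
        } else {
          A[upd, ] <- A[upd, , drop = FALSE] * piv -
            outer(A[upd, cc], A[pr, ])
          for (j in upd) {
            g <- vec_gcd(A[j, ])
            if (g > 1) A[j, ] <- A[j, ] / g
          }
        }
        mx <- max(abs(A[upd, ]))
        if (mx >= guard) stop("exact rank overflow guard tripped")
      }
    }
    r <- r + 1L
    pr <- pr + 1L
  }
  r
}

#' Floating-point rank via singular values
#'
#' Counts singular values above `tol` times the largest; used as an
#' independent cross-check of [rank_exact()].
#'
#' @param M numeric matrix.
#' @param tol relative tolerance, default `1e-8`.
#' @return integer rank estimate.
#' @export
rank_float <- function(M, tol = 1e-8) {
  if (is.null(M) || length(M) == 0L || nrow(M) == 0L || ncol(M) == 0L) {
    return(0L)
  }
  s <- svd(M, nu = 0, nv = 0)$d
  if (!length(s) || max(s) == 0) return(0L)
  sum(s > tol * max(s))
}

#' Betti number of (blurred) magnitude homology
#'
#' Degree 0: `dim C0 - rank(delta1)`; for the blurred theory this counts
#' weakly connected components of the subgraph with edges of length at most
#' `level`. Degree 1: `dim C1 - rank(delta1) - rank(delta2)`; for the blurred
#' theory this counts independent classes of undirected cycles modulo
#' replacement of an edge by a 2-path within the level. Ranks are exact over
#' the rationals.
#'
#' @param space a [quasimetric_space], [weighted_digraph] or distance matrix.
#' @param n homology degree, 0 or 1.
#' @param level nonnegative length threshold.
#' @param blurred use the blurred theory (default `TRUE`).
#' @return a nonnegative integer.
#' @export
betti_number <- function(space, n, level, blurred = TRUE) {
  n <- as.integer(n)
  if (!n %in% 0:1) stop("unsupported degree n = ", n, " (only 0 and 1)")
  if (level < 0) stop("level must be nonnegative")
  b0 <- enumerate_paths(space, 0L, level, blurred)
  b1 <- enumerate_paths(space, 1L, level, blurred)
  d1 <- boundary_matrix(b0, b1)
  r1 <- rank_exact(d1)
  if (n == 0L) {
    return(nrow(b0$tuples) - r1)
  }
  b2 <- enumerate_paths(space, 2L, level, blurred)
  d2 <- boundary_matrix(b1, b2)
  nrow(b1$tuples) - r1 - rank_exact(d2)
}

#' Strict magnitude homology Betti number
#'
#' The non-blurred theory: chain spaces are spanned by paths of length
#' exactly `level`. Degree 0 is `N` at level 0 and 0 otherwise; degree 1
#' counts pairs `(u, v)` with `d(u, v) = level` that admit no intermediate
#' node `w` with `d(u, w) + d(w, v) = d(u, v)`.
#'
#' @inheritParams betti_number
#' @export
magnitude_betti <- function(space, n, level) {
  betti_number(space, n, level, blurred = FALSE)
}

#' Weakly connected component count at a length threshold
#'
#' Union-find on the undirected graph with an edge `{u, v}` whenever
#' `min(d(u, v), d(v, u)) <= level`; no linear algebra involved, so it serves
#' as an independent oracle for the degree-0 blurred Betti number.
#'
#' @inheritParams betti_number
#' @return number of components, an integer.
#' @export
weak_component_count <- function(space, level) {
  if (level < 0) stop("level must be nonnegative")
  d <- as_distance_matrix(space)
  nn <- nrow(d)
  eps <- length_tol(level)
  parent <- seq_len(nn)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  und <- pmin(d, t(d))
  idx <- which(und <= level + eps & row(d) < col(d), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    a <- find(idx[k, 1]); b <- find(idx[k, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(nn), find, integer(1))))
}

#' Dump chain bases and boundary matrices as JSON
#'
#' Debug/inspection export: tuple lists and sparse (row, col, value) triplets
#' of the degree-1 and degree-2 boundary operators at one level.
#'
#' @inheritParams betti_number
#' @param path file to write; if `NULL`, the JSON string is returned.
#' @export
chain_complex_json <- function(space, level, blurred = TRUE, path = NULL) {
  b0 <- enumerate_paths(space, 0L, level, blurred)
  b1 <- enumerate_paths(space, 1L, level, blurred)
  b2 <- enumerate_paths(space, 2L, level, blurred)
  d1 <- boundary_matrix(b0, b1)
  d2 <- boundary_matrix(b1, b2)
  triplets <- function(M) {
    idx <- which(M != 0, arr.ind = TRUE)
    list(row = unname(idx[, 1]), col = unname(idx[, 2]), value = M[idx])
  }
  obj <- list(level = level, blurred = blurred,
              basis0 = b0$tuples, basis1 = b1$tuples, basis2 = b2$tuples,
              delta1 = triplets(d1), delta2 = triplets(d2))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
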