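# Independent oracles used across the suite. These deliberately avoid the
# production code paths they check.

# All-pairs shortest paths by iterated triangle relaxation (Floyd-Warshall),
# independent of the Dijkstra-based closure.
floyd_warshall <- function(d) {
  n <- nrow(d)
  out <- d
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      relax <- out[i, k] + out[k, ]
      out[i, ] <- pmin(out[i, ], relax)
    }
  }
  out
}

# Strict magnitude homology degree-1 dimension by direct census: pairs
# (u, v) with d(u, v) == level admitting no intermediate w (distinct from
# both) with d(u, w) + d(w, v) == level.
mh1_census <- function(d, level, tol = 1e-9) {
  n <- nrow(d)
  count <- 0L
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (u == v || !is.finite(d[u, v])) next
      if (abs(d[u, v] - level) > tol) next
      witness <- FALSE
      for (w in seq_len(n)) {
        if (w == u || w == v) next
        if (is.finite(d[u, w]) && is.finite(d[w, v]) &&
            abs(d[u, w] + d[w, v] - level) <= tol) {
          witness <- TRUE
          break
        }
      }
      if (!witness) count <- count + 1L
    }
  }
  count
}

# Small random integer matrix with entries in {-1, 0, 1}.
random_sign_matrix <- function(nr, nc, p_nonzero = 0.4) {
  matrix(sample(c(-1L, 0L, 1L), nr * nc, replace = TRUE,
                prob = c(p_nonzero / 2, 1 - p_nonzero, p_nonzero / 2)),
         nr, nc)
}

# Fixture graph with weights resampled inside the printed threshold
# intervals: first three edges in (0, 0.1], next two in (0.1, 0.2], last in
# (0.2, 0.3].
perturbed_example1 <- function() {
  w <- c(stats::runif(3, 0.01, 0.1), stats::runif(2, 0.11, 0.2),
         stats::runif(1, 0.21, 0.3))
  list(graph = example1_graph(w), weights = w)
}
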