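test_that("fixture Betti curves reproduce the worked-example vectors", {
  g <- example1_graph()
  grid <- seq(0, 0.5, by = 0.1)
  expect_identical(betti_curve(g, 0, grid)$values, c(5L, 2L, 1L, 1L, 1L, 1L))
  expect_identical(betti_curve(g, 1, grid)$values, c(0L, 0L, 1L, 2L, 2L, 1L))
})

test_that("perturbed fixture curves follow the derived stability characterization", {
  # Perturbing each edge weight within its tier interval keeps the degree-0
  # curve fixed: edge presence at every grid threshold is unchanged, and
  # degree-0 blurred Betti numbers count weak components.  The degree-1 curve
  # is NOT tier-invariant: the two-step path v1 -> v2 -> v4 has total length
  # w(v1,v2) + w(v2,v4), which ranges over (0.32, 0.5) across the tiers and
  # therefore can cross the 0.4 grid threshold.  When it does, that path
  # enters the degree-2 basis at 0.4 and fills one of the two cycles, so the
  # curve reads (0, 0, 1, 2, 1, 1) instead of (0, 0, 1, 2, 2, 1).
  grid <- seq(0, 0.5, by = 0.1)
  set.seed(314)
  seen <- c(early = FALSE, late = FALSE)
  for (i in 1:30) {
    p <- perturbed_example1()
    expect_identical(betti_curve(p$graph, 0, grid)$values,
                     c(5L, 2L, 1L, 1L, 1L, 1L))
    b1 <- betti_curve(p$graph, 1, grid)$values
    s <- p$weights[4] + p$weights[6]   # length of v1 -> v2 -> v4
    if (s > 0.4) {
      seen[["late"]] <- TRUE
      expect_identical(b1, c(0L, 0L, 1L, 2L, 2L, 1L))
    } else {
      seen[["early"]] <- TRUE
      expect_identical(b1, c(0L, 0L, 1L, 2L, 1L, 1L))
    }
  }
  expect_true(all(seen))   # both regimes actually exercised
})

test_that("single-node space has a constant unit degree-0 curve", {
  space <- quasimetric_space(matrix(0, 1, 1))
  expect_identical(betti_curve(space, 0, c(0, 0.5, 1))$values, c(1L, 1L, 1L))
})

test_that("default grids span the documented ranges inclusively", {
  g2 <- default_grids(2)
  expect_equal(g2$beta0$points, c(0, 1))
  expect_equal(g2$beta1$points, c(0, 2))
  g5 <- default_grids(5)
  expect_equal(g5$beta1$points, c(0, 0.5, 1.0, 1.5, 2.0))
  g256 <- default_grids(256)
  expect_length(g256$beta0$points, 256)
  expect_equal(diff(g256$beta0$points)[1], 1 / 255)
  expect_equal(diff(g256$beta1$points)[1], 2 / 255)
  expect_error(threshold_grid(0, 1, 1), "at least 2")
  expect_error(threshold_grid(1, 0, 8), "less than")
})

test_that("enumerate-once filtered curves equal naive per-level recomputation", {
  for (s in 1:4) {
    space <- random_quasimetric(7, seed = 700 + s)
    grid <- threshold_grid(0, max(space$d) * 1.1, 9)
    for (deg in 0:1) {
      fast <- betti_curve(space, deg, grid)$values
      naive <- vapply(grid$points,
                      function(l) betti_number(space, deg, l), numeric(1))
      expect_identical(fast, as.integer(naive))
    }
  }
})

test_that("curves are invariant to region permutation", {
  space <- random_quasimetric(8, seed = 808)
  grid <- threshold_grid(0, 1, 8)
  set.seed(1)
  perm <- sample(8)
  permuted <- quasimetric_space(space$d[perm, perm], is_closed = TRUE)
  for (deg in 0:1) {
    expect_identical(betti_curve(space, deg, grid)$values,
                     betti_curve(permuted, deg, grid)$values)
  }
})

test_that("subnetwork feature bundles have the documented layout and are deterministic", {
  set.seed(90)
  part <- synthetic_partition(3L)          # 9 subnetworks x 3 regions
  X <- matrix(rnorm(27 * 80), 80, 27)
  colnames(X) <- names(part$mapping)
  conn <- build_connectome(X)
  T_grid <- 8L
  fb <- subnetwork_features(conn, part, T = T_grid)
  expect_length(fb$x_betti, 18 * T_grid)
  expect_length(fb$beta0_joint, 9 * T_grid)
  expect_length(fb$x_connectome, 27 * 26)
  expect_identical(fb$subnetworks,
                   c("BGN", "CEREN", "DAN", "DMN", "FPN", "LN", "SMN",
                     "VAN", "VN"))
  fb2 <- subnetwork_features(conn, part, T = T_grid)
  expect_identical(fb$x_betti, fb2$x_betti)
  # degree-0 curves start at each subnetwork's node count
  expect_equal(unname(fb$beta0_joint[seq(1, 18 * T_grid / 2, by = T_grid)]),
               rep(3, 9))
})

test_that("unassigned regions are a configuration error naming the region", {
  part <- synthetic_partition(3L)
  X <- matrix(rnorm(28 * 60), 60, 28)
  colnames(X) <- c(names(part$mapping), "EXTRA")
  conn <- build_connectome(X)
  expect_error(subnetwork_features(conn, part, T = 4), "EXTRA")
})

test_that("two-class cohorts separate in at least one subnetwork curve", {
  spec <- cohort_spec(n_per_class = c(6L, 6L),
                      partition = synthetic_partition(3L),
                      T = 80L, seed = 5L)
  ch <- make_cohort(spec)
  fb <- cohort_features(ch, T = 8L)
  fm <- feature_matrices(fb)
  m0 <- colMeans(fm$betti[ch$labels == 0, , drop = FALSE])
  m1 <- colMeans(fm$betti[ch$labels == 1, , drop = FALSE])
  expect_gt(max(abs(m0 - m1)), 0.5)
})

test_that("long-format curve CSV round-trips the joint feature vector", {
  part <- synthetic_partition(3L)
  set.seed(17)
  X <- matrix(rnorm(27 * 60), 60, 27)
  colnames(X) <- names(part$mapping)
  fb <- list(subnetwork_features(build_connectome(X), part, T = 5L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves_csv(fb, path)
  back <- read_curves_csv(path)
  expect_equal(back[[1]], fb[[1]]$x_betti)
})
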