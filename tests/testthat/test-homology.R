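fixture <- example1_graph()

test_that("chain bases enumerate the expected tuples on the fixture", {
  b0 <- enumerate_paths(fixture, 0, 0.1, blurred = TRUE)
  expect_equal(nrow(b0$tuples), 5)
  b1 <- enumerate_paths(fixture, 1, 0.1, blurred = TRUE)
  expect_equal(unname(b1$tuples),
               matrix(c(1, 2, 1, 4, 3, 4), ncol = 2, byrow = TRUE)) # (v0,v1),(v0,v3),(v2,v3)
  # no 2-path at level 0.3 has an existing shortcut edge
  b2 <- enumerate_paths(fixture, 2, 0.3, blurred = TRUE)
  expect_equal(nrow(b2$tuples), 0)
  # at 0.5 exactly the 2-path (v1, v2, v4) enters
  b2b <- enumerate_paths(fixture, 2, 0.5, blurred = TRUE)
  expect_equal(unname(b2b$tuples), matrix(c(2, 3, 5), 1))
  expect_equal(b2b$lengths, 0.5)
  expect_error(enumerate_paths(fixture, 3, 1), "unsupported degree")
})

test_that("blurred boundary in degree 1 is the signed endpoint difference", {
  b0 <- enumerate_paths(fixture, 0, 0.2, blurred = TRUE)
  b1 <- enumerate_paths(fixture, 1, 0.2, blurred = TRUE)
  d1 <- boundary_matrix(b0, b1)
  # column for (v0, v1): +1 at (v1), -1 at (v0)
  col <- d1[, which(b1$keys == "1,2")]
  expect_equal(col, c(-1, 1, 0, 0, 0))
  expect_true(all(colSums(d1) == 0))  # every column is (target) - (source)
})

test_that("strict degree-1 boundary is the zero operator on positive-distance spaces", {
  for (lev in c(0.1, 0.2, 0.3)) {
    b0 <- enumerate_paths(fixture, 0, lev, blurred = FALSE)
    b1 <- enumerate_paths(fixture, 1, lev, blurred = FALSE)
    d1 <- boundary_matrix(b0, b1)
    expect_true(all(d1 == 0))
  }
})

test_that("a degenerate middle drop contributes zero but endpoint drops survive", {
  # two nodes with edges both ways: the 2-path (v0, v1, v0) is admissible
  d <- matrix(c(0, 0.2, 0.3, 0), 2, 2, byrow = TRUE)
  space <- quasimetric_space(d)
  b1 <- enumerate_paths(space, 1, 0.5, blurred = TRUE)
  b2 <- enumerate_paths(space, 2, 0.5, blurred = TRUE)
  expect_true("1,2,1" %in% b2$keys)
  d2 <- boundary_matrix(b1, b2)
  col <- d2[, which(b2$keys == "1,2,1")]
  # drop v0 -> (v1, v0) sign +1; drop middle -> (v0, v0) degenerate, 0;
  # drop last -> (v0, v1) sign +1
  expect_equal(col[which(b1$keys == "2,1")], 1)
  expect_equal(col[which(b1$keys == "1,2")], 1)
})

test_that("boundary operators compose to zero on random closed spaces", {
  for (s in 1:10) {
    space <- random_quasimetric(sample(4:12, 1), seed = 400 + s)
    lev <- stats::quantile(space$d[space$d > 0], 0.6)
    b0 <- enumerate_paths(space, 0, lev, blurred = TRUE)
    b1 <- enumerate_paths(space, 1, lev, blurred = TRUE)
    b2 <- enumerate_paths(space, 2, lev, blurred = TRUE)
    d1 <- boundary_matrix(b0, b1)
    d2 <- boundary_matrix(b1, b2)
    expect_true(all(d1 %*% d2 == 0))
  }
})

test_that("fixture Betti numbers match the worked example pointwise", {
  expect_equal(betti_number(fixture, 0, 0.1), 2)
  expect_equal(betti_number(fixture, 1, 0.3), 2)
  expect_equal(betti_number(fixture, 1, 0.5), 1)
  expect_error(betti_number(fixture, 2, 0.1), "unsupported degree")
})

test_that("degree-0 Betti number equals the union-find component count", {
  for (s in 1:20) {
    space <- random_quasimetric(8, seed = 500 + s)
    levels <- seq(0, max(space$d), length.out = 8)
    for (lev in levels) {
      expect_identical(betti_number(space, 0, lev),
                       weak_component_count(space, lev))
    }
  }
  # and on the non-complete fixture
  for (lev in seq(0, 0.5, by = 0.1)) {
    expect_identical(betti_number(fixture, 0, lev),
                     weak_component_count(fixture, lev))
  }
})

test_that("strict magnitude homology matches its direct characterizations", {
  for (s in 1:5) {
    space <- random_quasimetric(8, seed = 600 + s)
    n <- nrow(space$d)
    expect_equal(magnitude_betti(space, 0, 0), n)
    expect_equal(magnitude_betti(space, 0, 0.37), 0)
    # degree 1 against the triangle-census oracle at every pair distance
    levels <- unique(space$d[space$d > 0])
    for (lev in levels) {
      expect_equal(magnitude_betti(space, 1, lev), mh1_census(space$d, lev),
                   info = sprintf("seed %d level %g", s, lev))
    }
  }
})

test_that("exact rank agrees with the floating singular-value rank", {
  set.seed(77)
  for (i in 1:40) {
    M <- random_sign_matrix(sample(1:12, 1), sample(1:12, 1))
    expect_identical(rank_exact(M), rank_float(M))
  }
  expect_identical(rank_exact(matrix(0, 3, 3)), 0L)
  expect_identical(rank_exact(matrix(numeric(0), 0, 5)), 0L)
  expect_identical(rank_exact(diag(4)), 4L)
  # non-unit pivots exercise the fraction-free fallback
  M <- matrix(c(2, 4, 6, 4, 8, 12, 1, 0, 1), 3, 3, byrow = TRUE)
  expect_identical(rank_exact(M), 2L)
})

test_that("Betti values stabilize beyond the largest relevant length and beta0 never increases", {
  space <- random_quasimetric(7, seed = 901)
  top <- max(space$d)
  expect_identical(betti_number(space, 0, top), betti_number(space, 0, top * 3))
  expect_identical(betti_number(space, 1, 2 * top),
                   betti_number(space, 1, 5 * top))
  vals <- vapply(seq(0, top, length.out = 12),
                 function(l) betti_number(space, 0, l), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("chain-complex JSON dump round-trips tuples and sparse triplets", {
  path <- withr::local_tempfile(fileext = ".json")
  chain_complex_json(fixture, 0.5, blurred = TRUE, path = path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(obj$basis1), 6)
  expect_equal(obj$basis2, matrix(c(2, 3, 5), 1))
  expect_setequal(obj$delta2$value, c(1, -1, 1))
})
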