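test_that("sample_field draws reproducible uniform fields with axons of exact length", {
  f <- sample_field(1000, r = 0.02, h = 0.04, seed = 7)
  expect_s3_class(f, "cell_field")
  expect_true(all(f$positions >= 0 & f$positions <= 1))
  expect_true(all(f$angles >= 0 & f$angles < 2 * pi))
  expect_equal(sqrt(rowSums((f$heads - f$positions)^2)), rep(0.04, 1000),
               tolerance = 1e-12)
  # determinism contract
  expect_identical(sample_field(1000, r = 0.02, h = 0.04, seed = 7), f)
  expect_false(identical(sample_field(1000, r = 0.02, h = 0.04, seed = 8), f))
  # h = 0 forces head/tail coincidence
  f0 <- sample_field(1, r = 0.1, h = 0, seed = 1)
  expect_equal(f0$heads, f0$positions)
  expect_error(sample_field(0, r = 0.1), "positive integer")
  expect_error(sample_field(10, r = 0), "`r`")
})

test_that("mean neighbour count of a random interior point matches the occupancy B = pi R^2 n", {
  # Monte-Carlo check of the occupancy definition: disks kept fully interior
  # so no boundary truncation enters
  n <- 1e5
  r <- 0.02
  f <- sample_field(n, r = r, seed = 11)
  set.seed(12)
  qx <- runif(300, r, 1 - r)
  qy <- runif(300, r, 1 - r)
  counts <- vapply(seq_along(qx), function(i) {
    sum((f$positions[, 1] - qx[i])^2 + (f$positions[, 2] - qy[i])^2 <= r^2)
  }, numeric(1))
  expected <- pi * r^2 * n # 125.66
  expect_equal(mean(counts), expected, tolerance = 3 / expected)
})

test_that("the three coupling rules reproduce hand-checked geometries", {
  # circle: distance 0.05 vs diameters 0.06 / 0.04
  f <- cell_field(rbind(c(0.1, 0.5), c(0.15, 0.5)), r = 0.03)
  expect_equal(nrow(build_connectivity(f, "circle")$edges), 1)
  f2 <- cell_field(rbind(c(0.1, 0.5), c(0.15, 0.5)), r = 0.02)
  expect_equal(nrow(build_connectivity(f2, "circle")$edges), 0)
  # vector: head of A reaches tail of B, not conversely
  fv <- cell_field(rbind(c(0.2, 0.5), c(0.33, 0.5)), r = 0.02, h = 0.1,
                   angles = 0)
  g <- build_connectivity(fv, "vector")
  expect_true(g$directed)
  expect_equal(g$edges, rbind(c(1L, 2L)))
  expect_error(build_connectivity(fv, "nonsense"))
})

test_that("cell-list connectivity matches brute-force pairwise distances", {
  for (case in c("circle", "dipole", "vector")) {
    for (seed in 1:3) {
      f <- sample_field(80, r = 0.06, h = 0.1, seed = seed)
      g <- build_connectivity(f, case)
      expect_identical(edge_key(g$edges, g$directed),
                       edge_key(brute_edges(f, case), g$directed),
                       info = paste(case, seed))
    }
  }
})

test_that("dipole with h = 0 equals circle, and vector edges are a subset of dipole edges", {
  f <- sample_field(150, r = 0.05, h = 0, seed = 21)
  expect_identical(edge_key(build_connectivity(f, "dipole")$edges, FALSE),
                   edge_key(build_connectivity(f, "circle")$edges, FALSE))
  fh <- sample_field(150, r = 0.05, h = 0.1, seed = 22)
  vec <- edge_key(build_connectivity(fh, "vector")$edges, FALSE)
  dip <- edge_key(build_connectivity(fh, "dipole")$edges, FALSE)
  expect_true(all(unique(vec) %in% dip))
})

test_that("spanning detection follows the cluster/edge-contact definition", {
  # a chain of overlapping disks crossing the square spans
  r <- 0.06
  xs <- seq(0, 1, by = 2 * r * 0.9)
  chain <- cell_field(cbind(xs, 0.5), r = r)
  g <- build_connectivity(chain, "circle")
  expect_true(spanning_cluster_exists(g, chain))
  # two disjoint clusters touching only one edge each do not span
  two <- cell_field(rbind(c(0.02, 0.3), c(0.98, 0.7)), r = 0.05)
  g2 <- build_connectivity(two, "circle")
  expect_false(spanning_cluster_exists(g2, two))
  # empty-ish field: single interior cell
  one <- cell_field(cbind(0.5, 0.5), r = 0.05)
  expect_false(spanning_cluster_exists(build_connectivity(one, "circle"), one))
})

test_that("estimate_bc brackets the 0.5 crossing and errors outside the grid", {
  est <- estimate_bc("circle", n_cells = 400, n_realizations = 8,
                     b_grid = seq(0.5, 2, by = 0.25), seed = 5)
  expect_s3_class(est, "percolation_estimate")
  expect_true(est$b_c_hat >= 0.5 && est$b_c_hat <= 2)
  expect_true(all(est$spanning_curve$spanning_prob >= 0 &
                  est$spanning_curve$spanning_prob <= 1))
  # far-supercritical single-point grid cannot be bracketed
  expect_error(
    estimate_bc("circle", n_cells = 200, n_realizations = 5, b_grid = 10,
                seed = 1),
    "bracket"
  )
  # far-subcritical grid never crosses
  expect_error(
    estimate_bc("circle", n_cells = 200, n_realizations = 5,
                b_grid = c(0.05, 0.1), seed = 1),
    "never"
  )
})

test_that("spanning probability at fixed B is stable under more realizations", {
  span_prob <- function(n_real, seed) {
    n <- 400
    r <- sqrt(1.1 / (pi * n)) # B = 1.1
    set.seed(seed)
    mean(vapply(seq_len(n_real), function(k) {
      f <- sample_field(n, r = r)
      spanning_cluster_exists(build_connectivity(f, "circle"), f)
    }, logical(1)))
  }
  p1 <- span_prob(16, 31)
  p2 <- span_prob(32, 32)
  # binomial error at n = 16 is ~0.125; allow three sigma
  expect_lt(abs(p1 - p2), 0.38)
})

test_that("finite-size drift of the circle threshold is bounded at desk scale", {
  b1 <- estimate_bc("circle", n_cells = 1000, n_realizations = 12,
                    b_grid = seq(0.8, 1.5, by = 0.1), seed = 41)$b_c_hat
  b2 <- estimate_bc("circle", n_cells = 3000, n_realizations = 12,
                    b_grid = seq(0.8, 1.5, by = 0.1), seed = 42)$b_c_hat
  expect_lt(abs(b1 - b2), 0.15)
})
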