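parabola_profile <- function(zmax = 3, step = 0.01, vertex = 1) {
  z <- seq(0, zmax, by = step)
  free_energy_profile(z, (z - vertex)^2)
}

flat_profile <- function(level = 2, n = 101) {
  z <- seq(0, 1, length.out = n)
  free_energy_profile(z, rep(level, n))
}

test_that("profile constructor enforces its invariants", {
  expect_error(free_energy_profile(c(0, 1), c(0, 1)), "at least 3")
  expect_error(free_energy_profile(c(0, 1, 1), c(0, 1, 2)), "strictly increasing")
  expect_error(free_energy_profile(c(0, 1, 2), c(0, NA, 2)), "finite")
  expect_error(free_energy_profile(c(0, 1, 2), c(0, 1, 2), temperature = -1),
               "positive")
  expect_error(free_energy_profile(c(0, 1, 2), c(0, 1, 2), err = c(1, -1, 1)),
               "err")
})

test_that("read_profile handles the FES dialect and round-trips", {
  f <- tempfile(fileext = ".fes")
  writeLines(c("#! FIELDS z G err", "# comment", "0.0 5.0 0.1",
               "0.2 1.5 0.2", "0.1 3.0 0.3"), f)
  p <- read_profile(f)
  expect_equal(p$z, c(0, 0.1, 0.2))         # sorted ascending
  expect_equal(p$G, c(5, 3, 1.5))
  expect_equal(p$err, c(0.1, 0.3, 0.2))

  p2 <- make_profile(profile_spec_single_ion())
  f2 <- tempfile(fileext = ".fes")
  write_profile(p2, f2)
  p3 <- read_profile(f2)
  expect_equal(p3$z, p2$z, tolerance = 1e-9)
  expect_equal(p3$G, p2$G, tolerance = 1e-9)
})

test_that("read_profile reports malformed files with line numbers", {
  f <- tempfile()
  writeLines(c("0.0 1.0", "0.1 oops"), f)
  expect_error(read_profile(f), "line 2")
  writeLines(c("0.0 1.0", "0.1 2.0", "0.1 3.0"), f)
  expect_error(read_profile(f), "duplicate")
  writeLines("0.0 1.0", f)
  expect_error(read_profile(f), "fewer than 3|at least 3")
  expect_error(read_profile(tempfile()), "not found")
})

test_that("bulk_reference averages the tail and validates tail_fraction", {
  expect_equal(bulk_reference(flat_profile(level = 3.5)), 3.5)
  expect_error(bulk_reference(flat_profile(), tail_fraction = 0.6), "0.5")
  expect_error(bulk_reference(flat_profile(), tail_fraction = 0), "0.5")
  p <- make_profile(profile_spec_single_ion())
  expect_lt(abs(bulk_reference(p)), 0.1)    # generator plateau sits at 0
})

test_that("find_minima locates minima and ignores monotonic profiles", {
  p <- parabola_profile(vertex = 1)
  m <- find_minima(p, prominence_min = 0.5)
  expect_equal(nrow(m), 1)
  expect_lt(abs(m$z_min - 1), 0.01 + 1e-12)

  z <- seq(0, 1, by = 0.01)
  mono <- free_energy_profile(z, 5 * z)
  expect_equal(nrow(find_minima(mono, 1)), 0)
})

test_that("find_minima is invariant under energy offset and z shift", {
  p <- make_profile(profile_spec_single_ion())
  m0 <- find_minima(p, 1)
  p_shift <- free_energy_profile(p$z, p$G + 17.3)
  m1 <- find_minima(p_shift, 1)
  expect_equal(m1$z_min, m0$z_min)
  expect_equal(m1$depth, m0$depth, tolerance = 1e-12)
  p_zshift <- free_energy_profile(p$z + 0.5, p$G)
  m2 <- find_minima(p_zshift, 1)
  expect_equal(m2$depth, m0$depth, tolerance = 1e-12)
})

test_that("every reported minimum is at or below both neighbours", {
  for (spec in list(profile_spec_single_ion(), profile_spec_two_ion())) {
    p <- make_profile(spec)
    m <- find_minima(p, 1)
    for (i in m$index) {
      expect_lte(p$G[i], p$G[i - 1])
      expect_lte(p$G[i], p$G[i + 1])
    }
  }
})

test_that("global_minimum picks the deepest well with smaller-z tie-break", {
  z <- seq(0, 2, by = 0.01)
  two_wells <- free_energy_profile(
    z, -5 * exp(-(z - 0.5)^2 / 0.005) - 5 * exp(-(z - 1.5)^2 / 0.005))
  gm <- global_minimum(two_wells)
  expect_equal(gm$z_min, 0.5)

  flat <- flat_profile()
  gm_flat <- global_minimum(flat)
  expect_equal(gm_flat$depth, 0)
  expect_equal(gm_flat$z_min, flat$z[2])
})

test_that("depth_difference is a signed antisymmetric difference", {
  p <- make_profile(profile_spec_single_ion())
  m <- find_minima(p, 1, labels = attr(p, "well_labels"))
  s3 <- m[m$label == "S3", ]
  s4 <- m[m$label == "S4", ]
  expect_equal(depth_difference(p, s4, s3), 3, tolerance = 0.2)
  expect_equal(depth_difference(p, s3, s3), 0)
  expect_equal(depth_difference(p, s4, s3), -depth_difference(p, s3, s4))
})

test_that("unbinding_distance finds the flattening point", {
  p1 <- make_profile(profile_spec_single_ion())
  expect_equal(as.numeric(unbinding_distance(p1, tol = 1)), 2.0,
               tolerance = 0.06 / 2.0)
  p2 <- make_profile(profile_spec_two_ion())
  expect_equal(as.numeric(unbinding_distance(p2, tol = 1)), 1.0,
               tolerance = 0.06 / 1.0)
  flat <- flat_profile()
  expect_equal(as.numeric(unbinding_distance(flat, tol = 1)), flat$z[3])
})

test_that("unbinding_distance is monotone non-increasing in tol and warns when unconverged", {
  p <- make_profile(profile_spec_single_ion())
  tols <- c(0.5, 1, 2, 5, 10)
  d <- vapply(tols, function(tl) as.numeric(unbinding_distance(p, tl)), numeric(1))
  expect_true(all(diff(d) <= 0))

  z <- seq(0, 1, by = 0.01)
  # exponential rise: even the tail mean is more than tol away from the end
  steep <- free_energy_profile(z, exp(5 * z))
  expect_warning(u <- unbinding_distance(steep, tol = 1), "never flattens")
  expect_equal(as.numeric(u), 1)
  expect_false(attr(u, "converged"))
})

test_that("barrier_height matches a brute-force scan and handles edge shapes", {
  p <- make_profile(profile_spec_single_ion())
  m <- find_minima(p, 1, labels = attr(p, "well_labels"))
  s3 <- m[m$label == "S3", ]
  b <- barrier_height(p, s3, "increasing")
  # independent oracle: exhaustive scan over the grid
  oracle <- max(p$G[p$z >= s3$z_min]) - s3$G_min
  expect_equal(b, oracle)
  expect_gte(b, s3$depth - 1e-9)            # at least the well depth

  # truncated parabola: barrier equals plateau minus minimum
  # (prominence is limited by the lower left boundary, 0.25)
  z <- seq(0, 2, by = 0.01)
  G <- pmin((z - 0.5)^2, 1)
  tp <- free_energy_profile(z, G)
  mm <- find_minima(tp, 0.2)
  expect_equal(nrow(mm), 1)
  expect_equal(barrier_height(tp, mm[1, ], "increasing"), 1)

  # monotonically decreasing beyond the minimum: zero barrier
  dec <- free_energy_profile(z, c(rev(z[z <= 0.5]), -5 * (z[z > 0.5] - 0.5)))
  gm <- global_minimum(dec)
  expect_equal(barrier_height(dec, gm, "increasing"), 0)
})

test_that("block_error behaves like a standard error on iid data", {
  expect_equal(block_error(rep(3.2, 100), 10), 0)
  set.seed(101)
  x <- rnorm(10000)
  se <- block_error(x, 20)
  expect_gt(se, 0.005)                       # 1/sqrt(n) = 0.01, factor-2 band
  expect_lt(se, 0.02)
  expect_error(block_error(rnorm(10), 10), "too short")
  expect_error(block_error(rnorm(10), 1), ">= 2")
})

test_that("block_error grows with block size on correlated data then plateaus", {
  x <- make_ar1_series(20000, rho = 0.9, sigma = 1, seed = 7)
  se_small_blocks <- block_error(x, 1000)    # blocks shorter than corr. time
  se_large_blocks <- block_error(x, 20)
  expect_gt(se_large_blocks, se_small_blocks)
  # iid reference: no growth beyond noise
  y <- make_ar1_series(20000, rho = 0, sigma = 1, seed = 7)
  expect_lt(block_error(y, 20) / block_error(y, 1000), 2)
})
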