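test_that("intracellular action potential has the stated closed form", {
  expect_equal(intracellular_ap(0), -90)
  expect_equal(intracellular_ap(-5), -90)
  expect_equal(intracellular_ap(3), 96 * 27 * exp(-3) - 90)
  expect_equal(intracellular_ap(40), -90, tolerance = 1e-6)  # decays back
})

test_that("fiber potentials decay and broaden with depth, and superpose", {
  geom <- muscle_geometry()
  # same transverse position, two depths below the top electrode
  shallow <- fiber_potential(c(0, geom$muscle_radius - 1, 0), c(0, 0))
  deep <- fiber_potential(c(0, geom$muscle_radius - 11, 0), c(0, 0))
  expect_gt(diff(range(shallow)), diff(range(deep)))   # amplitude
  # duration: samples above 10% of each waveform's own peak
  dur <- function(w) sum(abs(w) > 0.1 * max(abs(w)))
  expect_gt(dur(deep), dur(shallow))
  # zero-length window
  expect_length(fiber_potential(c(0, 20, 0), c(0, 0), window_ms = 0), 0)
  expect_error(fiber_potential(c(0, 20, 0), c(0, 0), fs = 500), "1024")
})

test_that("MUAPs are linear in the fiber set", {
  pool <- build_pool(count = 3, seed = 5)
  grid <- grid_spec(3, 3, ied = 8)
  m <- compute_muaps(pool, grid, seed = 5)
  # a unit with one fiber equals that fiber's potential (axial center 0
  # so the standalone fiber interface sees the same geometry)
  single <- pool
  single$units <- pool$units[1, , drop = FALSE]
  single$units$n_fibers <- 1L
  single$units$axial_center <- 0
  single$fibers <- list(pool$fibers[[1]][1, , drop = FALSE])
  ms <- compute_muaps(single, grid, seed = 5)
  cv <- conduction_velocity(1)
  fp <- fiber_potential(pool$fibers[[1]][1, ], unlist(
    electrode_positions(grid)[1, c("x", "y")]), cv = cv)
  expect_equal(as.numeric(ms$waveforms[1, 1, ]), fp, tolerance = 1e-9)
  # duplicating a fiber doubles its contribution
  dbl <- single
  dbl$units$n_fibers <- 2L
  dbl$fibers <- list(single$fibers[[1]][c(1, 1), , drop = FALSE])
  md <- compute_muaps(dbl, grid, seed = 5)
  expect_equal(md$waveforms[1, , ], 2 * ms$waveforms[1, , ],
               tolerance = 1e-9)
  # subsample >= n_fibers is the identity
  mfull <- compute_muaps(pool, grid, fiber_subsample = 5000, seed = 5)
  expect_equal(mfull$waveforms, m$waveforms)
})

test_that("merging two units sums their MUAPs", {
  pool <- build_pool(count = 4, seed = 9)
  grid <- grid_spec(3, 2, ied = 8)
  m <- compute_muaps(pool, grid, seed = 9)
  pool$units$axial_center <- 0   # shared fascicle span for superposition
  merged <- pool
  merged$units <- pool$units[1, , drop = FALSE]
  merged$units$n_fibers <- pool$units$n_fibers[1] + pool$units$n_fibers[2]
  merged$fibers <- list(rbind(pool$fibers[[1]], pool$fibers[[2]]))
  # same CV for a clean superposition check
  tis <- tissue_electrical(cv_min = 4, cv_max = 4)
  m2 <- compute_muaps(pool, grid, tissue = tis, seed = 9)
  mm <- compute_muaps(merged, grid, tissue = tis, seed = 9)
  expect_equal(mm$waveforms[1, , ],
               m2$waveforms[1, , ] + m2$waveforms[2, , ], tolerance = 1e-9)
})

test_that("axial translation of grid and pool together leaves MUAPs unchanged", {
  pool <- build_pool(count = 3, seed = 12)
  g0 <- grid_spec(4, 3, ied = 8)
  g1 <- grid_spec(4, 3, ied = 8, origin = g0$origin + c(7, 0))
  shifted <- pool
  shifted$units$axial_center <- pool$units$axial_center + 7
  m0 <- compute_muaps(pool, g0, seed = 2)
  m1 <- compute_muaps(shifted, g1, seed = 2)
  expect_equal(m0$waveforms, m1$waveforms, tolerance = 1e-9)
})

test_that("peak-to-peak amplitude decreases monotonically with unit depth", {
  geom <- muscle_geometry()
  grid <- grid_spec(3, 3, ied = 4)
  p2p <- vapply(c(4, 10, 16, 22), function(rad_off) {
    pool <- build_pool(count = 2, seed = 3)
    ctr <- c(0, geom$muscle_radius - rad_off)
    pool$units <- pool$units[1, , drop = FALSE]
    pool$units$n_fibers <- 15L
    pool$units$axial_center <- 0
    fib <- pool$fibers[[1]][1:15, , drop = FALSE]
    fib[, "u"] <- ctr[1] + (fib[, "u"] - mean(fib[, "u"]))
    fib[, "w"] <- ctr[2] + (fib[, "w"] - mean(fib[, "w"]))
    pool$fibers <- list(fib)
    m <- compute_muaps(pool, grid, seed = 3)
    max(apply(m$waveforms[1, , ], 1, function(x) diff(range(x))))
  }, numeric(1))
  expect_true(all(diff(p2p) < 0))
})

test_that("conduction velocity stays in band and increases with size", {
  cv <- conduction_velocity(c(15, 100, 1500))
  expect_true(all(diff(cv) > 0))
  expect_true(all(cv >= 3.5 & cv <= 4.5))
  expect_error(tissue_electrical(cv_min = 1), "m/s")
})
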