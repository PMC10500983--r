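test_that("composite grid reproduces all printed montage configurations", {
  g <- composite_grid()
  expect_equal(g$n, 256L)
  expect_equal(g$span, c(100, 36))
  expect_equal(decimate_grid(g, 2)$n, 64L)
  expect_equal(decimate_grid(g, 3)$n, 35L)
  expect_equal(decimate_grid(g, 4)$n, 20L)
  expect_equal(decimate_grid(g, 2)$ied, 8)
  expect_equal(crop_center(g, 8, 8)$n, 63L)
  expect_equal(crop_center(g, 7, 5)$n, 34L)
  expect_equal(crop_center(g, 5, 4)$n, 19L)
  u <- ultradense_grid()
  expect_equal(u$n, 256L)
  expect_equal(u$span, c(50, 18))
  expect_equal(decimate_grid(u, 2)$n, 64L)
  expect_equal(decimate_grid(u, 2)$ied, 4)
})

test_that("decimation composes and factor 1 is the identity", {
  g <- composite_grid()
  expect_equal(decimate_grid(g, 1)$n, g$n)
  ab <- decimate_grid(decimate_grid(g, 2), 2)
  direct <- decimate_grid(g, 4)
  expect_equal(ab$n, direct$n)
  expect_equal(electrode_positions(ab), electrode_positions(direct))
  expect_error(decimate_grid(g, 0), "factor")
})

test_that("area bookkeeping follows the lattice", {
  g <- composite_grid()
  expect_equal(grid_area(g), 36)
  expect_equal(grid_area(crop_center(g, 8, 8)), 7 * 7 * 16 / 100)
  # odd row/col counts shrink the covered span (printed "32 cm^2" is the
  # rounded 9.6 x 3.2 cm descriptor)
  expect_equal(grid_area(decimate_grid(g, 2)), 30.72)
})

test_that("quadrant split partitions the composite grid", {
  g <- composite_grid()
  q <- split_quadrants(g)
  expect_length(q, 4)
  expect_true(all(vapply(q, function(x) x$n, integer(1)) == 64L))
  maps <- lapply(q, attr, "channel_map")
  all_idx <- sort(unlist(maps))
  expect_equal(all_idx, seq_len(256L))
  # channel maps round-trip to parent coordinates
  ppos <- electrode_positions(g)
  for (k in 1:4) {
    cpos <- electrode_positions(q[[k]])
    expect_equal(cpos$x, ppos$x[maps[[k]]])
    expect_equal(cpos$y, ppos$y[maps[[k]]])
  }
  expect_error(split_quadrants(grid_spec(13, 5, 4)), "composite")
})

test_that("simulated grids hit the requested spans and fail when too coarse", {
  g <- simulated_grid(10, 4)
  expect_equal(c(g$rows, g$cols), c(26L, 10L))
  expect_equal(grid_area(g), 36)
  expect_equal(grid_area(simulated_grid(4, 2)), 14.4)
  expect_equal(simulated_grid(10, 36)$cols, 2L)
  expect_error(simulated_grid(10, 40), "ied")
  # centered on the origin
  pos <- electrode_positions(g)
  expect_equal(mean(pos$x), 0, tolerance = 1e-12)
  expect_equal(mean(pos$y), 0, tolerance = 1e-12)
})

test_that("spatial interpolation preserves source electrodes and improves with density", {
  fine <- grid_spec(9, 9, ied = 2)
  coarse4 <- decimate_grid(fine, 2)   # 4-mm IED
  coarse8 <- decimate_grid(fine, 4)   # 8-mm IED
  # smooth synthetic field sampled on the grids
  field <- function(pos, t) {
    exp(-((pos$x - 2)^2 + (pos$y + 1)^2) / 40) * sin(t / 3) +
      0.3 * exp(-(pos$x^2 + pos$y^2) / 60) * cos(t / 5)
  }
  tt <- 1:50
  sample_grid <- function(g) {
    pos <- electrode_positions(g)
    t(vapply(tt, function(t) field(pos, t), numeric(nrow(pos))))
  }
  truth <- t(sample_grid(fine))
  from4 <- t(sample_grid(coarse4))
  from8 <- t(sample_grid(coarse8))
  up4 <- spatial_interpolate(from4, coarse4, fine)
  up8 <- spatial_interpolate(from8, coarse8, fine)
  # identity when grids match
  expect_equal(spatial_interpolate(from4, coarse4, coarse4), from4,
               tolerance = 1e-9)
  # source positions exactly preserved
  ppos <- electrode_positions(fine)
  cpos <- electrode_positions(coarse4)
  shared <- match(paste(cpos$x, cpos$y), paste(ppos$x, ppos$y))
  expect_equal(up4[shared, ], from4, tolerance = 1e-9)
  # denser source grid interpolates more faithfully
  cor4 <- mean(diag(cor(t(up4), t(truth))))
  cor8 <- mean(diag(cor(t(up8), t(truth))))
  expect_gt(cor4, cor8)
  expect_error(spatial_interpolate(from4[1:2, ], grid_spec(2, 1, 4), fine),
               "channel count|4 source")
})

test_that("grid JSON round-trips", {
  g <- composite_grid()
  path <- withr::local_tempfile(fileext = ".json")
  write_grid_json(g, path)
  g2 <- read_grid_json(path)
  expect_equal(g2$n, g$n)
  expect_equal(electrode_positions(g2), electrode_positions(g))
})
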