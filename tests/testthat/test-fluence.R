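test_that("a static rectangular aperture gives its closed-form fluence", {
  beam <- static_beam(xa = -50.5, xb = 50.5, open_pairs = 21:40, total_mu = 80)
  fm <- compute_fluence(beam, spacing_mm = 1)
  inside <- fm$values[fm$y > -49 & fm$y < 49, fm$x > -49 & fm$x < 49]
  expect_equal(unname(inside), matrix(80, nrow(inside), ncol(inside)),
               tolerance = 1e-9)
  outside <- fm$values[abs(fm$y) > 52, ]
  expect_equal(max(abs(outside)), 0)
  # edge pixel at x in [50, 51]: aperture covers half the pixel
  edge_col <- which(abs(fm$x - 50.5) < 1e-9)
  expect_equal(fm$values[which(abs(fm$y) < 1)[1], edge_col], 80 * 0.5,
               tolerance = 1e-9)
})

test_that("a constant-gap sliding window yields uniform interior fluence", {
  plan <- make_sliding_window_plan(1, "ramp", seed = 1)
  fm <- compute_fluence(plan$beams[[1]], spacing_mm = 1)
  # gap 10 mm swept over 80 mm at 100 MU -> 12.5 MU plateau
  interior <- fm$values[fm$y > -40 & fm$y < 40, fm$x > -25 & fm$x < 15]
  expect_equal(unname(interior), matrix(12.5, nrow(interior), ncol(interior)),
               tolerance = 1e-6)
})

test_that("analytic crossing-time integration matches brute-force subsampling", {
  for (seed in c(2, 9)) {
    plan <- make_sliding_window_plan(1, "random", seed = seed,
                                     n_control_points = 6)
    beam <- plan$beams[[1]]
    fm <- compute_fluence(beam, spacing_mm = 2, x_range = c(-60, 60),
                          y_range = c(-60, 60))
    oracle <- brute_force_fluence(beam, spacing_mm = 2, n_sub = 1000)
    expect_lte(max(abs(fm$values - oracle$values)), 0.001 * max(oracle$values))
  }
})

test_that("fluence integral is invariant under control-point refinement", {
  plan <- make_sliding_window_plan(1, "random", seed = 4, n_control_points = 11)
  beam <- plan$beams[[1]]
  idx2 <- sort(unique(c(beam$index, (beam$index[-1] + beam$index[-11]) / 2)))
  p <- interpolate_beam(beam, idx2)
  beam2 <- dynamic_beam("fine", idx2, p$bank_a, p$bank_b, beam$total_mu,
                        geometry = beam$geometry)
  f1 <- compute_fluence(beam, spacing_mm = 2)
  f2 <- compute_fluence(beam2, spacing_mm = 2)
  expect_equal(f1$values, f2$values, tolerance = 1e-9)
  expect_equal(fluence_integral(f1), fluence_integral(f2), tolerance = 1e-12)
})

test_that("leaf transmission adds dose under the leaves and bounds hold", {
  beam <- static_beam(xa = -20, xb = 20, total_mu = 50)
  fm <- compute_fluence(beam, spacing_mm = 2, transmission = 0.02)
  under_leaf <- fm$values[abs(fm$y) > 60, ]
  expect_equal(unname(under_leaf),
               matrix(1, nrow(under_leaf), ncol(under_leaf)), tolerance = 1e-9)
  expect_lte(max(fm$values), 50 * 1.02 + 1e-9)
  expect_error(compute_fluence(beam, transmission = 1.2), "transmission")
  expect_error(compute_fluence(beam, spacing_mm = 0.01), "spacing")
})

test_that("fluence differences behave elementwise with a faithful summary", {
  a <- uniform_map(10)
  b <- uniform_map(7)
  d <- fluence_difference(a, b)
  expect_equal(unname(d$values), matrix(3, 21, 21))
  expect_equal(d$summary$max_abs, 3)
  expect_equal(fluence_difference(a, a)$summary$max_abs, 0)
  b2 <- uniform_map(7, n = 11)
  expect_error(fluence_difference(a, b2), "different grids")
  # widening the sliding gap by a 0.5 mm trailing-bank shift raises the
  # plateau by MU * shift / sweep_length = 100 * 0.5 / 80, never lowers it
  plan <- make_sliding_window_plan(1, "ramp", seed = 1)
  f0 <- compute_fluence(plan$beams[[1]], spacing_mm = 1)
  f1 <- compute_fluence(shift_bank(plan$beams[[1]], "A", 0.5), spacing_mm = 1)
  d2 <- fluence_difference(f1, f0)
  expect_gte(min(d2$values), -1e-9)
  plateau <- d2$values[abs(d2$y) < 30, d2$x > -25 & d2$x < 15]
  expect_equal(unname(plateau), matrix(0.625, nrow(plateau), ncol(plateau)),
               tolerance = 1e-6)
  # and the independent subsampled renderer sees the same difference
  o0 <- brute_force_fluence(plan$beams[[1]], spacing_mm = 2, n_sub = 400)
  o1 <- brute_force_fluence(shift_bank(plan$beams[[1]], "A", 0.5),
                            spacing_mm = 2, n_sub = 400)
  f0c <- compute_fluence(plan$beams[[1]], spacing_mm = 2,
                         x_range = c(-60, 60), y_range = c(-60, 60))
  f1c <- compute_fluence(shift_bank(plan$beams[[1]], "A", 0.5), spacing_mm = 2,
                         x_range = c(-60, 60), y_range = c(-60, 60))
  expect_lte(max(abs((f1c$values - f0c$values) - (o1$values - o0$values))),
             0.002 * max(o0$values))
})

test_that("fluence maps round-trip through the CSV format", {
  plan <- make_sliding_window_plan(1, "pyramid", seed = 1)
  fm <- compute_fluence(plan$beams[[1]], spacing_mm = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fluence_csv(fm, path)
  back <- read_fluence_csv(path)
  expect_equal(back$x, fm$x)
  expect_equal(back$y, fm$y)
  expect_equal(back$values, fm$values, tolerance = 1e-6)
})
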