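test_that("with attenuation off, dose is the fluence carried along each ray", {
  beam <- static_beam(xa = -50, xb = 50, total_mu = 100, gantry = 0)
  plan <- treatment_plan("p", list(beam))
  ph <- make_phantom(voxel_mm = 4)
  dose <- compute_dose(plan, ph$phantom, attenuation_per_mm = 0)
  # gantry 0: rays run along z, dose constant along z and equal to the
  # normalized fluence (100 inside the field)
  mid <- dose$values[, which.min(abs(ph$phantom$y)), ]
  expect_equal(max(abs(mid[abs(ph$phantom$x) < 45, ] - 100)), 0,
               tolerance = 1e-6)
  expect_equal(max(abs(apply(dose$values, c(1, 2), stats::sd))), 0,
               tolerance = 1e-9)
})

test_that("opposed beams in a homogeneous cube give a symmetric midline profile", {
  b1 <- static_beam(xa = -50, xb = 50, gantry = 0)
  b2 <- static_beam(xa = -50, xb = 50, gantry = 180)
  plan <- treatment_plan("pp", list(b1, b2))
  ph <- make_phantom(voxel_mm = 4)
  dose <- compute_dose(plan, ph$phantom, attenuation_per_mm = 0.005)
  iz <- seq_along(ph$phantom$z)
  prof <- dose$values[which.min(abs(ph$phantom$x)),
                      which.min(abs(ph$phantom$y)), ]
  expect_equal(prof, rev(prof), tolerance = 1e-9)
})

test_that("the engine is linear in monitor units", {
  plan <- make_sliding_window_plan(2, "pyramid", seed = 1)
  ph <- make_phantom(voxel_mm = 4)
  d1 <- compute_dose(plan, ph$phantom, scale = 1)
  d2 <- compute_dose(plan, ph$phantom, scale = 1,
                     mu_per_beam = rep(200, 2))
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-9)
})

test_that("dose computation is bitwise deterministic", {
  plan <- make_sliding_window_plan(1, "random", seed = 8)
  ph <- make_phantom(voxel_mm = 4)
  d1 <- compute_dose(plan, ph$phantom)
  d2 <- compute_dose(plan, ph$phantom)
  expect_identical(d1$values, d2$values)
})

test_that("a plan with no fluence at the isocenter cannot be normalized", {
  beam <- static_beam(xa = 30, xb = 50)   # aperture off-center
  plan <- treatment_plan("off", list(beam))
  ph <- make_phantom(voxel_mm = 4)
  expect_error(compute_dose(plan, ph$phantom), "zero dose at the isocenter")
})

test_that("cumulative DVHs and their point metrics follow closed forms", {
  ph <- make_phantom(voxel_mm = 4)
  dims <- dim(ph$masks$target$voxels)
  # uniform dose
  uni <- structure(list(values = array(100, dims), x = ph$phantom$x,
                        y = ph$phantom$y, z = ph$phantom$z, voxel_mm = 4,
                        scale = 1), class = "dose_grid")
  dvh <- compute_dvh(uni, ph$masks$target)
  expect_equal(dvh$volume[1], 1)
  expect_true(all(diff(dvh$volume) <= 0))
  m <- dvh_metrics(dvh)
  expect_equal(c(m$d98, m$d2, m$dmean), c(100, 100, 100), tolerance = 0.1)
  # synthetic linear gradient 0..100 along x: V(d) = 1 - d/100
  grad <- uni
  grad$values <- array(rep((ph$phantom$x + 100) / 2, prod(dims) / dims[1]),
                       dims)
  box <- list(name = "box", voxels = array(TRUE, dims))
  dvh2 <- compute_dvh(grad, box, bin_width = 0.1)
  mid <- which.min(abs(dvh2$dose - 50))
  expect_equal(dvh2$volume[mid], 0.5, tolerance = 0.02)
  m2 <- dvh_metrics(dvh2)
  expect_equal(m2$d98, 2, tolerance = 1)
  expect_equal(m2$d2, 98, tolerance = 1)
  expect_equal(m2$dmean, 50, tolerance = 0.1)
  # halving the bin width barely moves the metrics
  m3 <- dvh_metrics(compute_dvh(grad, box, bin_width = 0.05))
  expect_lte(abs(m3$d98 - m2$d98), 0.05 + 1e-9)
  expect_lte(abs(m3$d2 - m2$d2), 0.05 + 1e-9)
  # guard rails
  expect_error(compute_dvh(uni, list(name = "wrong",
                                     voxels = array(TRUE, c(2, 2, 2)))),
               "congruent")
  expect_error(compute_dvh(uni, list(name = "empty",
                                     voxels = array(FALSE, dims))),
               "empty")
})

test_that("chamber dose averages a sphere and degenerates loudly", {
  ph <- make_phantom(voxel_mm = 2)
  dims <- dim(ph$masks$target$voxels)
  uni <- structure(list(values = array(42, dims), x = ph$phantom$x,
                        y = ph$phantom$y, z = ph$phantom$z, voxel_mm = 2,
                        scale = 1), class = "dose_grid")
  expect_equal(chamber_dose(uni), 42)
  grad <- uni
  grad$values <- array(rep((ph$phantom$x + 100) / 2, prod(dims) / dims[1]),
                       dims)
  # symmetric sphere at the isocenter sees the central gradient value
  expect_equal(chamber_dose(grad, radius_mm = 6), 50, tolerance = 0.01)
  # voxel centers sit at odd coordinates; a tiny sphere at the origin is empty
  expect_error(chamber_dose(uni, center = c(0, 0, 0), radius_mm = 0.4),
               "radius")
})
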