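test_that("dynamic beam invariants are enforced", {
  geom <- leaf_bank_geometry()
  np <- geom$n_pairs
  a <- matrix(-10, 3, np); b <- matrix(10, 3, np)
  expect_s3_class(dynamic_beam("b", c(0, 0.5, 1), a, b, 100), "dynamic_beam")
  # fewer than two control points
  expect_error(dynamic_beam("b", 0, a[1, , drop = FALSE], b[1, , drop = FALSE], 100),
               ">= 2 control points")
  # non-monotone index
  expect_error(dynamic_beam("b", c(0, 0.6, 0.4, 1), rbind(a, a[1, ]), rbind(b, b[1, ]), 100),
               "decreases at control point 3")
  # collision
  a2 <- a; a2[2, 5] <- 11
  expect_error(dynamic_beam("b", c(0, 0.5, 1), a2, b, 100),
               "collision.*control point 2")
  # index endpoints
  expect_error(dynamic_beam("b", c(0, 0.5, 0.9), a, b, 100), "end at 1")
  expect_error(dynamic_beam("b", c(0, 0.5, 1), a, b, 0), "total_mu")
})

test_that("leaf bank geometry matches the Millennium layout", {
  g <- leaf_bank_geometry()
  expect_equal(g$n_pairs, 60)
  expect_equal(sum(g$leaf_widths_mm), 400)
  expect_equal(sort(unique(g$leaf_widths_mm)), c(5, 10))
  expect_error(leaf_bank_geometry(c(5, -5)), "positive")
})

test_that("beam interpolation is linear in meterset fraction", {
  geom <- leaf_bank_geometry()
  np <- geom$n_pairs
  a <- matrix(0, 2, np); b <- matrix(20, 2, np)
  a[1, 1] <- 10; a[2, 1] <- 12   # pair 1 tip A moves 10 -> 12 mm
  beam <- dynamic_beam("b", c(0.0, 1.0), a, b, 100)
  # fractions 0.4 / 0.6 bracket 0.5; positions 10.8 / 11.2 average to 11
  p <- interpolate_beam(beam, 0.5)
  expect_equal(p$bank_a[1, 1], 11)
  expect_equal(interpolate_beam(beam, 0)$bank_a[1, 1], 10)
  expect_equal(interpolate_beam(beam, 1)$bank_a[1, 1], 12)
})

test_that("a minimal static MLC file parses to a two-control-point beam", {
  beam <- static_beam(xa = -50, xb = 50)
  path <- withr::local_tempfile(fileext = ".dva")
  write_mlc_file(beam, path)
  txt <- readLines(path)
  # cm serialization with 3 decimals, signed on the travel axis
  expect_true(any(grepl("^Leaf 21A = -5\\.000$", txt)))
  expect_true(any(grepl("^Leaf 21B = 5\\.000$", txt)))
  got <- read_mlc_file(path)
  expect_length(got$index, 2)
  expect_equal(got$index, c(0, 1))
  expect_equal(got$bank_a, beam$bank_a, tolerance = 1e-9)
})

test_that("MLC file write/read round trip is byte-stable and lossless to 0.01 mm", {
  for (preset in c("ramp", "pyramid", "random")) {
    plan <- make_sliding_window_plan(1, preset, seed = 42, n_control_points = 50)
    beam <- plan$beams[[1]]
    f1 <- withr::local_tempfile(fileext = ".dva")
    f2 <- withr::local_tempfile(fileext = ".dva")
    write_mlc_file(beam, f1)
    back <- read_mlc_file(f1)
    expect_lte(max(abs(back$bank_a - beam$bank_a)), 0.01 / 2 + 1e-9)
    expect_lte(max(abs(back$bank_b - beam$bank_b)), 0.01 / 2 + 1e-9)
    expect_equal(back$total_mu, beam$total_mu)
    expect_equal(back$gantry_angle, beam$gantry_angle)
    # canonical fixture: a file written from a parsed beam reproduces itself
    write_mlc_file(back, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("malformed MLC files are rejected with the offending location", {
  beam <- static_beam()
  path <- withr::local_tempfile(fileext = ".dva")
  write_mlc_file(beam, path)
  txt <- readLines(path)
  # non-monotone index sequence [0, 0.5, 0.4, 1]
  beam4 <- static_beam(ncp = 4)
  beam4$index <- c(0, 0.5, 0.6, 1)
  bad <- withr::local_tempfile(fileext = ".dva")
  write_mlc_file(beam4, bad)
  txt4 <- readLines(bad)
  txt4[txt4 == "Index = 0.60000"] <- "Index = 0.40000"
  writeLines(txt4, bad)
  expect_error(read_mlc_file(bad), "non-monotone Index at control point 3")
  # collision inside a control point
  bad2 <- withr::local_tempfile(fileext = ".dva")
  writeLines(sub("^Leaf 21A = -5\\.000$", "Leaf 21A = 6.000", txt), bad2)
  expect_error(read_mlc_file(bad2), "collision")
  # missing header key
  bad3 <- withr::local_tempfile(fileext = ".dva")
  writeLines(txt[-4], bad3)
  expect_error(read_mlc_file(bad3), "Total MU")
  # invalid beam is rejected before writing
  beam$index <- c(0, 2)
  expect_error(write_mlc_file(beam, path), "end at 1")
})
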