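#' Reconstruct a dynamic beam from a delivery record
#'
#' Converts a paired delivery log into a control-point MLC sequence placed at
#' the planned segment-boundary meterset fractions (carried in the log
#' header; the controller advances to the next segment exactly when the
#' cumulative fractional MU crosses the planned boundary).
#'
#' Within a segment the planned tip trajectory of every leaf is linear in
#' fractional MU, so the planned position at each boundary is recovered by
#' per-segment least squares of the planned samples against fractional MU,
#' evaluated at the boundary (exact up to the 0.01 mm planned-position
#' storage precision). In `"actual"` mode the delivered deviation is added
#' as the segment mean of `recorded - planned` over beam-on snapshots: a
#' zero-leverage estimator whose error stays at the scale of the 0.01 cm
#' recording quantization (endpoint-extrapolating regressions of the
#' recorded staircase amplify it, and two-point interpolation across the
#' segment change lands on the trajectory kink and errs by the local slope
#' change times half the sampling interval). Interior boundaries take the
#' mean of the estimates from the two adjacent segments. Beam-hold
#' snapshots are excluded; a segment with fewer than two distinct dose
#' fractions falls back to the mean of its (or, if empty, the nearest)
#' snapshots.
#'
#' In `"actual"` mode the recorded positions are used (the delivered
#' sequence); in `"planned"` mode the planned positions are used, which
#' round-trips the original plan and isolates the conversion accuracy
#' itself. Collisions created by estimation/rounding are resolved by
#' pinching both tips to their midpoint, with a warning.
#'
#' @param record a [delivery_record()] of a completed delivery (final
#'   fractional MU 1).
#' @param mode `"actual"` or `"planned"`.
#' @param total_mu monitor units for the reconstructed beam; defaults to the
#'   value in the log header (the reference plan's MU are kept).
#' @return a [dynamic_beam()].
#' @export
reconstruct_beam <- function(record, mode = c("actual", "planned"),
                             total_mu = NULL) {
  mode <- match.arg(mode)
  a <- record$bank_a_log
  b <- record$bank_b_log
  n <- length(a$time_ms)
  final_frac <- a$dose_index[n] / 25000
  if (abs(final_frac - 1) > 1e-9) {
    stop(sprintf("incomplete delivery: final fractional MU %.4f (expected 1.0)",
                 final_frac), call. = FALSE)
  }
  if (length(a$segment) == 0L) stop("empty segment stream", call. = FALSE)
  if (is.null(total_mu)) total_mu <- a$total_mu
  bounds <- a$boundaries
  nseg <- length(bounds) - 1L
  frac <- a$dose_index / 25000
  np <- a$geometry$n_pairs

  # per-segment boundary estimates: rows 2s-1 / 2s = start/end of segment s
  est_a <- matrix(NA_real_, 2L * nseg, np)
  est_b <- matrix(NA_real_, 2L * nseg, np)
  fit_segment <- function(planned, recorded, rows, f0, f1) {
    f <- frac[rows]
    P <- planned[rows, , drop = FALSE]
    if (length(rows) >= 2L && stats::var(f) > 1e-12) {
      fb <- mean(f)
      Pc <- colMeans(P)
      slope <- colSums((f - fb) * sweep(P, 2, Pc)) / sum((f - fb)^2)
      out <- rbind(Pc + slope * (f0 - fb), Pc + slope * (f1 - fb))
    } else {
      v <- colMeans(P)
      out <- rbind(v, v)
    }
    if (mode == "actual") {
      dev <- colMeans(recorded[rows, , drop = FALSE] - P)
      out <- out + rep(dev, each = 2L)
    }
    out
  }
  for (s in seq_len(nseg)) {
    rows <- which(a$segment == s & a$beam_on)
    if (!length(rows)) rows <- which(a$segment == s)
    if (!length(rows)) {
      # segment skipped entirely: take nearest snapshot by fraction
      rows <- which.min(abs(frac - (bounds[s] + bounds[s + 1]) / 2))
    }
    est_a[c(2L * s - 1L, 2L * s), ] <-
      fit_segment(a$planned, a$recorded, rows, bounds[s], bounds[s + 1])
    est_b[c(2L * s - 1L, 2L * s), ] <-
      fit_segment(b$planned, b$recorded, rows, bounds[s], bounds[s + 1])
  }
  cp_a <- matrix(NA_real_, nseg + 1L, np)
  cp_b <- matrix(NA_real_, nseg + 1L, np)
  cp_a[1, ] <- est_a[1, ]; cp_b[1, ] <- est_b[1, ]
  cp_a[nseg + 1L, ] <- est_a[2L * nseg, ]; cp_b[nseg + 1L, ] <- est_b[2L * nseg, ]
  if (nseg > 1L) {
    for (s in seq_len(nseg - 1L)) {
      cp_a[s + 1L, ] <- (est_a[2L * s, ] + est_a[2L * s + 1L, ]) / 2
      cp_b[s + 1L, ] <- (est_b[2L * s, ] + est_b[2L * s + 1L, ]) / 2
    }
  }
  bad <- cp_a > cp_b
  if (any(bad)) {
    warning(sprintf("%d interpolated collision(s) pinched to the pair midpoint",
                    sum(bad)), call. = FALSE)
    mid <- (cp_a[bad] + cp_b[bad]) / 2
    cp_a[bad] <- mid
    cp_b[bad] <- mid
  }
  dynamic_beam(a$field_id, bounds, cp_a, cp_b, total_mu,
               gantry_angle = a$gantry_angle, geometry = a$geometry)
}

#' Compare two dynamic beam sequences
#'
#' Maximum absolute leaf-tip position difference per control point. Beams on
#' the same meterset index grid are compared directly; otherwise both are
#' resampled (linearly in meterset fraction, the delivery motion model) onto
#' the union of the two index grids.
#'
#' @param a,b `dynamic_beam` objects with equal geometry.
#' @return numeric vector of per-control-point maxima of
#'   `|position_a - position_b|` in mm, with the comparison index grid as
#'   the `"index"` attribute.
#' @export
compare_sequences <- function(a, b) {
  if (!geometry_equal(a$geometry, b$geometry)) {
    stop("incompatible leaf bank geometries", call. = FALSE)
  }
  same_grid <- length(a$index) == length(b$index) &&
    max(abs(a$index - b$index)) < 1e-12
  if (same_grid) {
    grid <- a$index
    pa <- list(bank_a = a$bank_a, bank_b = a$bank_b)
    pb <- list(bank_a = b$bank_a, bank_b = b$bank_b)
  } else {
    grid <- sort(unique(c(a$index, b$index)))
    pa <- interpolate_beam(a, grid)
    pb <- interpolate_beam(b, grid)
  }
  d <- pmax(abs(pa$bank_a - pb$bank_a), abs(pa$bank_b - pb$bank_b))
  structure(apply(d, 1, max), index = grid)
}
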