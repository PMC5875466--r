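# Independent oracles and small builders used across the suite.

# Brute-force fluence renderer: subdivides every control-point interval into
# n_sub equal time steps and accumulates the pixel area coverage of the
# aperture at each step midpoint (overlap formula, no closed-form integral).
brute_force_fluence <- function(beam, spacing_mm = 2, n_sub = 1000,
                                x_range = c(-60, 60), y_range = c(-60, 60)) {
  h <- spacing_mm
  x <- seq(x_range[1] + h / 2, x_range[2] - h / 2, by = h)
  y <- seq(y_range[1] + h / 2, y_range[2] - h / 2, by = h)
  geom <- beam$geometry
  np <- geom$n_pairs
  pf <- matrix(0, np, length(x))
  for (k in seq_len(length(beam$index) - 1L)) {
    dmu <- (beam$index[k + 1L] - beam$index[k]) * beam$total_mu
    if (dmu <= 0) next
    for (s in seq_len(n_sub)) {
      t <- (s - 0.5) / n_sub
      ta <- beam$bank_a[k, ] * (1 - t) + beam$bank_a[k + 1L, ] * t
      tb <- beam$bank_b[k, ] * (1 - t) + beam$bank_b[k + 1L, ] * t
      # overlap of [x-h/2, x+h/2] with (ta, tb), per pair (rows) and pixel
      lo <- pmax(outer(ta, rep(1, length(x))), outer(rep(1, np), x - h / 2))
      hi <- pmin(outer(tb, rep(1, length(x))), outer(rep(1, np), x + h / 2))
      pf <- pf + dmu / n_sub * pmax(0, hi - lo) / h
    }
  }
  edges <- geom$pair_edges_mm
  w <- matrix(0, length(y), np)
  for (p in seq_len(np)) {
    w[, p] <- pmax(0, pmin(y + h / 2, edges[p + 1L]) - pmax(y - h / 2, edges[p])) / h
  }
  structure(list(x = x, y = y, values = w %*% pf, spacing_mm = h,
                 beam_id = beam$beam_id, total_mu = beam$total_mu,
                 transmission = 0),
            class = "fluence_map")
}

# Exhaustive gamma search: straight double loop over all eligible pixels and
# all displacement candidates, its own bilinear interpolation.
brute_force_gamma <- function(reference, evaluated, dose_pct = 3, dta_mm = 3,
                              threshold_pct = 10, step_mm = 0.1) {
  R <- reference$values
  E <- evaluated$values
  dcrit <- dose_pct / 100 * max(R)
  thresh <- threshold_pct / 100 * max(R)
  off <- seq(-3 * dta_mm, 3 * dta_mm, by = step_mm)
  disp <- expand.grid(dx = off, dy = off)
  disp <- disp[disp$dx^2 + disp$dy^2 <= (3 * dta_mm)^2 + 1e-9, ]
  r2 <- (disp$dx^2 + disp$dy^2) / dta_mm^2
  interp <- function(xq, yq) {
    hx <- reference$x[2] - reference$x[1]
    tx <- min(max((xq - reference$x[1]) / hx, 0), length(reference$x) - 1)
    ty <- min(max((yq - reference$y[1]) / hx, 0), length(reference$y) - 1)
    i <- min(floor(tx) + 1, length(reference$x) - 1)
    j <- min(floor(ty) + 1, length(reference$y) - 1)
    wx <- tx - (i - 1); wy <- ty - (j - 1)
    E[j, i] * (1 - wx) * (1 - wy) + E[j, i + 1] * wx * (1 - wy) +
      E[j + 1, i] * (1 - wx) * wy + E[j + 1, i + 1] * wx * wy
  }
  gmap <- matrix(NA_real_, nrow(R), ncol(R))
  for (j in seq_len(nrow(R))) {
    for (i in seq_len(ncol(R))) {
      if (R[j, i] < thresh) next
      best <- Inf
      for (q in seq_len(nrow(disp))) {
        ev <- interp(reference$x[i] + disp$dx[q], reference$y[j] + disp$dy[q])
        g2 <- ((ev - R[j, i]) / dcrit)^2 + r2[q]
        if (g2 < best) best <- g2
      }
      gmap[j, i] <- sqrt(best)
    }
  }
  list(gamma_map = gmap,
       passing_rate = 100 * mean(gmap[!is.na(gmap)] < 1))
}

# Minimal static-field beam: every listed pair open at (xa, xb) at both
# control points, others closed parked at `park`.
static_beam <- function(xa = -50, xb = 50, open_pairs = 21:40, total_mu = 100,
                        park = -60, gantry = 0, ncp = 2) {
  geom <- leaf_bank_geometry()
  a <- matrix(park, ncp, geom$n_pairs)
  b <- matrix(park, ncp, geom$n_pairs)
  a[, open_pairs] <- xa
  b[, open_pairs] <- xb
  dynamic_beam("static", seq(0, 1, length.out = ncp), a, b, total_mu,
               gantry_angle = gantry, geometry = geom)
}

# Small uniform fluence-map stub on its own grid.
uniform_map <- function(value, n = 21, spacing = 2) {
  x <- seq(-(n - 1) / 2, (n - 1) / 2) * spacing
  structure(list(x = x, y = x, values = matrix(value, n, n),
                 spacing_mm = spacing, beam_id = "stub", total_mu = value,
                 transmission = 0),
            class = "fluence_map")
}

# Smooth 2D bump map used by the gamma tests.
bump_map <- function(n = 50, spacing = 2, cx = 0, cy = 0, sigma = 25,
                     amp = 100) {
  x <- seq(-(n - 1) / 2, (n - 1) / 2) * spacing
  g <- expand.grid(y = x, x = x)
  vals <- matrix(amp * exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * sigma^2)), n, n)
  structure(list(x = x, y = x, values = vals, spacing_mm = spacing,
                 beam_id = "bump", total_mu = amp, transmission = 0),
            class = "fluence_map")
}

# Hand-built delivery record: linear sweep of one leaf pair with explicit
# planned/recorded matrices, for unit tests that need exact control.
toy_record <- function(fracs, planned_a, recorded_a = planned_a,
                       planned_b = planned_a + 20, recorded_b = planned_b,
                       boundaries = c(0, 1), beam_on = NULL, total_mu = 100) {
  geom <- leaf_bank_geometry()
  n <- length(fracs)
  np <- geom$n_pairs
  grow <- function(v) {
    m <- matrix(rep(as.matrix(v), length.out = n * np), n, np)
    m
  }
  if (is.null(beam_on)) beam_on <- rep(TRUE, n)
  seg <- findInterval(fracs, boundaries, rightmost.closed = TRUE, all.inside = TRUE)
  mk <- function(bank, p, r) {
    delivery_log(field_id = "toy", bank = bank,
                 time_ms = 55L * (seq_len(n) - 1L),
                 dose_index = as.integer(round(fracs * 25000)),
                 segment = seg, beam_on = beam_on,
                 planned = grow(p), recorded = grow(r),
                 boundaries = boundaries, total_mu = total_mu,
                 geometry = geom)
  }
  delivery_record(mk("A", planned_a, recorded_a), mk("B", planned_b, recorded_b))
}
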