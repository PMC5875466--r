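#' Error model for the delivery simulator
#'
#' @param offset_a_mm,offset_b_mm systematic recorded-position offsets added
#'   to every leaf of the bank, mm on the signed leaf-travel axis (a
#'   negative bank-A offset moves that bank outward).
#' @param jitter_sd_mm standard deviation of independent zero-mean Gaussian
#'   position jitter per leaf per snapshot, mm.
#' @return a named list understood by [simulate_delivery()].
#' @export
delivery_error_model <- function(offset_a_mm = 0, offset_b_mm = 0,
                                 jitter_sd_mm = 0) {
  em <- list(offset_a_mm = offset_a_mm, offset_b_mm = offset_b_mm,
             jitter_sd_mm = jitter_sd_mm)
  if (any(!vapply(em, is.finite, logical(1)))) {
    stop("error model parameters must be finite", call. = FALSE)
  }
  if (jitter_sd_mm < 0) stop("jitter_sd_mm must be >= 0", call. = FALSE)
  em
}

#' Simulate dynamic delivery of a beam and produce its log pair
#'
#' Emulates the MLC controller during a sliding-window delivery: snapshots
#' are taken every 55 ms; the cumulative fractional MU advances at the
#' nominal dose rate; planned positions are the beam interpolated at the
#' current fractional MU; delivered positions are planned plus the error
#' model (systematic per-bank offset and zero-mean jitter, with colliding
#' pairs pinched to their midpoint as a hardware interlock would);
#' recorded positions are the delivered ones quantized to 0.01 cm, the
#' finite recording precision of the log. If any leaf strays further from
#' its planned position than the hold tolerance, the beam holds: the dose
#' index does not advance and the snapshot is flagged beam-off.
#'
#' The delivered (pre-quantization) trajectory is attached as attribute
#' `"truth"` — a [dynamic_beam()] with one control point per snapshot — for
#' validation against ground truth.
#'
#' @param beam a [dynamic_beam()].
#' @param dose_rate_mu_min nominal dose rate, MU/min (default 600).
#' @param error_model a [delivery_error_model()].
#' @param seed integer seed for the jitter stream (`NULL` = leave RNG
#'   state alone).
#' @param hold_tolerance_mm controller hold tolerance, mm (default 2).
#' @return a [delivery_record()] with the `"truth"` attribute.
#' @export
simulate_delivery <- function(beam, dose_rate_mu_min = 600,
                              error_model = delivery_error_model(),
                              seed = NULL, hold_tolerance_mm = 2) {
  validate_dynamic_beam(beam)
  if (!is.finite(dose_rate_mu_min) || dose_rate_mu_min <= 0) {
    stop("dose rate must be > 0", call. = FALSE)
  }
  em <- do.call(delivery_error_model, error_model[names(error_model) %in%
                  names(formals(delivery_error_model))])
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  np <- beam$geometry$n_pairs
  dt_s <- 0.055
  df_step <- dose_rate_mu_min / 60 * dt_s / beam$total_mu  # fraction per step
  n_max <- 20L * (ceiling(1 / df_step) + 10L)
  frac <- numeric(n_max)
  beam_on <- logical(n_max)
  pl_a <- pl_b <- tr_a <- tr_b <- matrix(NA_real_, n_max, np)
  f <- 0
  n <- 0L
  repeat {
    n <- n + 1L
    if (n > n_max) stop("delivery stalled: beam held for too long", call. = FALSE)
    # positions and log share the dose-index quantization (1/25000 in MU)
    f <- round(f * 25000) / 25000
    p <- interpolate_beam(beam, f)
    jit_a <- if (em$jitter_sd_mm > 0) stats::rnorm(np, 0, em$jitter_sd_mm) else 0
    jit_b <- if (em$jitter_sd_mm > 0) stats::rnorm(np, 0, em$jitter_sd_mm) else 0
    ta <- p$bank_a[1, ] + em$offset_a_mm + jit_a
    tb <- p$bank_b[1, ] + em$offset_b_mm + jit_b
    coll <- ta > tb
    if (any(coll)) {
      mid <- (ta[coll] + tb[coll]) / 2
      ta[coll] <- mid
      tb[coll] <- mid
    }
    err <- max(abs(ta - p$bank_a[1, ]), abs(tb - p$bank_b[1, ]))
    on <- err <= hold_tolerance_mm
    frac[n] <- f
    beam_on[n] <- on
    pl_a[n, ] <- p$bank_a[1, ]; pl_b[n, ] <- p$bank_b[1, ]
    tr_a[n, ] <- ta; tr_b[n, ] <- tb
    if (f >= 1) break
    if (on) f <- min(1, f + df_step)
  }
  frac <- frac[seq_len(n)]
  beam_on <- beam_on[seq_len(n)]
  pl_a <- pl_a[seq_len(n), , drop = FALSE]
  pl_b <- pl_b[seq_len(n), , drop = FALSE]
  tr_a <- tr_a[seq_len(n), , drop = FALSE]
  tr_b <- tr_b[seq_len(n), , drop = FALSE]
  dose_index <- as.integer(round(frac * 25000))
  segment <- findInterval(frac, beam$index, rightmost.closed = TRUE,
                          all.inside = TRUE)
  time_ms <- as.integer(round((seq_len(n) - 1L) * 55))
  mk_log <- function(bank, planned, truth) {
    delivery_log(
      field_id = beam$beam_id, bank = bank, time_ms = time_ms,
      dose_index = dose_index, segment = segment, beam_on = beam_on,
      planned = planned, recorded = round(truth / 0.1) * 0.1,
      boundaries = beam$index, total_mu = beam$total_mu,
      gantry_angle = beam$gantry_angle,
      hold_tolerance_mm = hold_tolerance_mm, geometry = beam$geometry
    )
  }
  rec <- delivery_record(mk_log("A", pl_a, tr_a), mk_log("B", pl_b, tr_b))
  # normalize truth index to end exactly at 1 (holds leave duplicates, fine)
  truth <- dynamic_beam(paste0(beam$beam_id, ".delivered"), frac,
                        tr_a, tr_b, beam$total_mu,
                        gantry_angle = beam$gantry_angle,
                        geometry = beam$geometry)
  attr(rec, "truth") <- truth
  rec
}

#' Generate a sliding-window fixture plan
#'
#' Builds a seeded, leaf-speed-feasible dynamic plan used throughout the
#' package's validation studies: `n_beams` beams at evenly spaced gantry
#' angles, each a sliding-window sequence sweeping a modulated aperture
#' across the central 100 mm of the field (the 20 central 5 mm leaf pairs,
#' spanning -50..50 mm across pairs; other pairs stay closed and parked).
#'
#' Presets:
#' \describe{
#'   \item{`"ramp"`}{constant 10 mm gap sweeping at constant speed — the
#'     interior fluence is analytically `total_mu * gap / sweep_length`.}
#'   \item{`"pyramid"`}{per-pair constant gap growing linearly towards the
#'     central pairs — an analytic pyramid profile across pairs.}
#'   \item{`"random"`}{smoothly varying random gap and sweep speed per pair
#'     (seeded), emulating clinically modulated fields.}
#' }
#'
#' @param n_beams number of beams (>= 1); gantry angles at `360 / n_beams`
#'   spacing starting at 0.
#' @param modulation_preset `"ramp"`, `"pyramid"` or `"random"`.
#' @param seed integer seed (used by the `"random"` preset).
#' @param n_control_points control points per beam (default 25).
#' @param total_mu MU per beam (default 100).
#' @return a [treatment_plan()] with prescription dose 100.
#' @export
make_sliding_window_plan <- function(n_beams = 5, modulation_preset = "random",
                                     seed = 1, n_control_points = 25,
                                     total_mu = 100) {
  preset <- match.arg(modulation_preset, c("ramp", "pyramid", "random"))
  if (n_beams < 1) stop("n_beams must be >= 1", call. = FALSE)
  geom <- leaf_bank_geometry()
  np <- geom$n_pairs
  active <- which(geom$pair_centers_mm > -50 & geom$pair_centers_mm < 50)
  ncp <- n_control_points
  idx <- seq(0, 1, length.out = ncp)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  x0 <- -45; sweep_len <- 80; park <- -60
  beams <- vector("list", n_beams)
  for (b in seq_len(n_beams)) {
    bank_a <- matrix(park, ncp, np)
    bank_b <- matrix(park, ncp, np)
    for (p in active) {
      gap <- switch(preset,
        ramp = rep(10, ncp),
        pyramid = rep(4 + 12 * (1 - abs(geom$pair_centers_mm[p]) / 50), ncp),
        random = {
          raw <- stats::rnorm(ncp)
          sm <- stats::filter(c(raw[1], raw[1], raw, raw[ncp], raw[ncp]),
                              rep(1 / 5, 5), sides = 2)
          sm <- as.numeric(sm[3:(ncp + 2)])
          pmax(3, 9 + 5 * sm)
        })
      s <- switch(preset,
        ramp = idx,
        pyramid = idx,
        random = {
          inc <- stats::runif(ncp - 1, 0.4, 1.6)
          c(0, cumsum(inc)) / sum(inc)
        })
      tip_a <- x0 + sweep_len * s
      tip_b <- tip_a + gap
      # keep the leading tip monotone (no leaf reversal): limit gap shrink
      for (k in 2:ncp) {
        if (tip_b[k] < tip_b[k - 1]) tip_b[k] <- tip_b[k - 1]
      }
      bank_a[, p] <- tip_a
      bank_b[, p] <- tip_b
    }
    beams[[b]] <- dynamic_beam(
      sprintf("beam%02d", b), idx, bank_a, bank_b, total_mu,
      gantry_angle = (b - 1) * 360 / n_beams, geometry = geom
    )
  }
  treatment_plan(sprintf("sw_%s_seed%s", preset, format(seed)), beams,
                 prescription_dose = 100)
}

#' Build a phantom with target and organ-at-risk masks
#'
#' Preset `"cube_target_oars"`: a 200 mm homogeneous cube at 2 mm voxels
#' centred on the isocenter, with a cylindrical target (radius 25 mm,
#' half-length 30 mm, axis along Y through the isocenter) and two
#' cylindrical organs at risk of radius 15 mm, one posterior
#' (`z = -45` mm) and one lateral (`x = +45` mm). All masks are mutually
#' disjoint and deterministic.
#'
#' @param preset phantom preset name.
#' @param voxel_mm voxel edge length, mm (default 2).
#' @param side_mm cube side length, mm (default 200).
#' @return list with `phantom` (list: `x`, `y`, `z` voxel centers,
#'   `voxel_mm`, `half_side_mm`) and `masks` (named list of structure
#'   masks, each a list with `name` and logical array `voxels`).
#' @export
make_phantom <- function(preset = "cube_target_oars", voxel_mm = 2,
                         side_mm = 200) {
  preset <- match.arg(preset, "cube_target_oars")
  half <- side_mm / 2
  cc <- seq(-half + voxel_mm / 2, half - voxel_mm / 2, by = voxel_mm)
  phantom <- list(x = cc, y = cc, z = cc, voxel_mm = voxel_mm,
                  half_side_mm = half)
  g <- expand.grid(x = cc, y = cc, z = cc)
  dims <- c(length(cc), length(cc), length(cc))
  cyl_y <- function(cx, cz, r, hl) {
    array((g$x - cx)^2 + (g$z - cz)^2 <= r^2 & abs(g$y) <= hl, dims)
  }
  masks <- list(
    target = list(name = "target", voxels = cyl_y(0, 0, 25, 30)),
    oar_post = list(name = "oar_post", voxels = cyl_y(0, -45, 15, 30)),
    oar_lat = list(name = "oar_lat", voxels = cyl_y(45, 0, 15, 30))
  )
  list(phantom = phantom, masks = masks)
}
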