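#' Forward dose computation with the package's parallel-beam engine
#'
#' A deliberately simple, fully deterministic forward dose engine used
#' identically for the reference and the reconstructed plan, so that dose
#' *differences* isolate delivery effects. Each beam is modelled as a
#' parallel ray bundle at its gantry angle; the dose to a voxel is
#' `sum_beams MU_b * F_b(u, y) * exp(-mu * depth)` where `F_b` is the beam's
#' MU-weighted fluence at the ray's isocenter-plane coordinates (bilinear
#' lookup), `depth` the geometric path length from the phantom surface to
#' the voxel along the beam axis, and `mu` an effective linear attenuation
#' coefficient (default 0.005 / mm, a 6 MV-like value). No scatter, buildup
#' or heterogeneity corrections are applied.
#'
#' Doses are expressed in percent of prescription: by default the grid is
#' scaled so the reference plan gives 100 at the isocenter voxel. To compare
#' a second plan on the same scale, pass the first grid's `scale` back in.
#'
#' @param plan a [treatment_plan()].
#' @param phantom a phantom from [make_phantom()] (axis-aligned cube of
#'   homogeneous unit density centred at the isocenter).
#' @param mu_per_beam optional numeric vector of MU overriding each beam's
#'   `total_mu` (the fluence is rescaled proportionally).
#' @param scale optional fixed normalization factor (percent per engine dose
#'   unit); if `NULL`, computed so isocenter dose = 100.
#' @param attenuation_per_mm effective attenuation coefficient, 1/mm.
#' @param fluence_spacing_mm grid spacing used to render each beam's
#'   fluence, mm.
#' @return object of class `dose_grid`: `values` (3D array, dims x, y, z, in
#'   percent of prescription), `x`, `y`, `z` voxel-center coordinates (mm),
#'   `voxel_mm`, and `scale` (the normalization factor applied).
#' @export
compute_dose <- function(plan, phantom, mu_per_beam = NULL, scale = NULL,
                         attenuation_per_mm = 0.005, fluence_spacing_mm = 1) {
  beams <- plan$beams
  if (!is.null(mu_per_beam) && length(mu_per_beam) != length(beams)) {
    stop("mu_per_beam must have one entry per beam", call. = FALSE)
  }
  xs <- phantom$x; ys <- phantom$y; zs <- phantom$z
  L <- phantom$half_side_mm
  if (max(abs(c(range(xs), range(ys), range(zs)))) > L) {
    stop("isocenter grid extends outside the phantom", call. = FALSE)
  }
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  # accumulate as (y, x*z) then permute; depth and u depend on (x, z) only
  xz <- expand.grid(x = xs, z = zs)
  acc <- matrix(0, ny, nrow(xz))
  for (bi in seq_along(beams)) {
    beam <- beams[[bi]]
    fm <- compute_fluence(beam, spacing_mm = fluence_spacing_mm)
    mu_scale <- if (is.null(mu_per_beam)) 1 else mu_per_beam[bi] / beam$total_mu
    th <- beam$gantry_angle * pi / 180
    d <- c(sin(th), -cos(th))                       # beam direction in (x, z)
    u <- xz$x * cos(th) + xz$z * sin(th)            # isocenter-plane coordinate
    # path length from entry surface of the cube to the point, along d
    tx <- if (abs(d[1]) > 1e-12) {
      if (d[1] > 0) (xz$x + L) / d[1] else (xz$x - L) / d[1]
    } else rep(Inf, nrow(xz))
    tz <- if (abs(d[2]) > 1e-12) {
      if (d[2] > 0) (xz$z + L) / d[2] else (xz$z - L) / d[2]
    } else rep(Inf, nrow(xz))
    depth <- pmin(tx, tz)
    att <- exp(-attenuation_per_mm * depth)
    # fluence interpolated first onto the phantom y grid, then bilinear in u
    Fy <- t(vapply(seq_along(fm$x), function(i) {
      stats::approx(fm$y, fm$values[, i], xout = ys, rule = 2)$y
    }, numeric(ny)))                                 # (n_fx, ny) -> transpose below
    Fy <- t(Fy)                                      # ny x n_fx
    hx <- fm$x[2] - fm$x[1]
    tu <- pmin(pmax((u - fm$x[1]) / hx, 0), length(fm$x) - 1)
    iu <- pmin(floor(tu) + 1, length(fm$x) - 1L)
    wu <- tu - (iu - 1L)
    contrib <- Fy[, iu, drop = FALSE] * rep(1 - wu, each = ny) +
      Fy[, iu + 1L, drop = FALSE] * rep(wu, each = ny)
    acc <- acc + mu_scale * contrib * rep(att, each = ny)
  }
  values <- aperm(array(acc, dim = c(ny, nx, nz)), c(2, 1, 3))
  iso <- c(which.min(abs(xs)), which.min(abs(ys)), which.min(abs(zs)))
  if (is.null(scale)) {
    iso_dose <- values[iso[1], iso[2], iso[3]]
    if (iso_dose <= 0) {
      stop("zero dose at the isocenter under the reference plan; cannot normalize",
           call. = FALSE)
    }
    scale <- 100 / iso_dose
  }
  structure(
    list(values = values * scale, x = xs, y = ys, z = zs,
         voxel_mm = phantom$voxel_mm, scale = scale),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels at %g mm; isocenter %.1f%%, max %.1f%%\n",
              length(x$x), length(x$y), length(x$z), x$voxel_mm,
              x$values[which.min(abs(x$x)), which.min(abs(x$y)), which.min(abs(x$z))],
              max(x$values)))
  invisible(x)
}

#' Cumulative dose-volume histogram
#'
#' Cumulative DVH of the voxels inside a structure mask: `V(d)` = fraction
#' of the structure volume receiving at least dose `d`, evaluated at a
#' regular dose binning. `V(0) = 1` and the curve is non-increasing.
#'
#' @param dose a `dose_grid`.
#' @param mask a structure mask from [make_phantom()] (logical array
#'   congruent with the dose grid).
#' @param bin_width dose bin width in percent of prescription. Default 0.1.
#' @return object of class `dvh`: `dose` (bin edges), `volume` (fraction
#'   >= dose), `mean_dose`, `structure`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1) {
  if (!all(dim(mask$voxels) == dim(dose$values))) {
    stop("mask is not congruent with the dose grid", call. = FALSE)
  }
  d <- dose$values[mask$voxels]
  if (!length(d)) stop("empty structure mask", call. = FALSE)
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  # V(edge) = fraction of voxels with dose >= edge
  vol <- 1 - stats::ecdf(d)(edges - 1e-12)
  vol[1] <- 1
  structure(
    list(dose = edges, volume = vol, mean_dose = mean(d),
         bin_width = bin_width, structure = mask$name),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  m <- dvh_metrics(x)
  cat(sprintf("<dvh> '%s': D98 %.1f%%, D2 %.1f%%, Dmean %.1f%%\n",
              x$structure, m$d98, m$d2, m$dmean))
  invisible(x)
}

#' DVH point metrics D98%, D2%, Dmean
#'
#' `Dx%` is the dose received by at least x percent of the structure volume,
#' obtained by linear interpolation of the cumulative DVH (the near-minimum
#' D98% and near-maximum D2% recommended for target reporting); `Dmean` is
#' the voxel mean. All in percent of prescription.
#'
#' @param dvh a `dvh` from [compute_dvh()].
#' @return object of class `dvh_metrics`: list with `d98`, `d2`, `dmean`.
#' @export
dvh_metrics <- function(dvh) {
  dx <- function(x) {
    v <- x / 100
    vol <- dvh$volume
    dd <- dvh$dose
    i <- which(vol <= v)[1]   # first bin where the curve drops to <= v
    if (is.na(i)) return(dd[length(dd)])
    if (i == 1L || vol[i - 1L] <= vol[i]) return(dd[i])
    dd[i - 1L] + (dd[i] - dd[i - 1L]) * (vol[i - 1L] - v) / (vol[i - 1L] - vol[i])
  }
  m <- list(d98 = dx(98), d2 = dx(2), dmean = dvh$mean_dose)
  # interpolated point doses are only defined to the binning resolution
  slack <- if (is.null(dvh$bin_width)) 0.1 else dvh$bin_width
  if (!(m$d98 <= m$dmean + slack && m$dmean <= m$d2 + slack)) {
    warning("degenerate DVH: D98 <= Dmean <= D2 violated", call. = FALSE)
  }
  structure(m, class = "dvh_metrics")
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("D98 %.2f%%  D2 %.2f%%  Dmean %.2f%%\n", x$d98, x$d2, x$dmean))
  invisible(x)
}

#' Mean dose to a spherical chamber volume
#'
#' Volume-weighted mean dose over all voxels whose centers lie inside a
#' sphere, emulating the mean dose reported for an ionization chamber's
#' active volume (a 0.125 cm^3 chamber corresponds to a 3.1 mm radius).
#'
#' @param dose a `dose_grid`.
#' @param center length-3 sphere center (x, y, z) in mm. Default isocenter.
#' @param radius_mm sphere radius in mm.
#' @return scalar mean dose, percent of prescription.
#' @export
chamber_dose <- function(dose, center = c(0, 0, 0), radius_mm = 3.1) {
  g <- expand.grid(x = dose$x, y = dose$y, z = dose$z)
  inside <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <=
    radius_mm^2
  if (!any(inside)) {
    stop("no voxel centers inside the chamber sphere; increase radius_mm",
         call. = FALSE)
  }
  mean(dose$values[inside])
}
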