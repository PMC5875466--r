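#' Dynamic MLC beam (control-point sequence)
#'
#' A dynamic beam is an ordered sequence of control points, each holding a
#' cumulative meterset fraction ("index", 0 at the first control point, 1 at
#' the last) and the tip positions of both leaf banks. Between control points
#' every leaf tip moves linearly in meterset fraction, which is the standard
#' sliding-window delivery model.
#'
#' @param beam_id character beam identifier.
#' @param index numeric vector of cumulative meterset fractions in `[0, 1]`,
#'   non-decreasing, first 0 and last 1, length >= 2.
#' @param bank_a,bank_b numeric matrices (`length(index)` x `n_pairs`) of leaf
#'   tip positions in mm at isocenter; bank A from -X, bank B from +X, and
#'   `bank_a <= bank_b` elementwise (equality = closed pair).
#' @param total_mu total monitor units of the beam (> 0).
#' @param gantry_angle gantry angle in degrees.
#' @param geometry a [leaf_bank_geometry()].
#' @return Object of class `dynamic_beam`.
#' @seealso [read_mlc_file()], [write_mlc_file()], [compute_fluence()]
#' @export
dynamic_beam <- function(beam_id, index, bank_a, bank_b, total_mu,
                         gantry_angle = 0, geometry = leaf_bank_geometry()) {
  bank_a <- as.matrix(bank_a)
  bank_b <- as.matrix(bank_b)
  beam <- structure(
    list(beam_id = as.character(beam_id), index = as.numeric(index),
         bank_a = bank_a, bank_b = bank_b, total_mu = as.numeric(total_mu),
         gantry_angle = as.numeric(gantry_angle), geometry = geometry),
    class = "dynamic_beam"
  )
  validate_dynamic_beam(beam)
  beam
}

#' Validate a dynamic beam
#'
#' Checks the structural invariants: at least two control points, meterset
#' index non-decreasing from 0 to 1, position matrices of the right shape,
#' finite positions, and no leaf collision (`bank_a <= bank_b`, with a small
#' numeric slack for round-off).
#'
#' @param beam a `dynamic_beam`.
#' @param tol numeric slack in mm allowed on the collision check.
#' @return `beam`, invisibly; otherwise an error describing the violation.
#' @export
validate_dynamic_beam <- function(beam, tol = 1e-6) {
  n <- length(beam$index)
  if (n < 2L) stop("dynamic beam needs >= 2 control points", call. = FALSE)
  if (any(!is.finite(beam$index))) stop("non-finite meterset index", call. = FALSE)
  if (abs(beam$index[1]) > tol || abs(beam$index[n] - 1) > tol) {
    stop("meterset index must start at 0 and end at 1", call. = FALSE)
  }
  if (any(diff(beam$index) < -tol)) {
    k <- which(diff(beam$index) < -tol)[1] + 1L
    stop(sprintf("meterset index decreases at control point %d", k), call. = FALSE)
  }
  np <- beam$geometry$n_pairs
  if (!all(dim(beam$bank_a) == c(n, np)) || !all(dim(beam$bank_b) == c(n, np))) {
    stop("bank matrices must be n_control_points x n_pairs", call. = FALSE)
  }
  if (any(!is.finite(beam$bank_a)) || any(!is.finite(beam$bank_b))) {
    stop("non-finite leaf positions", call. = FALSE)
  }
  bad <- beam$bank_a > beam$bank_b + tol
  if (any(bad)) {
    k <- which(rowSums(bad) > 0)[1]
    stop(sprintf("leaf collision (tip A > tip B) at control point %d", k),
         call. = FALSE)
  }
  if (!is.finite(beam$total_mu) || beam$total_mu <= 0) {
    stop("total_mu must be > 0", call. = FALSE)
  }
  invisible(beam)
}

#' @export
print.dynamic_beam <- function(x, ...) {
  cat(sprintf("<dynamic_beam> '%s': %d control points, %g MU, gantry %g deg\n",
              x$beam_id, length(x$index), x$total_mu, x$gantry_angle))
  gaps <- x$bank_b - x$bank_a
  cat(sprintf("  open pairs at first/last CP: %d / %d; max gap %.1f mm\n",
              sum(gaps[1, ] > 0), sum(gaps[nrow(gaps), ] > 0), max(gaps)))
  invisible(x)
}

#' Interpolate leaf tip positions at arbitrary meterset fractions
#'
#' Linear interpolation of every leaf trajectory in meterset fraction, the
#' motion model implied by dynamic delivery. Repeated index values (zero-MU
#' control points) are handled by taking the later control point.
#'
#' @param beam a `dynamic_beam`.
#' @param fractions numeric vector of meterset fractions in `[0, 1]`.
#' @return list with matrices `bank_a`, `bank_b`
#'   (`length(fractions)` x `n_pairs`).
#' @export
interpolate_beam <- function(beam, fractions) {
  stopifnot(all(fractions >= -1e-9 & fractions <= 1 + 1e-9))
  f <- pmin(pmax(fractions, 0), 1)
  idx <- beam$index
  n <- length(idx)
  # interval such that idx[j] <= f < idx[j+1]; for ties take the last interval
  j <- findInterval(f, idx, rightmost.closed = TRUE, all.inside = TRUE)
  d <- idx[j + 1L] - idx[j]
  w <- ifelse(d > 0, (f - idx[j]) / d, 1)   # zero-width interval: later CP
  interp1 <- function(m) {
    m[j, , drop = FALSE] * (1 - w) + m[j + 1L, , drop = FALSE] * w
  }
  list(bank_a = interp1(beam$bank_a), bank_b = interp1(beam$bank_b))
}

#' Treatment plan: beams plus prescription
#'
#' @param plan_id character plan identifier.
#' @param beams list of [dynamic_beam()] objects (>= 1).
#' @param prescription_dose prescription dose in arbitrary units (> 0); only
#'   used to express doses as percentages.
#' @return Object of class `treatment_plan`.
#' @export
treatment_plan <- function(plan_id, beams, prescription_dose = 100) {
  if (length(beams) < 1L) stop("plan needs >= 1 beam", call. = FALSE)
  if (!all(vapply(beams, inherits, logical(1), "dynamic_beam"))) {
    stop("beams must all be dynamic_beam objects", call. = FALSE)
  }
  if (!is.finite(prescription_dose) || prescription_dose <= 0) {
    stop("prescription_dose must be > 0", call. = FALSE)
  }
  structure(list(plan_id = as.character(plan_id), beams = beams,
                 prescription_dose = as.numeric(prescription_dose)),
            class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("<treatment_plan> '%s': %d beams, %g MU total\n", x$plan_id,
              length(x$beams), sum(vapply(x$beams, `[[`, numeric(1), "total_mu"))))
  invisible(x)
}
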