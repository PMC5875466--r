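#' Systematic MLC opening expansion
#'
#' Expands the aperture of every open leaf pair by `total_mm`, divided
#' equally on each bank: at every control point the bank-A tip moves
#' `total_mm / 2` towards -X and the bank-B tip `total_mm / 2` towards +X.
#' Closed pairs (zero gap) are left untouched — expanding them would create
#' apertures where the plan has none.
#'
#' @param beam a [dynamic_beam()].
#' @param total_mm total opening increase in mm (may be negative to contract,
#'   as long as no pair collides).
#' @return the perturbed `dynamic_beam`.
#' @family error injection
#' @export
expand_opening <- function(beam, total_mm) {
  if (!is.finite(total_mm)) stop("total_mm must be finite", call. = FALSE)
  open <- beam$bank_b - beam$bank_a > 1e-9
  beam$bank_a[open] <- beam$bank_a[open] - total_mm / 2
  beam$bank_b[open] <- beam$bank_b[open] + total_mm / 2
  if (any(beam$bank_a > beam$bank_b + 1e-9)) {
    stop("contraction closes past collision: |total_mm| too large", call. = FALSE)
  }
  beam$beam_id <- sprintf("%s+open%g", beam$beam_id, total_mm)
  validate_dynamic_beam(beam)
  beam
}

#' Systematic single-bank shift
#'
#' Shifts all leaves of one bank outward by `mm` (bank A towards -X, bank B
#' towards +X) at every control point, open and closed pairs alike, so the
#' aperture of every pair grows by `mm` without touching the opposite bank.
#'
#' @param beam a [dynamic_beam()].
#' @param bank `"A"` or `"B"`.
#' @param mm outward shift in mm (>= 0).
#' @return the perturbed `dynamic_beam`.
#' @family error injection
#' @export
shift_bank <- function(beam, bank, mm) {
  bank <- match.arg(bank, c("A", "B"))
  if (!is.finite(mm) || mm < 0) stop("mm must be >= 0", call. = FALSE)
  if (bank == "A") beam$bank_a <- beam$bank_a - mm
  else beam$bank_b <- beam$bank_b + mm
  beam$beam_id <- sprintf("%s+shift%s%g", beam$beam_id, bank, mm)
  validate_dynamic_beam(beam)
  beam
}

#' Drop delivery segments from a beam
#'
#' Removes the control points ending the named segments (segment `k` is the
#' interval between control points `k` and `k + 1`), emulating a controller
#' that skips part of the sequence after a transient fault: the surviving
#' control points keep their original meterset index values (no
#' renormalization), so the aperture travels directly between them while the
#' meterset budget of the dropped segments is still delivered.
#'
#' @param beam a [dynamic_beam()].
#' @param segment_indices integer indices in `1 .. n_control_points - 2`
#'   (dropping the final segment would remove the last control point, which
#'   is retained by construction).
#' @return the perturbed `dynamic_beam`.
#' @family error injection
#' @export
drop_segments <- function(beam, segment_indices) {
  if (!length(segment_indices)) return(beam)
  n <- length(beam$index)
  segment_indices <- as.integer(segment_indices)
  if (any(segment_indices < 1L | segment_indices > n - 2L)) {
    stop("segment indices must lie in 1 .. n_control_points - 2 ",
         "(first and last control points are retained)", call. = FALSE)
  }
  drop_cp <- unique(segment_indices) + 1L
  if (length(drop_cp) >= n - 1L) {
    stop("cannot drop every interior segment", call. = FALSE)
  }
  keep <- setdiff(seq_len(n), drop_cp)
  beam$index <- beam$index[keep]
  beam$bank_a <- beam$bank_a[keep, , drop = FALSE]
  beam$bank_b <- beam$bank_b[keep, , drop = FALSE]
  beam$beam_id <- sprintf("%s+drop%d", beam$beam_id, length(drop_cp))
  validate_dynamic_beam(beam)
  beam
}
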