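#' Millennium-style leaf bank geometry
#'
#' Describes one opposed pair of MLC leaf banks (labelled A and B) projected
#' to the isocenter plane. The default is a 120-leaf Millennium-style carriage:
#' 60 opposed pairs per bank, the central 40 pairs 5.0 mm wide and the two
#' outer groups of 10 pairs 10.0 mm wide, spanning 400 mm in total.
#'
#' Coordinate convention used throughout the package: the leaf-travel axis X
#' is in mm at the isocenter plane; bank A tips approach the field from -X and
#' bank B tips from +X, so the aperture of pair `k` is the open interval
#' `(tip_A[k], tip_B[k])` and `tip_A <= tip_B` always (equality = closed pair).
#' The across-pair axis Y runs from `-sum(widths)/2` at the edge of pair 1 to
#' `+sum(widths)/2` at the edge of the last pair.
#'
#' @param leaf_widths_mm numeric vector of per-pair widths at isocenter, mm.
#'   Default: Millennium 120 layout (10 x 10 mm, 40 x 5 mm, 10 x 10 mm).
#' @return An object of class `leaf_bank_geometry`: list with `n_pairs`,
#'   `leaf_widths_mm`, `pair_edges_mm` (length `n_pairs + 1`, Y edges) and
#'   `pair_centers_mm`.
#' @examples
#' g <- leaf_bank_geometry()
#' g$n_pairs
#' range(g$pair_edges_mm)
#' @export
leaf_bank_geometry <- function(leaf_widths_mm = c(rep(10, 10), rep(5, 40), rep(10, 10))) {
  if (!is.numeric(leaf_widths_mm) || any(!is.finite(leaf_widths_mm)) ||
      any(leaf_widths_mm <= 0)) {
    stop("leaf widths must be positive finite numbers", call. = FALSE)
  }
  total <- sum(leaf_widths_mm)
  edges <- c(0, cumsum(leaf_widths_mm)) - total / 2
  structure(
    list(
      n_pairs = length(leaf_widths_mm),
      leaf_widths_mm = as.numeric(leaf_widths_mm),
      pair_edges_mm = edges,
      pair_centers_mm = (edges[-1] + edges[-length(edges)]) / 2
    ),
    class = "leaf_bank_geometry"
  )
}

#' @export
print.leaf_bank_geometry <- function(x, ...) {
  cat(sprintf("<leaf_bank_geometry> %d pairs, widths %g-%g mm, span %g mm\n",
              x$n_pairs, min(x$leaf_widths_mm), max(x$leaf_widths_mm),
              sum(x$leaf_widths_mm)))
  invisible(x)
}

geometry_equal <- function(a, b) {
  a$n_pairs == b$n_pairs &&
    isTRUE(all.equal(a$leaf_widths_mm, b$leaf_widths_mm, tolerance = 1e-9))
}
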