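#' Per-leaf RMS position errors of a delivery
#'
#' Root-mean-square of `planned - recorded` per leaf over the beam-on
#' snapshots of a delivery record (beam-hold snapshots are excluded: during
#' a hold the leaves are not expected to track). Banks A and B are reported
#' side by side, together with the plan-level maximum, the summary used to
#' grade how cleanly a dynamic delivery tracked its plan.
#'
#' @param record a [delivery_record()].
#' @return object of class `leaf_error_summary`: `per_leaf_rms` (matrix
#'   `n_pairs` x 2, columns A and B, mm) and `max_rms` (mm).
#' @export
rms_leaf_errors <- function(record) {
  on <- record$bank_a_log$beam_on
  if (!any(on)) stop("no beam-on snapshots in record", call. = FALSE)
  rms <- function(log) {
    d <- log$planned[on, , drop = FALSE] - log$recorded[on, , drop = FALSE]
    sqrt(colMeans(d^2))
  }
  per_leaf <- cbind(A = rms(record$bank_a_log), B = rms(record$bank_b_log))
  structure(list(per_leaf_rms = per_leaf, max_rms = max(per_leaf)),
            class = "leaf_error_summary")
}

#' @export
print.leaf_error_summary <- function(x, ...) {
  cat(sprintf("<leaf_error_summary> max RMS %.3f mm (bank A median %.3f, bank B median %.3f)\n",
              x$max_rms, stats::median(x$per_leaf_rms[, "A"]),
              stats::median(x$per_leaf_rms[, "B"])))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] for paired QA quantities (e.g. the
#' calculated vs measured dose-change ratios of an error-injection study),
#' returning both the coefficient r and its square.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r` and `r_squared`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with >= 3 pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2)
}

#' Confidence limit of a set of differences
#'
#' The confidence-limit statistic used to set QA action levels:
#' `|mean(diffs)| + 1.96 * sd(diffs)` with the sample (n - 1) standard
#' deviation. Invariant under negating all differences.
#'
#' @param diffs numeric vector of differences (>= 2 values), typically DVH
#'   metric differences in percent of prescription.
#' @return scalar confidence limit, same units as `diffs`.
#' @export
confidence_limit <- function(diffs) {
  if (length(diffs) < 2) stop("need >= 2 differences", call. = FALSE)
  abs(mean(diffs)) + 1.96 * stats::sd(diffs)
}

#' Compare DVH metrics of an original and a reconstructed plan
#'
#' Differences (reconstructed - original) in D98%, D2% and Dmean, with a
#' pass/flag verdict at the action level: the delivery is flagged when any
#' absolute difference strictly exceeds the level (a boundary value passes).
#'
#' @param original,reconstructed `dvh_metrics` (or lists with `d98`, `d2`,
#'   `dmean`) in percent of prescription.
#' @param action_level_pct action level in percent (default 1.0).
#' @param case_id optional case label.
#' @return object of class `plan_comparison`: `diffs` (named numeric:
#'   `d98`, `d2`, `dmean`), `verdict` (`"pass"` or `"flag"`), the inputs
#'   and the level.
#' @export
compare_plans <- function(original, reconstructed, action_level_pct = 1.0,
                          case_id = NA_character_) {
  diffs <- c(d98 = reconstructed$d98 - original$d98,
             d2 = reconstructed$d2 - original$d2,
             dmean = reconstructed$dmean - original$dmean)
  structure(
    list(case_id = case_id, original = original, reconstructed = reconstructed,
         diffs = diffs, action_level_pct = action_level_pct,
         verdict = if (any(abs(diffs) > action_level_pct)) "flag" else "pass"),
    class = "plan_comparison"
  )
}

#' @export
print.plan_comparison <- function(x, ...) {
  cat(sprintf("<plan_comparison>%s dD98 %+0.2f, dD2 %+0.2f, dDmean %+0.2f (%%): %s at %.1f%%\n",
              if (is.na(x$case_id)) "" else paste0(" ", x$case_id, ":"),
              x$diffs["d98"], x$diffs["d2"], x$diffs["dmean"],
              toupper(x$verdict), x$action_level_pct))
  invisible(x)
}

#' Bundled validation datasets
#'
#' Two small datasets shipped with the package, transcribed from a published
#' validation of log-file-based IMRT QA on a Varian-type linac:
#'
#' \describe{
#'   \item{`validation_ratios()`}{isocenter chamber-dose ratios for ten
#'     deliberately induced MLC errors on a five-beam prostate plan:
#'     `dcalc_ratio` = reconstructed-plan / reference-plan calculated dose,
#'     `dmeas_ratio` = measured erroneous / reference dose. The correlation
#'     of the two columns measures how faithfully log-based reconstruction
#'     tracks real dose changes.}
#'   \item{`clinical_dvh_audit()`}{target-volume D98%, D2% and Dmean (in
#'     percent of prescription) for 20 clinical plans (head & neck,
#'     prostate, breast, lung) and their log-reconstructed counterparts,
#'     plus the maximum per-leaf RMS position error (cm) of each delivery.}
#' }
#'
#' @return a `data.frame`.
#' @export
validation_ratios <- function() {
  read_commented_csv(system.file("extdata", "validation_ratios.csv",
                                 package = "dynaqa", mustWork = TRUE))
}

#' @rdname validation_ratios
#' @export
clinical_dvh_audit <- function() {
  read_commented_csv(system.file("extdata", "clinical_dvh_audit.csv",
                                 package = "dynaqa", mustWork = TRUE))
}

# leading '# ' lines are prose; '#' elsewhere is data (case labels)
read_commented_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  utils::read.csv(text = lines[!grepl("^#", lines)], comment.char = "",
                  stringsAsFactors = FALSE)
}

#' Pooled DVH-metric differences of the clinical audit
#'
#' Reconstructed-minus-original differences for all cases and all three
#' metrics (D98%, D2%, Dmean) of [clinical_dvh_audit()], the pooled sample
#' over which the audit's confidence limit is computed.
#'
#' @param audit a data frame in the layout of [clinical_dvh_audit()].
#' @return data.frame with `case`, `metric`, `diff` (percent of
#'   prescription).
#' @export
audit_differences <- function(audit = clinical_dvh_audit()) {
  data.frame(
    case = rep(audit$case, 3),
    metric = rep(c("d98", "d2", "dmean"), each = nrow(audit)),
    diff = c(audit$d98_recon - audit$d98_orig,
             audit$d2_recon - audit$d2_orig,
             audit$dmean_recon - audit$dmean_orig)
  )
}
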