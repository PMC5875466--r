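#' Configuration for an end-to-end QA run
#'
#' Carries everything a QA run fixes by convention: gamma criteria and
#' low-dose threshold, DVH action level, phantom preset, fluence grid
#' spacing, effective attenuation, and chamber radius.
#'
#' @param dose_pct,dta_mm,threshold_pct gamma criteria (see
#'   [gamma_analysis()]).
#' @param action_level_pct DVH-difference action level, percent.
#' @param phantom_preset preset name for [make_phantom()].
#' @param fluence_spacing_mm fluence grid spacing, mm.
#' @param attenuation_per_mm dose-engine attenuation, 1/mm.
#' @param chamber_radius_mm chamber sphere radius, mm.
#' @return a named list of class `qa_config`.
#' @export
qa_config <- function(dose_pct = 3, dta_mm = 3, threshold_pct = 10,
                      action_level_pct = 1.0,
                      phantom_preset = "cube_target_oars",
                      fluence_spacing_mm = 1, attenuation_per_mm = 0.005,
                      chamber_radius_mm = 3.1) {
  structure(as.list(environment()), class = "qa_config")
}

#' Run the full log-based QA pipeline on one plan
#'
#' The end-to-end patient-DVH QA workflow: reconstruct every beam from its
#' delivery log pair (actual mode, keeping the reference MU), render planned
#' and reconstructed fluence and compare them with gamma analysis, compute
#' per-leaf RMS summaries, recompute the dose for the reference and the
#' reconstructed plan with the same engine and normalization, extract DVH
#' metrics for every phantom structure, and grade the metric differences at
#' the action level. Deterministic given its inputs.
#'
#' @param plan a [treatment_plan()] (the reference plan).
#' @param records named list of [delivery_record()]s, one per beam, names
#'   matching the beam ids.
#' @param config a [qa_config()].
#' @return object of class `qa_report`: per-beam gamma results and RMS
#'   summaries, per-structure [compare_plans()] comparisons, chamber-dose
#'   ratio, and the overall verdict (`"pass"` unless any structure flags).
#' @export
run_qa <- function(plan, records, config = qa_config()) {
  ids <- vapply(plan$beams, `[[`, character(1), "beam_id")
  if (length(records) != length(plan$beams)) {
    stop(sprintf("unpaired log: %d beams but %d delivery records",
                 length(plan$beams), length(records)), call. = FALSE)
  }
  if (!is.null(names(records)) && !all(ids %in% names(records))) {
    stop("unpaired log: missing record(s) for beam(s) ",
         paste(setdiff(ids, names(records)), collapse = ", "), call. = FALSE)
  }
  recs <- if (is.null(names(records))) records else records[ids]
  beams_recon <- vector("list", length(ids))
  gamma_results <- vector("list", length(ids))
  rms <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    beams_recon[[i]] <- reconstruct_beam(recs[[i]], mode = "actual",
                                         total_mu = plan$beams[[i]]$total_mu)
    fm_plan <- compute_fluence(plan$beams[[i]],
                               spacing_mm = config$fluence_spacing_mm)
    fm_recon <- compute_fluence(beams_recon[[i]],
                                spacing_mm = config$fluence_spacing_mm)
    gamma_results[[i]] <- gamma_analysis(fm_plan, fm_recon,
                                         dose_pct = config$dose_pct,
                                         dta_mm = config$dta_mm,
                                         threshold_pct = config$threshold_pct)
    rms[[i]] <- rms_leaf_errors(recs[[i]])
  }
  names(beams_recon) <- names(gamma_results) <- names(rms) <- ids
  plan_recon <- treatment_plan(paste0(plan$plan_id, ".recon"), beams_recon,
                               plan$prescription_dose)
  ph <- make_phantom(config$phantom_preset)
  dose_ref <- compute_dose(plan, ph$phantom,
                           attenuation_per_mm = config$attenuation_per_mm,
                           fluence_spacing_mm = config$fluence_spacing_mm)
  dose_rec <- compute_dose(plan_recon, ph$phantom, scale = dose_ref$scale,
                           attenuation_per_mm = config$attenuation_per_mm,
                           fluence_spacing_mm = config$fluence_spacing_mm)
  comparisons <- lapply(ph$masks, function(m) {
    mo <- dvh_metrics(compute_dvh(dose_ref, m))
    mr <- dvh_metrics(compute_dvh(dose_rec, m))
    compare_plans(mo, mr, config$action_level_pct, case_id = m$name)
  })
  chamber_ratio <- chamber_dose(dose_rec, radius_mm = config$chamber_radius_mm) /
    chamber_dose(dose_ref, radius_mm = config$chamber_radius_mm)
  verdicts <- vapply(comparisons, `[[`, character(1), "verdict")
  structure(
    list(plan_id = plan$plan_id, config = config,
         beams_recon = beams_recon, gamma = gamma_results, rms = rms,
         comparisons = comparisons, chamber_ratio = chamber_ratio,
         max_rms = max(vapply(rms, `[[`, numeric(1), "max_rms")),
         verdict = if (any(verdicts == "flag")) "flag" else "pass"),
    class = "qa_report"
  )
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("== QA report for plan '%s' ==\n", x$plan_id))
  cat(sprintf("Beams: %d | gamma %g%%/%g mm (threshold %g%%)\n",
              length(x$gamma), x$config$dose_pct, x$config$dta_mm,
              x$config$threshold_pct))
  for (id in names(x$gamma)) {
    cat(sprintf("  %-10s gamma pass %6.2f%%   max leaf RMS %.3f mm\n",
                id, x$gamma[[id]]$passing_rate, x$rms[[id]]$max_rms))
  }
  cat(sprintf("Chamber dose ratio (recon/ref): %.4f\n", x$chamber_ratio))
  cat(sprintf("DVH differences (recon - ref, %% of prescription), action level %.1f%%:\n",
              x$config$action_level_pct))
  for (cmp in x$comparisons) {
    cat(sprintf("  %-10s dD98 %+6.2f  dD2 %+6.2f  dDmean %+6.2f  -> %s\n",
                cmp$case_id, cmp$diffs["d98"], cmp$diffs["d2"],
                cmp$diffs["dmean"], toupper(cmp$verdict)))
  }
  cat(sprintf("Overall verdict: %s\n", toupper(x$verdict)))
  invisible(x)
}
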