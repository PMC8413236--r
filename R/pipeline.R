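# Orchestration: phantom/scan -> quantification tables, and cohort ->
# the full statistical report bundle (decline regressions, Cox tables, KM
# summaries, horizon confusion metrics, AUC comparisons).  Every output is
# stamped with the effective parameters and seed so a run can be audited
# and reproduced.

#' Quantify cPPFE for a batch of scans
#'
#' Runs segmentation, carina localisation, upper-zone cropping, shell
#' quantification and radiologist gating per scan. A failing scan is
#' flagged in its row and the run continues.
#'
#' @param volumes named list of [as_ct_volume()] objects or NIfTI paths.
#' @param sidecars data.frame with one row per scan: `id`, `vppfe_present`
#'   (logical), optional `carina_slice` (manual carina; NA = auto-detect).
#' @param params a [cppfe_params()].
#' @return data.frame: per scan, shell/dense counts, `cppfe_percent`,
#'   `gated_percent`, `dichotomised`, carina/zone bookkeeping, `error`
#'   (NA when the scan succeeded), plus the parameters used.
#' @export
run_quantification <- function(volumes, sidecars, params = cppfe_params()) {
  if (length(volumes) == 0) stop("no input volumes")
  ids <- names(volumes)
  if (is.null(ids)) ids <- sidecars$id[seq_along(volumes)]
  rows <- lapply(seq_along(volumes), function(i) {
    id <- ids[i]
    sc <- sidecars[sidecars$id == id, , drop = FALSE]
    tryCatch({
      v <- volumes[[i]]
      if (is.character(v)) v <- read_ct_nifti(v)
      mask <- segment_lungs(v)
      override <- if (nrow(sc) && !is.null(sc$carina_slice) &&
                      !is.na(sc$carina_slice)) sc$carina_slice else NULL
      car <- detect_carina(v, manual_override = override, lung_mask = mask)
      uz <- upper_zone(mask, car, v$spacing)
      res <- compute_cppfe(v, mask, uz, params)
      present <- if (nrow(sc)) isTRUE(sc$vppfe_present) else TRUE
      res <- gate_by_radiologist(res, present)
      data.frame(id = id, carina_slice = car,
                 apex_slice = uz$apex_slice,
                 shell_voxels = res$shell_voxels_total,
                 dense_voxels = res$dense_shell_voxels_total,
                 cppfe_percent = res$cppfe_percent,
                 vppfe_present = present,
                 gated_percent = res$gated_percent,
                 dichotomised = res$dichotomised,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = id, carina_slice = NA_integer_,
                 apex_slice = NA_integer_, shell_voxels = NA_integer_,
                 dense_voxels = NA_integer_, cppfe_percent = NA_real_,
                 vppfe_present = NA, gated_percent = NA_real_,
                 dichotomised = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  out
}

#' Run the full cohort analysis
#'
#' Composes visual scoring, FVC eligibility, the decline mixed model and
#' its regressions, Cox/frailty-Cox mortality models, Kaplan-Meier
#' summaries, fixed-horizon confusion metrics and the paired AUC
#' comparison of the continuous computerised score against the 7-point
#' visual score.
#'
#' @param cohort a [generate_cohort()] result, or an equivalent list of
#'   `subjects`, `fvc_long`, `survival` tables.
#' @param cutpoint dichotomisation cutpoint for the computerised score.
#' @param horizon classification horizon in years.
#' @param boot_iterations C-index bootstrap iterations.
#' @param seed seed for the bootstrap.
#' @param covariates adjustment set for the decline and mortality models.
#' @return A `ppfe_report` list of result tables; every element of
#'   `config` echoes the effective parameters.
#' @export
run_cohort_analysis <- function(cohort, cutpoint = 2.5, horizon = 2,
                                boot_iterations = 500L, seed = 1L,
                                covariates = c("age", "male", "smoker",
                                               "antifibrotic",
                                               "dlco_ppred")) {
  subjects <- cohort$subjects
  n_centres <- length(unique(subjects$centre))
  mode <- if (n_centres > 1) "validation" else "derivation"

  elig <- apply_fvc_eligibility(cohort$fvc_long)
  fvc_elig <- cohort$fvc_long[cohort$fvc_long$id %in% elig$eligible_ids, ,
                              drop = FALSE]
  lme <- fit_fvc_lme(fvc_elig, subjects, use_centre = n_centres > 1)
  declines <- predict_decline(lme)

  subjects$cppfe_pos <- subjects$cppfe_percent >= cutpoint
  decline_tabs <- lapply(
    stats::setNames(c("vppfe_category", "cppfe_percent", "cppfe_pos"),
                    c("vppfe_category", "cppfe_continuous",
                      "cppfe_dichotomised")),
    function(v) tryCatch(
      regress_decline(declines, v, covariates, mode = mode,
                      subjects = subjects),
      error = function(e) list(error = conditionMessage(e))))

  sv <- cohort$survival
  sv$cppfe_pos <- sv$cppfe_percent >= cutpoint
  frailty_group <- if (n_centres > 1) "centre" else NULL
  cox_tabs <- lapply(
    stats::setNames(c("vppfe_category", "cppfe_pos"),
                    c("vppfe_category", "cppfe_dichotomised")),
    function(v) tryCatch(
      fit_cox(sv, c(covariates, v), frailty_group = frailty_group),
      error = function(e) list(error = conditionMessage(e))))

  cindex <- tryCatch(
    cindex_bootstrap(sv, covariates = c(covariates, "cppfe_pos"),
                     iterations = boot_iterations, seed = seed),
    error = function(e) list(error = conditionMessage(e)))

  sv$km_group <- ifelse(sv$vppfe_category == "absent", "no PPFE",
                        ifelse(sv$cppfe_pos, sprintf("cPPFE >= %g%%", cutpoint),
                               sprintf("cPPFE < %g%%", cutpoint)))
  km_c <- tryCatch(km_analysis(sv, "km_group"),
                   error = function(e) list(error = conditionMessage(e)))
  km_v <- tryCatch(km_analysis(sv, "vppfe_category"),
                   error = function(e) list(error = conditionMessage(e)))

  confusion <- list(
    cppfe = confusion_at_horizon(sv, sv$cppfe_pos, horizon),
    marked_vppfe = confusion_at_horizon(sv, sv$vppfe_category == "marked",
                                        horizon))
  status <- outcome_at_horizon(sv, horizon)
  auc_cmp <- tryCatch(
    compare_auc_delong(sv$cppfe_percent, sv$vppfe_7pt, status),
    error = function(e) list(error = conditionMessage(e)))

  structure(list(
    fvc_exclusions = elig$exclusions,
    lme = lme, declines = declines,
    decline_regressions = decline_tabs,
    cox = cox_tabs, cindex = cindex,
    km_cppfe = km_c, km_vppfe = km_v,
    confusion = confusion, auc_comparison = auc_cmp,
    config = list(cutpoint = cutpoint, horizon = horizon,
                  boot_iterations = boot_iterations, seed = seed,
                  covariates = covariates, mode = mode)),
    class = "ppfe_report")
}
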