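#!/usr/bin/env Rscript
# Simulate derivation- and validation-style IPF cohorts with known FVC
# trajectory and survival parameters.
#
# Writes: results/cohort_derivation/{subjects,fvc_long,survival}.csv
#         results/cohort_validation/{subjects,fvc_long,survival}.csv
#         results/cohort_truth.json (generative parameters)

suppressPackageStartupMessages(library(ppfequant))
seed <- 20240902L

deriv <- generate_cohort(cohort_spec(n_subjects = 142L, seed = seed))
valid <- generate_cohort(validation_cohort_spec(seed = seed + 1L))

write_cohort_csv(deriv, "results/cohort_derivation")
write_cohort_csv(valid, "results/cohort_validation")

summarise <- function(co, label) {
  s <- co$subjects
  cat(sprintf(
    "%s: n=%d | PPFE present %.0f%% | moderate %.0f%% marked %.0f%% | deaths %d | cPPFE>=2.5%%: %.0f%%\n",
    label, nrow(s), 100 * mean(s$vppfe_presence),
    100 * mean(s$vppfe_category == "moderate"),
    100 * mean(s$vppfe_category == "marked"),
    sum(co$survival$event), 100 * mean(s$cppfe_pos)))
}
summarise(deriv, "derivation")
summarise(valid, "validation")

jsonlite::write_json(
  list(derivation = list(seed = seed,
                         expected_event_fraction =
                           deriv$truth$expected_event_fraction,
                         extra_decline =
                           as.list(deriv$truth$spec$fvc_model$extra_decline),
                         log_hr = as.list(deriv$truth$spec$survival_model$log_hr)),
       validation = list(seed = seed + 1L,
                         expected_event_fraction =
                           valid$truth$expected_event_fraction,
                         log_hr = as.list(valid$truth$spec$survival_model$log_hr))),
  "results/cohort_truth.json", auto_unbox = TRUE, digits = NA)
cat("Cohort tables written under results/\n")
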