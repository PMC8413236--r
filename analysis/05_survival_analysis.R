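#!/usr/bin/env Rscript
# Mortality and classification analyses: Cox / frailty-Cox hazard ratios,
# bootstrapped concordance, Kaplan-Meier medians, 2-year confusion metrics,
# and the paired DeLong comparison of computerised vs visual scores.
#
# Reads:  results/cohort_derivation/, results/cohort_validation/
# Writes: results/cox_tables.csv, results/km_medians.csv,
#         results/classification_metrics.json

suppressPackageStartupMessages(library(ppfequant))
covars <- c("age", "male", "smoker", "antifibrotic", "dlco_ppred")
seed <- 20240905L

read_cohort <- function(dir) {
  sv <- read.csv(file.path(dir, "survival.csv"))
  sv$vppfe_category <- factor(sv$vppfe_category,
                              levels = c("absent", "moderate", "marked"))
  sv
}
sv_d <- read_cohort("results/cohort_derivation")
sv_v <- read_cohort("results/cohort_validation")

cox_rows <- list()
for (cohort in c("derivation", "validation")) {
  sv <- if (cohort == "derivation") sv_d else sv_v
  fg <- if (cohort == "validation") "centre" else NULL
  for (v in c("vppfe_category", "cppfe_pos")) {
    fit <- fit_cox(sv, c(covars, v), frailty_group = fg)
    tab <- fit$table
    tab$cohort <- cohort
    tab$c_index <- fit$c_index
    zp <- if (!is.null(fit$schoenfeld))
      fit$schoenfeld$p[fit$schoenfeld$term == "GLOBAL"] else NA
    tab$schoenfeld_global_p <- if (length(zp)) zp else NA
    cox_rows[[paste(cohort, v)]] <- tab
  }
}
cox_tab <- do.call(rbind, cox_rows)
write.csv(cox_tab, "results/cox_tables.csv", row.names = FALSE)
cat("Hazard ratios (PPFE terms):\n")
print(cox_tab[grepl("vppfe|cppfe", cox_tab$term),
              c("cohort", "term", "hr", "ci_lo", "ci_hi", "p", "c_index")],
      digits = 3, row.names = FALSE)

# combined cohort: KM risk groups, C-index bootstrap, 2-year metrics, AUC
sv_all <- rbind(sv_d, sv_v)
sv_all$km_group <- ifelse(sv_all$vppfe_category == "absent", "no PPFE",
                          ifelse(sv_all$cppfe_pos, "cPPFE >= 2.5%",
                                 "cPPFE < 2.5%"))
km <- km_analysis(sv_all, "km_group")
write.csv(km$groups, "results/km_medians.csv", row.names = FALSE)
cat(sprintf("\nLog-rank over %d groups: chi^2 = %.1f, p = %.2g\n",
            km$logrank_df + 1, km$logrank_chisq, km$logrank_p))
print(km$groups, digits = 3, row.names = FALSE)

ci <- cindex_bootstrap(sv_all, covariates = c(covars, "cppfe_pos"),
                       iterations = 500L, seed = seed)
cat(sprintf("\nC-index %.3f (bootstrap mean %.3f, 95%% CI %.3f-%.3f)\n",
            ci$c_index, ci$boot_mean, ci$ci_lo, ci$ci_hi))

conf_c <- confusion_at_horizon(sv_all, sv_all$cppfe_pos, horizon = 2)
conf_m <- confusion_at_horizon(sv_all, sv_all$vppfe_category == "marked",
                               horizon = 2)
status <- outcome_at_horizon(sv_all, 2)
cmp <- compare_auc_delong(sv_all$cppfe_percent, sv_all$vppfe_7pt, status)

jsonlite::write_json(
  list(cindex = ci[c("c_index", "boot_mean", "ci_lo", "ci_hi")],
       confusion_cppfe = conf_c, confusion_marked_vppfe = conf_m,
       auc_comparison = cmp, seed = seed),
  "results/classification_metrics.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("\n2-year metrics, cPPFE >= 2.5%%: sens %.1f spec %.1f PPV %.1f NPV %.1f (excluded %d)\n",
            conf_c$sensitivity, conf_c$specificity, conf_c$ppv, conf_c$npv,
            conf_c$counts["excluded"]))
cat(sprintf("2-year metrics, marked vPPFE:   sens %.1f spec %.1f PPV %.1f NPV %.1f\n",
            conf_m$sensitivity, conf_m$specificity, conf_m$ppv, conf_m$npv))
cat(sprintf("AUC continuous cPPFE %.3f vs 7-point vPPFE %.3f, DeLong p = %.3g\n",
            cmp$auc_a, cmp$auc_b, cmp$p))
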