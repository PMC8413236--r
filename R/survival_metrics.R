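# Survival and classification analyses: Cox and frailty-Cox models with
# Schoenfeld checks and concordance, bootstrapped C-index, Kaplan-Meier
# medians with Dorey-Korn-style confidence intervals and log-rank tests,
# fixed-horizon confusion metrics under censoring, and DeLong ROC machinery.

#' Fit a (frailty) Cox proportional-hazards model
#'
#' Efron ties; optional gamma frailty on a grouping variable (log-normal
#' available via `frailty_dist`). Reports hazard ratios with 95% confidence
#' intervals, the model concordance, and the Schoenfeld proportionality
#' test (global and per covariate) where it is computable.
#'
#' @param records data.frame with `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param frailty_group optional column name for the shared-frailty group.
#' @param frailty_dist `"gamma"` (default) or `"gaussian"` (log-normal
#'   frailty).
#' @return list: `table` (term, hr, ci_lo, ci_hi, p), `c_index`,
#'   `schoenfeld` (data.frame or NULL with a note), `fit`, `warnings`.
#' @export
fit_cox <- function(records, covariates, frailty_group = NULL,
                    frailty_dist = c("gamma", "gaussian")) {
  frailty_dist <- match.arg(frailty_dist)
  if (sum(records$event) < 1) stop("no events in the data")
  keep <- stats::complete.cases(records[c("time", "event", covariates,
                                          frailty_group)])
  dat <- records[keep, , drop = FALSE]
  rhs <- covariates
  frailty_note <- NULL
  if (!is.null(frailty_group)) {
    if (length(unique(dat[[frailty_group]])) < 2) {
      # a single shared group carries no between-group variance; the model
      # reduces exactly to the unpenalised fit
      frailty_note <- sprintf(
        "frailty group '%s' has a single level; term dropped", frailty_group)
    } else {
      rhs <- c(rhs, sprintf('frailty(%s, distribution = "%s")',
                            frailty_group, frailty_dist))
    }
  }
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(rhs, collapse = " + ")),
                            env = new.env(parent = environment()))
  assign("frailty", survival::frailty, envir = environment(form))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = "efron"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  beta <- fit$coefficients
  se <- sqrt(diag(as.matrix(fit$var)))[seq_along(beta)]
  tab <- data.frame(term = names(beta),
                    hr = exp(beta),
                    ci_lo = exp(beta - stats::qnorm(0.975) * se),
                    ci_hi = exp(beta + stats::qnorm(0.975) * se),
                    p = 2 * stats::pnorm(-abs(beta / se)), row.names = NULL)
  if (any(abs(beta) > 10)) {
    warns <- c(warns, "possible separation: unstable estimate flagged")
    warning("possible separation: very large coefficient(s)")
  }
  zph <- tryCatch({
    zt <- suppressWarnings(survival::cox.zph(fit))$table
    data.frame(term = rownames(zt), chisq = zt[, "chisq"], df = zt[, "df"],
               p = zt[, "p"], row.names = NULL)
  }, error = function(e) NULL)
  list(table = tab,
       c_index = unname(fit$concordance["concordance"]),
       schoenfeld = zph,
       schoenfeld_note = if (is.null(zph))
         "Schoenfeld test unavailable for this fit" else NULL,
       frailty_note = frailty_note,
       fit = fit, warnings = warns)
}

#' Bootstrap the concordance index
#'
#' Resamples subjects with replacement `iterations` times. With a model
#' formula the Cox model is refitted on each resample and its concordance
#' recorded; with a fixed `risk_score` the concordance of that score is
#' recomputed on each resample. Percentile 95% interval; bit-reproducible
#' under `seed`.
#'
#' @param records data.frame with `time`, `event` and covariates/score.
#' @param covariates covariate names for refitting (mutually exclusive with
#'   `risk_score`).
#' @param risk_score name of a fixed risk-score column.
#' @param iterations bootstrap iterations (default 500).
#' @param seed integer seed.
#' @return list: `c_index` (full sample), `boot_mean`, `ci_lo`, `ci_hi`,
#'   `iterations`.
#' @export
cindex_bootstrap <- function(records, covariates = NULL, risk_score = NULL,
                             iterations = 500L, seed = 1L) {
  if (is.null(covariates) == is.null(risk_score))
    stop("supply exactly one of covariates or risk_score")
  cstat <- function(dat) {
    if (!is.null(risk_score)) {
      survival::concordance(
        stats::as.formula(paste("survival::Surv(time, event) ~", risk_score)),
        data = dat, reverse = TRUE)$concordance
    } else {
      fit <- suppressWarnings(survival::coxph(
        stats::as.formula(paste("survival::Surv(time, event) ~",
                                paste(covariates, collapse = " + "))),
        data = dat, ties = "efron"))
      unname(fit$concordance["concordance"])
    }
  }
  full <- cstat(records)
  set.seed(seed)
  boots <- vapply(seq_len(iterations), function(i) {
    idx <- sample.int(nrow(records), replace = TRUE)
    tryCatch(cstat(records[idx, , drop = FALSE]), error = function(e)
      NA_real_)
  }, numeric(1))
  boots <- boots[!is.na(boots)]
  qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  list(c_index = full, boot_mean = mean(boots),
       ci_lo = qs[1], ci_hi = qs[2], iterations = iterations)
}

# Median survival and its CI from a single survfit stratum.  The point
# estimate is the earliest time at which the survival curve reaches 0.5.
# The interval inverts the pointwise log-log confidence band in the spirit
# of Dorey & Korn: the bound is the earliest time at which the relevant
# band limit drops to 0.5; a band that never reaches 0.5 within follow-up
# leaves that bound not-reached (NA) rather than erroring.
km_median_ci <- function(time, surv, lower, upper) {
  med <- if (any(surv <= 0.5)) time[which(surv <= 0.5)[1]] else NA_real_
  # the lower band sits below the curve and reaches 0.5 first (earliest
  # plausible median); the upper band reaches it last
  lo <- if (any(lower <= 0.5, na.rm = TRUE))
    time[which(lower <= 0.5)[1]] else NA_real_
  hi <- if (any(upper <= 0.5, na.rm = TRUE))
    time[which(upper <= 0.5)[1]] else NA_real_
  c(median = med, ci_lo = lo, ci_hi = hi)
}

#' Kaplan-Meier analysis by group
#'
#' Product-limit curves per group, median survival with a Dorey-Korn-style
#' interval from inverting the pointwise log-log band (an unreached bound
#' is reported as NA, "not reached"), and the k-group log-rank test.
#'
#' @param records data.frame with `time`, `event`.
#' @param group name of the grouping column (or NULL for a single group).
#' @return list: `groups` (group, n, events, median, ci_lo, ci_hi),
#'   `logrank_chisq`, `logrank_df`, `logrank_p` (NULL without grouping),
#'   `curves` (group, time, surv, lower, upper), `fit`.
#' @export
km_analysis <- function(records, group = NULL) {
  if (is.null(group)) {
    records$.g <- "all"; group <- ".g"
  }
  form <- stats::as.formula(paste("survival::Surv(time, event) ~", group))
  sf <- survival::survfit(form, data = records, conf.type = "log-log")
  strata <- if (is.null(sf$strata)) {
    stats::setNames(list(seq_along(sf$time)), unique(records[[group]])[1])
  } else {
    idx <- rep(seq_along(sf$strata), sf$strata)
    split(seq_along(sf$time), names(sf$strata)[idx])
  }
  rows <- lapply(names(strata), function(gname) {
    i <- strata[[gname]]
    est <- km_median_ci(sf$time[i], sf$surv[i], sf$lower[i], sf$upper[i])
    data.frame(group = sub("^[^=]*=", "", gname),
               n = sum(records[[group]] == sub("^[^=]*=", "", gname)),
               events = sum(sf$n.event[i]),
               median = est["median"], ci_lo = est["ci_lo"],
               ci_hi = est["ci_hi"], row.names = NULL)
  })
  groups <- do.call(rbind, rows)
  curves <- do.call(rbind, lapply(names(strata), function(gname) {
    i <- strata[[gname]]
    data.frame(group = sub("^[^=]*=", "", gname), time = sf$time[i],
               surv = sf$surv[i], lower = sf$lower[i], upper = sf$upper[i],
               row.names = NULL)
  }))
  lr_chisq <- lr_p <- lr_df <- NULL
  if (length(strata) > 1) {
    sd <- survival::survdiff(form, data = records)
    lr_df <- length(sd$n) - 1
    lr_chisq <- sd$chisq
    lr_p <- stats::pchisq(sd$chisq, lr_df, lower.tail = FALSE)
  }
  list(groups = groups, logrank_chisq = lr_chisq, logrank_df = lr_df,
       logrank_p = lr_p, curves = curves, fit = sf)
}

#' Classify outcome status at a fixed horizon under censoring
#'
#' Deaths before the horizon are events (1); subjects known to be alive at
#' the horizon are non-events (0); subjects censored before the horizon are
#' excluded (NA). A subject whose follow-up ends exactly at the horizon
#' while alive counts as a non-event.
#'
#' @param records data.frame with `time`, `event`.
#' @param horizon years (default 2).
#' @return Integer vector (1 / 0 / NA), one per record.
#' @export
outcome_at_horizon <- function(records, horizon = 2) {
  ifelse(records$event == 1 & records$time < horizon, 1L,
         ifelse(records$time >= horizon, 0L, NA_integer_))
}

#' Confusion metrics at a fixed horizon
#'
#' Cross-tabulates a binary classifier against [outcome_at_horizon()]
#' status; censored-before-horizon subjects enter no cell. Sensitivity,
#' specificity, PPV and NPV are percentages; with no events (or no
#' non-events) after exclusion the metrics are undefined and flagged.
#'
#' @param records data.frame with `time`, `event`.
#' @param classifier logical vector (or name of a logical column in
#'   `records`): the test-positive flag.
#' @param horizon years (default 2).
#' @return list: `counts` (TP, FP, FN, TN, excluded), `sensitivity`,
#'   `specificity`, `ppv`, `npv` (percent), `defined`.
#' @export
confusion_at_horizon <- function(records, classifier, horizon = 2) {
  flag <- if (is.character(classifier) && length(classifier) == 1)
    records[[classifier]] else classifier
  status <- outcome_at_horizon(records, horizon)
  keep <- !is.na(status) & !is.na(flag)
  tp <- sum(flag[keep] & status[keep] == 1)
  fp <- sum(flag[keep] & status[keep] == 0)
  fn <- sum(!flag[keep] & status[keep] == 1)
  tn <- sum(!flag[keep] & status[keep] == 0)
  defined <- (tp + fn) > 0 && (tn + fp) > 0
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(counts = c(TP = tp, FP = fp, FN = fn, TN = tn,
                  excluded = sum(!keep)),
       sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
       ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn),
       defined = defined)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' Trapezoidal AUC (equal to the Mann-Whitney statistic, mid-ranks for
#' ties) with the DeLong variance for the two-sided 95% interval.
#'
#' @param scores numeric risk scores (higher = more likely event).
#' @param outcome binary outcome (0/1; NAs dropped pairwise).
#' @return list: `auc`, `ci_lo`, `ci_hi`, `n_event`, `n_nonevent`.
#' @export
roc_auc <- function(scores, outcome) {
  keep <- !is.na(scores) & !is.na(outcome)
  scores <- scores[keep]; outcome <- outcome[keep]
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present")
  r <- pROC::roc(outcome, scores, direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(r, method = "delong"))
  list(auc = as.numeric(pROC::auc(r)), ci_lo = ci[1], ci_hi = ci[3],
       n_event = sum(outcome == 1), n_nonevent = sum(outcome == 0))
}

#' Compare two paired AUCs by the DeLong test
#'
#' Two-sided test of the AUC difference for two scores measured on the same
#' subjects. Identical (or perfectly rank-concordant) scores have a zero
#' difference with p = 1.
#'
#' @param scores_a,scores_b paired numeric scores.
#' @param outcome binary outcome (0/1); rows with any NA are dropped
#'   pairwise.
#' @return list: `auc_a`, `auc_b`, `difference`, `p`.
#' @export
compare_auc_delong <- function(scores_a, scores_b, outcome) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(outcome))
    stop("scores and outcome must be paired (equal length)")
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(outcome)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]
  outcome <- outcome[keep]
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present")
  ra <- pROC::roc(outcome, scores_a, direction = "<", quiet = TRUE)
  rb <- pROC::roc(outcome, scores_b, direction = "<", quiet = TRUE)
  diff <- as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))
  p <- tryCatch(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value,
    error = function(e) NA_real_)
  if (is.na(p) || is.nan(p)) p <- if (abs(diff) < 1e-12) 1 else NA_real_
  list(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       difference = diff, p = p)
}
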