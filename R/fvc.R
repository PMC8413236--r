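# The 1-year FVC decline statistic: an 18-month linear mixed-effects fit of
# absolute FVC with random intercept and slope per subject, from which each
# subject's predicted FVC at 1 year is expressed as a percentage fall from
# the observed baseline FVC.  Subjects enter only with a measurement within
# 3 months of baseline and another 3-18 months after baseline.

#' Apply longitudinal FVC eligibility
#'
#' A subject is eligible when the series contains at least two
#' measurements: one within `baseline_window` years of baseline and a
#' distinct one inside `followup_window` (defaults: 3 months, and 3-18
#' months).
#'
#' @param fvc_long data.frame with columns `id`, `time` (years from
#'   baseline), `fvc` (litres).
#' @param baseline_window latest time counting as a baseline measurement.
#' @param followup_window inclusive range for the follow-up measurement.
#' @return list with `eligible_ids` and machine-readable `exclusions`
#'   (`id`, `reason` one of `no_baseline_measurement`,
#'   `no_followup_measurement`).
#' @export
apply_fvc_eligibility <- function(fvc_long, baseline_window = 0.25,
                                  followup_window = c(0.25, 1.5)) {
  ids <- unique(fvc_long$id)
  reason <- character(0); excl <- character(0)
  eligible <- character(0)
  for (s in ids) {
    tt <- sort(fvc_long$time[fvc_long$id == s])
    has_base <- any(tt <= baseline_window)
    fu <- tt[tt >= followup_window[1] & tt <= followup_window[2]]
    # a single measurement cannot serve as both baseline and follow-up
    has_fu <- length(fu) > 0 &&
      (length(tt[tt <= baseline_window]) + length(fu) >
         length(intersect(tt[tt <= baseline_window], fu)))
    if (!has_base) {
      excl <- c(excl, s); reason <- c(reason, "no_baseline_measurement")
    } else if (!has_fu) {
      excl <- c(excl, s); reason <- c(reason, "no_followup_measurement")
    } else {
      eligible <- c(eligible, s)
    }
  }
  list(eligible_ids = eligible,
       exclusions = data.frame(id = excl, reason = reason,
                               stringsAsFactors = FALSE))
}

#' Apply cohort-level eligibility filters
#'
#' Table-driven exclusions: missing baseline lung function, under 3 months
#' of follow-up, missing antifibrotic information, and (for multivariable
#' analyses) missing DLco. The antifibrotic-regulatory trial subset (FVC
#' >= 50% predicted and DLco 30-79% predicted, both inclusive) is attached
#' as a flag, never applied as an exclusion.
#'
#' @param subjects data.frame with columns `baseline_fvc_ppred`,
#'   `dlco_ppred`, `antifibrotic` and optionally `followup_years`.
#' @return list with `subjects` (filtered, plus `trial_subset` and
#'   `has_dlco` flags) and `exclusions` (`id`, `reason`).
#' @export
apply_cohort_eligibility <- function(subjects) {
  excl <- data.frame(id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(subjects))
  note <- function(i, why) {
    excl <<- rbind(excl, data.frame(id = subjects$id[i], reason = why,
                                    stringsAsFactors = FALSE))
  }
  miss_fvc <- is.na(subjects$baseline_fvc_ppred)
  if (any(miss_fvc)) note(which(miss_fvc), "missing_baseline_lung_function")
  drop <- drop | miss_fvc
  if (!is.null(subjects$followup_years)) {
    short <- !is.na(subjects$followup_years) & subjects$followup_years < 0.25
    if (any(short)) note(which(short), "followup_under_3_months")
    drop <- drop | short
  }
  miss_af <- is.na(subjects$antifibrotic)
  if (any(miss_af)) note(which(miss_af), "missing_antifibrotic_information")
  drop <- drop | miss_af

  out <- subjects[!drop, , drop = FALSE]
  out$has_dlco <- !is.na(out$dlco_ppred)
  out$trial_subset <- out$has_dlco &
    !is.na(out$baseline_fvc_ppred) &
    out$baseline_fvc_ppred >= 50 &
    out$dlco_ppred >= 30 & out$dlco_ppred <= 79
  list(subjects = out, exclusions = excl)
}

#' Fit the longitudinal FVC mixed-effects model
#'
#' Restricted-maximum-likelihood fit of absolute FVC on gender, age, smoking
#' status, antifibrotic use, baseline percent-predicted FVC and study time,
#' with a random intercept and random time slope per subject; an optional
#' centre grouping adds a fixed centre effect and a random time slope at the
#' centre level. Optimiser warnings are captured and reported rather than
#' silently swallowed; a hard optimiser failure is an error.
#'
#' @param fvc_long longitudinal table (`id`, `time`, `fvc`), already
#'   filtered to eligible subjects.
#' @param subjects covariate table (`id`, `age`, `male`, `smoker`,
#'   `antifibrotic`, `baseline_fvc_ppred`, optionally `centre`).
#' @param use_centre add the centre terms (validation-style cohorts).
#' @return A `ppfe_lme` list: `fit` (the merMod), `data`, `converged`,
#'   `messages`.
#' @export
fit_fvc_lme <- function(fvc_long, subjects, use_centre = FALSE) {
  dat <- merge(fvc_long, subjects, by = "id")
  counts <- table(dat$id)
  if (any(counts < 2))
    stop("every subject must contribute at least two measurements")
  form <- fvc ~ male + age + smoker + antifibrotic + baseline_fvc_ppred +
    time + (1 + time | id)
  if (use_centre) {
    if (length(unique(dat$centre)) < 2)
      stop("centre adjustment requested but fewer than two centres present")
    form <- stats::update(form, . ~ . + centre + (0 + time | centre))
  }
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(lmerTest::lmer(form, data = dat, REML = TRUE),
             error = function(e) stop("LME fit failed: ",
                                      conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  # rank-deficient fixed effects are dropped silently by lme4; treat as error
  if (length(lme4::fixef(fit)) < length(attr(stats::terms(
        lme4::nobars(form)), "term.labels")) + 1)
    stop("model matrix is rank deficient")
  conv <- fit@optinfo$conv$opt == 0 &&
    length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(fit = fit, data = dat,
                 converged = conv, messages = unique(msgs)),
            class = "ppfe_lme")
}

#' Predict 1-year FVC decline per subject
#'
#' The decline is `100 * (observed baseline FVC - predicted FVC at 1 year) /
#' observed baseline FVC`, positive when FVC falls. The observed baseline is
#' the measurement closest to baseline within +/-3 months, ties broken
#' towards the earlier measurement. Prediction at one year is
#' subject-specific (fixed effects plus the subject's predicted random
#' effects); `level = "population"` gives the marginal prediction instead.
#'
#' @param model a [fit_fvc_lme()] result.
#' @param ids subjects to predict for; default all subjects in the fit.
#' @param level `"subject"` (default) or `"population"`.
#' @return data.frame: `id`, `baseline_fvc_obs`, `fvc_1y_pred`,
#'   `decline_percent`.
#' @export
predict_decline <- function(model, ids = NULL, level = c("subject",
                                                         "population")) {
  level <- match.arg(level)
  dat <- model$data
  if (is.null(ids)) ids <- unique(dat$id)
  missing_ids <- setdiff(ids, unique(dat$id))
  if (length(missing_ids))
    stop("subject(s) not in fitted model: ",
         paste(missing_ids, collapse = ", "))
  base_obs <- vapply(ids, function(s) {
    d <- dat[dat$id == s & dat$time <= 0.25, , drop = FALSE]
    d <- d[order(abs(d$time), d$time), , drop = FALSE]
    if (nrow(d) == 0) NA_real_ else d$fvc[1]
  }, numeric(1))
  nd <- dat[match(ids, dat$id), , drop = FALSE]
  nd$time <- 1
  pred <- stats::predict(model$fit, newdata = nd,
                         re.form = if (level == "subject") NULL else NA)
  data.frame(id = ids, baseline_fvc_obs = base_obs,
             fvc_1y_pred = as.numeric(pred),
             decline_percent = 100 * (base_obs - pred) / base_obs,
             row.names = NULL)
}

#' Regress 1-year decline on a PPFE variable
#'
#' Derivation-style cohorts use ordinary least squares; validation-style
#' cohorts use a mixed model with a random intercept per centre to absorb
#' between-centre differences. Estimates are reported with 95% confidence
#' intervals and p-values; linear models also report the model R-squared
#' and the studentised Breusch-Pagan heteroscedasticity check.
#'
#' @param declines data.frame from [predict_decline()] merged with subject
#'   covariates (or pass `subjects` to merge here).
#' @param ppfe_var name of the explanatory PPFE column (a factor is expanded
#'   to its contrasts).
#' @param covariates further adjustment columns (default the full set:
#'   age, gender, smoking, antifibrotic use, DLco).
#' @param mode `"derivation"` (linear model) or `"validation"` (mixed model
#'   with centre grouping).
#' @param subjects optional covariate table merged by `id`.
#' @return list: `table` (term, estimate, ci_lo, ci_hi, p), `r_squared`,
#'   `breusch_pagan` (statistic, p; linear mode only), `model`.
#' @export
regress_decline <- function(declines, ppfe_var,
                            covariates = c("age", "male", "smoker",
                                           "antifibrotic", "dlco_ppred"),
                            mode = c("derivation", "validation"),
                            subjects = NULL) {
  mode <- match.arg(mode)
  dat <- if (is.null(subjects)) declines else
    merge(declines, subjects, by = "id")
  dat <- dat[stats::complete.cases(dat[c("decline_percent", ppfe_var,
                                         covariates)]), , drop = FALSE]
  rhs <- paste(c(ppfe_var, covariates), collapse = " + ")
  if (mode == "derivation") {
    fit <- stats::lm(stats::reformulate(c(ppfe_var, covariates),
                                        "decline_percent"), data = dat)
    ci <- stats::confint(fit)
    sm <- summary(fit)
    tab <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      p = sm$coefficients[, 4], row.names = NULL)
    bp <- lmtest::bptest(fit, studentize = TRUE)
    list(table = tab, r_squared = sm$r.squared,
         breusch_pagan = list(statistic = unname(bp$statistic),
                              p = unname(bp$p.value)),
         model = fit)
  } else {
    if (length(unique(dat$centre)) < 2)
      stop("validation mode requires at least two centres")
    form <- stats::as.formula(paste("decline_percent ~", rhs, "+ (1 | centre)"))
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = dat, REML = TRUE)))
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit, method = "Wald")
    ci <- ci[rownames(sm), , drop = FALSE]
    tab <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      p = sm[, "Pr(>|t|)"], row.names = NULL)
    list(table = tab, r_squared = NA_real_, breusch_pagan = NULL,
         model = fit)
  }
}
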