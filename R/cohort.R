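# Synthetic IPF cohorts with known trajectory and hazard parameters.
#
# The generator emulates the statistical structure the downstream analyses
# assume: FVC trajectories from a linear mixed-effects model with random
# intercept and slope per subject, and survival from a proportional-hazards
# model with an exponential baseline, independent uniform censoring, and
# fixed centre offsets.  Default parameter values mirror a
# derivation-style cohort (n = 142, ~80% male, ~70% ever-smokers, mean DLco
# ~50% predicted, PPFE category mix 51/39/10%, an extra 18.3 percentage
# points of 1-year FVC decline and a log-hazard of log(7.70) for marked
# disease); `validation_cohort_spec()` provides a two-centre variant.

#' Specify a synthetic cohort
#'
#' @param n_subjects number of subjects.
#' @param covariates list of covariate distribution parameters: normal
#'   mean/sd plus clamp range for `age`, `dlco`, `fvc_ppred` and the
#'   predicted (reference) absolute FVC `pred_fvc`; Bernoulli probabilities
#'   `p_male`, `p_smoker`, `p_antifibrotic`.
#' @param centres named probabilities of centre membership (must sum to 1).
#' @param ppfe_probs named probabilities for `absent`/`moderate`/`marked`
#'   visual PPFE (must sum to 1).
#' @param cppfe_model continuous computerised score conditional on category:
#'   gamma shape/scale for moderate disease, shift + gamma for marked;
#'   absent scores 0 after gating.
#' @param fvc_model trajectory parameters: `decline_pct_year` baseline
#'   annual decline as a percentage of baseline FVC; `extra_decline`
#'   additional percentage points per year for moderate/marked PPFE;
#'   `decline_antifibrotic` additive effect of antifibrotic use (negative
#'   slows decline); random-effect standard deviations `re_int_sd` (L),
#'   `re_slope_sd` (L/year), correlation `re_corr`; residual sd (L);
#'   `visit_times` in years.
#' @param survival_model hazard parameters: exponential `baseline_rate`
#'   (events/year at reference covariates), named `log_hr` per covariate
#'   (age and DLco enter centred at 66 years and 50% predicted),
#'   `centre_log_hazard` fixed offsets, uniform censoring range `censor`.
#' @param seed integer seed; all output is deterministic given the seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 142L,
                        covariates = list(age_mean = 66, age_sd = 10,
                                          age_range = c(40, 90),
                                          p_male = 0.80, p_smoker = 0.70,
                                          p_antifibrotic = 0.82,
                                          dlco_mean = 50, dlco_sd = 17,
                                          dlco_range = c(15, 110),
                                          fvc_ppred_mean = 74,
                                          fvc_ppred_sd = 20,
                                          fvc_ppred_range = c(35, 130),
                                          pred_fvc_mean = 3.8,
                                          pred_fvc_sd = 0.5),
                        centres = c(A = 1),
                        ppfe_probs = c(absent = 0.51, moderate = 0.39,
                                       marked = 0.10),
                        cppfe_model = list(moderate_shape = 1.8,
                                           moderate_scale = 1.1,
                                           marked_shift = 3,
                                           marked_shape = 2,
                                           marked_scale = 2.2),
                        fvc_model = list(decline_pct_year = 4,
                                         extra_decline = c(moderate = 5.18,
                                                           marked = 18.3),
                                         decline_antifibrotic = -2,
                                         re_int_sd = 0.12,
                                         re_slope_sd = 0.06,
                                         re_corr = 0,
                                         resid_sd = 0.07,
                                         visit_times = c(0, 0.25, 0.5, 0.75,
                                                         1, 1.5)),
                        survival_model = list(baseline_rate = 0.14,
                                              log_hr = c(age = 0.015,
                                                         male = 0.1,
                                                         smoker = 0.05,
                                                         antifibrotic = -0.45,
                                                         dlco = -0.04,
                                                         moderate = 0.89,
                                                         marked = 2.04,
                                                         cppfe_pos = 0),
                                              centre_log_hazard = c(A = 0),
                                              censor = c(0.3, 8)),
                        seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects), covariates = covariates,
               centres = centres, ppfe_probs = ppfe_probs,
               cppfe_model = cppfe_model, fvc_model = fvc_model,
               survival_model = survival_model, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @param ... overrides passed on to [cohort_spec()].
#' @export
validation_cohort_spec <- function(...) {
  base <- cohort_spec(
    n_subjects = 145L,
    centres = c(B = 69 / 145, C = 76 / 145),
    ppfe_probs = c(absent = 0.28, moderate = 0.60, marked = 0.12),
    survival_model = list(baseline_rate = 0.14,
                          log_hr = c(age = 0.015, male = 0.1, smoker = 0.05,
                                     antifibrotic = -0.45, dlco = -0.04,
                                     moderate = 0.62, marked = 1.10,
                                     cppfe_pos = 0),
                          centre_log_hazard = c(B = 0.15, C = -0.15),
                          censor = c(0.3, 8)))
  base$covariates$p_antifibrotic <- 0.52
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  validate_cohort_spec(base)
  base
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 0) stop("n_subjects must be >= 0")
  if (abs(sum(spec$ppfe_probs) - 1) > 1e-8)
    stop("ppfe_probs must sum to 1")
  if (abs(sum(spec$centres) - 1) > 1e-8)
    stop("centre probabilities must sum to 1")
  fm <- spec$fvc_model
  if (fm$re_int_sd < 0 || fm$re_slope_sd < 0 || fm$resid_sd < 0)
    stop("variance components must be >= 0")
  if (abs(fm$re_corr) > 1)
    stop("random-effects correlation must lie in [-1, 1]")
  if (spec$survival_model$baseline_rate <= 0)
    stop("baseline hazard rate must be > 0")
  invisible(spec)
}

clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

# Upper-lobe grades consistent with a category; other lobes graded no
# higher than the worse upper lobe.
draw_lobar_grades <- function(category, n) {
  rul <- integer(n); lul <- integer(n)
  mod <- category == "moderate"
  pick <- sample(1:3, n, replace = TRUE)
  rul[mod] <- c(1, 0, 1)[pick[mod]]
  lul[mod] <- c(0, 1, 1)[pick[mod]]
  mk <- category == "marked"
  pickm <- sample(1:4, n, replace = TRUE)
  rul[mk] <- c(2, 2, 3, 3)[pickm[mk]]
  lul[mk] <- c(1, 2, 2, 3)[pickm[mk]]
  cap <- pmax(rul, lul)
  lower <- vapply(c("rml", "rll", "lin", "lll"), function(lb)
    as.integer(pmin(cap, stats::rbinom(n, 1, 0.25) *
                           sample(0:2, n, replace = TRUE))),
    integer(n))
  data.frame(rul_ppfe = rul, lul_ppfe = lul,
             rml_ppfe = lower[, "rml"], rll_ppfe = lower[, "rll"],
             lin_ppfe = lower[, "lin"], lll_ppfe = lower[, "lll"])
}

#' Generate a synthetic cohort
#'
#' Draws subjects, longitudinal FVC measurements and survival outcomes from
#' the generative model in a [cohort_spec()]. Deterministic given the spec's
#' seed. With `n_subjects = 0` the tables are returned empty but
#' well-formed.
#'
#' @param spec a [cohort_spec()].
#' @return A `ppfe_cohort` list: `subjects` (one row per subject with
#'   covariates, lobar grades, PPFE scores and baseline FVC), `fvc_long`
#'   (id, time in years, absolute FVC in litres), `survival` (id, time,
#'   event, covariates), and `truth` (all generative parameters plus each
#'   subject's noise-free 1-year decline percentage and hazard rate).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_subjects
  cv <- spec$covariates
  fm <- spec$fvc_model
  sm <- spec$survival_model

  if (n == 0) {
    subjects <- empty_subjects_table()
    return(structure(list(subjects = subjects,
                          fvc_long = data.frame(id = character(),
                                                time = numeric(),
                                                fvc = numeric()),
                          survival = data.frame(id = character(),
                                                time = numeric(),
                                                event = integer()),
                          truth = list(spec = spec)),
                     class = "ppfe_cohort"))
  }

  id <- sprintf("S%04d", seq_len(n))
  centre <- sample(names(spec$centres), n, replace = TRUE,
                   prob = spec$centres)
  age <- round(clamp(stats::rnorm(n, cv$age_mean, cv$age_sd), cv$age_range))
  male <- stats::rbinom(n, 1, cv$p_male)
  smoker <- stats::rbinom(n, 1, cv$p_smoker)
  antifibrotic <- stats::rbinom(n, 1, cv$p_antifibrotic)
  dlco <- clamp(stats::rnorm(n, cv$dlco_mean, cv$dlco_sd), cv$dlco_range)
  fvc_ppred <- clamp(stats::rnorm(n, cv$fvc_ppred_mean, cv$fvc_ppred_sd),
                     cv$fvc_ppred_range)
  pred_fvc <- pmax(stats::rnorm(n, cv$pred_fvc_mean, cv$pred_fvc_sd), 2)
  fvc_abs <- fvc_ppred / 100 * pred_fvc

  category <- factor(sample(names(spec$ppfe_probs), n, replace = TRUE,
                            prob = spec$ppfe_probs),
                     levels = c("absent", "moderate", "marked"))
  grades <- draw_lobar_grades(category, n)
  ild <- round(clamp(stats::rnorm(6 * n, 40, 13), c(0, 100)) / 5) * 5
  emph <- round(clamp(stats::rnorm(6 * n, 8, 10), c(0, 100)) / 5) * 5
  lobar_pct <- data.frame(matrix(ild, n, 6), matrix(emph, n, 6))
  names(lobar_pct) <- c(paste0(LOBES, "_ild"), paste0(LOBES, "_emph"))

  cm <- spec$cppfe_model
  cppfe <- numeric(n)
  nmod <- sum(category == "moderate"); nmk <- sum(category == "marked")
  cppfe[category == "moderate"] <-
    stats::rgamma(nmod, shape = cm$moderate_shape, scale = cm$moderate_scale)
  cppfe[category == "marked"] <- cm$marked_shift +
    stats::rgamma(nmk, shape = cm$marked_shape, scale = cm$marked_scale)
  cppfe <- round(cppfe, 2)

  # trajectory: subject slope in L/year realising the target percentage
  # decline of baseline FVC
  decline_pct <- fm$decline_pct_year +
    ifelse(category == "moderate", fm$extra_decline[["moderate"]],
           ifelse(category == "marked", fm$extra_decline[["marked"]], 0)) +
    antifibrotic * fm$decline_antifibrotic
  slope_abs <- -decline_pct / 100 * fvc_abs
  re_cov <- matrix(c(fm$re_int_sd^2,
                     fm$re_corr * fm$re_int_sd * fm$re_slope_sd,
                     fm$re_corr * fm$re_int_sd * fm$re_slope_sd,
                     fm$re_slope_sd^2), 2, 2)
  re <- if (all(re_cov == 0)) matrix(0, n, 2) else {
    ch <- chol(re_cov + diag(1e-12, 2))
    matrix(stats::rnorm(2 * n), n, 2) %*% ch
  }
  b_int <- re[, 1]; b_slope <- re[, 2]

  visits <- fm$visit_times
  fvc_long <- data.frame(
    id = rep(id, each = length(visits)),
    time = rep(visits, times = n))
  mu <- fvc_abs[match(fvc_long$id, id)] + b_int[match(fvc_long$id, id)] +
    (slope_abs + b_slope)[match(fvc_long$id, id)] * fvc_long$time
  fvc_long$fvc <- pmax(mu + stats::rnorm(nrow(fvc_long), 0, fm$resid_sd),
                       0.25)

  fvc0_true <- fvc_abs + b_int
  true_decline <- -100 * (slope_abs + b_slope) / fvc0_true

  # survival: exponential baseline, PH covariate effects, uniform censoring
  lp <- sm$log_hr[["age"]] * (age - 66) +
    sm$log_hr[["male"]] * male +
    sm$log_hr[["smoker"]] * smoker +
    sm$log_hr[["antifibrotic"]] * antifibrotic +
    sm$log_hr[["dlco"]] * (dlco - 50) +
    ifelse(category == "moderate", sm$log_hr[["moderate"]], 0) +
    ifelse(category == "marked", sm$log_hr[["marked"]], 0) +
    sm$log_hr[["cppfe_pos"]] * (cppfe >= 2.5) +
    sm$centre_log_hazard[centre]
  lambda <- sm$baseline_rate * exp(lp)
  t_event <- stats::rexp(n, lambda)
  t_cens <- stats::runif(n, sm$censor[1], sm$censor[2])
  time <- pmax(pmin(t_event, t_cens), 1e-3)
  event <- as.integer(t_event <= t_cens)

  subjects <- data.frame(id = id, centre = centre, age = age, male = male,
                         smoker = smoker, antifibrotic = antifibrotic,
                         dlco_ppred = dlco,
                         baseline_fvc_ppred = fvc_ppred,
                         baseline_fvc_abs = fvc_abs,
                         vppfe_category = category,
                         vppfe_presence = category != "absent",
                         cppfe_percent = ifelse(category == "absent", 0,
                                                cppfe),
                         stringsAsFactors = FALSE)
  subjects <- cbind(subjects, grades, lobar_pct)
  vs <- derive_vppfe(subjects)
  subjects$vppfe_7pt <- vs$seven_point
  subjects$cppfe_pos <- subjects$cppfe_percent >= 2.5

  survival <- data.frame(id = id, time = time, event = event,
                         centre = centre, age = age, male = male,
                         smoker = smoker, antifibrotic = antifibrotic,
                         dlco_ppred = dlco,
                         vppfe_category = category,
                         vppfe_7pt = subjects$vppfe_7pt,
                         cppfe_percent = subjects$cppfe_percent,
                         cppfe_pos = subjects$cppfe_pos,
                         stringsAsFactors = FALSE)

  truth <- list(spec = spec,
                true_fvc_baseline = stats::setNames(fvc0_true, id),
                true_fvc_1y = stats::setNames(fvc0_true + slope_abs + b_slope,
                                              id),
                true_decline_percent = stats::setNames(true_decline, id),
                lambda = stats::setNames(lambda, id),
                expected_event_fraction = expected_event_fraction(
                  lambda, sm$censor))
  structure(list(subjects = subjects, fvc_long = fvc_long,
                 survival = survival, truth = truth),
            class = "ppfe_cohort")
}

empty_subjects_table <- function() {
  out <- data.frame(id = character(), centre = character(), age = numeric(),
                    male = integer(), smoker = integer(),
                    antifibrotic = integer(), dlco_ppred = numeric(),
                    baseline_fvc_ppred = numeric(),
                    baseline_fvc_abs = numeric(),
                    vppfe_category = factor(character(),
                                            levels = c("absent", "moderate",
                                                       "marked")),
                    vppfe_presence = logical(), cppfe_percent = numeric(),
                    stringsAsFactors = FALSE)
  for (cl in lobar_columns()) out[[cl]] <- numeric()
  out$vppfe_7pt <- integer(); out$cppfe_pos <- logical()
  out
}

#' Event fraction implied by hazard and censoring parameters
#'
#' For exponential event times with subject rates `lambda` and independent
#' uniform censoring on `censor = c(a, b)`,
#' `P(event) = 1 - (exp(-lambda a) - exp(-lambda b)) / (lambda (b - a))`,
#' averaged over subjects.
#'
#' @param lambda per-subject hazard rates.
#' @param censor length-2 uniform censoring range (years).
#' @return Expected fraction of subjects whose event is observed.
#' @export
expected_event_fraction <- function(lambda, censor) {
  a <- censor[1]; b <- censor[2]
  mean(1 - (exp(-lambda * a) - exp(-lambda * b)) / (lambda * (b - a)))
}

#' Write cohort tables as CSV
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$fvc_long, file.path(dir, "fvc_long.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  invisible(dir)
}
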