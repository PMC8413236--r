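test_that("longitudinal eligibility applies the two-window rule", {
  fl <- data.frame(
    id = c("a", "b", "b", "c", "c", "d", "d", "d"),
    time = c(0, 0, 1.0, 0, 2 / 12, 0.1, 0.8, 1.4),
    fvc = 3)
  out <- apply_fvc_eligibility(fl)
  expect_setequal(out$eligible_ids, c("b", "d"))
  expect_equal(out$exclusions$reason[out$exclusions$id == "a"],
               "no_followup_measurement")
  expect_equal(out$exclusions$reason[out$exclusions$id == "c"],
               "no_followup_measurement")
  # 12 months lies inside 3-18 months; 2 months does not
})

test_that("eligibility filters are idempotent and order-independent", {
  set.seed(31)
  fl <- data.frame(id = rep(sprintf("s%02d", 1:30), each = 3),
                   time = runif(90, 0, 2), fvc = runif(90, 2, 4))
  once <- apply_fvc_eligibility(fl)
  again <- apply_fvc_eligibility(fl[fl$id %in% once$eligible_ids, ])
  expect_setequal(once$eligible_ids, again$eligible_ids)
  shuffled <- fl[sample(nrow(fl)), ]
  expect_setequal(apply_fvc_eligibility(shuffled)$eligible_ids,
                  once$eligible_ids)
})

test_that("cohort eligibility flags the trial subset inclusively", {
  subj <- data.frame(id = c("a", "b", "c", "d", "e"),
                     baseline_fvc_ppred = c(49, 50, 80, 70, NA),
                     dlco_ppred = c(50, 79, 29, NA, 50),
                     antifibrotic = c(1, 0, 1, 1, 0))
  out <- apply_cohort_eligibility(subj)
  expect_false("e" %in% out$subjects$id)    # missing lung function
  expect_equal(out$exclusions$reason[out$exclusions$id == "e"],
               "missing_baseline_lung_function")
  got <- out$subjects
  expect_false(got$trial_subset[got$id == "a"])  # FVC 49 < 50
  expect_true(got$trial_subset[got$id == "b"])   # DLco 79 inclusive
  expect_false(got$trial_subset[got$id == "c"])  # DLco 29 < 30
  expect_false(got$trial_subset[got$id == "d"])  # missing DLco
  expect_false(got$has_dlco[got$id == "d"])
})

test_that("the mixed model reproduces an exact linear trajectory", {
  d <- linear_fvc_data()
  fit <- fit_fvc_lme(d$fvc_long, d$subjects)
  expect_equal(unname(lme4::fixef(fit$fit)["time"]), -0.3, tolerance = 1e-6)
  dec <- predict_decline(fit)
  # FVC(t) = 3.0 - 0.3 t: decline = (3.0 - 2.7) / 3.0 = 10%
  expect_equal(dec$decline_percent, rep(10, nrow(dec)), tolerance = 1e-6)
})

test_that("a flat noise-free trajectory declines by zero", {
  d <- linear_fvc_data(slope = 0)
  fit <- fit_fvc_lme(d$fvc_long, d$subjects)
  dec <- predict_decline(fit)
  expect_equal(dec$decline_percent, rep(0, nrow(dec)), tolerance = 1e-6)
})

test_that("rank-deficient covariates are an error, never a silent drop", {
  d <- linear_fvc_data()
  d$subjects$dlco_ppred <- NULL
  d$subjects$baseline_fvc_ppred <- d$subjects$age * 2  # collinear
  expect_error(fit_fvc_lme(d$fvc_long, d$subjects), "rank deficient")
})

test_that("subjects absent from the fit cannot be predicted", {
  d <- linear_fvc_data()
  fit <- fit_fvc_lme(d$fvc_long, d$subjects)
  expect_error(predict_decline(fit, ids = "Z99"), "not in fitted model")
})

test_that("decline is invariant to rescaling the FVC series", {
  co <- generate_cohort(cohort_spec(n_subjects = 80, seed = 32))
  fit1 <- fit_fvc_lme(co$fvc_long, co$subjects)
  dec1 <- predict_decline(fit1)
  scaled <- co$fvc_long
  scaled$fvc <- scaled$fvc * 1.7
  fit2 <- fit_fvc_lme(scaled, co$subjects)
  dec2 <- predict_decline(fit2)
  expect_equal(dec2$decline_percent, dec1$decline_percent, tolerance = 1e-6)
})

test_that("subject-level 1-year predictions recover the generative truth", {
  sp <- cohort_spec(n_subjects = 300, seed = 33)
  sp$fvc_model$resid_sd <- 0.05
  co <- generate_cohort(sp)
  fit <- fit_fvc_lme(co$fvc_long, co$subjects)
  dec <- predict_decline(fit)
  err_pp <- 100 * abs(dec$fvc_1y_pred - co$truth$true_fvc_1y[dec$id]) /
    co$truth$true_fvc_baseline[dec$id]
  expect_lt(mean(err_pp), 1)
})

test_that("fixed-effect confidence intervals attain nominal coverage", {
  # data generated directly from the fitted model family
  beta_t <- -0.25
  hits <- 0L
  reps <- 60L
  for (r in seq_len(reps)) {
    set.seed(500 + r)
    n <- 100
    ids <- sprintf("c%03d", 1:n)
    subjects <- data.frame(id = ids, age = rnorm(n, 66, 8),
                           male = rbinom(n, 1, 0.8),
                           smoker = rbinom(n, 1, 0.7),
                           antifibrotic = rbinom(n, 1, 0.6),
                           baseline_fvc_ppred = rnorm(n, 75, 15))
    times <- c(0, 0.25, 0.5, 0.75, 1, 1.5)
    fl <- data.frame(id = rep(ids, each = length(times)),
                     time = rep(times, n))
    b_int <- rnorm(n, 0, 0.15); b_slope <- rnorm(n, 0, 0.08)
    j <- match(fl$id, ids)
    fl$fvc <- 2.0 + 0.01 * subjects$baseline_fvc_ppred[j] +
      0.1 * subjects$male[j] + (beta_t + b_slope[j]) * fl$time +
      b_int[j] + rnorm(nrow(fl), 0, 0.07)
    fit <- fit_fvc_lme(fl, subjects)
    est <- lme4::fixef(fit$fit)["time"]
    se <- sqrt(diag(as.matrix(vcov(fit$fit))))[["time"]]
    if (abs(est - beta_t) <= qnorm(0.975) * se) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.86)
})

test_that("decline regression modes and diagnostics behave", {
  co <- generate_cohort(cohort_spec(n_subjects = 250, seed = 34))
  fit <- fit_fvc_lme(co$fvc_long, co$subjects)
  dec <- predict_decline(fit)
  rg <- regress_decline(dec, "vppfe_category", subjects = co$subjects)
  expect_true(all(c("term", "estimate", "ci_lo", "ci_hi", "p") %in%
                    names(rg$table)))
  expect_true(is.finite(rg$r_squared))
  expect_true(is.finite(rg$breusch_pagan$p))
  expect_error(
    regress_decline(dec, "vppfe_category", subjects = co$subjects,
                    mode = "validation"),
    "two centres")

  cov <- generate_cohort(validation_cohort_spec(seed = 35))
  fitv <- fit_fvc_lme(cov$fvc_long, cov$subjects, use_centre = TRUE)
  decv <- predict_decline(fitv)
  rgv <- regress_decline(decv, "vppfe_category", subjects = cov$subjects,
                         mode = "validation")
  expect_true(all(is.finite(rgv$table$estimate)))
})
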