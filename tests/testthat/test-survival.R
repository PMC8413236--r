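test_that("confusion identities hold exactly over random integer tables", {
  set.seed(61)
  for (i in 1:25) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    fn <- sample(0:50, 1); tn <- sample(0:50, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    rec <- records_from_counts(tp, fp, fn, tn, censored = sample(0:10, 1))
    m <- confusion_at_horizon(rec, rec$flag, horizon = 2)
    expect_identical(unname(m$counts[c("TP", "FP", "FN", "TN")]),
                     c(tp, fp, fn, tn))
    if (tp + fp > 0) expect_equal(m$ppv, 100 * tp / (tp + fp))
    if (tn + fn > 0) expect_equal(m$npv, 100 * tn / (tn + fn))
    expect_equal(m$sensitivity, 100 * tp / (tp + fn))
    expect_equal(m$specificity, 100 * tn / (tn + fp))
  }
})

test_that("censored-before-horizon subjects enter no confusion cell", {
  rec <- records_from_counts(3, 2, 1, 4, censored = 5)
  m <- confusion_at_horizon(rec, rec$flag, horizon = 2)
  expect_equal(sum(m$counts[c("TP", "FP", "FN", "TN")]), 10)
  expect_equal(unname(m$counts["excluded"]), 5)
  # follow-up ending exactly at the horizon alive counts as a non-event
  rec2 <- data.frame(flag = c(TRUE, FALSE), time = c(2, 2),
                     event = c(0L, 1L))
  m2 <- confusion_at_horizon(rec2, rec2$flag, horizon = 2)
  expect_equal(unname(m2$counts["FP"]), 1)
  expect_equal(unname(m2$counts["TN"]), 1)
})

test_that("a perfect classifier scores 100 on all four metrics", {
  rec <- records_from_counts(20, 0, 0, 30)
  m <- confusion_at_horizon(rec, rec$flag)
  expect_equal(c(m$sensitivity, m$specificity, m$ppv, m$npv),
               rep(100, 4))
  deg <- confusion_at_horizon(records_from_counts(0, 3, 0, 7),
                              c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_false(deg$defined)
})

test_that("Cox recovery, null coverage and separation flagging", {
  sm <- cohort_spec()$survival_model
  sm$log_hr[] <- 0
  sm$log_hr[["cppfe_pos"]] <- log(2)
  co <- generate_cohort(cohort_spec(n_subjects = 3000, seed = 62,
                                    survival_model = sm))
  fit <- fit_cox(co$survival, c("age", "male", "cppfe_pos"))
  row <- fit$table[grepl("cppfe_pos", fit$table$term), ]
  se <- (log(row$ci_hi) - log(row$ci_lo)) / (2 * qnorm(0.975))
  expect_lt(abs(log(row$hr) - log(2)), 3 * se)
  expect_true(is.finite(fit$c_index))
  expect_true(!is.null(fit$schoenfeld))

  # null covariate: CI covers 1 in roughly 95% of replicates
  hits <- 0L; reps <- 60L
  for (r in seq_len(reps)) {
    smn <- sm; smn$log_hr[] <- 0
    con <- generate_cohort(cohort_spec(n_subjects = 250, seed = 700 + r,
                                       survival_model = smn))
    f <- fit_cox(con$survival, "male")
    if (f$table$ci_lo <= 1 && f$table$ci_hi >= 1) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.86)

  expect_error(fit_cox(data.frame(time = c(1, 2), event = c(0L, 0L),
                                  x = c(0, 1)), "x"), "no events")
})

test_that("frailty with a single centre matches the plain fit exactly", {
  co <- generate_cohort(cohort_spec(n_subjects = 400, seed = 63))
  plain <- fit_cox(co$survival, c("age", "dlco_ppred"))
  frail <- fit_cox(co$survival, c("age", "dlco_ppred"),
                   frailty_group = "centre")
  expect_equal(frail$table$hr, plain$table$hr, tolerance = 1e-4)
  expect_match(frail$frailty_note, "single level")
})

test_that("the concordance index is 0.5 for constant risk scores", {
  co <- generate_cohort(cohort_spec(n_subjects = 150, seed = 64))
  rec <- co$survival
  rec$score <- 1
  out <- cindex_bootstrap(rec, risk_score = "score", iterations = 20,
                          seed = 5)
  expect_equal(out$c_index, 0.5)
  expect_equal(out$boot_mean, 0.5)
})

test_that("a perfectly rank-ordered hazard without censoring gives C = 1", {
  rec <- data.frame(time = sort(rexp(80, 0.4)), event = 1L)
  rec$score <- -rec$time   # higher risk = earlier death
  out <- cindex_bootstrap(rec, risk_score = "score", iterations = 20,
                          seed = 6)
  expect_equal(out$c_index, 1)
})

test_that("the C-index bootstrap is reproducible and internally consistent", {
  co <- generate_cohort(cohort_spec(n_subjects = 250, seed = 65))
  a <- cindex_bootstrap(co$survival,
                        covariates = c("age", "dlco_ppred", "cppfe_pos"),
                        iterations = 60, seed = 11)
  b <- cindex_bootstrap(co$survival,
                        covariates = c("age", "dlco_ppred", "cppfe_pos"),
                        iterations = 60, seed = 11)
  expect_identical(a, b)
  expect_gte(a$c_index, a$ci_lo)
  expect_lte(a$c_index, a$ci_hi)
})

test_that("Kaplan-Meier matches the closed-form exponential median", {
  set.seed(66)
  rec <- data.frame(time = rexp(5000, log(2) / 2), event = 1L)
  km <- km_analysis(rec)
  expect_equal(km$groups$median, 2, tolerance = 0.1)
  expect_lte(km$groups$ci_lo, km$groups$median)
  expect_gte(km$groups$ci_hi, km$groups$median)
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(67)
  rec <- data.frame(time = rexp(300, 0.5), event = 1L)
  km <- km_analysis(rec)
  emp <- vapply(km$curves$time, function(t) mean(rec$time > t), numeric(1))
  expect_equal(km$curves$surv, emp, tolerance = 1e-12)
})

test_that("an all-censored group reports the median as not reached", {
  rec <- data.frame(time = runif(40, 1, 5), event = 0L)
  km <- km_analysis(rec)
  expect_true(is.na(km$groups$median))
  expect_true(is.na(km$groups$ci_hi))
})

test_that("the log-rank test separates distinct groups", {
  set.seed(68)
  rec <- data.frame(
    time = c(rexp(150, 0.2), rexp(150, 0.8)),
    event = 1L,
    g = rep(c("slow", "fast"), each = 150))
  km <- km_analysis(rec, "g")
  expect_lt(km$logrank_p, 1e-6)
  expect_equal(km$logrank_df, 1)
})

test_that("AUC behaves at its deterministic extremes and under ties", {
  y <- c(rep(0, 30), rep(1, 30))
  s <- c(runif(30, 0, 0.4), runif(30, 0.6, 1))
  expect_equal(roc_auc(s, y)$auc, 1)
  expect_error(roc_auc(s, rep(1, 60)), "both outcome classes")
  # mid-rank tie handling: half-credit for tied scores
  expect_equal(roc_auc(rep(1, 60), y)$auc, 0.5)
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(69)
  y <- rbinom(200, 1, 0.4)
  s <- rnorm(200) + y
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a)
  expect_equal(roc_auc(qlogis(plogis(s)) * 3 + 7, y)$auc, a)
  cmp <- compare_auc_delong(s, exp(s), y)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p, 1)
})

test_that("identical scores compare with zero difference and p = 1", {
  set.seed(70)
  y <- rbinom(100, 1, 0.5); s <- rnorm(100)
  cmp <- compare_auc_delong(s, s, y)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p, 1)
  expect_error(compare_auc_delong(s, s[-1], y), "paired")
})

test_that("a continuous score outranks its coarsened version", {
  # outcome driven by the continuous score; the 7-level version discards
  # within-level ordering, so the continuous AUC must win at large n
  wins <- 0L
  for (r in 1:10) {
    set.seed(800 + r)
    n <- 2000
    s <- rnorm(n)
    y <- rbinom(n, 1, plogis(1.5 * s))
    s7 <- as.integer(cut(s, breaks = quantile(s, seq(0, 1, length = 8)),
                         include.lowest = TRUE)) - 1L
    if (roc_auc(s, y)$auc > roc_auc(s7, y)$auc) wins <- wins + 1L
  }
  expect_gte(wins, 9)
})
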