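lobar_row <- function(grades = rep(0, 6), ild = rep(0, 6), emph = rep(0, 6),
                      id = "P1") {
  lobes <- c("rul", "rml", "rll", "lul", "lin", "lll")
  out <- data.frame(id = id)
  for (i in seq_along(lobes)) {
    out[[paste0(lobes[i], "_ppfe")]] <- grades[i]
    out[[paste0(lobes[i], "_ild")]] <- ild[i]
    out[[paste0(lobes[i], "_emph")]] <- emph[i]
  }
  out
}

test_that("visual score derivation matches the scale definitions", {
  all0 <- derive_vppfe(lobar_row())
  expect_false(all0$presence)
  expect_equal(as.character(all0$category), "absent")
  expect_equal(all0$seven_point, 0L)
  expect_equal(all0$total_extent, 0L)

  # RUL = 1, LUL = 1 -> sum 2, moderate
  mod <- derive_vppfe(lobar_row(grades = c(1, 0, 0, 1, 0, 0)))
  expect_equal(mod$seven_point, 2L)
  expect_equal(as.character(mod$category), "moderate")

  # RUL = 2, LUL = 2 -> sum 4, marked
  mk <- derive_vppfe(lobar_row(grades = c(2, 0, 0, 2, 0, 0)))
  expect_equal(mk$seven_point, 4L)
  expect_equal(as.character(mk$category), "marked")

  full <- derive_vppfe(lobar_row(grades = rep(3, 6)))
  expect_equal(full$total_extent, 18L)
  expect_equal(full$seven_point, 6L)
})

test_that("category partitions the 7-point scale exhaustively", {
  for (rul in 0:3) for (lul in 0:3) {
    v <- derive_vppfe(lobar_row(grades = c(rul, 0, 0, lul, 0, 0)))
    s <- rul + lul
    expected <- if (s == 0) "absent" else if (s <= 2) "moderate" else "marked"
    expect_equal(as.character(v$category), expected)
    expect_lte(v$seven_point, v$total_extent)
    expect_equal(v$presence, v$total_extent > 0)
  }
})

test_that("per-lobe-maximum category variant grades by the worse lobe", {
  v <- derive_vppfe(lobar_row(grades = c(3, 0, 0, 0, 0, 0)),
                    category_mode = "max")
  expect_equal(as.character(v$category), "marked")
  v2 <- derive_vppfe(lobar_row(grades = c(1, 0, 0, 1, 0, 0)),
                     category_mode = "max")
  expect_equal(as.character(v2$category), "moderate")
})

test_that("invalid grades and off-grid percentages are rejected", {
  expect_error(derive_vppfe(lobar_row(grades = c(4, 0, 0, 0, 0, 0))),
               "0..3")
  expect_error(validate_lobar_scores(lobar_row(ild = c(12, 0, 0, 0, 0, 0))),
               "multiples of 5")
})

test_that("morphologic severity is the sum of the two lobar means", {
  expect_equal(morphologic_severity(lobar_row(ild = rep(45, 6),
                                              emph = rep(10, 6))), 55)
  # hand-recomputed mean of an uneven ILD profile
  ild <- c(50, 40, 60, 50, 30, 40)
  expect_equal(morphologic_severity(lobar_row(ild = ild)), mean(ild))
  expect_equal(morphologic_severity(lobar_row()), 0)

  # bounds and the zero-iff-all-zero property over random score tables
  set.seed(42)
  for (i in 1:20) {
    ild <- sample(seq(0, 100, 5), 6, replace = TRUE)
    emph <- sample(seq(0, 100, 5), 6, replace = TRUE)
    s <- morphologic_severity(lobar_row(ild = ild, emph = emph))
    expect_gte(s, 0); expect_lte(s, 200)
    expect_equal(s == 0, all(c(ild, emph) == 0))
  }
})

test_that("implausible lower-lobe-only PPFE is flagged, not rejected", {
  expect_warning(
    flags <- validate_anatomic_consistency(
      lobar_row(grades = c(0, 1, 0, 0, 0, 0))),
    "middle/lower")
  expect_equal(nrow(flags), 1)

  ok <- validate_anatomic_consistency(lobar_row(grades = c(1, 0, 1, 0, 0, 0)))
  expect_equal(nrow(ok), 0)
  none <- validate_anatomic_consistency(lobar_row())
  expect_equal(nrow(none), 0)
})
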