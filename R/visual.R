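# Radiologist lobar scoring: PPFE grade 0-3 per lobe plus ILD and emphysema
# percentages (nearest 5%), with the lingula treated as a sixth lobe.

LOBES <- c("rul", "rml", "rll", "lul", "lin", "lll")
UPPER_LOBES <- c("rul", "lul")

lobar_columns <- function() {
  c(paste0(LOBES, "_ppfe"), paste0(LOBES, "_ild"), paste0(LOBES, "_emph"))
}

#' Validate a table of lobar visual scores
#'
#' One row per patient; columns `<lobe>_ppfe` (grade 0-3), `<lobe>_ild` and
#' `<lobe>_emph` (percent involvement, multiples of 5 in 0-100) for lobes
#' rul, rml, rll, lul, lin (lingula), lll. Percentages that are not
#' multiples of 5 are rejected, not rounded: the read is defined on a 5%
#' scale and silently rounding would mask upstream errors.
#'
#' @param scores data.frame of lobar scores.
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_lobar_scores <- function(scores) {
  miss <- setdiff(lobar_columns(), names(scores))
  if (length(miss))
    stop("missing lobar score columns: ", paste(miss, collapse = ", "))
  for (lb in LOBES) {
    g <- scores[[paste0(lb, "_ppfe")]]
    if (any(is.na(g)) || any(g != as.integer(g)) || any(g < 0 | g > 3))
      stop(sprintf("%s_ppfe grades must be integers in 0..3", lb))
    for (sfx in c("_ild", "_emph")) {
      p <- scores[[paste0(lb, sfx)]]
      if (any(is.na(p)) || any(p < 0 | p > 100) || any(p %% 5 != 0))
        stop(sprintf("%s%s must be multiples of 5 in 0..100", lb, sfx))
    }
  }
  invisible(scores)
}

#' Derive visual PPFE scores from lobar grades
#'
#' Produces, per patient: `presence` (any lobe affected), `seven_point` (sum
#' of the two upper-lobe grades, 0-6), `total_extent` (sum over six lobes,
#' 0-18), and the three-level `category` (absent / moderate / marked). The
#' default category splits the upper-lobe sum: 0 absent, 1-2 moderate,
#' above 2 marked. `category_mode = "max"` grades instead by the worse upper
#' lobe (1-2 moderate, 3 marked), an alternative reading of the same scale.
#'
#' @param scores validated lobar score table.
#' @param category_mode `"sum"` (default) or `"max"`.
#' @return data.frame with columns `presence`, `category`, `seven_point`,
#'   `total_extent` (plus `id` if present in the input).
#' @export
derive_vppfe <- function(scores, category_mode = c("sum", "max")) {
  category_mode <- match.arg(category_mode)
  validate_lobar_scores(scores)
  grades <- as.matrix(scores[paste0(LOBES, "_ppfe")])
  seven <- as.integer(rowSums(grades[, paste0(UPPER_LOBES, "_ppfe"),
                                     drop = FALSE]))
  total <- as.integer(rowSums(grades))
  key <- if (category_mode == "sum") seven
         else apply(grades[, paste0(UPPER_LOBES, "_ppfe"), drop = FALSE],
                    1, max)
  category <- factor(ifelse(key == 0, "absent",
                     ifelse(key <= 2, "moderate", "marked")),
                     levels = c("absent", "moderate", "marked"))
  out <- data.frame(presence = total > 0, category = category,
                    seven_point = seven, total_extent = total)
  if (!is.null(scores$id)) out <- cbind(id = scores$id, out)
  out
}

#' Morphological baseline disease severity
#'
#' The mean ILD percentage across the six lobes plus the mean emphysema
#' percentage across the six lobes, a 0-200 scale summarising structural
#' disease burden.
#'
#' @param scores validated lobar score table.
#' @return numeric vector, one value per patient.
#' @export
morphologic_severity <- function(scores) {
  validate_lobar_scores(scores)
  rowMeans(as.matrix(scores[paste0(LOBES, "_ild")])) +
    rowMeans(as.matrix(scores[paste0(LOBES, "_emph")]))
}

#' Flag anatomically implausible lobar PPFE patterns
#'
#' PPFE confined to middle or lower lobes with both upper lobes clear is not
#' seen in practice; such rows are flagged (never rejected) so they can be
#' reviewed upstream.
#'
#' @param scores validated lobar score table.
#' @return data.frame of flagged rows (`row`, `id` when present, `message`);
#'   zero rows when nothing is suspicious.
#' @export
validate_anatomic_consistency <- function(scores) {
  validate_lobar_scores(scores)
  grades <- as.matrix(scores[paste0(LOBES, "_ppfe")])
  upper <- rowSums(grades[, paste0(UPPER_LOBES, "_ppfe"), drop = FALSE])
  lower <- rowSums(grades[, paste0(setdiff(LOBES, UPPER_LOBES), "_ppfe"),
                          drop = FALSE])
  bad <- which(upper == 0 & lower > 0)
  out <- data.frame(
    row = bad,
    message = rep("PPFE in middle/lower lobes with clear upper lobes", length(bad)))
  if (!is.null(scores$id)) out$id <- scores$id[bad]
  if (length(bad))
    warning(sprintf("%d record(s) with middle/lower-lobe PPFE but clear upper lobes",
                    length(bad)))
  out
}
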