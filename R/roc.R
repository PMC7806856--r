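# Per-marker ROC diagnostics: empirical ROC curve, Mann-Whitney AUC,
# Youden-optimal midpoint cutoff, confusion-matrix metrics, and the
# rate->count consistency oracle that links printed sensitivity/specificity
# to predictive values through outlier-adjusted group sizes.

.mw_auc <- function(pos, neg) {
  # P(pos > neg) + 0.5 P(pos == neg), via midranks
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

.candidate_cutoffs <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  if (length(v) == 1L) return(c(v - 0.5, v + 0.5))
  c(v[1] - (v[2] - v[1]) / 2,
    (v[-length(v)] + v[-1]) / 2,
    v[length(v)] + (v[length(v)] - v[length(v) - 1]) / 2)
}

# vectorised sens/spec over a sorted candidate grid, O((n+m) log(n+m))
.sens_spec_grid <- function(pos, neg, cand, direction) {
  sp <- sort(pos); sn <- sort(neg)
  n_le_pos <- findInterval(cand, sp)        # pos values <= cand
  n_le_neg <- findInterval(cand, sn)
  n_lt_pos <- findInterval(cand, sp, left.open = TRUE)
  n_lt_neg <- findInterval(cand, sn, left.open = TRUE)
  if (direction == "pos_higher") {
    list(sens = (length(pos) - n_le_pos) / length(pos),
         spec = n_le_neg / length(neg))
  } else {
    list(sens = n_lt_pos / length(pos),
         spec = (length(neg) - n_lt_neg) / length(neg))
  }
}

#' Empirical ROC curve and AUC
#'
#' AUC is computed as the Mann-Whitney probability
#' `P(pos > neg) + 0.5 P(pos = neg)` (under `"pos_higher"`). With
#' `direction = "auto"` the orientation giving AUC >= 0.5 is chosen and
#' recorded, mirroring tables that annotate markers whose lower values
#' indicate the positive class. The curve is evaluated at midpoints between
#' consecutive distinct observed values plus one threshold beyond each
#' extreme, so it reaches both (sens 1, spec 0) and (sens 0, spec 1).
#'
#' @param pos,neg numeric marker values for the positive / negative class.
#' @param direction `"auto"`, `"pos_higher"` or `"pos_lower"`.
#' @return list: `curve` (data.frame `threshold`, `sens`, `spec`), `auc`,
#'   `direction` (resolved), `flipped` (TRUE if auto chose `"pos_lower"`).
#' @examples
#' rocAuc(c(2, 3), c(0, 1))$auc  # 1
#' @export
rocAuc <- function(pos, neg, direction = c("auto", "pos_higher",
                                           "pos_lower")) {
  direction <- match.arg(direction)
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (!length(pos) || !length(neg))
    stop("both classes need at least one value")
  auc <- .mw_auc(pos, neg)
  flipped <- FALSE
  if (direction == "auto") {
    flipped <- auc < 0.5
    direction <- if (flipped) "pos_lower" else "pos_higher"
  }
  if (direction == "pos_lower") auc <- 1 - .mw_auc(pos, neg)
  else auc <- .mw_auc(pos, neg)
  cand <- .candidate_cutoffs(pos, neg)
  ss <- .sens_spec_grid(pos, neg, cand, direction)
  list(curve = data.frame(threshold = cand, sens = ss$sens,
                          spec = ss$spec),
       auc = auc, direction = direction, flipped = flipped)
}

#' Youden-optimal cutoff
#'
#' Scans midpoints between consecutive distinct observed values (plus one
#' candidate beyond each extreme) and returns the threshold maximising
#' Youden's J = sens + spec - 1. Reporting midpoints reproduces the
#' half-step cutoffs typical of published tables (1.385, 9.035, ...). Ties
#' on J break toward higher sensitivity, then the lower threshold.
#'
#' @param pos,neg numeric values per class.
#' @param direction as in [rocAuc()].
#' @return list: `cutoff`, `sens`, `spec` (proportions), `j`, `direction`.
#' @examples
#' optimalCutoff(c(2, 3, 4), c(0, 1))$cutoff  # 1.5
#' @export
optimalCutoff <- function(pos, neg,
                          direction = c("auto", "pos_higher", "pos_lower")) {
  direction <- match.arg(direction)
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (direction == "auto")
    direction <- if (.mw_auc(pos, neg) < 0.5) "pos_lower" else "pos_higher"
  cand <- .candidate_cutoffs(pos, neg)
  ss <- .sens_spec_grid(pos, neg, cand, direction)
  j <- ss$sens + ss$spec - 1
  best <- order(-j, -ss$sens, cand)[1]
  list(cutoff = cand[best], sens = ss$sens[best],
       spec = ss$spec[best], j = j[best], direction = direction)
}

#' Confusion-matrix metrics at a fixed cutoff
#'
#' A subject is called positive iff its value is strictly greater than the
#' cutoff (under `"pos_higher"`; strictly lower under `"pos_lower"`), so a
#' midpoint cutoff assigns every observed value unambiguously. Metrics with
#' an empty denominator are `NA`, never 0.
#'
#' @param pos,neg numeric values per class (`NA`s dropped).
#' @param cutoff finite threshold (pg/mL).
#' @param direction `"pos_higher"` or `"pos_lower"`.
#' @return one-row data.frame: `tp`, `fp`, `tn`, `fn`, and `sens`, `spec`,
#'   `ppv`, `npv` in percent.
#' @export
metricsAtCutoff <- function(pos, neg, cutoff,
                            direction = c("pos_higher", "pos_lower")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(cutoff))
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  call_pos <- function(v) if (direction == "pos_higher") v > cutoff
  else v < cutoff
  tp <- sum(call_pos(pos)); fn <- length(pos) - tp
  fp <- sum(call_pos(neg)); tn <- length(neg) - fp
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             sens = pct(tp, tp + fn), spec = pct(tn, tn + fp),
             ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn))
}

#' Reconstruct confusion counts from printed rates
#'
#' The consistency oracle: given a printed sensitivity/specificity (percent)
#' and the class sizes, reconstructs the integer confusion counts
#' (`tp = round(sens * n_pos / 100)`, etc., rounding half away from zero —
#' the convention of the statistical software the rates came from) and the
#' implied PPV/NPV. Printed predictive values can then be verified exactly
#' against the reconstruction.
#'
#' @param sens,spec percentages in `[0, 100]`.
#' @param n_pos,n_neg class sizes (after outlier exclusion).
#' @return one-row data.frame: `tp`, `fp`, `tn`, `fn`, `ppv`, `npv`
#'   (percent, unrounded).
#' @examples
#' confusionFromRates(92.2, 44.8, 77, 29)  # ppv 81.6, npv 68.4
#' @export
confusionFromRates <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 100, spec >= 0, spec <= 100,
            n_pos >= 1, n_neg >= 1)
  rhu <- function(x) floor(x + 0.5)  # round half up
  tp <- rhu(sens * n_pos / 100)
  tn <- rhu(spec * n_neg / 100)
  fn <- n_pos - tp
  fp <- n_neg - tn
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             ppv = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn))
}

.contrast_classes <- function(contrast) {
  switch(contrast,
         diseased_vs_control = list(pos = c("IC_BPS", "OAB"),
                                    neg = "CONTROL"),
         ic_vs_oab = list(pos = "IC_BPS", neg = "OAB"),
         stop("unknown contrast: ", contrast))
}

#' Per-marker diagnostic table for a contrast
#'
#' For every marker: ROC with auto direction, Youden-optimal midpoint
#' cutoff, and confusion metrics at that cutoff. The positive class is the
#' pooled diseased arms (`diseased_vs_control`) or IC/BPS (`ic_vs_oab`);
#' markers whose lower values indicate the positive class are reported with
#' `direction = "pos_lower"`. Subjects missing a marker are dropped pairwise
#' for that marker only.
#'
#' @param qc a [CytokineQC-class] (or a [CytokineExperiment-class], in which
#'   case no cells are excluded).
#' @param contrast `"diseased_vs_control"` or `"ic_vs_oab"`.
#' @param markers markers to analyse (default: whole panel present).
#' @param dropLodFlagged drop markers flagged below LOD by QC
#'   (default FALSE: they are reported like the rest).
#' @return data.frame sorted by decreasing AUC: `marker`, `contrast`,
#'   `auc`, `cutoff`, `direction`, `tp`, `fp`, `tn`, `fn`, `sens`, `spec`,
#'   `ppv`, `npv`.
#' @export
markerDiagnostics <- function(qc,
                              contrast = c("diseased_vs_control",
                                           "ic_vs_oab"),
                              markers = NULL, dropLodFlagged = FALSE) {
  contrast <- match.arg(contrast)
  x <- if (is(qc, "CytokineQC")) qcCleaned(qc) else qc
  conc <- concentrations(x)
  grp <- as.character(subjectGroups(x))
  cls <- .contrast_classes(contrast)
  if (is.null(markers)) markers <- rownames(conc)
  if (dropLodFlagged && is(qc, "CytokineQC"))
    markers <- setdiff(markers, qcLodFlagged(qc))
  rows <- lapply(markers, function(mk) {
    pos <- conc[mk, grp %in% cls$pos]
    neg <- conc[mk, grp %in% cls$neg]
    pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
    if (!length(pos) || !length(neg)) return(NULL)
    roc <- rocAuc(pos, neg, "auto")
    oc <- optimalCutoff(pos, neg, roc$direction)
    met <- metricsAtCutoff(pos, neg, oc$cutoff, roc$direction)
    cbind(data.frame(marker = mk, contrast = contrast, auc = roc$auc,
                     cutoff = oc$cutoff, direction = roc$direction,
                     stringsAsFactors = FALSE),
          met)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out <- out[order(-out$auc, out$marker), ]
  rownames(out) <- NULL
  out
}
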