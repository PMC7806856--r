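# Group summaries and the three-group comparison (one-way ANOVA with
# pairwise post hoc), computed on post-QC concentrations.

#' Per-marker per-group summaries
#'
#' One row per marker x group with post-exclusion `n`, `mean`, `sd` and the
#' number of cells excluded by the outlier rule — the layout of the study's
#' group-level concentration table.
#'
#' @param qc a [CytokineQC-class].
#' @return data.frame: `marker`, `group`, `n`, `mean`, `sd`, `n_outliers`.
#'   Groups with no remaining values get `n = 0` and `NA` moments.
#' @export
summarizeGroups <- function(qc) {
  conc <- concentrations(qcCleaned(qc))
  grp <- as.character(subjectGroups(qcCleaned(qc)))
  log <- qcOutlierLog(qc)
  out <- expand.grid(marker = rownames(conc), group = .GROUPS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$marker, rownames(conc))), ]
  rownames(out) <- NULL
  stats <- mapply(function(mk, g) {
    v <- conc[mk, grp == g]
    v <- v[!is.na(v)]
    c(n = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) >= 2) sd(v) else if (length(v)) 0 else NA_real_,
      n_outliers = sum(log$marker == mk & log$group == g))
  }, out$marker, out$group)
  res <- cbind(out, as.data.frame(t(stats)))
  rownames(res) <- NULL
  res
}

#' One-way ANOVA with pairwise post hoc per marker
#'
#' Classical (equal-variance) one-way ANOVA on raw concentrations by
#' default, mirroring the study's analysis; Welch's correction and a log
#' transform are available. Post hoc pairwise comparisons use Tukey's HSD
#' (default) or Bonferroni-adjusted pairwise t tests; they are computed
#' regardless of the omnibus result but flagged significant only below
#' `alpha`.
#'
#' @param qc a [CytokineQC-class].
#' @param alpha significance level (default 0.05).
#' @param posthoc `"tukey"` or `"bonferroni"`.
#' @param welch use Welch's ANOVA for the omnibus test.
#' @param logTransform analyse `log(value)` instead of raw pg/mL.
#' @return list with `omnibus` (data.frame `marker`, `p_value`) and
#'   `posthoc` (data.frame `marker`, `pair`, `p_adj`, `significant`).
#'   Markers without >= 2 groups of >= 2 values are skipped with a warning.
#' @export
anovaPosthoc <- function(qc, alpha = 0.05,
                         posthoc = c("tukey", "bonferroni"),
                         welch = FALSE, logTransform = FALSE) {
  posthoc <- match.arg(posthoc)
  conc <- concentrations(qcCleaned(qc))
  grp <- factor(as.character(subjectGroups(qcCleaned(qc))),
                levels = .GROUPS)
  omni <- list(); ph <- list(); skipped <- character()
  for (mk in rownames(conc)) {
    v <- conc[mk, ]
    ok <- !is.na(v)
    if (logTransform) v <- log(v)
    tab <- table(grp[ok])
    if (sum(tab >= 2) < 2) { skipped <- c(skipped, mk); next }
    d <- data.frame(value = v[ok], group = droplevels(grp[ok]))
    p <- if (welch) {
      oneway.test(value ~ group, data = d, var.equal = FALSE)$p.value
    } else {
      fit <- aov(value ~ group, data = d)
      summary(fit)[[1]][["Pr(>F)"]][1]
    }
    omni[[mk]] <- data.frame(marker = mk, p_value = p,
                             stringsAsFactors = FALSE)
    if (posthoc == "tukey") {
      tk <- TukeyHSD(aov(value ~ group, data = d))$group
      ph[[mk]] <- data.frame(marker = mk, pair = rownames(tk),
                             p_adj = tk[, "p adj"],
                             stringsAsFactors = FALSE)
    } else {
      pt <- pairwise.t.test(d$value, d$group, p.adjust.method = "bonferroni")
      m <- pt$p.value
      pairs <- which(!is.na(m), arr.ind = TRUE)
      ph[[mk]] <- data.frame(
        marker = mk,
        pair = paste(rownames(m)[pairs[, 1]], colnames(m)[pairs[, 2]],
                     sep = "-"),
        p_adj = m[pairs], stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning("insufficient data, skipped: ", paste(skipped, collapse = ", "))
  posthoc_df <- do.call(rbind, ph)
  if (is.null(posthoc_df))
    posthoc_df <- data.frame(marker = character(), pair = character(),
                             p_adj = numeric())
  posthoc_df$significant <- posthoc_df$p_adj < alpha
  rownames(posthoc_df) <- NULL
  omnibus <- do.call(rbind, omni)
  if (is.null(omnibus))
    omnibus <- data.frame(marker = character(), p_value = numeric())
  rownames(omnibus) <- NULL
  list(omnibus = omnibus, posthoc = posthoc_df)
}
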