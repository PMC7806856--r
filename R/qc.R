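# QC: the study's two exclusion rules. (1) per marker x group, values
# strictly outside mean +/- k*SD (computed once, on all pre-exclusion
# values, sample SD) are excluded; (2) markers whose post-exclusion group
# mean falls below the assay's minimum detectable concentration are flagged.

#' QC result container
#'
#' @slot cleaned [CytokineExperiment-class] with excluded cells set to `NA`.
#' @slot outlierLog data.frame of excluded cells: `marker`, `group`,
#'   `subject_id`, `value`.
#' @slot lodFlagged character vector of below-LOD marker names.
#' @slot k the SD multiplier used.
#' @exportClass CytokineQC
setClass("CytokineQC",
         representation(cleaned = "CytokineExperiment",
                        outlierLog = "data.frame",
                        lodFlagged = "character", k = "numeric"))

setMethod("show", "CytokineQC", function(object) {
  cat("CytokineQC: mean +/-", object@k, "SD exclusion\n")
  cat("  excluded cells:", nrow(object@outlierLog), "\n")
  if (length(object@lodFlagged))
    cat("  below-LOD markers:",
        paste(object@lodFlagged, collapse = ", "), "\n")
})

#' @describeIn applyQC cleaned cohort with excluded cells as `NA`
#' @export
qcCleaned <- function(qc) qc@cleaned

#' @describeIn applyQC data.frame of excluded cells
#' @export
qcOutlierLog <- function(qc) qc@outlierLog

#' @describeIn applyQC names of markers flagged below LOD
#' @export
qcLodFlagged <- function(qc) qc@lodFlagged

#' Single-pass k-SD outlier exclusion
#'
#' Mean and sample SD are computed once on all non-missing input values;
#' values strictly outside `[mean - k*sd, mean + k*sd]` are excluded.
#' Boundary values are kept, so a zero-variance vector is returned intact.
#' The rule is single-pass by design: re-running it on the kept values can
#' exclude more (the SD shrinks), which is not what the study did.
#'
#' @param values numeric vector (pg/mL); `NA`s are ignored and not excluded.
#' @param k SD multiplier (default 3).
#' @return list: `kept` (input order preserved), `excluded`, `n_excluded`,
#'   and the logical `excluded_mask` aligned with the input.
#' @examples
#' excludeOutliers(c(rnorm(100), 50))$n_excluded
#' @export
excludeOutliers <- function(values, k = 3) {
  obs <- !is.na(values)
  if (sum(obs) < 2) stop("need at least 2 non-missing values")
  m <- mean(values[obs])
  s <- sd(values[obs])
  mask <- obs & (values < m - k * s | values > m + k * s)
  list(kept = values[obs & !mask], excluded = values[mask],
       n_excluded = sum(mask), excluded_mask = mask)
}

#' Apply the study's QC rules to a cohort
#'
#' Runs [excludeOutliers()] per marker x group and flags markers whose
#' post-exclusion mean in any group falls below the marker's minimum
#' detectable concentration. Flagged markers stay in the cleaned table (the
#' study still reports their summaries); downstream diagnostic steps decide
#' whether to drop them.
#'
#' @param x a [CytokineExperiment-class].
#' @param lodTable optional named numeric vector, marker -> minimum
#'   detectable concentration (pg/mL). Markers absent from it cannot be
#'   flagged; a warning lists them.
#' @param k SD multiplier (default 3).
#' @return A [CytokineQC-class].
#' @export
applyQC <- function(x, lodTable = NULL, k = 3) {
  conc <- concentrations(x)
  grp <- as.character(subjectGroups(x))
  log <- list()
  for (mk in rownames(conc)) {
    for (g in unique(grp)) {
      idx <- which(grp == g)
      v <- conc[mk, idx]
      if (sum(!is.na(v)) < 2) next
      res <- excludeOutliers(v, k = k)
      if (res$n_excluded > 0) {
        hit <- idx[res$excluded_mask]
        log[[length(log) + 1L]] <-
          data.frame(marker = mk, group = g,
                     subject_id = colnames(conc)[hit],
                     value = conc[mk, hit], stringsAsFactors = FALSE)
        conc[mk, hit] <- NA_real_
      }
    }
  }
  cleaned <- x
  assay(cleaned, "conc") <- conc
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(marker = character(), group = character(),
               subject_id = character(), value = numeric(),
               stringsAsFactors = FALSE)
  rownames(log) <- NULL
  flagged <- character()
  if (!is.null(lodTable)) {
    missing_lod <- setdiff(rownames(conc), names(lodTable))
    if (length(missing_lod))
      warning("no LOD available for: ",
              paste(missing_lod, collapse = ", "))
    for (mk in intersect(rownames(conc), names(lodTable))) {
      gm <- tapply(conc[mk, ], grp, mean, na.rm = TRUE)
      if (any(gm < lodTable[[mk]], na.rm = TRUE)) flagged <- c(flagged, mk)
    }
  }
  new("CytokineQC", cleaned = cleaned, outlierLog = log,
      lodFlagged = flagged, k = k)
}
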