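#' CytokineExperiment: subjects x markers cohort container
#'
#' S4 container for a multiplex urinary cytokine cohort, extending
#' [SummarizedExperiment::SummarizedExperiment]. The `"conc"` assay holds
#' marker concentrations in pg/mL (markers in rows, subjects in columns;
#' `NA` = not measured), `colData` carries the subject covariates (`group`,
#' `age`, `sex`, `bmi`, `dm`) and `rowData` the panel metadata.
#'
#' @aliases CytokineExperiment-class
#' @exportClass CytokineExperiment
setClass("CytokineExperiment", contains = "SummarizedExperiment")

setValidity("CytokineExperiment", function(object) {
  msgs <- character()
  if (!"conc" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'conc' is required")
  cd <- colData(object)
  need <- c("group", "age", "sex", "bmi", "dm")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste0("colData lacks column(s): ",
                           paste(miss, collapse = ", ")))
  if ("group" %in% colnames(cd)) {
    bad <- setdiff(unique(as.character(cd$group)), .GROUPS)
    if (length(bad))
      msgs <- c(msgs, paste0("invalid group label(s): ",
                             paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "subject ids (colnames) must be unique")
  if ("conc" %in% SummarizedExperiment::assayNames(object)) {
    a <- assay(object, "conc")
    if (any(a < 0, na.rm = TRUE))
      msgs <- c(msgs, "concentrations must be nonnegative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CytokineExperiment
#'
#' @param concentrations numeric matrix, markers x subjects (pg/mL, `NA`
#'   allowed). Rownames are canonical marker keys, colnames subject ids.
#' @param subjectData data.frame with one row per subject: columns `group`,
#'   `age`, `sex` (`"F"`/`"M"`), `bmi`, `dm` (logical).
#' @param panel panel metadata data.frame, see [markerPanel()].
#' @return A [CytokineExperiment-class] object.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("MIP-1b", "IL-10"), c("s1", "s2")))
#' cd <- data.frame(group = c("IC_BPS", "CONTROL"), age = c(50, 60),
#'                  sex = c("F", "F"), bmi = c(22, 25), dm = c(FALSE, FALSE))
#' CytokineExperiment(m, cd)
#' @export
CytokineExperiment <- function(concentrations, subjectData,
                               panel = markerPanel()) {
  if (is.null(rownames(concentrations)))
    stop("concentration matrix needs marker rownames")
  markers <- resolveMarkers(rownames(concentrations))
  rownames(concentrations) <- markers
  rd <- panel[match(markers, panel$marker), , drop = FALSE]
  rownames(rd) <- markers
  subjectData$group <- factor(as.character(subjectData$group),
                              levels = .GROUPS)
  subjectData$sex <- factor(as.character(subjectData$sex),
                            levels = c("F", "M"))
  se <- SummarizedExperiment(
    assays = list(conc = concentrations),
    colData = DataFrame(subjectData),
    rowData = DataFrame(rd))
  new("CytokineExperiment", se)
}

#' @describeIn CytokineExperiment-accessors concentration matrix
#'   (markers x subjects, pg/mL)
#' @export
concentrations <- function(x) assay(x, "conc")

#' Accessors for CytokineExperiment
#'
#' @param x a [CytokineExperiment-class].
#' @name CytokineExperiment-accessors
#' @return `concentrations()`: numeric matrix; `subjectGroups()`: factor of
#'   group labels; `subjectCovariates()`: data.frame of covariates.
NULL

#' @describeIn CytokineExperiment-accessors group factor, one entry per subject
#' @export
subjectGroups <- function(x) colData(x)$group

#' @describeIn CytokineExperiment-accessors covariate data.frame
#' @export
subjectCovariates <- function(x) {
  as.data.frame(colData(x)[, c("group", "age", "sex", "bmi", "dm")])
}

setMethod("show", "CytokineExperiment", function(object) {
  tab <- table(subjectGroups(object))
  cat("CytokineExperiment:", nrow(object), "markers x",
      ncol(object), "subjects\n")
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  missing cells:", sum(is.na(assay(object, "conc"))), "\n")
})

.COVARIATE_COLS <- c("subject_id", "group", "age", "sex", "bmi", "dm")

#' Read a cohort CSV
#'
#' Reads a wide-format cohort table: one row per subject, columns
#' `subject_id, group, age, sex, bmi, dm` followed by one column per marker
#' (pg/mL). Empty cells and `NA` become missing values (never zero).
#'
#' @param path CSV file path.
#' @param panel panel metadata; marker columns are validated against it.
#' @return A [CytokineExperiment-class].
#' @export
readCohort <- function(path, panel = markerPanel()) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(.COVARIATE_COLS, names(df))
  if (length(miss))
    stop("cohort CSV lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$group), .GROUPS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.GROUPS, collapse = "/"), ")")
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id values")
  markers <- resolveMarkers(setdiff(names(df), .COVARIATE_COLS))
  m <- t(as.matrix(df[, setdiff(names(df), .COVARIATE_COLS), drop = FALSE]))
  storage.mode(m) <- "double"
  rownames(m) <- markers
  colnames(m) <- df$subject_id
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative concentration for subject '%s', marker '%s'",
                 colnames(m)[neg[1, "col"]], rownames(m)[neg[1, "row"]]))
  cd <- df[, c("group", "age", "sex", "bmi", "dm")]
  cd$dm <- as.logical(cd$dm)
  rownames(cd) <- df$subject_id
  CytokineExperiment(m, cd, panel = panel)
}

#' Write a cohort CSV
#'
#' Inverse of [readCohort()]: writes the wide per-subject table. Values are
#' written at full precision so that read -> write -> read round trips.
#'
#' @param x a [CytokineExperiment-class].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeCohort <- function(x, path) {
  cd <- subjectCovariates(x)
  df <- data.frame(subject_id = colnames(x),
                   group = as.character(cd$group),
                   age = cd$age, sex = as.character(cd$sex),
                   bmi = cd$bmi, dm = cd$dm,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(t(concentrations(x)), check.names = FALSE))
  # %.17g guarantees doubles survive the text round trip exactly
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA
      df[[j]] <- v
    }
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write an analysis report
#'
#' Serialises a result table (or list of tables) deterministically: column
#' order as given, numeric columns rendered with a fixed number of decimals.
#'
#' @param results data.frame, or named list of data.frames (json only).
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @param digits decimals used for numeric rendering (default 3).
#' @return Invisibly, `path`.
#' @export
writeReport <- function(results, path, format = c("tsv", "json"),
                        digits = 3) {
  format <- match.arg(format)
  fmt <- function(df) {
    for (j in seq_along(df)) {
      if (is.double(df[[j]]))
        df[[j]] <- formatC(df[[j]], digits = digits, format = "f")
    }
    df
  }
  if (format == "tsv") {
    if (!is.data.frame(results))
      stop("tsv format requires a data.frame")
    utils::write.table(fmt(results), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    out <- if (is.data.frame(results)) fmt(results) else lapply(results, fmt)
    jsonlite::write_json(out, path, dataframe = "rows", na = "string",
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
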