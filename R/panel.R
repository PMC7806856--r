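# 31-analyte multiplex panel. Canonical keys are ASCII aliases (safe as CSV
# headers and list names); display names carry the Greek glyphs.
.PANEL <- data.frame(
  marker = c("MCP-1", "MIP-1a", "MIP-1b", "RANTES", "Eotaxin", "G-CSF",
             "GM-CSF", "VEGF", "NGF", "EGF", "CXCL10", "IFNa2", "IFNg",
             "TNFa", "TNFb", "IL-1a", "IL-1b", "IL-1RA", "IL-2", "IL-3",
             "IL-4", "IL-5", "IL-6", "IL-7", "IL-8", "IL-10", "IL-12p40",
             "IL-12p70", "IL-13", "IL-15", "IL-17A"),
  display = c("MCP-1", "MIP-1\u03b1", "MIP-1\u03b2", "RANTES", "Eotaxin",
              "G-CSF", "GM-CSF", "VEGF", "NGF", "EGF", "CXCL10",
              "IFN\u03b12", "IFN\u03b3", "TNF\u03b1", "TNF\u03b2",
              "IL-1\u03b1", "IL-1\u03b2", "IL-1RA", "IL-2", "IL-3", "IL-4",
              "IL-5", "IL-6", "IL-7", "IL-8", "IL-10", "IL-12p40",
              "IL-12p70", "IL-13", "IL-15", "IL-17A"),
  # analytes annotated as having study-group means below the assay's minimum
  # detectable concentration
  below_lod_note = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                     TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                     FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE,
                     FALSE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Marker panel metadata
#'
#' The 31-analyte urinary cytokine/chemokine/neurotrophin panel quantified by
#' bead-based multiplex immunoassay (pg/mL). Canonical marker keys are ASCII
#' (`"MIP-1b"`, `"IFNa2"`, ...) with Unicode display names alongside, and a
#' flag for analytes whose group means sit below the assay's minimum
#' detectable concentration.
#'
#' @return A data.frame with columns `marker`, `display`, `below_lod_note`.
#' @examples
#' head(markerPanel())
#' @export
markerPanel <- function() .PANEL

#' Resolve marker names to canonical panel keys
#'
#' Accepts canonical ASCII keys or display names and returns canonical keys.
#' Unknown names raise an error.
#'
#' @param x character vector of marker names.
#' @return character vector of canonical marker keys.
#' @export
resolveMarkers <- function(x) {
  p <- markerPanel()
  idx <- match(x, p$marker)
  alt <- match(x, p$display)
  idx[is.na(idx)] <- alt[is.na(idx)]
  if (anyNA(idx)) {
    stop("unknown marker name(s): ", paste(x[is.na(idx)], collapse = ", "))
  }
  p$marker[idx]
}
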