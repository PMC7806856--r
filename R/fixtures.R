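# Published summary statistics of the three-arm urine cytokine study
# (40 OAB / 40 IC-BPS / 30 control), transcribed as packaged constants.
# These drive the synthetic cohort generator, the default cascade rules and
# the rate->count consistency oracles; raw subject-level data were never
# deposited.

.gsRow <- function(marker, oab, ic, ctrl, p, posthoc = "") {
  data.frame(marker = marker,
             group = c("OAB", "IC_BPS", "CONTROL"),
             mean = c(oab[1], ic[1], ctrl[1]),
             sd = c(oab[2], ic[2], ctrl[2]),
             n_outliers = c(oab[3], ic[3], ctrl[3]),
             p_value = p, posthoc = posthoc,
             stringsAsFactors = FALSE)
}

.GROUP_SUMMARY <- do.call(rbind, list(
  .gsRow("MCP-1",   c(240.83, 188.74, 2), c(524.61, 511.31, 0), c(147.14, 109.74, 1), 0.000, "OAB-IC_BPS,OAB-CONTROL,IC_BPS-CONTROL"),
  .gsRow("MIP-1a",  c(1.60, 1.03, 0),     c(1.09, 0.58, 0),     c(1.34, 0.75, 1),     0.021, "OAB-CONTROL"),
  .gsRow("MIP-1b",  c(2.91, 2.27, 1),     c(2.93, 1.38, 2),     c(2.52, 1.82, 1),     0.614),
  .gsRow("RANTES",  c(6.65, 5.23, 1),     c(12.75, 7.59, 1),    c(6.04, 5.15, 1),     0.000, "OAB-IC_BPS,IC_BPS-CONTROL"),
  .gsRow("Eotaxin", c(4.65, 3.73, 2),     c(11.87, 8.41, 1),    c(4.98, 3.70, 0),     0.000, "OAB-IC_BPS,IC_BPS-CONTROL"),
  .gsRow("G-CSF",   c(7.92, 7.58, 1),     c(7.04, 7.05, 2),     c(11.72, 10.17, 1),   0.071),
  .gsRow("GM-CSF",  c(1.35, 0.48, 2),     c(1.30, 0.46, 0),     c(1.24, 0.50, 1),     0.653),
  .gsRow("VEGF",    c(13.64, 4.95, 1),    c(12.82, 6.68, 1),    c(10.97, 5.00, 0),    0.149),
  .gsRow("NGF",     c(0.27, 0.07, 1),     c(0.35, 0.15, 1),     c(0.26, 0.08, 0),     0.002, "OAB-IC_BPS,IC_BPS-CONTROL"),
  .gsRow("EGF",     c(5454.83, 3767.41, 0), c(6833.88, 4476.67, 0), c(6224.35, 4906.68, 0), 0.370),
  .gsRow("CXCL10",  c(24.77, 41.77, 1),   c(62.24, 49.15, 2),   c(13.81, 18.43, 1),   0.000, "OAB-IC_BPS,IC_BPS-CONTROL"),
  .gsRow("IFNa2",   c(3.66, 1.75, 1),     c(3.39, 1.89, 1),     c(3.22, 1.52, 1),     0.568),
  .gsRow("IFNg",    c(1.23, 0.19, 2),     c(1.19, 0.30, 0),     c(1.19, 0.19, 1),     0.783),
  .gsRow("TNFa",    c(0.82, 0.34, 1),     c(0.71, 0.25, 1),     c(0.82, 0.33, 1),     0.219),
  .gsRow("TNFb",    c(0.79, 0.13, 1),     c(0.74, 0.12, 1),     c(0.76, 0.12, 1),     0.210),
  .gsRow("IL-1a",   c(1.80, 1.39, 0),     c(1.35, 0.44, 1),     c(1.43, 0.75, 1),     0.089),
  .gsRow("IL-1b",   c(0.50, 0.15, 2),     c(0.52, 0.16, 1),     c(0.56, 0.27, 1),     0.445),
  .gsRow("IL-1RA",  c(390.56, 507.03, 1), c(467.29, 396.94, 1), c(325.52, 387.05, 1), 0.414),
  .gsRow("IL-2",    c(0.72, 0.17, 0),     c(0.82, 0.17, 0),     c(0.80, 0.19, 1),     0.028, "OAB-IC_BPS"),
  .gsRow("IL-3",    c(0.59, 0.22, 0),     c(0.51, 0.17, 0),     c(0.64, 0.25, 0),     0.034, "IC_BPS-CONTROL"),
  .gsRow("IL-4",    c(15.3, 10.88, 1),    c(12.44, 8.57, 0),    c(11.07, 15.16, 1),   0.293),
  .gsRow("IL-5",    c(0.61, 0.23, 1),     c(0.44, 0.11, 1),     c(0.54, 0.17, 1),     0.000, "OAB-IC_BPS,IC_BPS-CONTROL"),
  .gsRow("IL-6",    c(1.73, 2.34, 1),     c(2.36, 3.18, 2),     c(1.29, 1.35, 1),     0.214),
  .gsRow("IL-7",    c(1.41, 0.44, 1),     c(1.59, 0.63, 1),     c(1.52, 0.81, 1),     0.424),
  .gsRow("IL-8",    c(10.83, 12.28, 2),   c(10.97, 11.06, 0),   c(12.45, 20.98, 1),   0.890),
  .gsRow("IL-10",   c(1.48, 0.45, 1),     c(0.97, 0.31, 1),     c(1.23, 0.32, 1),     0.000, "OAB-IC_BPS,OAB-CONTROL,IC_BPS-CONTROL"),
  .gsRow("IL-12p40", c(0.90, 0.40, 1),    c(0.99, 0.45, 0),     c(0.79, 0.32, 0),     0.106),
  .gsRow("IL-12p70", c(1.34, 0.33, 1),    c(1.14, 0.38, 1),     c(1.28, 0.42, 0),     0.063),
  .gsRow("IL-13",   c(1.19, 0.38, 1),     c(1.21, 0.29, 1),     c(1.24, 0.40, 1),     0.841),
  .gsRow("IL-15",   c(1.64, 0.91, 1),     c(1.43, 0.55, 1),     c(1.21, 0.37, 1),     0.029, "OAB-CONTROL"),
  .gsRow("IL-17A",  c(0.93, 0.18, 1),     c(0.80, 0.17, 0),     c(0.97, 0.20, 1),     0.000, "OAB-IC_BPS,IC_BPS-CONTROL")
))

.dsRow <- function(marker, contrast, auc, cutoff, sens, spec, ppv, npv,
                direction = "pos_higher") {
  data.frame(marker = marker, contrast = contrast, auc = auc, cutoff = cutoff,
             sens = sens, spec = spec, ppv = ppv, npv = npv,
             direction = direction, stringsAsFactors = FALSE)
}

# Per-marker diagnostic values. Positive class: the diseased arms pooled
# (diseased_vs_control) or IC_BPS (ic_vs_oab). direction = "pos_lower" marks
# the footnoted markers where LOWER values indicate the positive class
# (higher values indicate controls, resp. OAB).
.DIAG_SUMMARY <- do.call(rbind, list(
  .dsRow("MCP-1",   "diseased_vs_control", 0.753, 204.235, 60.3, 72.4, 85.5, 40.4),
  .dsRow("IL-4",    "diseased_vs_control", 0.703, 10.610,  54.4, 86.2, 91.5, 41.0),
  .dsRow("CXCL10",  "diseased_vs_control", 0.685, 7.500,   66.2, 65.5, 83.6, 42.2),
  .dsRow("MIP-1b",  "diseased_vs_control", 0.674, 1.385,   92.2, 44.8, 81.6, 68.4),
  .dsRow("RANTES",  "diseased_vs_control", 0.666, 7.805,   53.8, 75.9, 85.7, 37.9),
  .dsRow("IL-8",    "diseased_vs_control", 0.651, 2.785,   82.1, 44.8, 80.0, 48.1),
  .dsRow("IL-17A",  "diseased_vs_control", 0.642, 0.925,   65.8, 62.1, 82.5, 40.0, "pos_lower"),
  .dsRow("IL-6",    "diseased_vs_control", 0.631, 1.165,   50.0, 79.3, 86.7, 37.7),
  .dsRow("NGF",     "diseased_vs_control", 0.624, 0.315,   41.0, 80.0, 84.2, 34.3),
  .dsRow("IL-15",   "diseased_vs_control", 0.611, 0.855,   97.4, 24.1, 77.6, 77.8),
  .dsRow("G-CSF",   "diseased_vs_control", 0.605, 4.820,   53.2, 72.4, 83.7, 36.8),
  .dsRow("Eotaxin", "diseased_vs_control", 0.604, 7.270,   40.3, 80.0, 83.8, 34.3),
  .dsRow("IL-10",   "ic_vs_oab", 0.829, 1.025,  74.4, 92.3, 90.6, 78.3, "pos_lower"),
  .dsRow("RANTES",  "ic_vs_oab", 0.814, 9.305,  61.5, 82.1, 77.4, 68.1),
  .dsRow("Eotaxin", "ic_vs_oab", 0.774, 9.035,  59.0, 89.5, 85.2, 68.0),
  .dsRow("CXCL10",  "ic_vs_oab", 0.768, 40.495, 65.8, 82.1, 78.1, 71.1),
  .dsRow("IL-12p70", "ic_vs_oab", 0.739, 1.085, 51.3, 94.9, 90.9, 66.1, "pos_lower"),
  .dsRow("NGF",     "ic_vs_oab", 0.725, 0.355,  35.9, 84.6, 70.0, 56.9),
  .dsRow("IL-6",    "ic_vs_oab", 0.716, 1.515,  52.6, 82.1, 74.1, 64.0),
  .dsRow("IL-17A",  "ic_vs_oab", 0.708, 0.885,  70.0, 59.0, 63.6, 65.7, "pos_lower"),
  .dsRow("MCP-1",   "ic_vs_oab", 0.704, 120.385, 90.0, 42.1, 62.1, 80.0),
  .dsRow("IL-1RA",  "ic_vs_oab", 0.703, 113.05, 89.7, 43.6, 61.4, 81.0)
))

.COVARIATE_SUMMARY <- data.frame(
  group = c("OAB", "IC_BPS", "CONTROL"),
  n = c(40L, 40L, 30L),
  age_mean = c(64.7, 49.3, 57.7),
  age_sd = c(8.9, 12.1, 10.1),
  age_min = c(39, 21, 39),
  age_max = c(78, 69, 71),
  n_female = c(30L, 34L, 30L),
  n_male = c(10L, 6L, 0L),
  n_dm = c(13L, 2L, 3L),
  bmi_mean = c(26.05, 21.94, 25.60),
  bmi_sd = c(3.49, 3.92, 4.39),
  stringsAsFactors = FALSE
)

# Covariate-adjusted odds ratios (logistic models controlling for age,
# gender, BMI, diabetes), with the pg/mL increment each OR is scaled to.
.orRow <- function(contrast, marker, p, or, lo, hi, unit) {
  data.frame(contrast = contrast, marker = marker, p_value = p,
             odds_ratio = or, ci_lo = lo, ci_hi = hi, unit_scale = unit,
             stringsAsFactors = FALSE)
}
.ADJUSTED_OR <- do.call(rbind, list(
  .orRow("oab_vs_control", "MCP-1",  0.032, 1.692, 1.046, 2.734, 100),
  .orRow("oab_vs_control", "IL-10",  0.004, 1.288, 1.083, 1.531, 0.1),
  .orRow("ic_vs_control",  "MCP-1",  0.008, 2.569, 1.282, 5.148, 100),
  .orRow("ic_vs_control",  "CXCL10", 0.004, 1.516, 1.146, 2.005, 10),
  .orRow("ic_vs_control",  "Eotaxin", 0.003, 1.181, 1.058, 1.319, 1),
  .orRow("ic_vs_control",  "RANTES", 0.014, 1.150, 1.028, 1.286, 1),
  .orRow("ic_vs_control",  "NGF",    0.027, 1.102, 1.011, 1.200, 0.01),
  .orRow("ic_vs_oab",      "MCP-1",  0.006, 1.358, 1.092, 1.688, 100),
  .orRow("ic_vs_oab",      "Eotaxin", 0.001, 1.294, 1.115, 1.503, 1),
  .orRow("ic_vs_oab",      "CXCL10", 0.005, 1.246, 1.068, 1.454, 10),
  .orRow("ic_vs_oab",      "RANTES", 0.004, 1.201, 1.060, 1.361, 1),
  .orRow("ic_vs_oab",      "NGF",    0.028, 1.126, 1.013, 1.252, 0.01),
  .orRow("ic_vs_oab",      "IL-17A", 0.007, 0.939, 0.897, 0.983, 0.01),
  .orRow("ic_vs_oab",      "IL-12p70", 0.003, 0.678, 0.522, 0.879, 0.1),
  .orRow("ic_vs_oab",      "IL-10",  0.001, 0.633, 0.484, 0.828, 0.1),
  .orRow("ic_vs_oab",      "IFNa2",  0.008, 0.520, 0.322, 0.840, 1)
))

#' Published study constants
#'
#' Packaged transcription of the study's summary tables: per-group clinical
#' covariates, per-marker per-group mean/SD/outlier counts, per-marker ROC
#' diagnostic values (AUC, Youden cutoff, sensitivity/specificity/PPV/NPV per
#' contrast), covariate-adjusted odds ratios with their per-unit scales, and
#' enrolled group sizes. These are the targets the synthetic cohort generator
#' emulates and the inputs to the rate-to-count consistency oracle.
#'
#' @return A list with elements:
#' \describe{
#'   \item{groupSizes}{named integer vector, enrolled subjects per group.}
#'   \item{covariateSummary}{data.frame of per-group covariate summaries.}
#'   \item{groupSummary}{data.frame marker x group: `mean`, `sd` (pg/mL),
#'     `n_outliers` excluded by the 3-SD rule, omnibus `p_value`, `posthoc`
#'     significant pairs.}
#'   \item{diagnosticSummary}{data.frame of per-marker diagnostics by contrast
#'     (`diseased_vs_control`, `ic_vs_oab`): `auc`, `cutoff` (pg/mL),
#'     `sens`/`spec`/`ppv`/`npv` (percent), `direction`.}
#'   \item{adjustedOR}{data.frame of adjusted odds ratios with `unit_scale`.}
#'   \item{orUnits}{named numeric vector, pg/mL increment per OR unit.}
#' }
#' @examples
#' fx <- publishedFixtures()
#' subset(fx$diagnosticSummary, marker == "MIP-1b")
#' @export
publishedFixtures <- function() {
  units <- unique(.ADJUSTED_OR[, c("marker", "unit_scale")])
  list(
    groupSizes = c(OAB = 40L, IC_BPS = 40L, CONTROL = 30L),
    covariateSummary = .COVARIATE_SUMMARY,
    groupSummary = .GROUP_SUMMARY,
    diagnosticSummary = .DIAG_SUMMARY,
    adjustedOR = .ADJUSTED_OR,
    orUnits = setNames(units$unit_scale, units$marker)
  )
}

#' Look up a marker x group summary cell
#'
#' Convenience accessor for the packaged group-summary constants.
#'
#' @param marker canonical marker key.
#' @param group one of `"IC_BPS"`, `"OAB"`, `"CONTROL"`.
#' @return One-row data.frame with `mean`, `sd`, `n_outliers`.
#' @export
fixtureCell <- function(marker, group) {
  out <- .GROUP_SUMMARY[.GROUP_SUMMARY$marker == marker & .GROUP_SUMMARY$group == group,
                 c("mean", "sd", "n_outliers")]
  if (nrow(out) != 1L) stop("no fixture cell for ", marker, " / ", group)
  out
}
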