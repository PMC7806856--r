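# The hierarchical screen-then-confirm diagnostic cascade: a sensitive
# screening rule separates diseased subjects from controls; screen-positive
# subjects are assigned IC/BPS or OAB by branch-specific confirmation rules.
# The published algorithm evaluates each confirmation cytokine separately;
# the combiner/on-conflict options here make an explicit joint decision rule
# out of the separate rules and are a documented extension.

.testRule <- function(marker, cutoff, direction = c("higher", "lower"),
                      label) {
  direction <- match.arg(direction)
  stopifnot(is.finite(cutoff))
  list(marker = marker, cutoff = cutoff, direction = direction,
       label = label)
}

.ruleFires <- function(rule, value) {
  if (is.na(value)) return(NA)
  if (rule$direction == "higher") value > rule$cutoff else value < rule$cutoff
}

#' Cascade configuration
#'
#' @slot screen screening rule (list: `marker`, `cutoff`, `direction`,
#'   `label`); fires = diseased, else control.
#' @slot icRules confirmation rules voting for IC/BPS.
#' @slot oabRules confirmation rules voting for OAB.
#' @slot combiner `"majority"`, `"any"`, `"all"` or `"single"` (first rule
#'   only) — how votes within a branch are combined.
#' @slot onConflict `"indeterminate"`, `"prefer_ic"` or `"prefer_oab"` when
#'   both branches fire.
#' @exportClass CascadeConfig
setClass("CascadeConfig",
         representation(screen = "list", icRules = "list",
                        oabRules = "list", combiner = "character",
                        onConflict = "character"))

setValidity("CascadeConfig", function(object) {
  msgs <- character()
  if (!object@combiner %in% c("majority", "any", "all", "single"))
    msgs <- c(msgs, "unknown combiner")
  if (!object@onConflict %in% c("indeterminate", "prefer_ic", "prefer_oab"))
    msgs <- c(msgs, "unknown conflict policy")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CascadeConfig", function(object) {
  fmt <- function(r) sprintf("%s %s %g -> %s", r$marker,
                             if (r$direction == "higher") ">" else "<",
                             r$cutoff, r$label)
  cat("CascadeConfig\n  screen:", fmt(object@screen), "\n")
  for (r in object@icRules) cat("  confirm:", fmt(r), "\n")
  for (r in object@oabRules) cat("  confirm:", fmt(r), "\n")
  cat("  combiner:", object@combiner, " on conflict:", object@onConflict,
      "\n")
})

#' Build a cascade configuration
#'
#' @param screen,icRules,oabRules rules created with `list(marker=, cutoff=,
#'   direction=, label=)` semantics; see [defaultCascadeConfig()].
#' @param combiner,onConflict vote combination and conflict policy.
#' @return A [CascadeConfig-class].
#' @export
cascadeConfig <- function(screen, icRules, oabRules,
                          combiner = c("majority", "any", "all", "single"),
                          onConflict = c("indeterminate", "prefer_ic",
                                         "prefer_oab")) {
  new("CascadeConfig", screen = screen, icRules = icRules,
      oabRules = oabRules, combiner = match.arg(combiner),
      onConflict = match.arg(onConflict))
}

#' The published pilot cascade
#'
#' Screen: MIP-1b > 1.385 pg/mL calls a subject diseased (highest-
#' sensitivity marker for diseased vs control). Confirmation for IC/BPS:
#' eotaxin > 9.035, CXCL10 > 40.495, RANTES > 9.305 (each votes IC).
#' Confirmation for OAB: IL-10 > 1.025 (higher values indicate OAB).
#' Cutoffs are the published Youden-optimal values.
#'
#' @param fixtures packaged constants, see [publishedFixtures()].
#' @param combiner,onConflict see [cascadeConfig()].
#' @return A [CascadeConfig-class].
#' @export
defaultCascadeConfig <- function(fixtures = publishedFixtures(),
                                 combiner = "majority",
                                 onConflict = "indeterminate") {
  t3 <- fixtures$diagnosticSummary
  cut3 <- function(mk, ct) t3$cutoff[t3$marker == mk & t3$contrast == ct]
  cascadeConfig(
    screen = .testRule("MIP-1b", cut3("MIP-1b", "diseased_vs_control"),
                       "higher", "DISEASED"),
    icRules = list(
      .testRule("Eotaxin", cut3("Eotaxin", "ic_vs_oab"), "higher", "IC_BPS"),
      .testRule("CXCL10", cut3("CXCL10", "ic_vs_oab"), "higher", "IC_BPS"),
      .testRule("RANTES", cut3("RANTES", "ic_vs_oab"), "higher", "IC_BPS")),
    oabRules = list(
      .testRule("IL-10", cut3("IL-10", "ic_vs_oab"), "higher", "OAB")),
    combiner = combiner, onConflict = onConflict)
}

.combineVotes <- function(rules, values, combiner) {
  fires <- vapply(rules, function(r) isTRUE(.ruleFires(r, values[r$marker])),
                  logical(1))
  switch(combiner,
         majority = sum(fires) > length(rules) / 2,
         any = any(fires),
         all = all(fires),
         single = fires[1])
}

#' Classify subjects through the cascade
#'
#' Screen-negative subjects are called CONTROL without consulting the
#' confirmation markers. Screen-positive subjects are called IC_BPS if the
#' IC branch fires (under the combiner) and the OAB branch does not, OAB in
#' the converse case, the conflict policy's label if both fire, and
#' INDETERMINATE if neither does. Subjects missing the screen marker are
#' unevaluable (`NA`).
#'
#' @param x a [CytokineExperiment-class] or [CytokineQC-class].
#' @param config a [CascadeConfig-class].
#' @return character vector (one entry per subject, named by subject id)
#'   in `{CONTROL, IC_BPS, OAB, INDETERMINATE, NA}`.
#' @export
classifySubjects <- function(x, config) {
  validObject(config)
  if (is(x, "CytokineQC")) x <- qcCleaned(x)
  conc <- concentrations(x)
  out <- setNames(rep(NA_character_, ncol(conc)), colnames(conc))
  for (i in seq_len(ncol(conc))) {
    values <- conc[, i]
    screen <- .ruleFires(config@screen, values[config@screen$marker])
    if (is.na(screen)) next
    if (!screen) { out[i] <- "CONTROL"; next }
    ic <- .combineVotes(config@icRules, values, config@combiner)
    oab <- .combineVotes(config@oabRules, values, config@combiner)
    out[i] <- if (ic && !oab) "IC_BPS"
    else if (oab && !ic) "OAB"
    else if (ic && oab) switch(config@onConflict,
                               indeterminate = "INDETERMINATE",
                               prefer_ic = "IC_BPS",
                               prefer_oab = "OAB")
    else "INDETERMINATE"
  }
  out
}

#' Evaluate the cascade against true labels
#'
#' Diagnostic rates of the two stages: `screen_ppv` is the percentage of
#' screen-positive subjects who are truly diseased and `screen_npv` the
#' percentage of screen-negative subjects who are truly controls (the
#' published "diagnostic rates" of the screening stage). Each confirmation
#' rule is additionally scored on its own, as in the published algorithm:
#' among screen-positive truly-diseased subjects, the percentage whose
#' single-rule call (rule fires -> rule label, else the other branch's
#' label) matches their true group. `accuracy` is the overall three-class
#' accuracy over evaluable subjects (INDETERMINATE counts as wrong).
#'
#' @param x a [CytokineExperiment-class] or [CytokineQC-class] with true
#'   group labels.
#' @param config a [CascadeConfig-class].
#' @return list: `calls` (data.frame `subject_id`, `truth`, `call`,
#'   `screen_positive`), `screen_ppv`, `screen_npv`, `ruleRates`
#'   (data.frame `marker`, `branch`, `n`, `correct_pct`), `accuracy`,
#'   `n_unevaluable`.
#' @export
evaluateCascade <- function(x, config) {
  if (is(x, "CytokineQC")) x <- qcCleaned(x)
  calls <- classifySubjects(x, config)
  truth <- as.character(subjectGroups(x))
  conc <- concentrations(x)
  evaluable <- !is.na(calls)
  screen_pos <- evaluable & calls != "CONTROL"
  screen_neg <- evaluable & calls == "CONTROL"
  diseased <- truth %in% c("IC_BPS", "OAB")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  screen_ppv <- pct(sum(screen_pos & diseased), sum(screen_pos))
  screen_npv <- pct(sum(screen_neg & !diseased), sum(screen_neg))

  scoreRule <- function(rule, other_label) {
    idx <- which(screen_pos & diseased)
    fires <- vapply(idx, function(i) .ruleFires(rule, conc[rule$marker, i]),
                    NA)
    ok <- !is.na(fires)
    call <- ifelse(fires[ok], rule$label, other_label)
    data.frame(marker = rule$marker, branch = rule$label, n = sum(ok),
               correct_pct = pct(sum(call == truth[idx][ok]), sum(ok)),
               stringsAsFactors = FALSE)
  }
  ruleRates <- rbind(
    do.call(rbind, lapply(config@icRules, scoreRule, other_label = "OAB")),
    do.call(rbind, lapply(config@oabRules, scoreRule,
                          other_label = "IC_BPS")))
  rownames(ruleRates) <- NULL
  accuracy <- pct(sum(calls[evaluable] == truth[evaluable]),
                  sum(evaluable))
  list(calls = data.frame(subject_id = colnames(conc), truth = truth,
                          call = calls, screen_positive = screen_pos,
                          row.names = NULL, stringsAsFactors = FALSE),
       screen_ppv = screen_ppv, screen_npv = screen_npv,
       ruleRates = ruleRates, accuracy = accuracy,
       n_unevaluable = sum(!evaluable))
}
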