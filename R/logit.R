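# Covariate-adjusted logistic odds ratios. One binary logistic model per
# marker and contrast: case ~ marker + age + sex + bmi + dm, maximum
# likelihood, with the marker OR rescaled to a per-unit pg/mL increment
# (e.g. "per 100 pg/mL") as published tables do.

.logit_contrasts <- c("oab_vs_control", "ic_vs_control", "ic_vs_oab")

.logit_classes <- function(contrast) {
  switch(contrast,
         oab_vs_control = list(case = "OAB", ref = "CONTROL"),
         ic_vs_control = list(case = "IC_BPS", ref = "CONTROL"),
         ic_vs_oab = list(case = "IC_BPS", ref = "OAB"),
         stop("unknown contrast: ", contrast))
}

#' Covariate-adjusted logistic fit for one marker
#'
#' Fits `case ~ marker + age + sex + bmi + dm` by maximum likelihood on
#' complete cases and reports the marker's odds ratio per `unitScale` pg/mL
#' with a Wald 95% CI: `OR = exp(beta * unitScale)`. Sex is coded F = 0 /
#' M = 1, diabetes no = 0 / yes = 1; continuous covariates enter unscaled.
#' (Quasi-)separation is detected from fitted probabilities pinned at 0/1;
#' such fits are returned with `converged = FALSE` and `NA` estimates.
#'
#' @param x a [CytokineExperiment-class] (or [CytokineQC-class], in which
#'   case post-exclusion values are used).
#' @param contrast `"oab_vs_control"`, `"ic_vs_control"` or `"ic_vs_oab"`.
#' @param marker canonical marker key.
#' @param unitScale pg/mL increment per OR unit (default 1).
#' @return one-row data.frame: `contrast`, `marker`, `unit_scale`,
#'   `odds_ratio`, `ci_lo`, `ci_hi`, `p_value`, `n`, `converged`.
#' @export
fitMarkerLogit <- function(x, contrast, marker, unitScale = 1) {
  contrast <- match.arg(contrast, .logit_contrasts)
  if (is(x, "CytokineQC")) x <- qcCleaned(x)
  cls <- .logit_classes(contrast)
  cd <- subjectCovariates(x)
  keep <- as.character(cd$group) %in% c(cls$case, cls$ref)
  d <- data.frame(y = as.integer(as.character(cd$group)[keep] == cls$case),
                  conc = concentrations(x)[marker, keep],
                  age = cd$age[keep],
                  sex = as.integer(cd$sex[keep] == "M"),
                  bmi = cd$bmi[keep],
                  dm = as.integer(cd$dm[keep]))
  d <- d[complete.cases(d), ]
  if (length(unique(d$y)) < 2)
    stop("both classes must be present for contrast ", contrast)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ conc + age + sex + bmi + dm, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  converged <- fit$converged && !sep
  row <- function(or, lo, hi, p) {
    data.frame(contrast = contrast, marker = marker,
               unit_scale = unitScale, odds_ratio = or, ci_lo = lo,
               ci_hi = hi, p_value = p, n = nrow(d),
               converged = converged, stringsAsFactors = FALSE)
  }
  if (!converged) return(row(NA_real_, NA_real_, NA_real_, NA_real_))
  b <- coef(fit)[["conc"]]
  se <- sqrt(vcov(fit)["conc", "conc"])
  z <- b / se
  row(exp(b * unitScale),
      exp((b - 1.96 * se) * unitScale),
      exp((b + 1.96 * se) * unitScale),
      2 * pnorm(-abs(z)))
}

#' Adjusted odds ratios for a marker panel across all contrasts
#'
#' Runs [fitMarkerLogit()] for every marker in `unitTable` under all three
#' contrasts (OAB vs control, IC/BPS vs control, IC/BPS vs OAB).
#'
#' @param x a [CytokineExperiment-class] or [CytokineQC-class].
#' @param unitTable named numeric vector marker -> pg/mL per OR unit
#'   (default: the published unit table, `publishedFixtures()$orUnits`).
#' @return data.frame of fits sorted by contrast then marker.
#' @export
runAdjustedModels <- function(x, unitTable = publishedFixtures()$orUnits) {
  rows <- list()
  for (ct in .logit_contrasts) {
    for (mk in names(unitTable)) {
      rows[[paste(ct, mk)]] <-
        fitMarkerLogit(x, ct, mk, unitScale = unitTable[[mk]])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$contrast, .logit_contrasts), out$marker), ]
  rownames(out) <- NULL
  out
}
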