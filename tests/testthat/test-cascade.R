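test_that("the default configuration encodes the published rule set", {
  cfg <- defaultCascadeConfig()
  expect_equal(cfg@screen$marker, "MIP-1b")
  expect_equal(cfg@screen$cutoff, 1.385)
  expect_equal(cfg@screen$direction, "higher")
  ic <- setNames(vapply(cfg@icRules, `[[`, 0, "cutoff"),
                 vapply(cfg@icRules, `[[`, "", "marker"))
  expect_equal(ic, c(Eotaxin = 9.035, CXCL10 = 40.495, RANTES = 9.305))
  expect_equal(cfg@oabRules[[1]]$marker, "IL-10")
  expect_equal(cfg@oabRules[[1]]$cutoff, 1.025)
  # higher IL-10 votes OAB
  expect_equal(cfg@oabRules[[1]]$direction, "higher")
  expect_equal(cfg@oabRules[[1]]$label, "OAB")
  expect_equal(cfg@combiner, "majority")
  expect_equal(cfg@onConflict, "indeterminate")
})

# single-subject panel helper
panelCohort <- function(mip, eot, cxc, ran, il10, group = "IC_BPS") {
  m <- matrix(c(mip, eot, cxc, ran, il10), ncol = 1,
              dimnames = list(c("MIP-1b", "Eotaxin", "CXCL10", "RANTES",
                                "IL-10"), "s1"))
  cd <- data.frame(group = group, age = 50, sex = "F", bmi = 24,
                   dm = FALSE, row.names = "s1")
  CytokineExperiment(m, cd)
}

test_that("subjects route through screen and confirmation as specified", {
  cfg <- defaultCascadeConfig()
  # screen-negative short-circuits to CONTROL whatever the other markers say
  expect_equal(unname(classifySubjects(
    panelCohort(1.0, 100, 100, 100, 100), cfg)), "CONTROL")
  # hand-evaluated: 3/3 IC votes, OAB rule negative -> IC_BPS
  expect_equal(unname(classifySubjects(
    panelCohort(3, 20, 80, 15, 0.5), cfg)), "IC_BPS")
  # conflict: all IC votes and the OAB rule fire -> policy decides
  conflicted <- panelCohort(3, 20, 80, 15, 2.0)
  expect_equal(unname(classifySubjects(conflicted, cfg)), "INDETERMINATE")
  cfg_ic <- defaultCascadeConfig(onConflict = "prefer_ic")
  expect_equal(unname(classifySubjects(conflicted, cfg_ic)), "IC_BPS")
  cfg_oab <- defaultCascadeConfig(onConflict = "prefer_oab")
  expect_equal(unname(classifySubjects(conflicted, cfg_oab)), "OAB")
  # OAB rule alone fires -> OAB; nothing fires -> INDETERMINATE
  expect_equal(unname(classifySubjects(
    panelCohort(3, 1, 1, 1, 2.0), cfg)), "OAB")
  expect_equal(unname(classifySubjects(
    panelCohort(3, 1, 1, 1, 0.5), cfg)), "INDETERMINATE")
  # missing screen marker -> unevaluable
  expect_true(is.na(classifySubjects(
    panelCohort(NA, 20, 80, 15, 0.5), cfg)))
})

test_that("vote combiners behave as documented", {
  base <- panelCohort(3, 20, 1, 1, 0.5)   # only eotaxin votes IC
  expect_equal(unname(classifySubjects(
    base, defaultCascadeConfig(combiner = "any"))), "IC_BPS")
  expect_equal(unname(classifySubjects(
    base, defaultCascadeConfig(combiner = "majority"))), "INDETERMINATE")
  expect_equal(unname(classifySubjects(
    base, defaultCascadeConfig(combiner = "all"))), "INDETERMINATE")
  expect_equal(unname(classifySubjects(
    base, defaultCascadeConfig(combiner = "single"))), "IC_BPS")
})

test_that("label counts are conserved and screening is monotone in cutoff", {
  sim <- generateCohort(defaultGeneratorSpec(seed = 70))
  calls <- classifySubjects(sim$cohort, defaultCascadeConfig())
  n <- ncol(sim$cohort)
  expect_equal(sum(is.na(calls)) +
                 sum(calls %in% c("CONTROL", "IC_BPS", "OAB",
                                  "INDETERMINATE"), na.rm = TRUE), n)
  # raising the screen cutoff never increases screen-positive count
  cuts <- c(0.5, 1.385, 2.5, 4)
  pos <- vapply(cuts, function(cut) {
    cfg <- defaultCascadeConfig()
    cfg@screen$cutoff <- cut
    sum(classifySubjects(sim$cohort, cfg) != "CONTROL", na.rm = TRUE)
  }, 0)
  expect_true(all(diff(pos) <= 0))
})

test_that("perfectly separating markers give 100% rates everywhere", {
  n <- 10
  mk <- c("MIP-1b", "Eotaxin", "CXCL10", "RANTES", "IL-10")
  block <- function(mip, eot, cxc, ran, il10, g, tag) {
    m <- matrix(rep(c(mip, eot, cxc, ran, il10), n), nrow = 5,
                dimnames = list(mk, sprintf("%s%02d", tag, 1:n)))
    cd <- data.frame(group = rep(g, n), age = rep(50, n),
                     sex = rep("F", n), bmi = rep(24, n),
                     dm = rep(FALSE, n),
                     row.names = colnames(m))
    list(m = m, cd = cd)
  }
  ic <- block(5, 20, 90, 20, 0.2, "IC_BPS", "i")
  oab <- block(5, 1, 1, 1, 3, "OAB", "o")
  ctl <- block(0.5, 1, 1, 1, 0.2, "CONTROL", "c")
  x <- CytokineExperiment(cbind(ic$m, oab$m, ctl$m),
                          rbind(ic$cd, oab$cd, ctl$cd))
  ev <- evaluateCascade(x, defaultCascadeConfig())
  expect_equal(ev$screen_ppv, 100)
  expect_equal(ev$screen_npv, 100)
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$ruleRates$correct_pct, rep(100, 4))
  expect_equal(ev$n_unevaluable, 0)
})

test_that("under label shuffling the screen PPV approaches prevalence", {
  set.seed(71)
  spec <- defaultGeneratorSpec(seed = 72, outlierRate = 0,
                               nPerGroup = c(IC_BPS = 2000, OAB = 2000,
                                             CONTROL = 1500))
  sim <- generateCohort(spec)
  x <- sim$cohort
  # permute group labels uniformly: marker-label association destroyed
  cd <- SummarizedExperiment::colData(x)
  cd$group <- sample(cd$group)
  SummarizedExperiment::colData(x) <- cd
  ev <- evaluateCascade(x, defaultCascadeConfig())
  prevalence <- 100 * 4000 / 5500
  expect_lt(abs(ev$screen_ppv - prevalence), 3)
})

test_that("cascade screen rates equal ROC metrics on identical input", {
  sim <- generateCohort(defaultGeneratorSpec(seed = 73))
  x <- sim$cohort
  ev <- evaluateCascade(x, defaultCascadeConfig())
  grp <- as.character(subjectGroups(x))
  conc <- concentrations(x)
  m <- metricsAtCutoff(conc["MIP-1b", grp != "CONTROL"],
                       conc["MIP-1b", grp == "CONTROL"],
                       1.385, "pos_higher")
  expect_equal(ev$screen_ppv, m$ppv)
  expect_equal(ev$screen_npv, m$npv)
})

test_that("screen rates on a large simulated cohort match the analytic
           lognormal tails", {
  spec <- defaultGeneratorSpec(seed = 74, outlierRate = 0,
                               nPerGroup = c(IC_BPS = 10000, OAB = 10000,
                                             CONTROL = 10000))
  sim <- generateCohort(spec)
  x <- sim$cohort
  grp <- as.character(subjectGroups(x))
  conc <- concentrations(x)
  cut <- 1.385
  tail_p <- function(mean, sd) {
    p <- lognormalParams(mean, sd)
    plnorm(cut, p$mu, p$sigma, lower.tail = FALSE)
  }
  t2 <- publishedFixtures()$groupSummary
  cell <- function(g) t2[t2$marker == "MIP-1b" & t2$group == g, ]
  sens_true <- (tail_p(cell("IC_BPS")$mean, cell("IC_BPS")$sd) +
                  tail_p(cell("OAB")$mean, cell("OAB")$sd)) / 2
  spec_true <- 1 - tail_p(cell("CONTROL")$mean, cell("CONTROL")$sd)
  m <- metricsAtCutoff(conc["MIP-1b", grp != "CONTROL"],
                       conc["MIP-1b", grp == "CONTROL"], cut, "pos_higher")
  se_sens <- sqrt(sens_true * (1 - sens_true) / 20000)
  se_spec <- sqrt(spec_true * (1 - spec_true) / 10000)
  expect_lt(abs(m$sens / 100 - sens_true), 3 * se_sens)
  expect_lt(abs(m$spec / 100 - spec_true), 3 * se_spec)
})

test_that("cascade YAML round trip preserves the rule set", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "screen:", "  marker: MIP-1b", "  cutoff: 2.0", "  label: DISEASED",
    "ic_rules:",
    "  - {marker: Eotaxin, cutoff: 9.035, label: IC_BPS}",
    "oab_rules:",
    "  - {marker: IL-10, cutoff: 1.025, label: OAB}",
    "combiner: single", "on_conflict: prefer_ic"), f)
  cfg <- readCascadeConfig(f)
  expect_equal(cfg@screen$cutoff, 2.0)
  expect_equal(length(cfg@icRules), 1L)
  expect_equal(cfg@combiner, "single")
  expect_equal(cfg@onConflict, "prefer_ic")
})
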