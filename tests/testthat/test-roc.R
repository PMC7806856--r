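test_that("AUC handles separation and ties per the Mann-Whitney definition", {
  expect_equal(rocAuc(c(2, 3), c(0, 1))$auc, 1.0)
  expect_equal(rocAuc(1, 1, direction = "pos_higher")$auc, 0.5)
  # curve endpoints reach (1,0) and (0,1)
  curve <- rocAuc(c(2, 3), c(0, 1))$curve
  expect_equal(curve$sens[1], 1); expect_equal(curve$spec[1], 0)
  expect_equal(curve$sens[nrow(curve)], 0)
  expect_equal(curve$spec[nrow(curve)], 1)
  expect_error(rocAuc(numeric(0), c(1)), "at least one")
})

test_that("AUC equals brute-force pair enumeration", {
  set.seed(20)
  for (i in 1:10) {
    pos <- round(rlnorm(20, 1, 1), 2)   # rounding forces ties
    neg <- round(rlnorm(15, 0.5, 1), 2)
    expect_equal(rocAuc(pos, neg, "pos_higher")$auc,
                 bruteForceAuc(pos, neg), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  pos <- rlnorm(40, 1, 0.6); neg <- rlnorm(30, 0.6, 0.6)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 30)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE)))
  expect_equal(rocAuc(pos, neg, "pos_higher")$auc, ref, tolerance = 1e-12)
})

test_that("direction flip maps AUC to 1 - AUC and swaps sens/spec", {
  set.seed(22)
  pos <- rlnorm(25, 1, 0.5); neg <- rlnorm(25, 1.4, 0.5)
  hi <- rocAuc(pos, neg, "pos_higher")
  lo <- rocAuc(pos, neg, "pos_lower")
  expect_equal(lo$auc, 1 - hi$auc, tolerance = 1e-12)
  # auto picks the orientation with AUC >= 0.5 and records the flip
  auto <- rocAuc(pos, neg, "auto")
  expect_true(auto$auc >= 0.5)
  expect_true(auto$flipped)
  expect_equal(auto$direction, "pos_lower")
  # at a fixed cutoff, flipping exchanges the roles of the two classes
  m_hi <- metricsAtCutoff(pos, neg, 1.2, "pos_higher")
  m_lo <- metricsAtCutoff(neg, pos, 1.2, "pos_lower")
  expect_equal(m_hi$sens, m_lo$spec)
  expect_equal(m_hi$spec, m_lo$sens)
})

test_that("Youden cutoff is the straddling midpoint with stated tie-breaks", {
  # separable case: midpoint of the gap, perfect sens/spec
  oc <- optimalCutoff(c(2, 3, 4), c(0, 1), "pos_higher")
  expect_equal(oc$cutoff, 1.5)
  expect_equal(oc$sens, 1); expect_equal(oc$spec, 1)
  # constructed J tie: exhaustive scan oracle confirms the chosen break
  oc2 <- optimalCutoff(c(1, 3), c(0, 2), "pos_higher")
  oracle <- bruteForceYouden(c(1, 3), c(0, 2))
  expect_equal(oc2$j, oracle$j)
  expect_equal(oc2$sens, oracle$sens)  # tie broken toward sensitivity
  expect_equal(oc2$cutoff, 0.5)
  # optimal J always matches the exhaustive scan
  set.seed(23)
  for (i in 1:10) {
    pos <- round(rlnorm(15, 1, 0.8), 1); neg <- round(rlnorm(12, 0.4, 0.8), 1)
    oc3 <- optimalCutoff(pos, neg, "pos_higher")
    expect_equal(oc3$j, bruteForceYouden(pos, neg)$j, tolerance = 1e-12)
  }
})

test_that("large-sample Gaussian cutoff approaches the midpoint of means", {
  set.seed(24)
  pos <- rnorm(1e5, 1, 1); neg <- rnorm(1e5, 0, 1)
  oc <- optimalCutoff(pos, neg, "pos_higher")
  expect_lt(abs(oc$cutoff - 0.5), 0.1)
})

test_that("metrics at a cutoff satisfy the confusion identities", {
  m <- metricsAtCutoff(c(2, 3), c(0, 1), 1.5, "pos_higher")
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(2, 2, 0, 0))
  expect_equal(c(m$sens, m$spec, m$ppv, m$npv), c(100, 100, 100, 100))
  # degenerate: nothing called positive -> ppv missing, not zero
  m2 <- metricsAtCutoff(c(1, 2), c(0.5, 0.7), 10, "pos_higher")
  expect_equal(m2$tp, 0); expect_equal(m2$fp, 0)
  expect_true(is.na(m2$ppv))
  expect_equal(m2$npv, 50)
  # self-consistency: metrics recomputed from own counts
  set.seed(25)
  pos <- rlnorm(30); neg <- rlnorm(25, -0.5)
  m3 <- metricsAtCutoff(pos, neg, 1, "pos_higher")
  expect_equal(m3$sens, 100 * m3$tp / (m3$tp + m3$fn))
  expect_equal(m3$spec, 100 * m3$tn / (m3$tn + m3$fp))
  expect_equal(m3$ppv, 100 * m3$tp / (m3$tp + m3$fp))
  expect_equal(m3$npv, 100 * m3$tn / (m3$tn + m3$fn))
  expect_equal(m3$tp + m3$fn, 30)
  expect_equal(m3$tn + m3$fp, 25)
})

test_that("counts reconstructed from printed rates reproduce the published
           predictive values", {
  # screening marker: sens 92.2 / spec 44.8 on 77 diseased vs 29 controls
  r <- confusionFromRates(92.2, 44.8, 77, 29)
  expect_equal(c(r$tp, r$tn), c(71, 13))
  expect_equal(round(r$ppv, 1), 81.6)
  expect_equal(round(r$npv, 1), 68.4)
  r2 <- confusionFromRates(61.5, 82.1, 39, 39)
  expect_equal(round(r2$ppv, 1), 77.4)
  r3 <- confusionFromRates(100, 100, 10, 10)
  expect_equal(c(r3$ppv, r3$npv), c(100, 100))
})

test_that("empirical AUC converges to the binormal closed form", {
  set.seed(26)
  mu1 <- 1; mu0 <- 0; s0 <- 1; s1 <- 1; n <- 1e4
  pos <- rnorm(n, mu1, s1); neg <- rnorm(n, mu0, s0)
  target <- pnorm((mu1 - mu0) / sqrt(s0^2 + s1^2))
  # MC standard error of the AUC estimate, conservative bound
  se <- sqrt(target * (1 - target) / n) * 2
  expect_lt(abs(rocAuc(pos, neg, "pos_higher")$auc - target), 3 * se)
})

test_that("per-marker diagnostics table is internally consistent", {
  sim <- generateCohort(defaultGeneratorSpec(seed = 41))
  qc <- applyQC(sim$cohort)
  d <- markerDiagnostics(qc, "ic_vs_oab")
  expect_true(all(d$auc >= 0.5))                     # auto-normalised
  expect_true(!is.unsorted(rev(d$auc)))              # sorted by AUC desc
  # recomputing metrics at the reported cutoffs reproduces each row
  conc <- concentrations(qcCleaned(qc))
  grp <- as.character(subjectGroups(qcCleaned(qc)))
  for (i in sample(nrow(d), 5)) {
    pos <- conc[d$marker[i], grp == "IC_BPS"]
    neg <- conc[d$marker[i], grp == "OAB"]
    m <- metricsAtCutoff(pos[!is.na(pos)], neg[!is.na(neg)],
                         d$cutoff[i], d$direction[i])
    expect_equal(m$sens, d$sens[i])
    expect_equal(m$ppv, d$ppv[i])
  }
})
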