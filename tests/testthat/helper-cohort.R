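# Shared fixtures built in code.

# tiny three-subject cohort covering all three groups
toyCohortCsv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "subject_id,group,age,sex,bmi,dm,MIP-1b,Eotaxin,IL-10,EGF",
    "s1,IC_BPS,45,F,21.5,FALSE,2.9,11.9,0.95,6800",
    "s2,OAB,66,M,26.1,TRUE,3.1,4.6,1.5,5400",
    "s3,CONTROL,58,F,25.2,FALSE,1.2,5.0,1.2,NA"),
    path)
  path
}

# deterministic cohort with prescribed values for a single marker
makeCohort <- function(values_by_group, marker = "MIP-1b") {
  grp <- rep(names(values_by_group), lengths(values_by_group))
  n <- length(grp)
  conc <- matrix(unlist(values_by_group), nrow = 1,
                 dimnames = list(marker, sprintf("s%03d", seq_len(n))))
  cd <- data.frame(group = grp, age = rep(50, n), sex = rep("F", n),
                   bmi = rep(24, n), dm = rep(FALSE, n),
                   row.names = colnames(conc))
  CytokineExperiment(conc, cd)
}

# brute-force AUC oracle: explicit enumeration of all pos x neg pairs
bruteForceAuc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# brute-force Youden scan over a dense threshold grid (observed values and
# midpoints), mirroring the stated tie-breaks
bruteForceYouden <- function(pos, neg, direction = "pos_higher") {
  v <- sort(unique(c(pos, neg)))
  cand <- sort(unique(c(v - 1e-9, v, (v[-length(v)] + v[-1]) / 2,
                        v[1] - 1, v[length(v)] + 1)))
  sens <- spec <- numeric(length(cand))
  for (i in seq_along(cand)) {
    if (direction == "pos_higher") {
      sens[i] <- mean(pos > cand[i]); spec[i] <- mean(neg <= cand[i])
    } else {
      sens[i] <- mean(pos < cand[i]); spec[i] <- mean(neg >= cand[i])
    }
  }
  j <- sens + spec - 1
  best <- order(-j, -sens, cand)[1]
  list(j = j[best], sens = sens[best], spec = spec[best])
}
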