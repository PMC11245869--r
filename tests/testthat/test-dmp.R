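test_that("the unmoderated OLS path matches a per-probe lm oracle exactly", {
  set.seed(81)
  ph <- makePheno(15L, 15L)
  B <- matrix(runif(100 * 30, 0.2, 0.8), 100, 30,
              dimnames = list(sprintf("cg%03d", 1:100), ph$sample_id))
  out <- dmpTest(B, ph, covariates = c("age", "sex"),
                 robust = FALSE, moderate = FALSE)
  grp <- as.numeric(ph$group == "deceased")
  sexN <- as.numeric(factor(ph$sex)) - 1
  for (i in c(1, 7, 23, 50, 100)) {
    fit <- summary(lm(B[i, ] ~ grp + ph$age + sexN))$coefficients
    expect_equal(out$coefficient[i], fit["grp", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(out$t[i], fit["grp", "t value"], tolerance = 1e-10)
    expect_equal(out$p[i], fit["grp", "Pr(>|t|)"], tolerance = 1e-10)
  }
  ## and across all probes via vectorized oracle pieces
  oracleT <- vapply(seq_len(100), function(i)
    summary(lm(B[i, ] ~ grp + ph$age + sexN))$coefficients["grp",
                                                           "t value"],
    numeric(1))
  expect_lt(max(abs(out$t - oracleT)), 1e-8)
})

test_that("the dual DMP rule requires both adjusted p and delta-beta", {
  set.seed(82)
  ph <- makePheno(12L, 12L)
  ## probe 1: no effect; probe 2: tiny but ultra-precise shift (0.03);
  ## probe 3: large, clear shift (0.15)
  dec <- ph$group == "deceased"
  B <- rbind(
    flat = runif(24, 0.4, 0.41),
    tiny = 0.4 + 0.03 * dec + rnorm(24, 0, 0.001),
    big = 0.4 + 0.15 * dec + rnorm(24, 0, 0.02))
  colnames(B) <- ph$sample_id
  out <- dmpTest(B, ph, moderate = FALSE)
  expect_false(out$is_dmp[out$probe_id == "flat"])
  tiny <- out[out$probe_id == "tiny", ]
  expect_lt(tiny$p_bh, 0.05)
  expect_false(tiny$is_dmp)  # delta-beta 0.03 < 0.05 blocks the call
  expect_true(out$is_dmp[out$probe_id == "big"])
  expect_equal(out$delta_beta[out$probe_id == "flat"],
               mean(B["flat", dec]) - mean(B["flat", !dec]))
})

test_that("robust fitting downweights outliers relative to OLS", {
  set.seed(83)
  ph <- makePheno(15L, 15L)
  dec <- ph$group == "deceased"
  y <- 0.4 + 0.08 * dec + rnorm(30, 0, 0.02)
  y[1] <- 0.95  # gross outlier in the survived group
  B <- rbind(p1 = y); colnames(B) <- ph$sample_id
  ols <- dmpTest(B, ph, robust = FALSE, moderate = FALSE)
  rob <- dmpTest(B, ph, robust = TRUE, moderate = FALSE)
  expect_lt(abs(rob$coefficient - 0.08), abs(ols$coefficient - 0.08))
})

test_that("rank-deficient designs are rejected with the aliased column named", {
  ph <- makePheno(6L, 6L)
  ph$dup <- as.numeric(ph$group == "deceased")
  B <- matrix(runif(24, 0.3, 0.7), 2, 12,
              dimnames = list(c("a", "b"), ph$sample_id))
  expect_error(dmpTest(B, ph, covariates = "dup"), "dup")
})

test_that("planted DMPs are recovered with controlled FDR on a synthetic cohort", {
  cfg <- SimulationConfig(nSurvived = 25L, nDeceased = 25L,
                          nProbes = 4000L, nDmp = 50L,
                          dmpDeltaBeta = 0.10, nDvp = 20L,
                          nCellRefProbes = 60L, clockNCpgs = 10L,
                          bimodalFraction = 0, sexChromFraction = 0,
                          flagFraction = 0, seed = 84L)
  ds <- simulateDataset(cfg)
  tr <- probeTruth(ds)
  out <- dmpTest(ds, phenotype(ds),
                 covariates = c("age", "sex", "complications"))
  planted <- tr$probe_id[tr$label == "dmp"]
  called <- out$probe_id[out$is_dmp]
  expect_gte(mean(planted %in% called), 0.8)
  ## clock CpGs carry a real group shift via the latent acceleration,
  ## so only null, cell-reference and bimodal probes count as false
  trueEffect <- tr$probe_id[tr$label %in% c("dmp", "dmr", "clock")]
  expect_lte(mean(!(called %in% trueEffect)), 0.10)
  ## hyper/hypo partition is exhaustive and disjoint
  hyper <- called[out$delta_beta[match(called, out$probe_id)] > 0]
  hypo <- called[out$delta_beta[match(called, out$probe_id)] < 0]
  expect_identical(sort(c(hyper, hypo)), sort(called))
})

test_that("moment-matching moderation recovers the prior and matches limma", {
  dfres <- 18
  ## all variances equal: moderated variances equal the common value
  same <- ebayesModerate(rep(0.04, 50), dfres)
  expect_equal(same$varPost, rep(0.04, 50), tolerance = 1e-6)
  set.seed(85)
  d0 <- 4; s02 <- 0.04
  s2 <- s02 * d0 / rchisq(10000, d0) * rchisq(10000, dfres) / dfres
  mod <- ebayesModerate(s2, dfres)
  expect_lt(abs(mod$dfPrior - d0) / d0, 0.5)
  expect_lt(abs(mod$varPrior - s02) / s02, 0.5)
  ## shrinkage moves every variance toward the prior
  expect_true(all((mod$varPost >= pmin(s2, mod$varPrior) - 1e-12) &
                  (mod$varPost <= pmax(s2, mod$varPrior) + 1e-12)))
  ## independent cross-check against limma's squeezeVar
  sq <- limma::squeezeVar(s2, dfres)
  expect_equal(mod$varPost, sq$var.post, tolerance = 0.02)
  expect_equal(mod$dfPrior, sq$df.prior, tolerance = 0.3)
})

test_that("differential variability calls follow the dual threshold rule", {
  set.seed(86)
  ph <- makePheno(25L, 25L)
  dec <- ph$group == "deceased"
  B <- rbind(
    equal = 0.5 + rnorm(50, 0, 0.03),
    inflated = 0.5 + rnorm(50, 0, ifelse(dec, 0.12, 0.03)),
    constant = rep(0.5, 50))
  colnames(B) <- ph$sample_id
  out <- dvpTest(B, ph)
  expect_false(out$is_dvp[out$probe_id == "equal"])
  infl <- out[out$probe_id == "inflated", ]
  expect_true(infl$is_dvp)
  expect_identical(infl$direction, "hypervariable")
  expect_true(out$degenerate[out$probe_id == "constant"])
  expect_false(out$is_dvp[out$probe_id == "constant"])
})

test_that("a variance ratio exactly at the threshold is not called", {
  ph <- makePheno(5L, 5L)
  sv <- c(-2, -1, 0, 1, 2) * 0.01 + 0.5
  dv <- 0.5 + (sv - 0.5) * 4  # sample variance ratio exactly 16
  B <- rbind(edge = c(sv, dv))
  colnames(B) <- ph$sample_id
  out <- dvpTest(B, ph, vrThreshold = 4)  # |log2 VR| == 4 exactly
  expect_equal(out$log_variance_ratio, 4, tolerance = 1e-12)
  expect_false(out$is_dvp)
})

test_that("planted variance inflation is detected and direction reported", {
  cfg <- SimulationConfig(nSurvived = 25L, nDeceased = 25L,
                          nProbes = 1200L, nDmp = 10L, nDvp = 40L,
                          dvpVarianceRatio = 16, nCellRefProbes = 60L,
                          clockNCpgs = 10L, bimodalFraction = 0,
                          sexChromFraction = 0, flagFraction = 0,
                          seed = 87L)
  ds <- simulateDataset(cfg)
  tr <- probeTruth(ds)
  out <- dvpTest(ds, phenotype(ds))
  planted <- tr$probe_id[tr$label == "dvp"]
  hit <- out$is_dvp[match(planted, out$probe_id)]
  expect_gte(mean(hit), 0.85)
  expect_true(all(out$direction[match(planted[hit], out$probe_id)] ==
                  "hypervariable"))
})
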