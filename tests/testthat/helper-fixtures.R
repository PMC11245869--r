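# Shared fixtures: all data built in code at test time.

# Small but structurally complete simulation config.
smallConfig <- function(seed = 1L, ...) {
  args <- list(nProbes = 800L, nDmp = 20L, nDvp = 20L,
               nDmrRegions = 2L, dmrProbesPerRegion = 4L,
               nCellRefProbes = 60L, clockNCpgs = 10L,
               bimodalFraction = 0, sexChromFraction = 0,
               flagFraction = 0, probeFailFraction = 0,
               seed = as.integer(seed))
  args[names(list(...))] <- list(...)
  do.call(SimulationConfig, args)
}

# Phenotype sheet for inference tests, no methylation attached. The
# first two samples pin both sexes and complication levels so the
# reference design is always full rank.
makePheno <- function(nSurvived = 27L, nDeceased = 23L) {
  n <- nSurvived + nDeceased
  ph <- data.frame(
    sample_id = sprintf("P%03d", seq_len(n)),
    group = rep(c("survived", "deceased"), c(nSurvived, nDeceased)),
    age = stats::rnorm(n, 65, 5),
    sex = sample(c("F", "M"), n, replace = TRUE),
    complications = stats::rbinom(n, 1, 0.3),
    stringsAsFactors = FALSE)
  ph$sex[1:2] <- c("F", "M")
  ph$complications[1:3] <- c(0L, 1L, 0L)
  ph
}

# Matched cohort: each deceased sample shares its baseline covariates
# with a survived partner (plus a few unmatched survivors), emulating a
# propensity-matched case-control design with balanced risk factors.
makeMatchedPheno <- function(nPairs = 23L, nExtraSurvived = 4L) {
  covs <- data.frame(age = stats::rnorm(nPairs, 65, 5),
                     sex = sample(c("F", "M"), nPairs, TRUE),
                     complications = stats::rbinom(nPairs, 1, 0.3),
                     stringsAsFactors = FALSE)
  covs$sex[1:2] <- c("F", "M")
  covs$complications[1:2] <- c(0L, 1L)
  extra <- data.frame(age = stats::rnorm(nExtraSurvived, 65, 5),
                      sex = sample(c("F", "M"), nExtraSurvived, TRUE),
                      complications = stats::rbinom(nExtraSurvived, 1,
                                                    0.3),
                      stringsAsFactors = FALSE)
  ph <- rbind(cbind(group = "survived", rbind(covs, extra)),
              cbind(group = "deceased", covs))
  ph$sample_id <- sprintf("P%03d", seq_len(nrow(ph)))
  ph
}

# Estimator generated from the survivor reference model:
# est = b_age*age + b_sex*sex + b_compl*compl + noise, identically in
# both groups (null) unless shifted.
makeNullEstimate <- function(ph, bAge = 1, bSex = 1, bCompl = 2,
                             sigma = 2.5) {
  est <- bAge * ph$age + bSex * (ph$sex == "M") +
    bCompl * ph$complications + stats::rnorm(nrow(ph), 0, sigma)
  stats::setNames(est, ph$sample_id)
}

# Independent brute-force Cox partial log-likelihood (Breslow-free:
# assumes no tied event times), for the grid-search oracle.
coxPartialLogLik <- function(b, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll
}
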