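## Synthetic methylation cohort generator.
##
## Probe-level structure (layout) and sample-level structure are drawn
## from independent substreams of the master seed, so that
## makeToyClock(config) can rebuild the exact clock embedded in
## simulateDataset(config) without regenerating the cohort.

.CHROMS <- c(paste0("chr", 1:22), "chrX", "chrY")

## Gauss-Hermite expectation of f(mu + sd*Z), Z ~ N(0,1).
.ghExpect <- function(f, mu, sd, gh) {
  drop(gh$w %*% f(mu + sd * sqrt(2) * gh$x)) / sqrt(pi)
}

## Solve the M-scale shift whose induced beta-scale mean difference
## equals `target` (signed), accounting for the Gaussian M noise.
.solveDeltaM <- function(mu, sd, target, gh) {
  base <- .ghExpect(expit2, mu, sd, gh)
  g <- function(d) .ghExpect(expit2, mu + d, sd, gh) - base - target
  lo <- -25; hi <- 25
  if (g(lo) * g(hi) > 0) .stopf("delta-beta target %.3f unreachable", target)
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

## Probe-level layout: ids, coordinates, annotation, planted-probe
## assignment and per-probe generative parameters.
.simLayout <- function(config) {
  .withSeed(.subSeed(config@seed, "layout"), {
    P <- config@nProbes
    ids <- sprintf("cg%07d", seq_len(P))

    nSex <- round(config@sexChromFraction * P)
    chromPool <- c(sample(paste0("chr", 1:22), P - nSex, replace = TRUE),
                   sample(c("chrX", "chrY"), nSex, replace = TRUE))
    chrom <- factor(chromPool, levels = .CHROMS)
    ord <- order(as.integer(chrom))
    chrom <- chrom[ord]

    ## lognormal inter-probe gaps give CpG-island-like clustering
    gaps <- pmax(10, round(stats::rlnorm(P, log(300), 1.2)))

    label <- rep("null", P)
    regionId <- rep(NA_integer_, P)
    autosomal <- which(as.integer(chrom) <= 22L)

    ## contiguous region probes: runs of k autosomal probes on one chrom,
    ## gaps overridden so each region spans <= dmrSpanBp
    k <- config@dmrProbesPerRegion
    if (config@nDmrRegions > 0L && k >= 2L) {
      runStarts <- integer(0)
      chromInt <- as.integer(chrom)
      eligible <- which(seq_len(P) <= P - k + 1L)
      eligible <- eligible[chromInt[eligible] <= 22L &
                           chromInt[eligible] == chromInt[eligible + k - 1L]]
      for (r in seq_len(config@nDmrRegions)) {
        ok <- eligible[vapply(eligible, function(s)
          all(label[s:(s + k - 1L)] == "null"), logical(1))]
        if (!length(ok))
          .stopf("probe budget infeasible: cannot place region %d", r)
        s <- sample(ok, 1)
        idx <- s:(s + k - 1L)
        label[idx] <- "dmr"
        regionId[idx] <- r
        gaps[idx[-1]] <- max(10L, floor(config@dmrSpanBp / (k - 1L)))
        runStarts <- c(runStarts, s)
      }
    }

    pick <- function(n, lab) {
      free <- intersect(which(label == "null"), autosomal)
      if (length(free) < n)
        .stopf("probe budget infeasible: %d '%s' probes requested", n, lab)
      idx <- sample(free, n)
      label[idx] <<- lab
      idx
    }
    nBimodal <- ceiling(config@bimodalFraction * P)
    idxDmp <- pick(config@nDmp, "dmp")
    idxDvp <- pick(config@nDvp, "dvp")
    idxClock <- pick(config@clockNCpgs, "clock")
    idxCellRef <- pick(config@nCellRefProbes, "cellref")
    idxBimodal <- pick(nBimodal, "bimodal")

    ## positions: cumulative gaps within chromosome
    pos <- integer(P)
    for (ch in levels(chrom)) {
      i <- which(chrom == ch)
      if (length(i)) pos[i] <- 10000L + cumsum(gaps[i])
    }

    ## baseline M-value means from the canonical bimodal methylome
    comp <- sample(1:3, P, replace = TRUE, prob = c(0.35, 0.35, 0.30))
    mu <- c(stats::rnorm(P, -2.5, 0.7), stats::rnorm(P, 2.5, 0.7),
            stats::rnorm(P, 0, 1))[(comp - 1L) * P + seq_len(P)]
    sdM <- stats::runif(P, 0.15, 0.35)
    ## planted-probe baselines overridden below as needed
    mu[idxDmp] <- logit2(stats::runif(length(idxDmp), 0.20, 0.70))
    idxDmrAll <- which(label == "dmr")
    mu[idxDmrAll] <- logit2(stats::runif(length(idxDmrAll), 0.25, 0.65))

    gh <- pracma::gaussHermite(21)
    dmpSign <- rep_len(c(1, -1), length(idxDmp))
    dmpDeltaM <- mapply(function(m, s, sg)
      .solveDeltaM(m, s, sg * config@dmpDeltaBeta, gh),
      mu[idxDmp], sdM[idxDmp], dmpSign)
    dmrSign <- rep_len(c(1, -1), config@nDmrRegions)
    dmrDeltaM <- numeric(P)
    for (i in idxDmrAll)
      dmrDeltaM[i] <- .solveDeltaM(mu[i], sdM[i],
                                   dmrSign[regionId[i]] * config@dmrDeltaBeta,
                                   gh)

    ## beta-linear probe families
    dvpMean <- stats::runif(length(idxDvp), 0.30, 0.70)
    dvpSd0 <- 0.02
    clockMean <- stats::runif(length(idxClock), 0.35, 0.65)
    clockSlope <- sample(c(-1, 1), length(idxClock), replace = TRUE) *
      stats::runif(length(idxClock), 0.008, 0.012)
    cellTypes <- c("CD8naive", "CD4T", "CD8pCD28nCD45RAn", "NK",
                   "Gran", "PlasmaBlast")[seq_len(config@nCellTypes)]
    if (length(cellTypes) < config@nCellTypes)
      cellTypes <- c(cellTypes,
                     paste0("CellType", seq_len(config@nCellTypes -
                                                length(cellTypes))))
    cellRef <- matrix(pmin(pmax(stats::rbeta(length(idxCellRef) *
                                             config@nCellTypes, 0.5, 0.5),
                                0.05), 0.95),
                      nrow = length(idxCellRef),
                      ncol = config@nCellTypes,
                      dimnames = list(ids[ord][idxCellRef], cellTypes))

    ## exclusion flags and engineered detection failures on null probes
    flags <- matrix(FALSE, P, length(.flagCols),
                    dimnames = list(NULL, .flagCols))
    flags[, "on_sex_chromosome"] <- as.integer(chrom) > 22L
    nullAuto <- intersect(which(label == "null"), autosomal)
    for (fc in setdiff(.flagCols, "on_sex_chromosome")) {
      nf <- round(config@flagFraction * P)
      if (nf > 0 && length(nullAuto))
        flags[sample(nullAuto, min(nf, length(nullAuto))), fc] <- TRUE
    }
    flagged <- rowSums(flags) > 0
    failCand <- setdiff(nullAuto, which(flagged))
    nPF <- round(config@probeFailFraction * P)
    idxProbeFail <- if (nPF > 0 && length(failCand))
      sample(failCand, min(nPF, length(failCand))) else integer(0)

    ## gene / genic-feature annotation
    nGenes <- max(20L, P %/% 5L)
    genic <- stats::runif(P) < 0.85
    gene <- ifelse(genic, sprintf("G%05d", sample.int(nGenes, P, TRUE)),
                   NA_character_)
    feature <- ifelse(genic,
                      sample(c("TSS1500", "TSS200", "5'UTR", "1stExon",
                               "Body", "3'UTR"),
                             P, TRUE,
                             prob = c(.18, .12, .14, .08, .42, .06)),
                      "intergenic")

    list(ids = ids[ord], chrom = as.character(chrom), pos = pos,
         label = label, regionId = regionId,
         mu = mu, sdM = sdM,
         idxDmp = idxDmp, dmpSign = dmpSign, dmpDeltaM = dmpDeltaM,
         idxDmrAll = idxDmrAll, dmrSign = dmrSign, dmrDeltaM = dmrDeltaM,
         idxDvp = idxDvp, dvpMean = dvpMean, dvpSd0 = dvpSd0,
         idxClock = idxClock, clockMean = clockMean,
         clockSlope = clockSlope,
         idxCellRef = idxCellRef, cellRef = cellRef,
         cellTypes = cellTypes,
         idxBimodal = idxBimodal,
         idxProbeFail = idxProbeFail, flags = flags,
         gene = gene, feature = feature)
  })
}

## Sample-level structure: nested case-control selection from a latent
## pool whose survival follows the exponential hazard
## rate_i = baselineHazard * exp(hazardPerAccelUnit * accel_i).
.simSamples <- function(config, layout) {
  .withSeed(.subSeed(config@seed, "samples"), {
    ns <- config@nSurvived; nd <- config@nDeceased
    nf <- config@nFailedSamples
    n <- ns + nd + nf
    poolN <- max(400L, 10L * n)
    accel <- stats::rnorm(poolN, 0, config@accelSd)
    rate <- config@baselineHazard * exp(config@hazardPerAccelUnit * accel)
    tt <- stats::rexp(poolN, rate)
    event <- tt <= config@followupYears
    if (sum(event) < nd || sum(!event) < ns + nf)
      .stopf(paste0("infeasible configuration: latent pool yielded %d ",
                    "events / %d survivors for %d / %d requested"),
             sum(event), sum(!event), nd, ns)
    iDec <- sample(which(event), nd)
    iSur <- sample(which(!event), ns)
    iFail <- sample(setdiff(which(!event), iSur), nf)
    sel <- c(iSur, iDec, iFail)
    n <- length(sel)
    grp <- c(rep("survived", ns), rep("deceased", nd),
             rep("survived", nf))
    ph <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      group = grp,
      age = round(stats::rnorm(n, 67, 2.5)),
      sex = sample(c("F", "M"), n, TRUE),
      complications = stats::rbinom(n, 1, 0.3),
      hba1c = round(stats::rnorm(n, 7.1, 0.5), 2),
      egfr = round(stats::rnorm(n, 82, 12), 1),
      hscrp = round(exp(stats::rnorm(n, log(2.3), 0.55)), 2),
      ldl = round(stats::rnorm(n, 115, 22), 1),
      duration = pmax(1, round(stats::rnorm(n, 15, 7))),
      bmi = round(stats::rnorm(n, 27.5, 2.8), 1),
      hypertension = stats::rbinom(n, 1, 0.6),
      smoking = stats::rbinom(n, 1, 0.25),
      batch = NA_integer_,
      followup_time = ifelse(grp == "deceased", tt[sel],
                             config@followupYears),
      event = as.integer(grp == "deceased"),
      qc_fail = c(rep(FALSE, ns + nd), rep(TRUE, nf)),
      stringsAsFactors = FALSE)
    ## balanced batch assignment within group
    for (g in unique(ph$group)) {
      i <- which(ph$group == g)
      ph$batch[i] <- rep_len(seq_len(config@batchLevels), length(i))
    }
    ## Dirichlet cell fractions
    a <- config@dirichletAlpha
    gm <- matrix(stats::rgamma(n * length(a), shape = rep(a, each = n)),
                 nrow = n)
    fr <- gm / rowSums(gm)
    colnames(fr) <- layout$cellTypes
    list(phenotype = ph, accel = accel[sel], cellFractions = fr)
  })
}

#' Simulate a seeded synthetic methylation cohort
#'
#' Generates a full [DnamExperiment-class] with the statistical
#' structure the downstream pipeline assumes: logistic-transformed
#' Gaussian M-value betas with a bimodal baseline methylome; planted
#' group-mean shifts calibrated on the beta scale; variance-inflated
#' probes; contiguous region effects with shared per-sample deviations;
#' two-mode probes; Dirichlet cell composition mixed into a
#' cell-discriminating probe set; balanced batch effects; detection
#' p-values with configurable failures; and exponential survival times
#' whose log-hazard is linear in a latent acceleration that also drives
#' the toy clock's CpGs. Identical config (including seed) gives
#' byte-identical output.
#'
#' @param config a [SimulationConfig-class].
#' @return A [DnamExperiment-class] with `beta`, `detp`, `meth` and
#'   `unmeth` assays, annotated probes, the phenotype sheet as
#'   `colData`, and generator truth (see [probeTruth()],
#'   [sampleTruth()], [toyClock()], [cellReference()]) in `metadata()`.
#' @examples
#' ds <- simulateDataset(SimulationConfig(nProbes = 1000L, seed = 1L))
#' ds
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  layout <- .simLayout(config)
  samp <- .simSamples(config, layout)
  ph <- samp$phenotype
  n <- nrow(ph)
  P <- config@nProbes

  beta <- .withSeed(.subSeed(config@seed, "beta"), {
    dec <- ph$group == "deceased"
    ## logistic M-value backbone
    M <- matrix(stats::rnorm(P * n), P, n) * layout$sdM + layout$mu
    ## balanced batch wobble on null probes only (planted and clock
    ## probes stay exactly calibrated)
    if (config@batchLevels > 1L) {
      nullIdx <- which(layout$label == "null")
      bEff <- matrix(stats::rnorm(length(nullIdx) * config@batchLevels,
                                  0, 0.05),
                     ncol = config@batchLevels)
      M[nullIdx, ] <- M[nullIdx, ] + bEff[, ph$batch]
    }
    if (length(layout$idxDmp))
      M[layout$idxDmp, dec] <- M[layout$idxDmp, dec] + layout$dmpDeltaM
    if (length(layout$idxDmrAll)) {
      for (r in seq_len(config@nDmrRegions)) {
        i <- which(layout$regionId == r)
        ## shared per-sample deviation induces spatial autocorrelation
        u <- stats::rnorm(n, 0, 0.35)
        M[i, ] <- M[i, ] + rep(u, each = length(i))
        M[i, dec] <- M[i, dec] + layout$dmrDeltaM[i]
      }
    }
    B <- expit2(M)
    ## beta-linear families
    if (length(layout$idxDvp)) {
      sd1 <- layout$dvpSd0 * sqrt(config@dvpVarianceRatio)
      sds <- ifelse(dec, sd1, layout$dvpSd0)
      B[layout$idxDvp, ] <- layout$dvpMean +
        matrix(stats::rnorm(length(layout$idxDvp) * n), ncol = n) *
        rep(sds, each = length(layout$idxDvp))
    }
    if (length(layout$idxClock))
      B[layout$idxClock, ] <- layout$clockMean +
        outer(layout$clockSlope, samp$accel) +
        matrix(stats::rnorm(length(layout$idxClock) * n, 0,
                            config@clockProbeNoiseSd), ncol = n)
    if (length(layout$idxCellRef))
      B[layout$idxCellRef, ] <- layout$cellRef %*% t(samp$cellFractions) +
        matrix(stats::rnorm(length(layout$idxCellRef) * n, 0, 0.01),
               ncol = n)
    if (length(layout$idxBimodal)) {
      mode <- matrix(stats::rbinom(length(layout$idxBimodal) * n, 1, 0.5),
                     ncol = n)
      B[layout$idxBimodal, ] <- 0.2 + 0.6 * mode +
        matrix(stats::rnorm(length(layout$idxBimodal) * n, 0, 0.05),
               ncol = n)
    }
    .clampBeta(B)
  })
  dimnames(beta) <- list(layout$ids, ph$sample_id)

  extras <- .withSeed(.subSeed(config@seed, "aux"), {
    detp <- matrix(stats::runif(P * n, 0, 0.008), P, n)
    if (config@nFailedSamples > 0L)
      detp[, ph$qc_fail] <- stats::runif(P * sum(ph$qc_fail), 0.05, 0.4)
    for (i in layout$idxProbeFail) {
      j <- sample(which(!ph$qc_fail), sample(1:2, 1))
      detp[i, j] <- stats::runif(length(j), 0.02, 0.1)
    }
    total <- matrix(stats::rgamma(P * n, shape = 10, scale = 300), P, n)
    meth <- pmin(beta * (total + 100), total)
    unmeth <- total - meth
    miss <- NULL
    if (config@missingFraction > 0)
      miss <- which(matrix(stats::runif(P * n) < config@missingFraction,
                           P, n))
    list(detp = detp, meth = meth, unmeth = unmeth, miss = miss)
  })
  if (!is.null(extras$miss)) beta[extras$miss] <- NA_real_
  dimnames(extras$detp) <- dimnames(beta)

  ann <- data.frame(probe_id = layout$ids, chrom = layout$chrom,
                    position = layout$pos, gene = layout$gene,
                    feature = layout$feature,
                    stringsAsFactors = FALSE)
  ann <- cbind(ann, as.data.frame(layout$flags))

  probeTr <- data.frame(
    probe_id = layout$ids, label = layout$label,
    region_id = layout$regionId,
    true_delta_beta = 0, true_log2_vr = 0,
    stringsAsFactors = FALSE)
  probeTr$true_delta_beta[layout$idxDmp] <-
    layout$dmpSign * config@dmpDeltaBeta
  probeTr$true_delta_beta[layout$idxDmrAll] <-
    layout$dmrSign[layout$regionId[layout$idxDmrAll]] * config@dmrDeltaBeta
  probeTr$true_log2_vr[layout$idxDvp] <- log2(config@dvpVarianceRatio)

  sampleTr <- data.frame(sample_id = ph$sample_id, accel = samp$accel,
                         stringsAsFactors = FALSE)
  sampleTr <- cbind(sampleTr, as.data.frame(samp$cellFractions))

  clock <- .buildToyClock(config, layout)

  DnamExperiment(beta, phenotype = ph, annotation = ann,
                 detp = extras$detp, meth = extras$meth,
                 unmeth = extras$unmeth,
                 metadata = list(
                   config = config,
                   truth = list(probes = probeTr, samples = sampleTr,
                                clock = clock,
                                cellReference = layout$cellRef)))
}

.buildToyClock <- function(config, layout) {
  w <- layout$clockSlope / sum(layout$clockSlope^2)
  names(w) <- layout$ids[layout$idxClock]
  ## clock value = 67 + accel (+ noise): an affine readout of the
  ## latent acceleration anchored at the cohort mean age
  ClockModel(name = "toyAccelClock",
             intercept = 67 - sum(w * layout$clockMean),
             coefficients = w, transform = "identity",
             missingPolicy = "error")
}

#' Rebuild the toy clock embedded in a simulated dataset
#'
#' Deterministic given the config: returns the same [ClockModel-class]
#' that [simulateDataset()] stores in the dataset's truth metadata. Its
#' value on a sample equals `67 + accel` plus probe noise scaled by
#' `clockProbeNoiseSd` (exactly affine in the latent acceleration when
#' that noise is zero).
#'
#' @param config a [SimulationConfig-class] with
#'   `clockNCpgs <= nProbes`.
#' @return A [ClockModel-class] referencing existing probe ids.
#' @export
makeToyClock <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .buildToyClock(config, .simLayout(config))
}
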