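#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData rowRanges
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
NULL

## ---------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------

#' Configuration for the synthetic methylation cohort generator
#'
#' Holds every knob of [simulateDataset()]: cohort composition, probe
#' budget, planted differential-methylation / differential-variability /
#' region effects, bimodal probes, cell-composition structure, batch
#' structure, the toy clock, and the survival model. Defaults emulate a
#' matched type-2-diabetes cohort of 27 survivors and 23 deceased
#' followed for 16.8 years on an EPIC-like array.
#'
#' @slot nSurvived,nDeceased samples per group.
#' @slot nProbes total probes on the simulated array.
#' @slot nDmp number of planted differentially methylated positions.
#' @slot dmpDeltaBeta target group-mean difference on the beta scale.
#' @slot nDvp number of planted differentially variable positions.
#' @slot dvpVarianceRatio deceased/survived variance ratio at DVP probes
#'   (on the beta scale).
#' @slot nDmrRegions,dmrProbesPerRegion,dmrSpanBp,dmrDeltaBeta planted
#'   region effects: count, probes per region, genomic span (bp), and
#'   per-probe beta shift.
#' @slot bimodalFraction fraction of probes given a two-mode
#'   across-sample mixture (0.2/0.8 modes).
#' @slot nCellTypes,dirichletAlpha,nCellRefProbes cell-composition
#'   structure: number of blood cell types, Dirichlet concentration for
#'   per-sample fractions, and number of cell-discriminating probes.
#' @slot batchLevels number of array batches (balanced across groups).
#' @slot clockNCpgs,clockProbeNoiseSd probes driven linearly (beta
#'   scale) by the latent acceleration, and their residual noise.
#' @slot accelSd standard deviation (years) of the latent age
#'   acceleration.
#' @slot hazardPerAccelUnit log-hazard slope per year of acceleration.
#' @slot baselineHazard baseline event rate per year.
#' @slot followupYears administrative censoring time.
#' @slot nFailedSamples extra samples engineered to fail sample QC.
#' @slot probeFailFraction fraction of probes given a detection p-value
#'   > 0.01 in at least one sample.
#' @slot sexChromFraction fraction of probes placed on chrX/chrY.
#' @slot flagFraction per-category rate of exclusion-list flags.
#' @slot missingFraction fraction of beta cells set missing.
#' @slot seed master integer seed; all substreams derive from it.
#'
#' @seealso [SimulationConfig()], [simulateDataset()]
#' @export
setClass("SimulationConfig",
  representation(
    nSurvived = "integer", nDeceased = "integer", nProbes = "integer",
    nDmp = "integer", dmpDeltaBeta = "numeric",
    nDvp = "integer", dvpVarianceRatio = "numeric",
    nDmrRegions = "integer", dmrProbesPerRegion = "integer",
    dmrSpanBp = "integer", dmrDeltaBeta = "numeric",
    bimodalFraction = "numeric",
    nCellTypes = "integer", dirichletAlpha = "numeric",
    nCellRefProbes = "integer",
    batchLevels = "integer",
    clockNCpgs = "integer", clockProbeNoiseSd = "numeric",
    accelSd = "numeric",
    hazardPerAccelUnit = "numeric", baselineHazard = "numeric",
    followupYears = "numeric",
    nFailedSamples = "integer", probeFailFraction = "numeric",
    sexChromFraction = "numeric", flagFraction = "numeric",
    missingFraction = "numeric",
    seed = "integer"
  ),
  prototype(
    nSurvived = 27L, nDeceased = 23L, nProbes = 20000L,
    nDmp = 50L, dmpDeltaBeta = 0.10,
    nDvp = 50L, dvpVarianceRatio = 16,
    nDmrRegions = 5L, dmrProbesPerRegion = 5L,
    dmrSpanBp = 500L, dmrDeltaBeta = 0.08,
    bimodalFraction = 0.01,
    nCellTypes = 6L,
    dirichletAlpha = c(3, 9, 1.5, 2.5, 13, 1),
    nCellRefProbes = 200L,
    batchLevels = 2L,
    clockNCpgs = 30L, clockProbeNoiseSd = 0.02,
    accelSd = 5,
    hazardPerAccelUnit = 0.1, baselineHazard = 0.03,
    followupYears = 16.8,
    nFailedSamples = 0L, probeFailFraction = 0,
    sexChromFraction = 0.02, flagFraction = 0.005,
    missingFraction = 0,
    seed = 1L
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(nSurvived = object@nSurvived, nDeceased = object@nDeceased,
           nProbes = object@nProbes, nDmp = object@nDmp,
           nDvp = object@nDvp, nDmrRegions = object@nDmrRegions,
           dmrProbesPerRegion = object@dmrProbesPerRegion,
           nCellTypes = object@nCellTypes,
           nCellRefProbes = object@nCellRefProbes,
           batchLevels = object@batchLevels,
           clockNCpgs = object@clockNCpgs,
           nFailedSamples = object@nFailedSamples)
  if (any(cnt < 0L)) msg <- c(msg, "all counts must be >= 0")
  if (!(object@dmpDeltaBeta > 0 && object@dmpDeltaBeta < 1))
    msg <- c(msg, "dmpDeltaBeta must lie in (0,1)")
  if (object@dvpVarianceRatio <= 0)
    msg <- c(msg, "dvpVarianceRatio must be positive")
  if (any(object@dirichletAlpha <= 0))
    msg <- c(msg, "dirichletAlpha must be positive")
  if (length(object@dirichletAlpha) != object@nCellTypes)
    msg <- c(msg, "dirichletAlpha length must equal nCellTypes")
  if (object@nCellTypes < 2L) msg <- c(msg, "need >= 2 cell types")
  nSpecial <- object@nDmp + object@nDvp +
    object@nDmrRegions * object@dmrProbesPerRegion +
    object@clockNCpgs + object@nCellRefProbes +
    ceiling(object@bimodalFraction * object@nProbes)
  if (nSpecial > object@nProbes)
    msg <- c(msg, sprintf(
      "probe budget infeasible: %d special probes requested but nProbes = %d",
      nSpecial, object@nProbes))
  if (object@followupYears <= 0) msg <- c(msg, "followupYears must be > 0")
  if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nSurvived,nDeceased group sizes (defaults 27 and 23).
#' @param nProbes total probes (default 20000).
#' @param nDmp,dmpDeltaBeta planted DMP count and target beta-scale
#'   group difference (defaults 50 and 0.10).
#' @param nDvp,dvpVarianceRatio planted DVP count and variance ratio
#'   (defaults 50 and 16).
#' @param nDmrRegions,dmrProbesPerRegion,dmrSpanBp,dmrDeltaBeta planted
#'   region structure.
#' @param bimodalFraction fraction of two-mode probes.
#' @param nCellTypes,dirichletAlpha,nCellRefProbes cell-composition
#'   structure.
#' @param batchLevels array batches.
#' @param clockNCpgs,clockProbeNoiseSd,accelSd toy-clock structure.
#' @param hazardPerAccelUnit,baselineHazard,followupYears survival model.
#' @param nFailedSamples,probeFailFraction,sexChromFraction,
#'   flagFraction,missingFraction QC-failure structure.
#' @param seed master seed.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(nProbes = 2000L, seed = 7L)
#' @export
SimulationConfig <- function(nSurvived = 27L, nDeceased = 23L,
                             nProbes = 20000L,
                             nDmp = 50L, dmpDeltaBeta = 0.10,
                             nDvp = 50L, dvpVarianceRatio = 16,
                             nDmrRegions = 5L, dmrProbesPerRegion = 5L,
                             dmrSpanBp = 500L, dmrDeltaBeta = 0.08,
                             bimodalFraction = 0.01,
                             nCellTypes = 6L,
                             dirichletAlpha = c(3, 9, 1.5, 2.5, 13, 1),
                             nCellRefProbes = 200L,
                             batchLevels = 2L,
                             clockNCpgs = 30L, clockProbeNoiseSd = 0.02,
                             accelSd = 5,
                             hazardPerAccelUnit = 0.1,
                             baselineHazard = 0.03,
                             followupYears = 16.8,
                             nFailedSamples = 0L, probeFailFraction = 0,
                             sexChromFraction = 0.02,
                             flagFraction = 0.005,
                             missingFraction = 0,
                             seed = 1L) {
  if (length(dirichletAlpha) == 1L)
    dirichletAlpha <- rep(dirichletAlpha, nCellTypes)
  new("SimulationConfig",
      nSurvived = as.integer(nSurvived), nDeceased = as.integer(nDeceased),
      nProbes = as.integer(nProbes),
      nDmp = as.integer(nDmp), dmpDeltaBeta = dmpDeltaBeta,
      nDvp = as.integer(nDvp), dvpVarianceRatio = dvpVarianceRatio,
      nDmrRegions = as.integer(nDmrRegions),
      dmrProbesPerRegion = as.integer(dmrProbesPerRegion),
      dmrSpanBp = as.integer(dmrSpanBp), dmrDeltaBeta = dmrDeltaBeta,
      bimodalFraction = bimodalFraction,
      nCellTypes = as.integer(nCellTypes),
      dirichletAlpha = dirichletAlpha,
      nCellRefProbes = as.integer(nCellRefProbes),
      batchLevels = as.integer(batchLevels),
      clockNCpgs = as.integer(clockNCpgs),
      clockProbeNoiseSd = clockProbeNoiseSd,
      accelSd = accelSd,
      hazardPerAccelUnit = hazardPerAccelUnit,
      baselineHazard = baselineHazard,
      followupYears = followupYears,
      nFailedSamples = as.integer(nFailedSamples),
      probeFailFraction = probeFailFraction,
      sexChromFraction = sexChromFraction,
      flagFraction = flagFraction,
      missingFraction = missingFraction,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  cohort: %d survived + %d deceased (+%d QC failures), %d probes\n",
              object@nSurvived, object@nDeceased, object@nFailedSamples,
              object@nProbes))
  cat(sprintf("  planted: %d DMP (d-beta %.3f), %d DVP (VR %.1f), %d regions x %d probes\n",
              object@nDmp, object@dmpDeltaBeta, object@nDvp,
              object@dvpVarianceRatio, object@nDmrRegions,
              object@dmrProbesPerRegion))
  cat(sprintf("  clock: %d CpGs, accel sd %.1f y; hazard %.3f/y x exp(%.2f accel)\n",
              object@clockNCpgs, object@accelSd, object@baselineHazard,
              object@hazardPerAccelUnit))
  cat(sprintf("  seed: %d\n", object@seed))
})

## ---------------------------------------------------------------------
## DnamExperiment
## ---------------------------------------------------------------------

#' Container for a methylation cohort
#'
#' A [RangedSummarizedExperiment][SummarizedExperiment::RangedSummarizedExperiment-class]
#' holding a `beta` assay (probes x samples methylation fractions),
#' optional `detp`, `meth` and `unmeth` assays, probe annotation as
#' `rowRanges` (with `gene`, `feature` and exclusion-flag columns), and
#' the sample phenotype sheet as `colData`. Generator truth (planted
#' probe labels, latent acceleration, true cell fractions, the toy
#' clock and cell reference) lives in `metadata()`.
#'
#' @export
setClass("DnamExperiment", contains = "RangedSummarizedExperiment")

setValidity("DnamExperiment", function(object) {
  msg <- character()
  if (!"beta" %in% assayNames(object))
    msg <- c(msg, "a 'beta' assay is required")
  else {
    b <- assay(object, "beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta values must lie in [0,1] or be missing")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

.featureVocab <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                   "3'UTR", "intergenic")
.flagCols <- c("on_sex_chromosome", "maps_to_snp", "cross_reactive",
               "non_specific", "variant_containing", "masked")

#' Construct a DnamExperiment
#'
#' @param beta probes x samples matrix of methylation fractions.
#' @param phenotype data.frame of per-sample covariates; rows matched to
#'   `colnames(beta)` via a `sample_id` column or rownames.
#' @param annotation data.frame of probe annotation with columns
#'   `probe_id`, `chrom`, `position` (1-based), `gene`, `feature`, and
#'   logical flag columns; rows matched to `rownames(beta)`.
#' @param detp,meth,unmeth optional matrices conformable with `beta`.
#' @param metadata list stored in `metadata()`.
#' @return A [DnamExperiment-class].
#' @export
DnamExperiment <- function(beta, phenotype = NULL, annotation = NULL,
                           detp = NULL, meth = NULL, unmeth = NULL,
                           metadata = list()) {
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    .stopf("beta matrix must carry probe rownames and sample colnames")
  assays <- list(beta = beta)
  for (nm in c("detp", "meth", "unmeth")) {
    m <- get(nm)
    if (!is.null(m)) {
      if (!identical(dim(m), dim(beta)))
        .stopf("'%s' matrix is not conformable with beta", nm)
      dimnames(m) <- dimnames(beta)
      assays[[nm]] <- m
    }
  }
  if (is.null(annotation)) {
    rr <- GRanges(rep("chrUn", nrow(beta)),
                  IRanges(seq_len(nrow(beta)), width = 1L))
    names(rr) <- rownames(beta)
  } else {
    idx <- match(rownames(beta), annotation$probe_id)
    if (anyNA(idx))
      .stopf("annotation missing probes: %s",
             paste(head(rownames(beta)[is.na(idx)], 5), collapse = ", "))
    ann <- annotation[idx, , drop = FALSE]
    rr <- GRanges(ann$chrom, IRanges(ann$position, width = 1L))
    names(rr) <- ann$probe_id
    extra <- setdiff(colnames(ann), c("probe_id", "chrom", "position"))
    S4Vectors::mcols(rr) <- DataFrame(ann[, extra, drop = FALSE])
  }
  if (is.null(phenotype)) {
    cd <- DataFrame(row.names = colnames(beta))
  } else {
    key <- if ("sample_id" %in% colnames(phenotype))
      phenotype$sample_id else rownames(phenotype)
    idx <- match(colnames(beta), key)
    if (anyNA(idx))
      .stopf("phenotype missing samples: %s",
             paste(head(colnames(beta)[is.na(idx)], 5), collapse = ", "))
    cd <- DataFrame(phenotype[idx, , drop = FALSE],
                    row.names = colnames(beta))
  }
  se <- SummarizedExperiment(assays = assays, rowRanges = rr,
                             colData = cd, metadata = metadata)
  new("DnamExperiment", se)
}

setMethod("show", "DnamExperiment", function(object) {
  cat(sprintf("DnamExperiment: %d probes x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  assays: %s\n", paste(assayNames(object), collapse = ", ")))
  grp <- colData(object)$group
  if (!is.null(grp)) {
    tb <- table(grp)
    cat(sprintf("  groups: %s\n",
                paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  }
  tr <- metadata(object)$truth
  if (!is.null(tr))
    cat(sprintf("  truth: %s\n",
                paste(sprintf("%s=%d", names(table(tr$probes$label)),
                              table(tr$probes$label)), collapse = ", ")))
})

## ---------------------------------------------------------------------
## ClockModel / PCClockModel
## ---------------------------------------------------------------------

#' Linear DNA methylation estimator (clock, EpiScore, surrogate)
#'
#' One schema serves every coefficient-driven DNAm estimator: age
#' clocks, telomere-length surrogates, pace-of-aging measures,
#' EpiScores, protein surrogates and inflammation scores. The estimate
#' for a sample is `transform(intercept + sum(weight_i * beta_i))`,
#' where `transform` is `identity` or the piecewise log-linear
#' `horvath_age` transform with its `adultAge` anchor.
#'
#' @slot name estimator name.
#' @slot intercept numeric intercept.
#' @slot coefficients named numeric vector, probe id -> weight.
#' @slot transform `"identity"` or `"horvath_age"`.
#' @slot adultAge anchor age of the `horvath_age` transform.
#' @slot missingPolicy how to treat model probes absent from the data:
#'   `"error"`, `"impute_reference_mean"`, or `"impute_cohort_mean"`.
#' @slot referenceMeans named numeric vector of reference beta means
#'   (required by `impute_reference_mean`).
#' @slot standardize z-scale each probe's betas across samples before
#'   weighting (the EpiScore convention).
#' @export
setClass("ClockModel",
  representation(name = "character", intercept = "numeric",
                 coefficients = "numeric", transform = "character",
                 adultAge = "numeric", missingPolicy = "character",
                 referenceMeans = "numeric", standardize = "logical"),
  prototype(name = "clock", intercept = 0,
            coefficients = c(cg = 0)[0], transform = "identity",
            adultAge = 20, missingPolicy = "impute_cohort_mean",
            referenceMeans = numeric(), standardize = FALSE))

setValidity("ClockModel", function(object) {
  msg <- character()
  if (!length(object@coefficients) && object@intercept == 0 &&
      FALSE) msg <- c(msg, "")  # intercept-only models are allowed
  if (length(object@coefficients) &&
      is.null(names(object@coefficients)))
    msg <- c(msg, "coefficients must be named by probe id")
  if (anyDuplicated(names(object@coefficients)))
    msg <- c(msg, "duplicate probe ids in coefficients")
  if (!object@transform %in% c("identity", "horvath_age"))
    msg <- c(msg, sprintf("unknown transform '%s'", object@transform))
  if (!object@missingPolicy %in%
      c("error", "impute_reference_mean", "impute_cohort_mean"))
    msg <- c(msg, sprintf("unknown missing policy '%s'",
                          object@missingPolicy))
  if (object@missingPolicy == "impute_reference_mean" &&
      !length(object@referenceMeans))
    msg <- c(msg, "impute_reference_mean requires referenceMeans")
  if (length(msg)) msg else TRUE
})

#' Create a ClockModel
#'
#' @param name estimator name.
#' @param intercept intercept.
#' @param coefficients named numeric vector (probe id -> weight); may be
#'   empty for an intercept-only model.
#' @param transform `"identity"` (default) or `"horvath_age"`.
#' @param adultAge anchor for the `horvath_age` transform (default 20).
#' @param missingPolicy `"impute_cohort_mean"` (default),
#'   `"impute_reference_mean"` or `"error"`.
#' @param referenceMeans named reference beta means.
#' @param standardize z-scale betas per probe before weighting.
#' @return A validated [ClockModel-class].
#' @examples
#' m <- ClockModel("toy", intercept = 10, coefficients = c(cg1 = 2, cg2 = -1))
#' @export
ClockModel <- function(name, intercept = 0, coefficients = numeric(),
                       transform = "identity", adultAge = 20,
                       missingPolicy = "impute_cohort_mean",
                       referenceMeans = numeric(),
                       standardize = FALSE) {
  new("ClockModel", name = name, intercept = as.numeric(intercept),
      coefficients = coefficients, transform = transform,
      adultAge = adultAge, missingPolicy = missingPolicy,
      referenceMeans = referenceMeans, standardize = standardize)
}

setMethod("show", "ClockModel", function(object) {
  cat(sprintf("ClockModel '%s': %d CpGs, intercept %.4g, transform %s%s\n",
              object@name, length(object@coefficients), object@intercept,
              object@transform,
              if (object@standardize) " (standardized betas)" else ""))
})

#' Principal-component clock model
#'
#' Estimate = `intercept + sum_k w_k * (t(rotation) %*% (beta - center))_k`:
#' betas are centered, projected onto component loadings, and the
#' component scores combined linearly.
#'
#' @slot name estimator name.
#' @slot center named numeric vector of per-probe centers.
#' @slot rotation probes x components loading matrix (rownames = probe
#'   ids, colnames = component names).
#' @slot componentWeights named numeric vector, component -> weight.
#' @slot intercept numeric intercept.
#' @export
setClass("PCClockModel",
  representation(name = "character", center = "numeric",
                 rotation = "matrix", componentWeights = "numeric",
                 intercept = "numeric"))

setValidity("PCClockModel", function(object) {
  msg <- character()
  if (is.null(rownames(object@rotation)) ||
      is.null(colnames(object@rotation)))
    msg <- c(msg, "rotation needs probe rownames and component colnames")
  else {
    if (!all(rownames(object@rotation) %in% names(object@center)))
      msg <- c(msg, "rotation probes must be a subset of center probes")
    if (!all(names(object@componentWeights) %in%
             colnames(object@rotation)))
      msg <- c(msg, "componentWeights keys must be rotation components")
  }
  if (length(msg)) msg else TRUE
})

#' Create a PCClockModel
#'
#' @param name estimator name.
#' @param center named per-probe centers.
#' @param rotation probes x components loading matrix.
#' @param componentWeights named component weights.
#' @param intercept intercept.
#' @return A validated [PCClockModel-class].
#' @export
PCClockModel <- function(name, center, rotation, componentWeights,
                         intercept = 0) {
  new("PCClockModel", name = name, center = center, rotation = rotation,
      componentWeights = componentWeights,
      intercept = as.numeric(intercept))
}

setMethod("show", "PCClockModel", function(object) {
  cat(sprintf("PCClockModel '%s': %d probes -> %d components, intercept %.4g\n",
              object@name, nrow(object@rotation), ncol(object@rotation),
              object@intercept))
})
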