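#' Accessors for DnamExperiment
#'
#' `betaValues()` and `detP()` return the beta / detection-p assay
#' matrices; `phenotype()` the sample sheet as a data.frame;
#' `probeAnnotation()` the probe annotation as a data.frame with
#' 1-based `position`; `probeTruth()`, `sampleTruth()`, `toyClock()` and
#' `cellReference()` expose generator truth for synthetic datasets.
#'
#' @param x a [DnamExperiment-class].
#' @return See the per-accessor description.
#' @name dnam-accessors
NULL

#' @rdname dnam-accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname dnam-accessors
#' @export
setMethod("betaValues", "DnamExperiment",
          function(x) assay(x, "beta"))

#' @rdname dnam-accessors
#' @export
setGeneric("detP", function(x) standardGeneric("detP"))

#' @rdname dnam-accessors
#' @export
setMethod("detP", "DnamExperiment", function(x) {
  if (!"detp" %in% assayNames(x)) NULL else assay(x, "detp")
})

#' @rdname dnam-accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname dnam-accessors
#' @export
setMethod("phenotype", "DnamExperiment", function(x) {
  df <- as.data.frame(colData(x))
  if (!"sample_id" %in% colnames(df))
    df <- cbind(sample_id = rownames(df), df)
  df
})

#' @rdname dnam-accessors
#' @export
setGeneric("probeAnnotation",
           function(x) standardGeneric("probeAnnotation"))

#' @rdname dnam-accessors
#' @export
setMethod("probeAnnotation", "DnamExperiment", function(x) {
  rr <- rowRanges(x)
  df <- data.frame(probe_id = names(rr),
                   chrom = as.character(seqnames(rr)),
                   position = start(rr),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(S4Vectors::mcols(rr)))
})

#' @rdname dnam-accessors
#' @export
setGeneric("probeTruth", function(x) standardGeneric("probeTruth"))

#' @rdname dnam-accessors
#' @export
setMethod("probeTruth", "DnamExperiment",
          function(x) metadata(x)$truth$probes)

#' @rdname dnam-accessors
#' @export
setGeneric("sampleTruth", function(x) standardGeneric("sampleTruth"))

#' @rdname dnam-accessors
#' @export
setMethod("sampleTruth", "DnamExperiment",
          function(x) metadata(x)$truth$samples)

#' @rdname dnam-accessors
#' @export
setGeneric("toyClock", function(x) standardGeneric("toyClock"))

#' @rdname dnam-accessors
#' @export
setMethod("toyClock", "DnamExperiment",
          function(x) metadata(x)$truth$clock)

#' @rdname dnam-accessors
#' @export
setGeneric("cellReference", function(x) standardGeneric("cellReference"))

#' @rdname dnam-accessors
#' @export
setMethod("cellReference", "DnamExperiment",
          function(x) metadata(x)$truth$cellReference)

#' Compute a DNAm estimate from betas and a coefficient model
#'
#' Dispatches on the model class: [ClockModel-class] gives
#' `transform(intercept + sum_i w_i beta_i)` per sample;
#' [PCClockModel-class] centers, projects onto component loadings and
#' combines component scores. `beta` may be a probes x samples matrix
#' or a [DnamExperiment-class].
#'
#' @param beta probes x samples beta matrix or [DnamExperiment-class].
#' @param model a [ClockModel-class] or [PCClockModel-class].
#' @param ... unused.
#' @return Named numeric vector of per-sample estimates.
#' @examples
#' b <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("cg1", "cg2"), "S1"))
#' m <- ClockModel("toy", 10, c(cg1 = 2, cg2 = -1))
#' computeEstimate(b, m)  # 10.5
#' @export
setGeneric("computeEstimate",
           function(beta, model, ...) standardGeneric("computeEstimate"))
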