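## Sample-QC and probe-filter cascade.

#' Compute beta values from intensity matrices
#'
#' `beta = M / (M + U + offset)`, the methylated / total intensity
#' ratio with the conventional stabilizing offset.
#'
#' @param meth,unmeth conformable non-negative intensity matrices.
#' @param offset stabilizer added to the denominator (default 100).
#' @return Matrix of betas in `[0, 1)`; cells with a zero denominator
#'   are missing.
#' @examples
#' computeBeta(matrix(300), matrix(100), 100)  # 0.6
#' @export
computeBeta <- function(meth, unmeth, offset = 100) {
  if (!identical(dim(meth), dim(unmeth)))
    .stopf("intensity matrices are not conformable")
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    .stopf("negative intensities")
  den <- meth + unmeth + offset
  beta <- meth / den
  beta[den == 0] <- NA_real_
  dimnames(beta) <- dimnames(meth)
  beta
}

.newFilterReport <- function(kind) {
  structure(list(kind = kind, rules = list()), class = "FilterReport")
}

.addRule <- function(report, rule, removed, params = NULL) {
  report$rules[[length(report$rules) + 1L]] <-
    list(rule = rule, removed = removed, n_removed = length(removed),
         params = params)
  report
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport (%s): %d rules\n", x$kind, length(x$rules)))
  for (r in x$rules)
    cat(sprintf("  %-28s removed %d\n", r$rule, r$n_removed))
  invisible(x)
}

#' Sample quality control on detection p-values
#'
#' Keeps samples whose mean probe detection p-value is below `alpha`.
#'
#' @param detp probes x samples detection p-value matrix in `[0, 1]`.
#' @param alpha mean-detection-p threshold (default 0.05).
#' @return List with `kept` (sample ids) and `report` (a FilterReport).
#' @export
sampleQC <- function(detp, alpha = 0.05) {
  if (is(detp, "DnamExperiment")) detp <- detP(detp)
  if (is.null(detp) || !length(detp)) .stopf("empty detection-p matrix")
  if (any(detp < 0 | detp > 1, na.rm = TRUE))
    .stopf("detection p-values must lie in [0, 1]")
  meanp <- colMeans(detp, na.rm = TRUE)
  keep <- meanp < alpha
  report <- .addRule(.newFilterReport("sample"),
                     "mean_detection_p >= alpha",
                     colnames(detp)[!keep],
                     params = list(alpha = alpha))
  list(kept = colnames(detp)[keep], report = report)
}

#' Probe filter cascade
#'
#' Drops a probe if its detection p-value exceeds `detpThreshold` in at
#' least one sample, if it lies on a sex chromosome, or if any
#' exclusion flag (SNP-mapping, cross-reactive, non-specific,
#' variant-containing, masked) is set. The rules are independent
#' predicates, so their order does not affect the retained set; the
#' report counts removals rule by rule on the surviving pool so counts
#' plus retained equal the input exactly.
#'
#' @param detp probes x samples detection p-value matrix.
#' @param annotation probe annotation data.frame with `probe_id` and the
#'   flag columns; must cover all probes unless
#'   `missingAnnotation = "unflagged"`.
#' @param detpThreshold per-observation detection-p cutoff
#'   (default 0.01).
#' @param missingAnnotation `"error"` (default) or `"unflagged"`: how to
#'   treat probes absent from the annotation.
#' @return List with `kept` (probe ids) and `report`.
#' @export
probeFilter <- function(detp, annotation, detpThreshold = 0.01,
                        missingAnnotation = c("error", "unflagged")) {
  missingAnnotation <- match.arg(missingAnnotation)
  probes <- rownames(detp)
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx)) {
    if (missingAnnotation == "error")
      .stopf("probes absent from annotation: %s",
             paste(head(probes[is.na(idx)], 5), collapse = ", "))
    message(sprintf("%d probes absent from annotation; treated as unflagged",
                    sum(is.na(idx))))
  }
  getFlag <- function(col) {
    v <- rep(FALSE, length(probes))
    ok <- !is.na(idx)
    if (col %in% colnames(annotation))
      v[ok] <- as.logical(annotation[[col]][idx[ok]]) %in% TRUE
    v
  }
  failDetp <- apply(detp > detpThreshold, 1, any, na.rm = TRUE)
  sexChrom <- getFlag("on_sex_chromosome")
  if ("chrom" %in% colnames(annotation)) {
    ok <- !is.na(idx)
    sexChrom[ok] <- sexChrom[ok] |
      annotation$chrom[idx[ok]] %in% c("chrX", "chrY", "X", "Y")
  }
  report <- .newFilterReport("probe")
  drop <- rep(FALSE, length(probes))
  addSeq <- function(rule, pred, params = NULL) {
    newly <- pred & !drop
    report <<- .addRule(report, rule, probes[newly], params)
    drop <<- drop | pred
  }
  addSeq("detection_p > threshold in >= 1 sample", failDetp,
         list(threshold = detpThreshold))
  addSeq("sex_chromosome", sexChrom)
  for (fc in c("maps_to_snp", "cross_reactive", "non_specific",
               "variant_containing", "masked"))
    addSeq(fc, getFlag(fc))
  list(kept = probes[!drop], report = report)
}

## Gaussian-mixture/BIC multimodality call on one vector: multimodal if
## a 2- or 3-component 1-D mixture beats the single component by BIC.
.isMultimodal <- function(x, minBicGain = 6) {
  x <- x[is.finite(x)]
  if (length(x) < 5L || stats::sd(x) < 1e-8) return(FALSE)
  bic <- tryCatch(
    suppressWarnings(mclust::mclustBIC(x, G = 1:3,
                                       modelNames = c("E", "V"),
                                       verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(bic)) return(FALSE)
  b1 <- suppressWarnings(max(bic[1, ], na.rm = TRUE))
  bM <- suppressWarnings(max(bic[-1, ], na.rm = TRUE))
  is.finite(bM) && (bM - b1) > minBicGain
}

#' Multimodality screen within survivor sex strata
#'
#' Within each sex stratum of the survived group, each probe's beta
#' distribution is screened for bi-/tri-modality with a 1-D
#' Gaussian-mixture BIC comparison (1 vs 2-3 components); probes called
#' multimodal in any stratum are dropped. Degenerate (constant) probes
#' are treated as unimodal. Strata below `minStratumSize` are skipped
#' with a warning.
#'
#' @param beta probes x samples matrix or [DnamExperiment-class].
#' @param phenotype data.frame with `sample_id`, `group` and `sex`
#'   (taken from the object when omitted).
#' @param minStratumSize minimum samples per stratum (default 5).
#' @param minBicGain BIC margin a multi-component fit must exceed
#'   (default 6).
#' @return List with `kept` (probe ids) and `report` (records method,
#'   margin and strata used).
#' @export
multimodalityFilter <- function(beta, phenotype = NULL,
                                minStratumSize = 5L, minBicGain = 6) {
  if (is(beta, "DnamExperiment")) {
    if (is.null(phenotype)) phenotype <- phenotype(beta)
    beta <- betaValues(beta)
  }
  stopifnot(all(c("sample_id", "group", "sex") %in% colnames(phenotype)))
  surv <- phenotype[phenotype$group == "survived", ]
  multimodal <- rep(FALSE, nrow(beta))
  strata <- character(0)
  for (sx in unique(surv$sex)) {
    ids <- intersect(surv$sample_id[surv$sex == sx], colnames(beta))
    if (length(ids) < minStratumSize) {
      .warnf("stratum sex=%s has %d < %d samples; skipped",
             sx, length(ids), minStratumSize)
      next
    }
    strata <- c(strata, sx)
    sub <- beta[, ids, drop = FALSE]
    multimodal <- multimodal |
      vapply(seq_len(nrow(sub)),
             function(i) .isMultimodal(sub[i, ], minBicGain),
             logical(1))
  }
  report <- .addRule(.newFilterReport("probe"),
                     "multimodal_in_survivor_stratum",
                     rownames(beta)[multimodal],
                     params = list(method = "gaussian_mixture_bic",
                                   min_bic_gain = minBicGain,
                                   strata = strata,
                                   min_stratum_size = minStratumSize))
  list(kept = rownames(beta)[!multimodal], report = report)
}

#' Apply the full QC cascade to a dataset
#'
#' Runs [sampleQC()], [probeFilter()] and optionally
#' [multimodalityFilter()] and returns the filtered
#' [DnamExperiment-class] plus the combined reports.
#'
#' @param x a [DnamExperiment-class] with a `detp` assay.
#' @param sampleAlpha mean-detection-p sample cutoff (default 0.05).
#' @param detpThreshold probe-level detection-p cutoff (default 0.01).
#' @param multimodality run the survivor-strata multimodality screen
#'   (default TRUE when `group` and `sex` phenotype columns exist).
#' @return List with `data` (filtered object) and `reports`.
#' @export
applyQC <- function(x, sampleAlpha = 0.05, detpThreshold = 0.01,
                    multimodality = NULL) {
  stopifnot(is(x, "DnamExperiment"))
  detp <- detP(x)
  if (is.null(detp)) .stopf("dataset has no 'detp' assay")
  sq <- sampleQC(detp, sampleAlpha)
  x <- x[, sq$kept]
  pf <- probeFilter(detP(x), probeAnnotation(x), detpThreshold)
  x <- x[pf$kept, ]
  reports <- list(sample = sq$report, probe = pf$report)
  ph <- phenotype(x)
  if (is.null(multimodality))
    multimodality <- all(c("group", "sex") %in% colnames(ph))
  if (isTRUE(multimodality)) {
    mf <- multimodalityFilter(betaValues(x), ph)
    x <- x[mf$kept, ]
    reports$multimodality <- mf$report
  }
  list(data = x, reports = reports)
}
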