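## Coefficient-file-driven DNAm estimator engine.

## Assemble the model's probe x sample beta submatrix, applying the
## missing-probe policy; returns the matrix in model probe order.
.modelBetas <- function(beta, model) {
  probes <- names(model@coefficients)
  if (!length(probes))
    return(matrix(0, 0, ncol(beta),
                  dimnames = list(NULL, colnames(beta))))
  missing <- setdiff(probes, rownames(beta))
  sub <- matrix(NA_real_, length(probes), ncol(beta),
                dimnames = list(probes, colnames(beta)))
  found <- intersect(probes, rownames(beta))
  sub[found, ] <- beta[found, , drop = FALSE]
  if (length(missing)) {
    if (model@missingPolicy == "error")
      .stopf("model '%s': %d probes absent from data: %s%s",
             model@name, length(missing),
             paste(head(missing, 5), collapse = ", "),
             if (length(missing) > 5) ", ..." else "")
    if (model@missingPolicy == "impute_reference_mean") {
      rm <- model@referenceMeans[missing]
      if (anyNA(rm))
        .stopf("model '%s': no reference mean for %s", model@name,
               paste(head(missing[is.na(rm)], 5), collapse = ", "))
      sub[missing, ] <- rm
    }
    message(sprintf("model '%s': imputed %d missing probes (%s)",
                    model@name, length(missing), model@missingPolicy))
  }
  ## cohort-mean imputation also covers missing cells (NA betas)
  if (anyNA(sub)) {
    if (model@missingPolicy == "error" && anyNA(sub))
      .stopf("model '%s': missing beta values under policy 'error'",
             model@name)
    rmean <- rowMeans(sub, na.rm = TRUE)
    if (model@missingPolicy == "impute_reference_mean") {
      known <- !is.na(model@referenceMeans[probes])
      rmean[known] <- model@referenceMeans[probes][known]
    }
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- rmean[idx[, 1]]
  }
  sub
}

#' @describeIn computeEstimate linear estimator on a beta matrix
#' @export
setMethod("computeEstimate", signature(beta = "matrix",
                                       model = "ClockModel"),
  function(beta, model, ...) {
    sub <- .modelBetas(beta, model)
    if (model@standardize && nrow(sub)) {
      s <- apply(sub, 1, stats::sd)
      s[s == 0 | is.na(s)] <- 1
      sub <- (sub - rowMeans(sub)) / s
    }
    raw <- model@intercept +
      if (nrow(sub)) drop(crossprod(sub, model@coefficients)) else 0
    raw <- rep_len(raw, ncol(beta))
    names(raw) <- colnames(beta)
    if (model@transform == "horvath_age")
      raw <- horvathAgeTransform(raw, model@adultAge)
    raw
  })

#' @describeIn computeEstimate linear estimator on a DnamExperiment
#' @export
setMethod("computeEstimate", signature(beta = "DnamExperiment",
                                       model = "ClockModel"),
  function(beta, model, ...) computeEstimate(betaValues(beta), model))

#' @describeIn computeEstimate principal-component estimator
#' @export
setMethod("computeEstimate", signature(beta = "matrix",
                                       model = "PCClockModel"),
  function(beta, model, ...) {
    probes <- rownames(model@rotation)
    missing <- setdiff(probes, rownames(beta))
    if (length(missing))
      .stopf("PC model '%s': %d probes absent from data: %s",
             model@name, length(missing),
             paste(head(missing, 5), collapse = ", "))
    centered <- beta[probes, , drop = FALSE] - model@center[probes]
    if (anyNA(centered)) {
      rmean <- rowMeans(centered, na.rm = TRUE)
      idx <- which(is.na(centered), arr.ind = TRUE)
      centered[idx] <- rmean[idx[, 1]]
    }
    scores <- crossprod(model@rotation, centered)  # components x samples
    w <- model@componentWeights
    est <- model@intercept +
      drop(crossprod(scores[names(w), , drop = FALSE], w))
    names(est) <- colnames(beta)
    est
  })

#' @describeIn computeEstimate principal-component estimator on a
#'   DnamExperiment
#' @export
setMethod("computeEstimate", signature(beta = "DnamExperiment",
                                       model = "PCClockModel"),
  function(beta, model, ...) computeEstimate(betaValues(beta), model))

#' Piecewise age transform of first-generation epigenetic clocks
#'
#' Maps the linear predictor `x` to years: `(1 + adultAge) * exp(x) - 1`
#' for `x < 0` and `(1 + adultAge) * x + adultAge` for `x >= 0`. The two
#' branches agree at `x = 0` (value `adultAge`); the lower limit is -1.
#'
#' @param x numeric linear predictor.
#' @param adultAge anchor age (default 20).
#' @return Numeric vector of ages in years.
#' @examples
#' horvathAgeTransform(c(-Inf, 0, 1))  # -1, 20, 41
#' @export
horvathAgeTransform <- function(x, adultAge = 20) {
  ifelse(x < 0, (1 + adultAge) * exp(x) - 1,
         (1 + adultAge) * x + adultAge)
}

#' Battery of estimates from a directory or list of models
#'
#' Applies every model to the betas and assembles the sample x
#' estimator table used by downstream inference.
#'
#' @param beta probes x samples beta matrix or [DnamExperiment-class].
#' @param models list of [ClockModel-class] / [PCClockModel-class]
#'   objects (named or carrying their own names).
#' @return data.frame with `sample_id` and one column per estimator.
#' @export
estimateTable <- function(beta, models) {
  if (is(beta, "DnamExperiment")) beta <- betaValues(beta)
  if (is(models, "ClockModel") || is(models, "PCClockModel"))
    models <- list(models)
  out <- data.frame(sample_id = colnames(beta),
                    stringsAsFactors = FALSE)
  for (m in models) {
    nm <- if (is(m, "ClockModel")) m@name else m@name
    out[[nm]] <- computeEstimate(beta, m)
  }
  out
}

#' Age-acceleration residuals
#'
#' Residuals of the least-squares regression of an estimate on
#' chronological age, optionally including estimated cell-count columns
#' (the intrinsic variant). Residuals sum to zero by construction.
#'
#' @param estimates named numeric vector of per-sample estimates.
#' @param chronologicalAge numeric vector, same length/order.
#' @param cellCounts optional numeric matrix or data.frame of
#'   per-sample cell-count covariates.
#' @return Numeric vector of residuals (years, for age clocks).
#' @export
ageAcceleration <- function(estimates, chronologicalAge,
                            cellCounts = NULL) {
  if (length(estimates) < 3L)
    .stopf("need at least 3 samples")
  if (anyNA(chronologicalAge))
    .stopf("missing chronological ages")
  X <- cbind(`(Intercept)` = 1, age = chronologicalAge)
  if (!is.null(cellCounts)) {
    cc <- as.matrix(cellCounts)
    if (is.null(colnames(cc)))
      colnames(cc) <- paste0("cell", seq_len(ncol(cc)))
    X <- cbind(X, cc)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)),
                                   qrX$pivot[seq_len(qrX$rank)])]
    .stopf("collinear design; aliased columns: %s",
           paste(aliased, collapse = ", "))
  }
  res <- qr.resid(qrX, estimates)
  names(res) <- names(estimates)
  res
}
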