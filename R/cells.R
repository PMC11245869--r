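## Reference-based cell-type deconvolution.

#' Estimate cell-type fractions from betas and a reference panel
#'
#' Per sample, solves the constrained least-squares problem
#' `beta ~ R f` over the probes shared between the data and the
#' reference: non-negative least squares (`constraint = "nonneg"`), or
#' non-negative with fractions summing to one
#' (`constraint = "nonneg_sum_to_one"`, the default), implemented as
#' NNLS on a system augmented with a heavily weighted sum row followed
#' by exact renormalization.
#'
#' @param beta probes x samples matrix or [DnamExperiment-class].
#' @param reference probes x cell-types matrix of reference betas in
#'   `[0, 1]` with unique probe rownames and >= 2 cell-type columns.
#' @param constraint `"nonneg_sum_to_one"` or `"nonneg"`.
#' @param minProbes minimum shared probes required (default: number of
#'   cell types).
#' @return List with `fractions` (samples x cell types), `residualNorm`
#'   per sample, and `nProbes` used.
#' @examples
#' R <- matrix(runif(40), 20, 2,
#'             dimnames = list(sprintf("cg%02d", 1:20), c("A", "B")))
#' b <- cbind(S1 = R %*% c(0.3, 0.7))
#' estimateCellFractions(b, R)$fractions
#' @export
estimateCellFractions <- function(beta, reference,
                                  constraint = c("nonneg_sum_to_one",
                                                 "nonneg"),
                                  minProbes = NULL) {
  constraint <- match.arg(constraint)
  if (is(beta, "DnamExperiment")) beta <- betaValues(beta)
  if (is.null(dim(beta))) beta <- cbind(sample = beta)
  stopifnot(!is.null(rownames(reference)), ncol(reference) >= 2L)
  if (any(reference < 0 | reference > 1, na.rm = TRUE))
    .stopf("reference betas must lie in [0, 1]")
  shared <- intersect(rownames(beta), rownames(reference))
  if (is.null(minProbes)) minProbes <- ncol(reference)
  if (length(shared) < minProbes)
    .stopf("only %d probes shared between data and reference (need >= %d)",
           length(shared), minProbes)
  R <- as.matrix(reference[shared, , drop = FALSE])
  B <- beta[shared, , drop = FALSE]
  k <- ncol(R)
  lambda <- 1e4  # weight of the sum-to-one row in the augmented system
  fr <- matrix(NA_real_, ncol(B), k,
               dimnames = list(colnames(B), colnames(R)))
  rn <- setNames(rep(NA_real_, ncol(B)), colnames(B))
  for (j in seq_len(ncol(B))) {
    y <- B[, j]
    ok <- is.finite(y)
    if (sum(ok) < minProbes)
      .stopf("sample '%s': only %d finite shared probes", colnames(B)[j],
             sum(ok))
    if (constraint == "nonneg") {
      fit <- pracma::lsqnonneg(R[ok, , drop = FALSE], y[ok])
      f <- fit$x
    } else {
      Ra <- rbind(R[ok, , drop = FALSE], rep(lambda, k))
      fit <- pracma::lsqnonneg(Ra, c(y[ok], lambda))
      f <- fit$x
      s <- sum(f)
      if (s <= 0) .stopf("degenerate fit for sample '%s'", colnames(B)[j])
      f <- f / s
    }
    fr[j, ] <- f
    rn[j] <- sqrt(sum((y[ok] - drop(R[ok, , drop = FALSE] %*% f))^2))
  }
  list(fractions = fr, residualNorm = rn, nProbes = length(shared))
}
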