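## Two-stage residual-outcome regression machinery on the estimator
## battery: IQR outlier fences, survivor-only reference model, cohort
## residualization, Student's t comparison, BH adjustment.

#' IQR outlier mask
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles
#' computed once on the full pooled vector by linear interpolation
#' (type-7 quantiles).
#'
#' @param values numeric vector (>= 4 finite values).
#' @return Logical vector, `TRUE` = keep; attribute `"fences"` records
#'   the fences and quantile convention.
#' @examples
#' iqrOutlierMask(c(1:9, 1000))  # only 1000 flagged
#' @export
iqrOutlierMask <- function(values) {
  finite <- is.finite(values)
  if (sum(finite) < 4L) .stopf("need >= 4 finite values")
  q <- stats::quantile(values[finite], c(0.25, 0.75), type = 7,
                       names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  keep <- finite & values >= lo & values <= hi
  attr(keep, "fences") <- c(lower = lo, upper = hi)
  attr(keep, "quantile_type") <- 7L
  keep
}

.codeSex <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  as.numeric(factor(sex, levels = sort(unique(sex)))) - 1
}

#' Fit the survivor reference model for one estimator
#'
#' Ordinary least squares of the estimate on chronological age, sex and
#' presence of complications, over the survived group only. Survivor
#' residuals sum to zero by construction.
#'
#' @param estimates named numeric per-sample estimates (names =
#'   sample ids).
#' @param phenotype data.frame with `sample_id`, `group`, `age`, `sex`,
#'   `complications`.
#' @param minSurvivors minimum survivors required (default 5).
#' @return List of class `ReferenceModel`: `coefficients`, `sigma`,
#'   `df_residual`, `coding`, and a `predict` function over the whole
#'   cohort.
#' @export
fitReferenceModel <- function(estimates, phenotype, minSurvivors = 5L) {
  ph <- phenotype
  idx <- match(ph$sample_id, names(estimates))
  if (anyNA(idx)) .stopf("estimates missing for some phenotype samples")
  y <- estimates[idx]
  X <- cbind(`(Intercept)` = 1, age = as.numeric(ph$age),
             sex = .codeSex(ph$sex),
             complications = as.numeric(ph$complications))
  surv <- ph$group == "survived" & is.finite(y)
  if (sum(surv) < minSurvivors)
    .stopf("only %d survivors with finite estimates (need >= %d)",
           sum(surv), minSurvivors)
  Xs <- X[surv, , drop = FALSE]
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    aliased <- colnames(Xs)[setdiff(seq_len(ncol(Xs)),
                                    qrX$pivot[seq_len(qrX$rank)])]
    .stopf("collinear reference design; aliased: %s",
           paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrX, y[surv])
  res <- y[surv] - drop(Xs %*% beta)
  df <- sum(surv) - ncol(Xs)
  out <- list(coefficients = beta,
              sigma = if (df > 0) sqrt(sum(res^2) / df) else NA_real_,
              df_residual = df,
              n_survivors = sum(surv),
              coding = "sex and complications coded 0/1",
              X = X, sample_id = ph$sample_id)
  class(out) <- "ReferenceModel"
  out
}

#' @export
print.ReferenceModel <- function(x, ...) {
  cat("ReferenceModel (survivors only)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  sigma %.4g on %d df (%d survivors)\n", x$sigma,
              x$df_residual, x$n_survivors))
  invisible(x)
}

#' Two-stage residual-outcome test for one estimator
#'
#' The four steps in order: (1) IQR outlier removal on the pooled
#' estimates; (2) survivor-only reference model of the estimate on age,
#' sex and complications; (3) residualization of the whole cohort
#' against that model; (4) two-sample Student's t-test (equal variance
#' by default) of the residuals between deceased and survived.
#' BH adjustment across a battery is applied by
#' [residualTestBattery()].
#'
#' @param estimates named numeric per-sample estimates.
#' @param phenotype data.frame with `sample_id`, `group`, `age`, `sex`,
#'   `complications`.
#' @param estimator estimator name carried into the result.
#' @param welch use Welch's unequal-variance t (default FALSE:
#'   Student's).
#' @return One-row data.frame: estimator, outliers removed, per-group
#'   median `[Q1; Q3]` of the raw estimates after outlier removal,
#'   group mean residuals, t statistic, degrees of freedom, nominal p.
#' @export
residualOutcomeTest <- function(estimates, phenotype,
                                estimator = "estimate",
                                welch = FALSE) {
  ph <- phenotype
  y <- estimates[match(ph$sample_id, names(estimates))]
  keep <- iqrOutlierMask(y)
  phk <- ph[keep, , drop = FALSE]
  yk <- y[keep]
  if (!any(phk$group == "survived") || !any(phk$group == "deceased"))
    .stopf("a group is empty after outlier removal")
  rm <- fitReferenceModel(setNames(yk, phk$sample_id), phk)
  Xk <- rm$X
  resid <- yk - drop(Xk %*% rm$coefficients)
  dec <- phk$group == "deceased"
  qs <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    sprintf("%.2f [%.2f; %.2f]", q[2], q[1], q[3])
  }
  if (stats::sd(resid[dec]) < 1e-12 && stats::sd(resid[!dec]) < 1e-12) {
    tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
               p.value = if (isTRUE(all.equal(mean(resid[dec]),
                                              mean(resid[!dec]))))
                 1 else 0)
    degenerate <- TRUE
  } else {
    tt <- stats::t.test(resid[dec], resid[!dec], var.equal = !welch)
    degenerate <- FALSE
  }
  data.frame(
    estimator = estimator,
    n_outliers_removed = sum(!keep),
    n_survived = sum(!dec), n_deceased = sum(dec),
    median_iqr_survived = qs(yk[!dec]),
    median_iqr_deceased = qs(yk[dec]),
    mean_residual_survived = mean(resid[!dec]),
    mean_residual_deceased = mean(resid[dec]),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value,
    degenerate_variance = degenerate,
    stringsAsFactors = FALSE)
}

#' Residual-outcome tests across an estimator battery with BH
#'
#' Runs [residualOutcomeTest()] per estimator column and adjusts the
#' nominal p-values with Benjamini-Hochberg. Significance is flagged at
#' both q = 0.05 and q = 0.10.
#'
#' @param estimates data.frame with `sample_id` and one column per
#'   estimator (see [estimateTable()]).
#' @param phenotype phenotype data.frame.
#' @param welch use Welch's t (default FALSE).
#' @return data.frame with one row per estimator, BH-adjusted p, and
#'   `sig_q05` / `sig_q10` flags.
#' @export
residualTestBattery <- function(estimates, phenotype, welch = FALSE) {
  est_cols <- setdiff(colnames(estimates), "sample_id")
  rows <- lapply(est_cols, function(nm) {
    residualOutcomeTest(setNames(estimates[[nm]], estimates$sample_id),
                        phenotype, estimator = nm, welch = welch)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bhAdjust(out$p)
  out$sig_q05 <- out$p_bh < 0.05
  out$sig_q10 <- out$p_bh < 0.10
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Monotone step-up adjusted p-values, capped at 1
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise >= `p`.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return Spearman's rho; `NA` with a warning when either vector has
#'   zero rank variance.
#' @export
spearmanCor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) .stopf("need >= 3 paired finite values")
  if (stats::sd(rank(x[ok])) == 0 || stats::sd(rank(y[ok])) == 0) {
    .warnf("zero rank variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok], method = "spearman")
}
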