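## Differential methylation (DMP) and differential variability (DVP)
## calling, with empirical-Bayes variance moderation.

.designMatrix <- function(phenotype, covariates) {
  ph <- phenotype
  X <- cbind(`(Intercept)` = 1,
             group = as.numeric(ph$group == "deceased"))
  for (cv in covariates) {
    v <- ph[[cv]]
    if (is.null(v)) .stopf("covariate '%s' not in phenotype", cv)
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)),
                                   qrX$pivot[seq_len(qrX$rank)])]
    .stopf("design not full rank; aliased columns: %s",
           paste(aliased, collapse = ", "))
  }
  X
}

## Huber IRLS for one response; returns coef, weighted-LS covariance
## scale and residual variance under the final weights.
.huberFit <- function(X, y, k = 1.345, maxit = 50L, tol = 1e-8) {
  b <- qr.coef(qr(X), y)
  w <- rep(1, length(y))
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% b)
    s <- stats::median(abs(r)) * 1.4826
    if (s < 1e-10) { w <- rep(1, length(y)); break }
    wNew <- pmin(1, k * s / abs(r))
    wNew[!is.finite(wNew)] <- 1
    fit <- lm.wfit(X, y, wNew)
    bNew <- fit$coefficients
    done <- max(abs(bNew - b)) < tol * max(1, max(abs(b)))
    b <- bNew; w <- wNew
    if (done) break
  }
  r <- y - drop(X %*% b)
  dfres <- length(y) - ncol(X)
  s2 <- sum(w * r^2) / dfres
  XtWX <- crossprod(X * sqrt(w))
  list(coef = b, s2 = s2, XtWXinv = solve(XtWX))
}

#' Per-CpG differential methylation test
#'
#' Fits, per probe, a linear model of beta on group (deceased vs
#' survived) plus covariates, by ordinary least squares or Huber
#' M-estimation (`robust = TRUE`; tuning constant 1.345, MAD scale,
#' <= 50 IRLS iterations). With `moderate = TRUE`, per-probe residual
#' variances are shrunk toward a common prior by closed-form
#' moment-matching ([ebayesModerate()]) and the group t-statistic uses
#' the augmented degrees of freedom. P-values are BH-adjusted across
#' probes; a probe is called a DMP when the adjusted p is below
#' `bhThreshold` and the raw group-mean beta difference exceeds
#' `deltaBetaThreshold` in absolute value (both rules together).
#'
#' @param beta probes x samples matrix or [DnamExperiment-class].
#' @param phenotype data.frame with `sample_id` and `group`, plus any
#'   covariate columns.
#' @param covariates character vector of covariate column names
#'   (e.g. age, sex, complications, cell-count estimates, batch).
#' @param robust Huber M-estimation instead of OLS (default FALSE).
#' @param moderate empirical-Bayes variance moderation (default TRUE).
#' @param bhThreshold BH-adjusted p cutoff (default 0.05).
#' @param deltaBetaThreshold absolute raw group-difference cutoff
#'   (default 0.05).
#' @return data.frame per probe: `probe_id`, `delta_beta` (raw
#'   deceased - survived mean difference), `coefficient` (adjusted
#'   group effect), `t`, `df`, `p`, `p_bh`, `is_dmp`.
#' @export
dmpTest <- function(beta, phenotype, covariates = character(0),
                    robust = FALSE, moderate = TRUE,
                    bhThreshold = 0.05, deltaBetaThreshold = 0.05) {
  if (is(beta, "DnamExperiment")) {
    if (missing(phenotype)) phenotype <- phenotype(beta)
    beta <- betaValues(beta)
  }
  ph <- phenotype
  B <- beta[, match(ph$sample_id, colnames(beta)), drop = FALSE]
  X <- .designMatrix(ph, covariates)
  n <- nrow(X); kX <- ncol(X); dfres <- n - kX
  dec <- ph$group == "deceased"
  deltaBeta <- rowMeans(B[, dec, drop = FALSE]) -
    rowMeans(B[, !dec, drop = FALSE])

  if (!robust) {
    fit <- lm.fit(X, t(B))
    cfAll <- fit$coefficients
    if (is.null(dim(cfAll))) cfAll <- cbind(cfAll)  # single-probe input
    cf <- cfAll["group", ]
    res <- as.matrix(fit$residuals)
    s2 <- colSums(res^2) / dfres
    XtXinv <- chol2inv(chol(crossprod(X)))
    vg <- XtXinv[2, 2]
  } else {
    P <- nrow(B)
    cf <- s2 <- vgv <- numeric(P)
    for (i in seq_len(P)) {
      hf <- .huberFit(X, B[i, ])
      cf[i] <- hf$coef["group"]
      s2[i] <- hf$s2
      vgv[i] <- hf$XtWXinv[2, 2]
    }
  }
  if (moderate) {
    mod <- ebayesModerate(s2, dfres)
    s2use <- mod$varPost
    dfuse <- mod$dfTotal
  } else {
    s2use <- s2
    dfuse <- dfres
  }
  se <- if (!robust) sqrt(s2use * vg) else sqrt(s2use * vgv)
  tstat <- cf / se
  p <- 2 * pt(-abs(tstat), dfuse)
  pbh <- bhAdjust(p)
  data.frame(probe_id = rownames(B),
             delta_beta = deltaBeta,
             coefficient = unname(cf),
             t = unname(tstat), df = dfuse, p = unname(p),
             p_bh = pbh,
             is_dmp = pbh < bhThreshold &
               abs(deltaBeta) > deltaBetaThreshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

.trigammaInverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    x <- 0.5 + 1 / yy
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2)
      x <- x + dif
      if (x <= 0) x <- 1e-8
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Moment-matching estimate of a scaled-inverse-chi-squared prior
#' `(d0, s0^2)` from the distribution of log sample variances, followed
#' by the posterior shrinkage
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`. When the prior degrees of
#' freedom cannot be estimated (non-finite moment), the raw variances
#' are returned unmoderated with a message.
#'
#' @param s2 positive per-probe residual variances.
#' @param df residual degrees of freedom of each fit (scalar).
#' @return List: `varPost`, `dfPrior` (`d0`), `varPrior` (`s0^2`),
#'   `dfTotal` (`d0 + df`, capped for infinite priors).
#' @export
ebayesModerate <- function(s2, df) {
  if (any(s2 <= 0, na.rm = TRUE)) .stopf("variances must be positive")
  e <- log(s2) - (digamma(df / 2) - log(df / 2))
  emean <- mean(e)
  if (stats::var(e) < 1e-14) {
    ## no spread at all: nothing to shrink, infinitely strong prior
    return(list(varPost = s2, dfPrior = Inf, varPrior = mean(s2),
                dfTotal = Inf))
  }
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar)) {
    message("prior df estimate non-finite; variances left unmoderated")
    return(list(varPost = s2, dfPrior = 0, varPrior = NA_real_,
                dfTotal = df))
  }
  if (evar <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
    return(list(varPost = rep(s02, length(s2)), dfPrior = d0,
                varPrior = s02, dfTotal = Inf))
  }
  d0 <- 2 * .trigammaInverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  if (!is.finite(d0) || !is.finite(s02)) {
    message("prior estimate non-finite; variances left unmoderated")
    return(list(varPost = s2, dfPrior = 0, varPrior = NA_real_,
                dfTotal = df))
  }
  list(varPost = (d0 * s02 + df * s2) / (d0 + df),
       dfPrior = d0, varPrior = s02, dfTotal = df + d0)
}

#' Per-CpG differential variability test
#'
#' Methylation absolute-deviation analysis: per probe, deviations
#' `z = |beta - group center|` are compared between groups by a
#' two-sample equal-variance t-test (the Levene/Brown-Forsythe
#' regression form), and the group variance ratio
#' (deceased / survived) is reported on a log scale. A probe is called
#' a DVP when `|log2 VR| > vrThreshold` (strict) and the nominal
#' deviation p-value is below `pThreshold`.
#'
#' @param beta probes x samples matrix or [DnamExperiment-class].
#' @param phenotype data.frame with `sample_id` and `group`.
#' @param center `"mean"` (default) or `"median"` group center for the
#'   deviations.
#' @param logBase base of the variance-ratio log (default 2).
#' @param vrThreshold log-variance-ratio cutoff (default 2, i.e. a
#'   4-fold change in base 2).
#' @param pThreshold nominal p cutoff (default 0.001).
#' @return data.frame per probe: `probe_id`, `log_variance_ratio`,
#'   `levene_t`, `levene_p`, `direction`, `degenerate` (zero
#'   within-group variance; excluded from calls), `is_dvp`.
#' @export
dvpTest <- function(beta, phenotype, center = c("mean", "median"),
                    logBase = 2, vrThreshold = 2, pThreshold = 0.001) {
  center <- match.arg(center)
  if (is(beta, "DnamExperiment")) {
    if (missing(phenotype)) phenotype <- phenotype(beta)
    beta <- betaValues(beta)
  }
  ph <- phenotype
  B <- beta[, match(ph$sample_id, colnames(beta)), drop = FALSE]
  dec <- ph$group == "deceased"
  nd <- sum(dec); ns <- sum(!dec)
  if (nd < 3L || ns < 3L) .stopf("each group needs >= 3 samples")
  Bd <- B[, dec, drop = FALSE]; Bs <- B[, !dec, drop = FALSE]
  ctr <- function(M) if (center == "mean") rowMeans(M)
    else apply(M, 1, stats::median)
  zd <- abs(Bd - ctr(Bd)); zs <- abs(Bs - ctr(Bs))
  mzd <- rowMeans(zd); mzs <- rowMeans(zs)
  vzd <- rowSums((zd - mzd)^2) / (nd - 1)
  vzs <- rowSums((zs - mzs)^2) / (ns - 1)
  sp2 <- ((nd - 1) * vzd + (ns - 1) * vzs) / (nd + ns - 2)
  tstat <- (mzd - mzs) / sqrt(sp2 * (1 / nd + 1 / ns))
  p <- 2 * pt(-abs(tstat), nd + ns - 2)
  vd <- rowSums((Bd - rowMeans(Bd))^2) / (nd - 1)
  vs <- rowSums((Bs - rowMeans(Bs))^2) / (ns - 1)
  degenerate <- vd == 0 | vs == 0
  lvr <- ifelse(degenerate, NA_real_, log(vd / vs) / log(logBase))
  data.frame(probe_id = rownames(B),
             log_variance_ratio = lvr,
             levene_t = unname(tstat), levene_p = unname(p),
             direction = ifelse(is.na(lvr), NA_character_,
                                ifelse(lvr > 0, "hypervariable",
                                       "hypovariable")),
             degenerate = degenerate,
             is_dvp = !degenerate & !is.na(lvr) &
               abs(lvr) > vrThreshold & p < pThreshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
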