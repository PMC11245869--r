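## Propensity-score matching and survival association.

.smd <- function(x, treated) {
  mt <- mean(x[treated]); mc <- mean(x[!treated])
  s <- sqrt((stats::var(x[treated]) + stats::var(x[!treated])) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (mt - mc) / s
}

#' Propensity-score nearest-neighbour matching
#'
#' Fits a logistic regression of group membership (deceased = treated)
#' on the baseline covariates, then matches each treated unit 1:1 (or
#' 1:`ratio`) to the nearest unmatched control on the propensity score,
#' greedily in descending treated score order, without replacement.
#'
#' @param phenotype data.frame with `sample_id`, `group` and the
#'   covariate columns.
#' @param covariates character vector of covariate column names
#'   (complete cases required).
#' @param ratio controls per treated unit (default 1).
#' @param caliper optional maximum score distance; pairs beyond it are
#'   not formed.
#' @return List: `pairs` (treated id, control id, score distance),
#'   `scores`, `smd_before`, `smd_after` (per covariate standardized
#'   mean differences), `model` (the logistic fit).
#' @export
propensityMatch <- function(phenotype, covariates, ratio = 1L,
                            caliper = NULL) {
  ph <- phenotype
  stopifnot(all(c("sample_id", "group") %in% colnames(ph)),
            all(covariates %in% colnames(ph)))
  X <- ph[, covariates, drop = FALSE]
  for (j in seq_along(X)) if (!is.numeric(X[[j]]))
    X[[j]] <- as.numeric(factor(X[[j]])) - 1
  if (!all(complete.cases(X))) .stopf("covariates contain missing values")
  treated <- ph$group == "deceased"
  if (!any(treated) || all(treated)) .stopf("both groups must be non-empty")
  df <- data.frame(.treated = as.integer(treated), X)
  fit <- suppressWarnings(glm(.treated ~ ., data = df,
                              family = binomial()))
  if (!fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE))
    .stopf(paste0("separation suspected in the propensity logistic fit; ",
                  "consider penalized estimation or fewer covariates"))
  score <- fitted(fit)
  names(score) <- ph$sample_id

  tIdx <- which(treated)[order(score[treated], decreasing = TRUE)]
  avail <- which(!treated)
  pairs <- NULL
  for (rep_k in seq_len(ratio)) {
    for (i in tIdx) {
      if (!length(avail)) break
      d <- abs(score[avail] - score[i])
      j <- avail[which.min(d)]
      dist <- abs(score[j] - score[i])
      if (!is.null(caliper) && dist > caliper) next
      pairs <- rbind(pairs, data.frame(
        treated_id = ph$sample_id[i], control_id = ph$sample_id[j],
        distance = dist, stringsAsFactors = FALSE))
      avail <- setdiff(avail, j)
    }
  }
  matchedIdx <- c(match(pairs$treated_id, ph$sample_id),
                  match(pairs$control_id, ph$sample_id))
  smdB <- vapply(seq_along(covariates),
                 function(j) .smd(X[[j]], treated), numeric(1))
  smdA <- vapply(seq_along(covariates), function(j)
    .smd(X[[j]][matchedIdx], treated[matchedIdx]), numeric(1))
  names(smdB) <- names(smdA) <- covariates
  list(pairs = pairs, scores = score,
       smd_before = smdB, smd_after = smdA, model = fit)
}

#' Cox proportional-hazards association of an estimator with mortality
#'
#' Partial-likelihood fit (Efron tie handling) of
#' `Surv(followup_time, event) ~ estimator + covariates`; reports the
#' hazard ratio per unit of the estimator with its Wald 95% CI.
#'
#' @param estimates named numeric per-sample estimates.
#' @param phenotype data.frame with `sample_id`, `followup_time`,
#'   `event` and the covariate columns.
#' @param estimator name carried into the result.
#' @param covariates character vector of adjustment columns (default
#'   none).
#' @return List: `hr`, `ci` (length-2), `loghr`, `se`, `p`, `n`,
#'   `n_events`, `fit` (the `coxph` object).
#' @export
coxAssociation <- function(estimates, phenotype,
                           estimator = "estimate",
                           covariates = character(0)) {
  ph <- phenotype
  y <- estimates[match(ph$sample_id, names(estimates))]
  df <- data.frame(.time = ph$followup_time, .event = ph$event,
                   .est = y)
  for (cv in covariates) {
    v <- ph[[cv]]
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    df[[cv]] <- v
  }
  df <- df[complete.cases(df), , drop = FALSE]
  nCoef <- 1L + length(covariates)
  if (sum(df$.event) < nCoef)
    .warnf("only %d events for %d coefficients", sum(df$.event), nCoef)
  fm <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~ .est",
    if (length(covariates))
      paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- tryCatch(
    survival::coxph(fm, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w)))
        .stopf("Cox fit did not converge: %s", conditionMessage(w))
      suppressWarnings(survival::coxph(fm, data = df, ties = "efron"))
    })
  s <- summary(fit)
  b <- coef(fit)[".est"]
  se <- sqrt(diag(fit$var))[1]
  list(estimator = estimator,
       hr = exp(b), ci = exp(b + c(-1, 1) * qnorm(0.975) * se),
       loghr = unname(b), se = unname(se),
       p = s$coefficients[".est", "Pr(>|z|)"],
       n = nrow(df), n_events = sum(df$.event), fit = fit)
}
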