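test_that("IQR fences flag exactly the points outside 1.5 IQR", {
  expect_true(all(iqrOutlierMask(rep(3, 10))))
  keep <- iqrOutlierMask(c(1:9, 1000))
  expect_identical(which(!keep), 10L)
  ## linear-interpolation quartiles of (1..9, 1000): Q1 = 3.25 (rank
  ## 3.25), Q3 = 7.75 (rank 7.75), IQR = 4.5
  f <- attr(keep, "fences")
  expect_equal(unname(f), c(3.25 - 1.5 * 4.5, 7.75 + 1.5 * 4.5))
  ## symmetric data strictly inside the fences: nothing flagged
  expect_true(all(iqrOutlierMask(c(-2, -1, 0, 1, 2))))
  expect_error(iqrOutlierMask(c(1, 2, NA, NA)), ">= 4")
})

test_that("reference model recovers exact and noisy survivor structure", {
  set.seed(71)
  ph <- makePheno()
  est <- setNames(2 * ph$age, ph$sample_id)
  rm <- fitReferenceModel(est, ph)
  expect_equal(unname(rm$coefficients["age"]), 2, tolerance = 1e-10)
  surv <- ph$group == "survived"
  res <- est[surv] - drop(rm$X[surv, ] %*% rm$coefficients)
  expect_lt(max(abs(res)), 1e-9)
  ## survivor residual sum is 0 by the normal equations
  est2 <- makeNullEstimate(ph)
  rm2 <- fitReferenceModel(est2, ph)
  res2 <- est2[surv] - drop(rm2$X[surv, ] %*% rm2$coefficients)
  expect_lt(abs(sum(res2)), 1e-9)
  ## collinearity is an error naming the aliased column
  ph3 <- ph; ph3$complications <- ph3$age
  expect_error(fitReferenceModel(est2, ph3), "complications")
})

test_that("survivor-model coefficients are recovered within 3 SE in most replicates", {
  set.seed(72)
  ok <- replicate(200, {
    ph <- makePheno(27L, 23L)
    y <- 1.2 * ph$age - 0.5 * (ph$sex == "M") + rnorm(nrow(ph), 0, 0.5)
    rm <- fitReferenceModel(setNames(y, ph$sample_id), ph)
    surv <- ph$group == "survived"
    X <- rm$X[surv, ]
    se <- rm$sigma * sqrt(diag(solve(crossprod(X))))
    abs(rm$coefficients["age"] - 1.2) <= 3 * se["age"] &&
      abs(rm$coefficients["sex"] - (-0.5)) <= 3 * se["sex"]
  })
  expect_gte(mean(ok), 0.95)
})

test_that("identical groups give t = 0 and p = 1; planted shifts are detected", {
  ph <- makePheno(10L, 10L)
  ph$age <- rep(60:69, 2); ph$sex <- rep(c("F", "M"), 10)
  ph$complications <- rep(c(0L, 0L, 1L, 1L, 0L), 4)
  y <- rep(1:10 + 0.5, 2)
  out <- residualOutcomeTest(setNames(y, ph$sample_id), ph)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  ## +5 sigma shift: p < 0.001 in every replicate
  set.seed(73)
  ps <- replicate(20, {
    ph <- makePheno()
    y <- makeNullEstimate(ph, sigma = 1)
    y[ph$group == "deceased"] <- y[ph$group == "deceased"] + 5
    residualOutcomeTest(setNames(y, ph$sample_id), ph)$p
  })
  expect_true(all(ps < 0.001))
})

test_that("with covariates unrelated to the estimate the test matches a plain t-test", {
  set.seed(74)
  pres <- pt <- numeric(400)
  for (i in seq_len(400)) {
    ph <- makePheno()
    y <- setNames(rnorm(nrow(ph)), ph$sample_id)  # independent of covs
    pres[i] <- residualOutcomeTest(y, ph)$p
    pt[i] <- t.test(y[ph$group == "deceased"],
                    y[ph$group == "survived"], var.equal = TRUE)$p.value
  }
  ks <- suppressWarnings(ks.test(pres, pt))
  expect_gt(ks$p.value, 0.05)
})

test_that("the battery applies BH across estimators with both flags", {
  set.seed(75)
  ph <- makePheno()
  tab <- data.frame(sample_id = ph$sample_id)
  for (k in 1:6) tab[[paste0("est", k)]] <- makeNullEstimate(ph)
  tab$est1[ph$group == "deceased"] <-
    tab$est1[ph$group == "deceased"] + 8
  out <- residualTestBattery(tab, ph)
  expect_identical(nrow(out), 6L)
  expect_true(all(out$p_bh >= out$p))
  expect_true(out$sig_q05[out$estimator == "est1"])
  expect_identical(out$p_bh, bhAdjust(out$p))
})

test_that("BH adjustment matches the hand formula and the step-up decision oracle", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(76)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    adj <- bhAdjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    for (q in c(0.05, 0.1, 0.2)) {
      ## classic step-up: reject p_(1..k*) for largest k with
      ## p_(k) <= k q / m
      ord <- order(p); m <- length(p)
      ks <- which(p[ord] <= seq_len(m) * q / m)
      rejOracle <- logical(m)
      if (length(ks)) rejOracle[ord[seq_len(max(ks))]] <- TRUE
      expect_identical(adj <= q, rejOracle)
    }
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("spearman handles perfect, inverted and tied rankings", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearmanCor(x, x), 1)
  expect_equal(spearmanCor(x, -x), -1)
  ## tied vector against the explicit midrank Pearson formula
  a <- c(1, 2, 2, 3); b <- c(1, 3, 2, 2)
  ra <- rank(a); rb <- rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(spearmanCor(a, b), oracle)
  expect_warning(r0 <- spearmanCor(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(r0))
})

test_that("propensity matching balances a confounded design", {
  set.seed(77)
  n1 <- 28L; n0 <- 130L
  ph <- data.frame(
    sample_id = sprintf("M%03d", seq_len(n1 + n0)),
    group = rep(c("deceased", "survived"), c(n1, n0)),
    x1 = c(rnorm(n1, 0.8), rnorm(n0)),
    x2 = c(rnorm(n1, 0.6), rnorm(n0)))
  m <- propensityMatch(ph, c("x1", "x2"))
  expect_gt(max(abs(m$smd_before)), 0.5)
  expect_true(all(abs(m$smd_after) < 0.2))
  ## every treated matched exactly once; no control reused
  expect_identical(nrow(m$pairs), n1)
  expect_identical(anyDuplicated(m$pairs$treated_id), 0L)
  expect_identical(anyDuplicated(m$pairs$control_id), 0L)
})

test_that("identical covariates give equal scores and zero post-match SMD", {
  ph <- data.frame(sample_id = paste0("S", 1:20),
                   group = rep(c("deceased", "survived"), 10),
                   x1 = 1, x2 = 2)
  m <- propensityMatch(ph, c("x1", "x2"))
  expect_lt(diff(range(m$scores)), 1e-12)
  expect_true(all(m$smd_after == 0))
  expect_identical(nrow(m$pairs), 10L)
})

test_that("Cox log-HR matches a brute-force partial-likelihood grid", {
  set.seed(78)
  n <- 30
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(0.8 * x)) + runif(n, 0, 1e-4)  # no ties
  event <- rbinom(n, 1, 0.8)
  ph <- data.frame(sample_id = paste0("S", 1:n),
                   followup_time = time, event = event)
  cx <- coxAssociation(setNames(x, ph$sample_id), ph)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, coxPartialLogLik, numeric(1),
               time = time, event = event, x = x)
  expect_lt(abs(cx$loghr - grid[which.max(ll)]), 1e-3)
  ## rescaling the estimator divides the log-HR, p unchanged
  cx2 <- coxAssociation(setNames(10 * x, ph$sample_id), ph)
  expect_equal(cx2$loghr, cx$loghr / 10, tolerance = 1e-6)
  expect_equal(cx2$p, cx$p, tolerance = 1e-6)
})

test_that("few events relative to coefficients triggers a warning", {
  ph <- data.frame(sample_id = paste0("S", 1:8),
                   followup_time = 1:8,
                   event = c(1, rep(0, 7)),
                   a = rnorm(8), b = rnorm(8))
  expect_warning(
    coxAssociation(setNames(rnorm(8), ph$sample_id), ph,
                   covariates = c("a", "b")),
    "events")
})
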