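test_that("linear estimates match hand arithmetic and the dot-product oracle", {
  b <- matrix(c(0.5, 0.5), 2, 1,
              dimnames = list(c("cg1", "cg2"), "S1"))
  m <- ClockModel("toy", intercept = 10,
                  coefficients = c(cg1 = 2, cg2 = -1))
  expect_equal(unname(computeEstimate(b, m)), 10.5)
  ## all-zero weights give the intercept for every sample
  m0 <- ClockModel("zero", intercept = 3,
                   coefficients = c(cg1 = 0, cg2 = 0))
  b2 <- matrix(runif(10), 2, 5,
               dimnames = list(c("cg1", "cg2"), paste0("S", 1:5)))
  expect_equal(unname(computeEstimate(b2, m0)), rep(3, 5))
  ## 5-probe toy vs independently coded dot product
  set.seed(51)
  probes <- paste0("cg", 1:5)
  B <- matrix(runif(5 * 8), 5, 8,
              dimnames = list(probes, paste0("S", 1:8)))
  w <- rnorm(5); names(w) <- probes
  mm <- ClockModel("five", intercept = 1.5, coefficients = w)
  oracle <- vapply(seq_len(8),
                   function(j) 1.5 + sum(w * B[probes, j]), numeric(1))
  expect_lt(max(abs(computeEstimate(B, mm) - oracle)), 1e-12)
})

test_that("horvath age transform is continuous at 0 with the stated limits", {
  expect_equal(horvathAgeTransform(0), 20)
  expect_equal(horvathAgeTransform(1), 41)
  expect_equal(horvathAgeTransform(-Inf), -1)
  eps <- 1e-10
  expect_lt(abs(horvathAgeTransform(-eps) - horvathAgeTransform(eps)),
            1e-8)
  m <- ClockModel("h", intercept = 0, coefficients = c(cg1 = 1),
                  transform = "horvath_age")
  b <- matrix(0, 1, 1, dimnames = list("cg1", "S1"))
  expect_equal(unname(computeEstimate(b, m)), 20)
})

test_that("PC estimates reduce to linear models and match the matrix oracle", {
  probes <- paste0("cg", 1:3)
  rot <- diag(3); dimnames(rot) <- list(probes, paste0("PC", 1:3))
  ctr <- setNames(rep(0, 3), probes)
  w <- setNames(c(2, -1, 0.5), paste0("PC", 1:3))
  pc <- PCClockModel("pc", ctr, rot, w, intercept = 4)
  lin <- ClockModel("lin", intercept = 4,
                    coefficients = setNames(c(2, -1, 0.5), probes))
  B <- matrix(runif(9), 3, 3, dimnames = list(probes, paste0("S", 1:3)))
  expect_equal(computeEstimate(B, pc), computeEstimate(B, lin),
               tolerance = 1e-12)
  ## beta = center gives the intercept
  ctr2 <- setNames(runif(3), probes)
  pc2 <- PCClockModel("pc2", ctr2, rot, w, intercept = 7)
  expect_equal(unname(computeEstimate(cbind(S1 = ctr2), pc2)), 7)
  ## random 10-probe / 3-component toy vs explicit matrix product
  set.seed(52)
  probes10 <- paste0("cg", 1:10)
  rot10 <- matrix(rnorm(30), 10, 3,
                  dimnames = list(probes10, paste0("PC", 1:3)))
  ctr10 <- setNames(runif(10), probes10)
  w3 <- setNames(rnorm(3), paste0("PC", 1:3))
  pc10 <- PCClockModel("pc10", ctr10, rot10, w3, intercept = -2)
  B10 <- matrix(runif(10 * 6), 10, 6,
                dimnames = list(probes10, paste0("S", 1:6)))
  oracle <- vapply(seq_len(6), function(j)
    -2 + sum(w3 * drop(t(rot10) %*% (B10[, j] - ctr10))), numeric(1))
  expect_lt(max(abs(computeEstimate(B10, pc10) - oracle)), 1e-12)
})

test_that("probes outside a model never influence its estimate; identity models are linear in beta", {
  set.seed(53)
  probes <- paste0("cg", 1:6)
  B <- matrix(runif(6 * 4), 6, 4,
              dimnames = list(probes, paste0("S", 1:4)))
  m <- ClockModel("m", 2, setNames(rnorm(3), probes[1:3]))
  e1 <- computeEstimate(B, m)
  B2 <- B; B2[4:6, ] <- runif(12)
  expect_identical(e1, computeEstimate(B2, m))
  a <- 0.3
  Bmix <- a * B + (1 - a) * B2
  expect_equal(computeEstimate(Bmix, m),
               a * e1 + (1 - a) * computeEstimate(B2, m),
               tolerance = 1e-12)
})

test_that("missing-probe policies behave as declared", {
  B <- matrix(0.4, 1, 2, dimnames = list("cg1", c("S1", "S2")))
  mErr <- ClockModel("e", 0, c(cg1 = 1, cgX = 1),
                     missingPolicy = "error")
  expect_error(computeEstimate(B, mErr), "cgX")
  mCoh <- ClockModel("c", 0, c(cg1 = 1, cgX = 2),
                     missingPolicy = "impute_cohort_mean")
  expect_message(e <- computeEstimate(B, mCoh), "imputed 1")
  expect_true(all(is.na(e) | is.finite(e)))
  mRef <- ClockModel("r", 0, c(cg1 = 1, cgX = 2),
                     missingPolicy = "impute_reference_mean",
                     referenceMeans = c(cgX = 0.25))
  expect_message(e2 <- computeEstimate(B, mRef), "imputed")
  expect_equal(unname(e2), rep(0.4 + 2 * 0.25, 2))
})

test_that("standardized (EpiScore-style) models weight z-scaled betas", {
  set.seed(54)
  B <- matrix(runif(8), 2, 4,
              dimnames = list(c("cg1", "cg2"), paste0("S", 1:4)))
  m <- ClockModel("z", 0, c(cg1 = 1, cg2 = -1), standardize = TRUE)
  e <- computeEstimate(B, m)
  z <- t(scale(t(B)))
  expect_equal(unname(e), unname(z["cg1", ] - z["cg2", ]),
               tolerance = 1e-12)
})

test_that("age acceleration residuals behave as regression residuals", {
  set.seed(55)
  age <- runif(30, 50, 80)
  expect_lt(max(abs(ageAcceleration(age, age))), 1e-10)
  expect_lt(max(abs(ageAcceleration(age + 7, age))), 1e-10)
  accel <- rnorm(50)
  age2 <- runif(50, 50, 80)
  est <- age2 + 2 * accel + rnorm(50, 0, 1)
  r <- ageAcceleration(est, age2)
  expect_lt(abs(sum(r)), 1e-9)
  expect_gt(cor(r, accel), 0.8)
  ## intrinsic variant accepts cell-count columns; collinearity errors
  cells <- matrix(runif(100), 50, 2)
  expect_lt(abs(sum(ageAcceleration(est, age2, cells))), 1e-9)
  expect_error(ageAcceleration(est, age2, cbind(age2, age2)),
               "collinear")
})

test_that("estimates separate the groups in the planted direction", {
  ds <- simulateDataset(smallConfig(seed = 1L))
  est <- computeEstimate(ds, toyClock(ds))
  ph <- phenotype(ds)
  expect_gt(mean(est[ph$group == "deceased"]),
            mean(est[ph$group == "survived"]))
})

test_that("estimateTable assembles a battery across model types", {
  ds <- simulateDataset(smallConfig(seed = 2L))
  m2 <- ClockModel("const", intercept = 5)
  tab <- estimateTable(ds, list(toyClock(ds), m2))
  expect_identical(colnames(tab), c("sample_id", "toyAccelClock",
                                    "const"))
  expect_equal(tab$const, rep(5, ncol(ds)))
})
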