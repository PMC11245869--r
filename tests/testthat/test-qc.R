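test_that("computeBeta follows the intensity-ratio definition", {
  expect_equal(computeBeta(matrix(0), matrix(1000), 100)[1, 1], 0)
  expect_equal(computeBeta(matrix(700), matrix(700), 0)[1, 1], 0.5)
  expect_equal(computeBeta(matrix(300), matrix(100), 100)[1, 1], 0.6)
  expect_true(is.na(computeBeta(matrix(0), matrix(0), 0)[1, 1]))
  expect_error(computeBeta(matrix(-1), matrix(1)), "negative")
  expect_error(computeBeta(matrix(1, 2, 2), matrix(1, 3, 2)),
               "conformable")
  b <- computeBeta(matrix(runif(20, 0, 5000), 5),
                   matrix(runif(20, 0, 5000), 5))
  expect_true(all(b >= 0 & b < 1))
})

test_that("sampleQC keeps samples by mean detection p-value", {
  m <- matrix(0, 10, 4, dimnames = list(paste0("cg", 1:10),
                                        paste0("S", 1:4)))
  expect_identical(sampleQC(m)$kept, paste0("S", 1:4))
  m[, 2] <- 1
  sq <- sampleQC(m)
  expect_identical(sq$kept, paste0("S", c(1, 3, 4)))
  expect_identical(sq$report$rules[[1]]$removed, "S2")
  expect_error(sampleQC(matrix(numeric(0), 0, 0)), "empty")
  expect_error(sampleQC(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("engineered sample failures are removed, mirroring a 56 -> 50 cohort", {
  ds <- simulateDataset(smallConfig(seed = 21L, nFailedSamples = 6L))
  expect_identical(ncol(ds), 56L)
  sq <- sampleQC(detP(ds))
  expect_length(sq$kept, 50L)
  expect_setequal(sq$report$rules[[1]]$removed,
                  phenotype(ds)$sample_id[phenotype(ds)$qc_fail])
})

test_that("probeFilter drops by detection p, sex chromosome and flags", {
  ann <- data.frame(probe_id = paste0("cg", 1:5),
                    chrom = c("chr1", "chr1", "chrX", "chr2", "chr3"),
                    position = 1:5,
                    maps_to_snp = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                    cross_reactive = FALSE, non_specific = FALSE,
                    variant_containing = FALSE, masked = FALSE,
                    on_sex_chromosome = c(FALSE, FALSE, TRUE, FALSE,
                                          FALSE))
  detp <- matrix(0.005, 5, 3, dimnames = list(ann$probe_id,
                                              paste0("S", 1:3)))
  detp["cg2", 2] <- 0.02  # fails in exactly one sample
  pf <- probeFilter(detp, ann)
  expect_setequal(pf$kept, c("cg1", "cg5"))
  ## report removals partition the removed set exactly
  removed <- unlist(lapply(pf$report$rules, `[[`, "removed"))
  expect_setequal(removed, c("cg2", "cg3", "cg4"))
  expect_identical(length(removed) + length(pf$kept), 5L)
  ## missing annotation handling
  expect_error(probeFilter(detp, ann[-1, ]), "absent")
  expect_message(
    pf2 <- probeFilter(detp, ann[-1, ], missingAnnotation = "unflagged"),
    "unflagged")
  expect_true("cg1" %in% pf2$kept)
})

test_that("filter rules are independent predicates (order-stable cascade)", {
  set.seed(31)
  n <- 200L
  ann <- data.frame(probe_id = sprintf("cg%03d", 1:n),
                    chrom = sample(c(paste0("chr", 1:5), "chrX"), n, TRUE),
                    position = 1:n,
                    maps_to_snp = runif(n) < 0.1,
                    cross_reactive = runif(n) < 0.1,
                    non_specific = FALSE,
                    variant_containing = runif(n) < 0.05,
                    masked = FALSE,
                    on_sex_chromosome = FALSE)
  detp <- matrix(runif(n * 4, 0, 0.02), n, 4,
                 dimnames = list(ann$probe_id, paste0("S", 1:4)))
  pf <- probeFilter(detp, ann)
  ## independent recomputation as one vectorized predicate
  bad <- apply(detp > 0.01, 1, any) | ann$chrom == "chrX" |
    ann$maps_to_snp | ann$cross_reactive | ann$variant_containing
  expect_setequal(pf$kept, ann$probe_id[!bad])
  expect_identical(sum(vapply(pf$report$rules, `[[`, integer(1),
                              "n_removed")) + length(pf$kept), n)
})

test_that("multimodality screen keeps degenerate and unimodal probes, drops planted two-mode probes", {
  set.seed(41)
  n <- 26
  ph <- data.frame(sample_id = sprintf("S%02d", 1:n),
                   group = "survived",
                   sex = rep(c("F", "M"), each = n / 2))
  b <- rbind(
    constant = rep(0.5, n),
    unimodal = pmin(pmax(rnorm(n, 0.5, 0.05), 0.01), 0.99),
    bimodal = 0.2 + 0.6 * rbinom(n, 1, 0.5) + rnorm(n, 0, 0.03))
  colnames(b) <- ph$sample_id
  mf <- multimodalityFilter(b, ph)
  expect_true(all(c("constant", "unimodal") %in% mf$kept))
  expect_false("bimodal" %in% mf$kept)
  expect_identical(mf$report$rules[[1]]$params$method,
                   "gaussian_mixture_bic")
})

test_that("unimodal probes survive the screen in at least 95% of seeded draws", {
  set.seed(42)
  n <- 25
  ph <- data.frame(sample_id = sprintf("S%02d", 1:n),
                   group = "survived", sex = "F")
  b <- matrix(pmin(pmax(rnorm(200 * n, 0.5, 0.07), 0.01), 0.99),
              200, n, dimnames = list(sprintf("u%03d", 1:200),
                                      ph$sample_id))
  mf <- multimodalityFilter(b, ph)
  expect_gte(length(mf$kept) / 200, 0.95)
})

test_that("small strata are skipped with a warning", {
  ph <- data.frame(sample_id = paste0("S", 1:6), group = "survived",
                   sex = rep(c("F", "M"), c(5, 1)))
  b <- matrix(runif(6 * 2, 0.3, 0.7), 2, 6,
              dimnames = list(c("a", "b"), ph$sample_id))
  expect_warning(multimodalityFilter(b, ph), "skipped")
})

test_that("a clean dataset passes the cascade untouched", {
  ds <- simulateDataset(smallConfig(seed = 22L))
  qc <- applyQC(ds, multimodality = FALSE)
  expect_identical(dim(qc$data), dim(ds))
  expect_identical(sum(vapply(qc$reports$sample$rules, `[[`,
                              integer(1), "n_removed")), 0L)
})

test_that("the full cascade removes flagged probes and bimodal probes", {
  ds <- simulateDataset(smallConfig(seed = 23L, bimodalFraction = 0.02,
                                    sexChromFraction = 0.05,
                                    flagFraction = 0.01,
                                    probeFailFraction = 0.01))
  qc <- applyQC(ds, multimodality = TRUE)
  tr <- probeTruth(ds)
  ann <- probeAnnotation(ds)
  kept <- rownames(qc$data)
  expect_false(any(ann$probe_id[ann$chrom %in% c("chrX", "chrY")] %in%
                   kept))
  bimodal <- tr$probe_id[tr$label == "bimodal"]
  expect_lt(mean(bimodal %in% kept), 0.2)
  ## planted DMP probes are autosomal and unflagged; nearly all survive
  ## (the modality screen has a small false-flag rate at stratum n ~ 10)
  expect_gte(mean(tr$probe_id[tr$label == "dmp"] %in% kept), 0.85)
})
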