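## End-to-end driver: simulate/ingest -> QC -> clocks + cells ->
## residual-outcome tests -> DMP/DVP/DMR -> enrichment -> survival,
## with a provenance manifest.

.pipelineDefaults <- function() {
  list(
    seed = 1L,
    out_dir = "methylsurv_out",
    stages = list(simulate = TRUE, qc = TRUE, clocks = TRUE,
                  cells = TRUE, residual_test = TRUE, match = FALSE,
                  dmp = TRUE, dvp = TRUE, dmr = TRUE,
                  enrichment = TRUE, cox = TRUE),
    simulate = list(),
    inputs = list(beta = NULL, detp = NULL, phenotype = NULL,
                  annotation = NULL, clock_files = NULL,
                  cell_reference = NULL, gmt = NULL),
    qc = list(sample_alpha = 0.05, detp_threshold = 0.01,
              multimodality = FALSE),
    residual_test = list(welch = FALSE),
    match = list(covariates = c("age", "sex", "hba1c", "egfr", "hscrp",
                                "ldl", "duration", "bmi")),
    dmp = list(covariates = c("age", "sex", "complications"),
               robust = FALSE, moderate = TRUE, bh_threshold = 0.05,
               delta_beta_threshold = 0.05),
    dvp = list(log_base = 2, vr_threshold = 2, p_threshold = 0.001),
    dmr = list(seed_p = 0.01, merge_dist = 500, window = 500),
    enrichment = list(alpha = 0.05),
    cox = list(covariates = c("age", "sex", "hypertension", "smoking",
                              "bmi", "egfr", "hba1c", "hscrp", "ldl",
                              "duration"))
  )
}

.mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults) &&
        !(path %in% c("simulate", "inputs")))
      .stopf("unknown configuration key '%s'", full)
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]])))
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]], full)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Build a pipeline configuration
#'
#' Merges user settings over the documented defaults, rejecting unknown
#' keys. Defaults mirror the pipeline's stated thresholds: sample mean
#' detection p < 0.05, probe detection p <= 0.01, BH 0.05 with
#' delta-beta 0.05 for DMP calls, |log2 VR| > 2 with p < 0.001 for DVP
#' calls, and Sidak 0.05 for regions.
#'
#' @param ... named settings (see [runPipeline()]), or a single list.
#' @return A validated config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  cfg <- .mergeConfig(.pipelineDefaults(), user)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys as in [pipelineConfig()].
#' @return A `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  pipelineConfig(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or ingest), QC,
#' clock estimates + cell deconvolution, residual-outcome battery,
#' propensity matching, DMP/DVP/DMR calling, enrichment, Cox
#' association — writing each result table to `out_dir` together with a
#' provenance manifest (config hash, seed, parameters, row counts per
#' stage). Reruns with the same config and seed produce byte-identical
#' tables.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @return Invisibly, a list with the per-stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "methylSurv",
                   version = as.character(utils::packageVersion("methylSurv")),
                   config_hash = configHash(unclass(config)),
                   seed = config$seed, stages = list())
  results <- list()
  stamp <- function(stage, rows, params = NULL, file = NULL) {
    manifest$stages[[stage]] <<- list(rows = rows, params = params,
                                      file = file)
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(error = conditionMessage(e))
    writeJsonReport(manifest, file.path(outDir, "manifest.json"))
    .stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  }
  st <- config$stages

  ## --- data ---
  if (isTRUE(st$simulate)) {
    simArgs <- config$simulate
    simArgs$seed <- config$seed
    ds <- tryCatch(simulateDataset(do.call(SimulationConfig, simArgs)),
                   error = function(e) fail("simulate", e))
    stamp("simulate", nrow(ds), simArgs)
  } else {
    inp <- config$inputs
    ds <- tryCatch({
      beta <- readMatrixTsv(inp$beta)
      detp <- if (!is.null(inp$detp)) readMatrixTsv(inp$detp)
      ph <- readPhenotype(inp$phenotype)
      ann <- readAnnotationBed(inp$annotation)
      DnamExperiment(beta, phenotype = ph, annotation = ann,
                     detp = detp)
    }, error = function(e) fail("ingest", e))
    stamp("ingest", nrow(ds))
  }

  ## --- QC ---
  if (isTRUE(st$qc)) {
    qc <- tryCatch(
      applyQC(ds, sampleAlpha = config$qc$sample_alpha,
              detpThreshold = config$qc$detp_threshold,
              multimodality = config$qc$multimodality),
      error = function(e) fail("qc", e))
    ds <- qc$data
    writeJsonReport(lapply(qc$reports, function(r)
      lapply(r$rules, function(x) x[c("rule", "n_removed")])),
      file.path(outDir, "filter_report.json"))
    stamp("qc", nrow(ds), config$qc, "filter_report.json")
    results$qc_reports <- qc$reports
  }
  ph <- phenotype(ds)
  results$data <- ds

  ## --- clocks ---
  if (isTRUE(st$clocks)) {
    models <- tryCatch({
      if (!is.null(config$inputs$clock_files))
        lapply(config$inputs$clock_files, readClockModel)
      else if (!is.null(toyClock(ds))) list(toyClock(ds))
      else list()
    }, error = function(e) fail("clocks", e))
    est <- tryCatch(estimateTable(ds, models),
                    error = function(e) fail("clocks", e))
    fwrite(est, file.path(outDir, "estimates.tsv"), sep = "\t")
    stamp("clocks", nrow(est), file = "estimates.tsv")
    results$estimates <- est
  }

  ## --- cells ---
  if (isTRUE(st$cells)) {
    ref <- if (!is.null(config$inputs$cell_reference))
      readMatrixTsv(config$inputs$cell_reference)
    else cellReference(ds)
    if (!is.null(ref) &&
        length(intersect(rownames(ref), rownames(ds))) >= ncol(ref)) {
      cf <- tryCatch(estimateCellFractions(ds, ref),
                     error = function(e) fail("cells", e))
      cfr <- data.frame(sample_id = rownames(cf$fractions),
                        cf$fractions, check.names = FALSE)
      fwrite(cfr, file.path(outDir, "cell_fractions.tsv"), sep = "\t")
      stamp("cells", nrow(cfr), file = "cell_fractions.tsv")
      results$cell_fractions <- cf
    }
  }

  ## --- residual-outcome battery ---
  if (isTRUE(st$residual_test) && !is.null(results$estimates)) {
    rt <- tryCatch(
      residualTestBattery(results$estimates, ph,
                          welch = config$residual_test$welch),
      error = function(e) fail("residual_test", e))
    fwrite(rt, file.path(outDir, "residual_tests.tsv"), sep = "\t")
    stamp("residual_test", nrow(rt), file = "residual_tests.tsv")
    results$residual_tests <- rt
  }

  ## --- matching ---
  if (isTRUE(st$match)) {
    mt <- tryCatch(propensityMatch(ph, config$match$covariates),
                   error = function(e) fail("match", e))
    fwrite(mt$pairs, file.path(outDir, "matched_pairs.csv"))
    stamp("match", nrow(mt$pairs), file = "matched_pairs.csv")
    results$match <- mt
  }

  ## --- DMP / DVP / DMR ---
  ann <- probeAnnotation(ds)
  if (isTRUE(st$dmp)) {
    covs <- intersect(config$dmp$covariates, colnames(ph))
    dmp <- tryCatch(
      dmpTest(ds, ph, covariates = covs, robust = config$dmp$robust,
              moderate = config$dmp$moderate,
              bhThreshold = config$dmp$bh_threshold,
              deltaBetaThreshold = config$dmp$delta_beta_threshold),
      error = function(e) fail("dmp", e))
    fwrite(dmp, file.path(outDir, "dmp.tsv"), sep = "\t")
    stamp("dmp", sum(dmp$is_dmp),
          c(config$dmp[c("robust", "moderate")],
            list(covariates = covs)), "dmp.tsv")
    results$dmp <- dmp
  }
  if (isTRUE(st$dvp)) {
    dvp <- tryCatch(
      dvpTest(ds, ph, logBase = config$dvp$log_base,
              vrThreshold = config$dvp$vr_threshold,
              pThreshold = config$dvp$p_threshold),
      error = function(e) fail("dvp", e))
    fwrite(dvp, file.path(outDir, "dvp.tsv"), sep = "\t")
    stamp("dvp", sum(dvp$is_dvp, na.rm = TRUE), config$dvp, "dvp.tsv")
    results$dvp <- dvp
  }
  if (isTRUE(st$dmr) && !is.null(results$dmp)) {
    ord <- order(ann$chrom, ann$position)
    dmr <- tryCatch(
      dmrCombp(results$dmp$p[ord], ann[ord, ],
               seedP = config$dmr$seed_p,
               mergeDist = config$dmr$merge_dist,
               windowBp = config$dmr$window),
      error = function(e) fail("dmr", e))
    fwrite(dmr, file.path(outDir, "dmr.tsv"), sep = "\t")
    stamp("dmr", nrow(dmr), config$dmr, "dmr.tsv")
    results$dmr <- dmr
  }

  ## --- enrichment ---
  if (isTRUE(st$enrichment) && !is.null(results$dmp)) {
    universe <- unique(stats::na.omit(ann$gene))
    dmpGenes <- unique(stats::na.omit(
      ann$gene[match(results$dmp$probe_id[results$dmp$is_dmp],
                     ann$probe_id)]))
    sets <- if (!is.null(config$inputs$gmt)) readGmt(config$inputs$gmt)
      else NULL
    if (!is.null(sets) && length(dmpGenes)) {
      enr <- tryCatch(
        fisherEnrichment(dmpGenes, sets, universe,
                         alpha = config$enrichment$alpha),
        error = function(e) fail("enrichment", e))
      fwrite(enr, file.path(outDir, "enrichment.tsv"), sep = "\t")
      stamp("enrichment", nrow(enr), file = "enrichment.tsv")
      results$enrichment <- enr
    }
  }

  ## --- Cox ---
  if (isTRUE(st$cox) && !is.null(results$estimates)) {
    estCols <- setdiff(colnames(results$estimates), "sample_id")
    covs <- intersect(config$cox$covariates, colnames(ph))
    cox <- lapply(estCols, function(nm) tryCatch(
      coxAssociation(setNames(results$estimates[[nm]],
                              results$estimates$sample_id),
                     ph, estimator = nm, covariates = covs),
      error = function(e) fail("cox", e)))
    coxTab <- do.call(rbind, lapply(cox, function(cx)
      data.frame(estimator = cx$estimator, hr = cx$hr,
                 ci_lower = cx$ci[1], ci_upper = cx$ci[2], p = cx$p,
                 n = cx$n, n_events = cx$n_events)))
    writeJsonReport(coxTab, file.path(outDir, "cox.json"))
    stamp("cox", nrow(coxTab), list(covariates = covs), "cox.json")
    results$cox <- coxTab
  }

  writeJsonReport(manifest, file.path(outDir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}
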