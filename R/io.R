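## Readers and writers for the pipeline's plain-text formats: TSV
## matrices, phenotype CSV, BED-like annotation (0-based half-open on
## disk, 1-based in memory), GMT gene sets, coefficient CSVs and JSON
## reports.

#' @importFrom data.table fread fwrite
NULL

#' Read / write a probes-x-samples matrix as TSV
#'
#' First column `probe_id`, remaining columns one per sample.
#' Round-trips exactly (numeric at full precision).
#'
#' @param path file path.
#' @param x numeric matrix with dimnames.
#' @return `readMatrixTsv`: the matrix; `writeMatrixTsv`: `path`,
#'   invisibly.
#' @export
readMatrixTsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (colnames(dt)[1] != "probe_id")
    .stopf("%s: first column must be 'probe_id' (line 1)", path)
  if (anyDuplicated(dt[[1]]))
    .stopf("%s: duplicate probe id '%s'", path,
           dt[[1]][anyDuplicated(dt[[1]])])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' @rdname readMatrixTsv
#' @export
writeMatrixTsv <- function(x, path) {
  dt <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write the sample phenotype sheet as CSV
#'
#' @param path file path.
#' @param phenotype data.frame with a `sample_id` column.
#' @return `readPhenotype`: the data.frame.
#' @export
readPhenotype <- function(path) {
  df <- fread(path, sep = ",", header = TRUE, data.table = FALSE)
  if (!"sample_id" %in% colnames(df))
    .stopf("%s: missing 'sample_id' column (line 1)", path)
  if (anyDuplicated(df$sample_id))
    .stopf("%s: duplicate sample ids", path)
  df
}

#' @rdname readPhenotype
#' @export
writePhenotype <- function(phenotype, path) {
  fwrite(phenotype, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Read / write probe annotation as BED-like TSV
#'
#' On disk: 0-based half-open coordinates (`chrom`, `start`, `end`,
#' `probe_id`, `gene`, `feature`, then logical flag columns). In
#' memory: 1-based `position` (probes are single sites, so
#' `position = start + 1` and `end = start + 1`).
#'
#' @param path file path.
#' @param annotation in-memory annotation with `probe_id`, `chrom`,
#'   `position`, `gene`, `feature` and flag columns.
#' @return `readAnnotationBed`: the in-memory annotation data.frame.
#' @export
readAnnotationBed <- function(path) {
  df <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("chrom", "start", "end", "probe_id")
  if (!all(need %in% colnames(df)))
    .stopf("%s: missing columns %s (line 1)", path,
           paste(setdiff(need, colnames(df)), collapse = ", "))
  if (any(df$end <= df$start))
    .stopf("%s: malformed interval at line %d", path,
           which(df$end <= df$start)[1] + 1L)
  out <- data.frame(probe_id = df$probe_id, chrom = df$chrom,
                    position = df$start + 1L,
                    stringsAsFactors = FALSE)
  for (cn in setdiff(colnames(df), c(need)))
    out[[cn]] <- df[[cn]]
  out
}

#' @rdname readAnnotationBed
#' @export
writeAnnotationBed <- function(annotation, path) {
  df <- data.frame(chrom = annotation$chrom,
                   start = annotation$position - 1L,
                   end = annotation$position,
                   probe_id = annotation$probe_id,
                   stringsAsFactors = FALSE)
  for (cn in setdiff(colnames(annotation),
                     c("probe_id", "chrom", "position")))
    df[[cn]] <- annotation[[cn]]
  fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' One set per line: name, description, then member genes,
#' tab-separated. Duplicate set names are rejected.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector per set.
#' @return `readGmt`: named list of gene vectors (descriptions in
#'   attribute `"descriptions"`).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    .stopf("%s: line %d has fewer than 3 fields", path, bad[1])
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    .stopf("%s: duplicate set name '%s' at line %d", path,
           nms[anyDuplicated(nms)], anyDuplicated(nms))
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- nms
  attr(sets, "descriptions") <-
    setNames(vapply(parts, `[[`, character(1), 2L), nms)
  sets
}

#' @rdname readGmt
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (anyDuplicated(names(sets))) .stopf("duplicate set names")
  if (is.null(descriptions))
    descriptions <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------
## Coefficient files
## ---------------------------------------------------------------------

#' Read / write a linear estimator coefficient file
#'
#' CSV with leading `#key=value` metadata lines (`name`, `intercept`,
#' `transform`, `adult_age`, `missing_policy`, `standardize`) followed
#' by a `probe_id,weight[,reference_mean]` table. Duplicate probe rows
#' and unknown transform or policy ids are rejected with the offending
#' line number; write-then-read round-trips to an identical model.
#'
#' @param path file path.
#' @param model a [ClockModel-class].
#' @return `readClockModel`: a validated [ClockModel-class].
#' @export
readClockModel <- function(path) {
  lines <- readLines(path)
  metaIdx <- grep("^#", lines)
  meta <- list()
  for (i in metaIdx) {
    kv <- sub("^#", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) .stopf("%s: malformed metadata at line %d", path, i)
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[setdiff(seq_along(lines), metaIdx)]
  body <- body[nzchar(body)]
  if (!length(body)) .stopf("%s: no coefficient table", path)
  hdr <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!identical(hdr[1:2], c("probe_id", "weight")))
    .stopf("%s: header must start 'probe_id,weight' (line %d)", path,
           metaIdx[length(metaIdx)] + 1L)
  hasRef <- length(hdr) >= 3L && hdr[3] == "reference_mean"
  coefs <- numeric(0); refs <- numeric(0)
  if (length(body) > 1L) {
    rows <- strsplit(body[-1], ",", fixed = TRUE)
    ids <- vapply(rows, `[[`, character(1), 1L)
    dup <- anyDuplicated(ids)
    if (dup)
      .stopf("%s: duplicate probe '%s' at line %d", path, ids[dup],
             which(lines == body[dup + 1L])[1])
    w <- suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), 2L)))
    if (anyNA(w))
      .stopf("%s: non-numeric weight at line %d", path,
             which(lines == body[which(is.na(w))[1] + 1L])[1])
    coefs <- setNames(w, ids)
    if (hasRef) {
      rv <- suppressWarnings(as.numeric(vapply(rows, function(r)
        if (length(r) >= 3L) r[[3L]] else NA_character_, character(1))))
      refs <- setNames(rv, ids)
      refs <- refs[!is.na(refs)]
    }
  }
  ClockModel(name = meta$name %||% "clock",
             intercept = as.numeric(meta$intercept %||% 0),
             coefficients = coefs,
             transform = meta$transform %||% "identity",
             adultAge = as.numeric(meta$adult_age %||% 20),
             missingPolicy = meta$missing_policy %||%
               "impute_cohort_mean",
             referenceMeans = refs,
             standardize = isTRUE(as.logical(meta$standardize %||%
                                             "FALSE")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readClockModel
#' @export
writeClockModel <- function(model, path) {
  stopifnot(is(model, "ClockModel"))
  meta <- c(sprintf("#name=%s", model@name),
            sprintf("#intercept=%.17g", model@intercept),
            sprintf("#transform=%s", model@transform),
            sprintf("#adult_age=%.17g", model@adultAge),
            sprintf("#missing_policy=%s", model@missingPolicy),
            sprintf("#standardize=%s", model@standardize))
  hasRef <- length(model@referenceMeans) > 0
  hdr <- if (hasRef) "probe_id,weight,reference_mean" else
    "probe_id,weight"
  rows <- character(0)
  if (length(model@coefficients)) {
    ids <- names(model@coefficients)
    rows <- if (hasRef) {
      rf <- model@referenceMeans[ids]
      sprintf("%s,%.17g,%s", ids, model@coefficients,
              ifelse(is.na(rf), "", sprintf("%.17g", rf)))
    } else sprintf("%s,%.17g", ids, model@coefficients)
  }
  writeLines(c(meta, hdr, rows), path)
  invisible(path)
}

#' Read / write a principal-component clock model as a CSV trio
#'
#' `<prefix>_center.csv` (`probe_id,center`), `<prefix>_rotation.csv`
#' (`probe_id` + one column per component), `<prefix>_weights.csv`
#' (`component,weight` with `#name` / `#intercept` metadata).
#'
#' @param prefix path prefix for the three files.
#' @param model a [PCClockModel-class].
#' @return `readPCClockModel`: a validated [PCClockModel-class].
#' @export
readPCClockModel <- function(prefix) {
  ctr <- fread(paste0(prefix, "_center.csv"), data.table = FALSE)
  rot <- fread(paste0(prefix, "_rotation.csv"), data.table = FALSE)
  wLines <- readLines(paste0(prefix, "_weights.csv"))
  meta <- list()
  for (l in grep("^#", wLines, value = TRUE)) {
    kv <- sub("^#", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  wBody <- wLines[!grepl("^#", wLines)]
  wdf <- utils::read.csv(text = paste(wBody, collapse = "\n"))
  center <- setNames(ctr$center, ctr$probe_id)
  rotation <- as.matrix(rot[, -1, drop = FALSE])
  rownames(rotation) <- rot$probe_id
  PCClockModel(name = meta$name %||% "pcclock",
               center = center, rotation = rotation,
               componentWeights = setNames(wdf$weight, wdf$component),
               intercept = as.numeric(meta$intercept %||% 0))
}

#' @rdname readPCClockModel
#' @export
writePCClockModel <- function(model, prefix) {
  stopifnot(is(model, "PCClockModel"))
  fwrite(data.frame(probe_id = names(model@center),
                    center = model@center),
         paste0(prefix, "_center.csv"))
  fwrite(data.frame(probe_id = rownames(model@rotation),
                    model@rotation, check.names = FALSE),
         paste0(prefix, "_rotation.csv"))
  writeLines(c(sprintf("#name=%s", model@name),
               sprintf("#intercept=%.17g", model@intercept),
               "component,weight",
               sprintf("%s,%.17g", names(model@componentWeights),
                       model@componentWeights)),
             paste0(prefix, "_weights.csv"))
  invisible(prefix)
}

#' Write a JSON report
#'
#' @param x list to serialize.
#' @param path file path.
#' @export
writeJsonReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits `beta.tsv`, `detp.tsv`, `meth.tsv`/`unmeth.tsv` when present,
#' `phenotype.csv`, `annotation.bed.tsv` (0-based half-open),
#' `truth_probes.tsv`, `truth_samples.tsv`, `cell_reference.tsv` and
#' the toy clock as `clock.csv`.
#'
#' @param x a [DnamExperiment-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(x, dir) {
  stopifnot(is(x, "DnamExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixTsv(betaValues(x), file.path(dir, "beta.tsv"))
  if (!is.null(detP(x)))
    writeMatrixTsv(detP(x), file.path(dir, "detp.tsv"))
  for (a in intersect(c("meth", "unmeth"), assayNames(x)))
    writeMatrixTsv(assay(x, a), file.path(dir, paste0(a, ".tsv")))
  writePhenotype(phenotype(x), file.path(dir, "phenotype.csv"))
  writeAnnotationBed(probeAnnotation(x),
                     file.path(dir, "annotation.bed.tsv"))
  tr <- metadata(x)$truth
  if (!is.null(tr)) {
    fwrite(tr$probes, file.path(dir, "truth_probes.tsv"), sep = "\t")
    fwrite(tr$samples, file.path(dir, "truth_samples.tsv"), sep = "\t")
    writeMatrixTsv(tr$cellReference, file.path(dir, "cell_reference.tsv"))
    writeClockModel(tr$clock, file.path(dir, "clock.csv"))
  }
  invisible(dir)
}
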