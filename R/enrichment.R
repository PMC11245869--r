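## Gene-set over-representation and genic-feature summarization.

#' Fisher over-representation of a gene list in GMT gene sets
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) of the
#' overlap between the query gene list and each set, within the stated
#' universe. Sets are intersected with the universe first; the query
#' list must be a subset of the universe.
#'
#' @param geneList character vector of query genes.
#' @param geneSets named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param universe character vector of all assayable genes.
#' @param alpha significance cutoff on the nominal Fisher p
#'   (default 0.05).
#' @return data.frame per set: `set`, `overlap`, `set_size`,
#'   `list_size`, `universe_size`, `p`, `odds_ratio`, `significant`.
#' @examples
#' fisherEnrichment(c("a", "b", "c"),
#'                  list(S = c("a", "b", "c")), letters[1:10])
#' @export
fisherEnrichment <- function(geneList, geneSets, universe,
                             alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) .stopf("empty universe")
  geneList <- unique(geneList)
  if (!all(geneList %in% universe))
    .stopf("gene list contains genes outside the universe: %s",
           paste(head(setdiff(geneList, universe), 5), collapse = ", "))
  N <- length(universe)
  k <- length(geneList)
  rows <- lapply(names(geneSets), function(nm) {
    s <- intersect(unique(geneSets[[nm]]), universe)
    m <- length(s)
    ov <- length(intersect(geneList, s))
    p <- phyper(ov - 1L, m, N - m, k, lower.tail = FALSE)
    a <- ov; b <- k - ov; cc <- m - ov; d <- N - m - b
    orr <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    data.frame(set = nm, overlap = ov, set_size = m, list_size = k,
               universe_size = N, p = p, odds_ratio = orr,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}

#' Genic-feature distribution of called DMPs
#'
#' Counts and percentages of genic DMPs per genic feature class
#' (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR); intergenic probes
#' are excluded from the denominator. Percentages sum to 100 within
#' rounding.
#'
#' @param dmp either a [dmpTest()] result (rows with `is_dmp = TRUE`
#'   are used) or a character vector of probe ids.
#' @param annotation probe annotation with `probe_id` and `feature`.
#' @return data.frame: `feature`, `count`, `percent`.
#' @export
summarizeGenicDistribution <- function(dmp, annotation) {
  probes <- if (is.data.frame(dmp)) dmp$probe_id[dmp$is_dmp %in% TRUE]
    else as.character(dmp)
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx))
    .stopf("annotation missing DMP probes: %s",
           paste(head(probes[is.na(idx)], 5), collapse = ", "))
  feat <- annotation$feature[idx]
  genic <- feat != "intergenic" & !is.na(feat)
  feat <- feat[genic]
  lv <- intersect(c("1stExon", "3'UTR", "5'UTR", "Body", "TSS1500",
                    "TSS200"), unique(feat))
  tb <- table(factor(feat, levels = lv))
  data.frame(feature = names(tb), count = as.integer(tb),
             percent = if (sum(tb)) 100 * as.integer(tb) / sum(tb)
               else numeric(length(tb)),
             stringsAsFactors = FALSE)
}
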