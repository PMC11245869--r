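## Region calling by spatially-correlated p-value combination
## (Stouffer-Liptak-Kechris with distance-binned autocorrelation and
## Sidak region correction).

.clipP <- function(p) pmin(pmax(p, 1e-15), 1 - 1e-15)

## correlation-adjusted Stouffer-Liptak combination of p-values given a
## correlation matrix Sigma
.stoufferLiptak <- function(p, Sigma) {
  z <- qnorm(1 - .clipP(p))
  v <- sum(Sigma)
  if (v <= 0) v <- length(p)
  1 - pnorm(sum(z) / sqrt(v))
}

#' Estimate distance-binned autocorrelation of p-value z-scores
#'
#' Pearson correlation of `qnorm(1 - p)` between probe pairs whose
#' genomic distance falls in each bin, pooled across chromosomes.
#' Negative estimates and bins with fewer than `minPairs` pairs are set
#' to zero.
#'
#' @param p nominal per-probe p-values.
#' @param chrom,pos probe coordinates, sorted by (chrom, pos).
#' @param bins upper bin edges in bp (default `seq(50, 500, 50)`).
#' @param minPairs minimum pairs per bin (default 20).
#' @return data.frame with `max_dist` and `rho`.
#' @export
acfEstimate <- function(p, chrom, pos, bins = seq(50, 500, by = 50),
                        minPairs = 20L) {
  z <- qnorm(1 - .clipP(p))
  maxD <- max(bins)
  za <- zb <- vector("list", length(bins))
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; z <- z[ord]
  n <- length(z)
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && chrom[j] == chrom[i] && pos[j] - pos[i] <= maxD) {
      b <- findInterval(pos[j] - pos[i], c(0, bins), left.open = TRUE)
      if (b >= 1L && b <= length(bins)) {
        za[[b]] <- c(za[[b]], z[i])
        zb[[b]] <- c(zb[[b]], z[j])
      }
      j <- j + 1L
    }
  }
  rho <- vapply(seq_along(bins), function(b) {
    if (length(za[[b]]) < minPairs) return(0)
    r <- suppressWarnings(stats::cor(za[[b]], zb[[b]]))
    if (!is.finite(r)) 0 else max(0, min(r, 0.99))
  }, numeric(1))
  data.frame(max_dist = bins, rho = rho)
}

.rhoLookup <- function(acf) {
  function(d) {
    out <- numeric(length(d))
    out[d == 0] <- 1
    nz <- d > 0
    idx <- findInterval(d[nz], c(0, acf$max_dist), left.open = TRUE)
    r <- ifelse(idx >= 1 & idx <= nrow(acf), acf$rho[pmin(idx, nrow(acf))], 0)
    r[d[nz] > max(acf$max_dist)] <- 0
    out[nz] <- r
    out
  }
}

.sigmaFor <- function(pos, rhoAt) {
  D <- abs(outer(pos, pos, "-"))
  Sigma <- matrix(rhoAt(as.vector(D)), nrow(D), ncol(D))
  diag(Sigma) <- 1
  Sigma
}

#' Call differentially methylated regions by combining neighbouring
#' p-values
#'
#' The comb-p-style procedure: (1) estimate the autocorrelation of
#' z-transformed nominal p-values in genomic-distance bins
#' ([acfEstimate()]); (2) smooth each probe's p-value by a
#' correlation-adjusted Stouffer-Liptak combination over its
#' `windowBp` neighbourhood; (3) seed candidate regions where the
#' smoothed p falls below `seedP`, merging seeds separated by at most
#' `mergeDist` bp; (4) score each region by the correlation-adjusted
#' Stouffer-Liptak combination of the *original* p-values of all
#' probes inside it; (5) Sidak-correct the region p using the ratio of
#' total probe-covered bases to region width. Single-probe regions are
#' suppressed.
#'
#' @param p nominal per-probe p-values (e.g. from [dmpTest()]).
#' @param annotation data.frame with `probe_id`, `chrom`, `position`,
#'   sorted by (chrom, position); unsorted input is an error.
#' @param seedP smoothed-p seed threshold (default 0.01).
#' @param mergeDist maximum gap between merged seeds in bp
#'   (default 500).
#' @param windowBp smoothing half-window in bp (default 500).
#' @param bins ACF distance-bin edges (default `seq(50, 500, 50)`).
#' @param acf optional precomputed ACF (data.frame `max_dist`, `rho`);
#'   overrides estimation.
#' @param alpha Sidak-corrected significance cutoff (default 0.05).
#' @return data.frame of regions: `chrom`, `start` (0-based), `end`
#'   (half-open), `n_probes`, `min_p`, `stouffer_liptak_p`, `sidak_p`,
#'   `is_significant`. Zero rows when no region qualifies.
#' @export
dmrCombp <- function(p, annotation, seedP = 0.01, mergeDist = 500L,
                     windowBp = 500L, bins = seq(50, 500, by = 50),
                     acf = NULL, alpha = 0.05) {
  stopifnot(length(p) == nrow(annotation))
  chrom <- as.character(annotation$chrom)
  pos <- annotation$position
  ord <- order(chrom, pos)
  if (!identical(ord, seq_along(p))) {
    if (is.unsorted(ord)) .stopf("annotation must be sorted by (chrom, position)")
    .stopf("annotation must be sorted by (chrom, position)")
  }
  if (is.null(acf)) acf <- acfEstimate(p, chrom, pos, bins)
  rhoAt <- .rhoLookup(acf)
  n <- length(p)
  z <- qnorm(1 - .clipP(p))

  ## smoothed p per probe over its +/- windowBp neighbourhood
  pSmooth <- numeric(n)
  lo <- 1L
  for (i in seq_len(n)) {
    while (lo < i && (chrom[lo] != chrom[i] ||
                      pos[i] - pos[lo] > windowBp)) lo <- lo + 1L
    hi <- i
    while (hi < n && chrom[hi + 1L] == chrom[i] &&
           pos[hi + 1L] - pos[i] <= windowBp) hi <- hi + 1L
    J <- lo:hi
    Sigma <- .sigmaFor(pos[J], rhoAt)
    pSmooth[i] <- .stoufferLiptak(p[J], Sigma)
  }

  ## seed and merge
  seed <- which(pSmooth < seedP)
  regions <- list()
  if (length(seed)) {
    newReg <- c(TRUE, chrom[seed[-1]] != chrom[seed[-length(seed)]] |
                  diff(pos[seed]) > mergeDist)
    grp <- cumsum(newReg)
    for (g in unique(grp)) {
      s <- seed[grp == g]
      members <- which(chrom == chrom[s[1]] &
                       pos >= min(pos[s]) & pos <= max(pos[s]))
      if (length(members) < 2L) next
      Sigma <- .sigmaFor(pos[members], rhoAt)
      pr <- .stoufferLiptak(p[members], Sigma)
      width <- max(pos[members]) - min(pos[members]) + 1L
      exponent <- max(1, n / width)
      sidak <- 1 - (1 - pr)^exponent
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = chrom[s[1]],
        start = min(pos[members]) - 1L,
        end = max(pos[members]),
        n_probes = length(members),
        min_p = min(p[members]),
        stouffer_liptak_p = pr,
        sidak_p = sidak,
        is_significant = sidak < alpha,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(regions))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      min_p = numeric(0), stouffer_liptak_p = numeric(0),
                      sidak_p = numeric(0), is_significant = logical(0)))
  out <- do.call(rbind, regions)
  out[order(out$sidak_p), , drop = FALSE]
}
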