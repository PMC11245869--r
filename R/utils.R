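#' @import methods
#' @importFrom stats quantile qnorm pnorm rnorm runif rexp rbinom rgamma
#'   lm lm.fit lm.wfit glm binomial t.test p.adjust pt median mad sd var
#'   coef resid fitted predict phyper setNames complete.cases cor
#' @importFrom utils head tail
NULL

## logit2 / expit2: the M-value transform used throughout (base 2, the
## array-analysis convention).
logit2 <- function(beta) log2(beta / (1 - beta))

expit2 <- function(m) 1 / (1 + 2^(-m))

## Clamp betas strictly inside (0,1); array betas are reported in [0,1)
## but downstream M-value work needs an open interval.
.clampBeta <- function(b, eps = 1e-6) pmin(pmax(b, eps), 1 - eps)

## Deterministic polynomial hash of a character scalar, reduced mod a
## Mersenne prime; used to derive independent substreams from one user
## seed and to fingerprint configs. Pure double arithmetic (exact below
## 2^53), so no integer overflow.
.hash32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  h
}

## Substream seed: mixes the master seed with a stream tag, kept < 2^31
## so it is a valid R integer seed.
.subSeed <- function(seed, tag) {
  as.integer((.hash32(paste0(tag, ":", seed)) + seed) %% 2147483647L)
}

## Evaluate expr under a seeded local RNG state, restoring the caller's.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Short hex fingerprint of an R object (structure-sensitive, not
## serialization-version-sensitive beyond the deparse).
configHash <- function(x) {
  sprintf("%08x", .hash32(paste(deparse(x), collapse = "\n")))
}
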