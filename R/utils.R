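#' @keywords internal
"_PACKAGE"

## RNG scoping: every stochastic entry point takes a seed and must neither
## depend on nor disturb the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Derive a per-stage child seed from a master seed; stays below 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483587L
}

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors in the package's internal ACGT(+N) alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Normalize a nucleotide string to the internal alphabet: uppercase, U -> T.
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return named numeric vector with `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  ## prop.test without continuity correction is the Wilson score interval;
  ## its small-count warning concerns the test p-value, which is unused here
  ci <- suppressWarnings(stats::prop.test(x, n, correct = FALSE))$conf.int
  c(estimate = x / n, lower = ci[1], upper = ci[2])
}
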