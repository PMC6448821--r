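## Independent oracles, implemented without reference to the package
## internals they are used to check.

## Needleman-Wunsch score by explicit dynamic programming over a full
## (n+1) x (m+1) matrix. N never matches.
nwScoreOracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- (0:n) * gap
  F[1, ] <- (0:m) * gap
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
      F[i + 1, j + 1] <- max(F[i, j] + s,
                             F[i, j + 1] + gap,
                             F[i + 1, j] + gap)
    }
  }
  F[n + 1, m + 1]
}

## Percent identity by direct column counting over two aligned rows.
pidOracle <- function(rowA, rowB, gaps = "exclude") {
  a <- strsplit(rowA, "")[[1]]
  b <- strsplit(rowB, "")[[1]]
  match <- a == b & a != "-" & a != "N" & b != "N"
  denom <- if (gaps == "exclude") sum(a != "-" & b != "-") else length(a)
  100 * sum(match) / denom
}

## Per-window identity by explicit column counting (gaps as mismatches).
windowIdOracle <- function(rowA, rowB, window, step) {
  a <- strsplit(rowA, "")[[1]]
  b <- strsplit(rowB, "")[[1]]
  match <- a == b & a != "-" & a != "N" & b != "N"
  starts <- seq(1, length(a) - window + 1, by = step)
  vapply(starts, function(s) 100 * sum(match[s:(s + window - 1)]) / window,
         0)
}

## Translate-and-compare classification of a single codon pair under the
## standard genetic code, written against Biostrings' code table directly.
codonClassOracle <- function(ref, alt) {
  gc <- Biostrings::GENETIC_CODE
  nd <- sum(strsplit(ref, "")[[1]] != strsplit(alt, "")[[1]])
  if (nd == 0) return("none")
  if (gc[[ref]] == "*" || gc[[alt]] == "*") return("stop")
  if (nd >= 2) return("multi_hit")
  if (gc[[ref]] == gc[[alt]]) "synonymous" else "nonsynonymous"
}

## Two-sided exact binomial p for k successes in n trials at p = 0.5,
## by full enumeration of outcome probabilities (minimum-likelihood
## convention): sum P(X = j) over all j whose probability does not exceed
## the observed one. choose() is exact for the n used in tests.
binomPOracle <- function(k, n) {
  pj <- choose(n, 0:n) / 2^n
  sum(pj[pj <= pj[k + 1] * (1 + 1e-07)])
}

## Positions at which two equal-length sequences differ.
diffPositionsOracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  which(av != bv)
}

## Random DNA string.
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
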