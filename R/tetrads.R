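## Tetrad segregation analysis and the serial-passaging division budget.

TETRAD_PHENOTYPES <- c("positive", "negative", "dead")

#' Classify one tetrad's segregation pattern
#'
#' @param spores Character vector of exactly four spore phenotypes, each
#'   \code{positive}, \code{negative} or \code{dead}.
#' @return List with \code{pattern} (\code{"pos:neg"} among viable spores),
#'   \code{complete} (no dead spores), and tallies \code{nPos, nNeg, nDead}.
#' @examples
#' classifyTetrad(c("positive", "positive", "negative", "negative"))$pattern
#' @export
classifyTetrad <- function(spores) {
  if (length(spores) != 4L) {
    stop("a tetrad has exactly 4 spores, got ", length(spores),
         call. = FALSE)
  }
  spores <- tolower(spores)
  if (!all(spores %in% TETRAD_PHENOTYPES)) {
    stop("spore phenotypes must be in {positive, negative, dead}",
         call. = FALSE)
  }
  nPos <- sum(spores == "positive")
  nNeg <- sum(spores == "negative")
  nDead <- sum(spores == "dead")
  list(pattern = paste0(nPos, ":", nNeg),
       complete = nDead == 0L,
       nPos = nPos, nNeg = nNeg, nDead = nDead)
}

tetradSporeColumns <- function(tetrads) {
  cols <- grep("^spore[1-4]$", names(tetrads), value = TRUE)
  if (length(cols) != 4L) {
    stop("tetrad table needs columns spore1..spore4", call. = FALSE)
  }
  sort(cols)
}

#' Segregation analysis of a tetrad phenotype table
#'
#' Tallies segregation patterns over fully viable tetrads (no dead spores),
#' tests the pooled spore counts against a 1:1 ratio with an exact
#' two-sided binomial test, and judges consistency with a single dominant
#' locus. Under such a locus every fully viable tetrad is 2:2; occasional
#' deviant tetrads (e.g. gene-conversion-induced 3:1) are tolerated up to
#' \code{deviantThreshold} of tetrads before consistency is rejected. The
#' two-sided p-value follows the minimum-likelihood convention (summing
#' outcome probabilities no larger than the observed one), the convention
#' of \code{\link[stats]{binom.test}}.
#'
#' @param tetrads Data frame with columns \code{tetrad} and
#'   \code{spore1..spore4} (phenotypes \code{positive/negative/dead}).
#' @param deviantThreshold Tolerated fraction of non-2:2 fully viable
#'   tetrads (default 0.1).
#' @return A \linkS4class{SegregationResult}.
#' @examples
#' tt <- data.frame(tetrad = 1:15,
#'                  spore1 = "positive", spore2 = "positive",
#'                  spore3 = "negative", spore4 = "negative")
#' segregationAnalysis(tt)
#' @export
segregationAnalysis <- function(tetrads, deviantThreshold = 0.1) {
  cols <- tetradSporeColumns(tetrads)
  cls <- lapply(seq_len(nrow(tetrads)), function(i) {
    classifyTetrad(as.character(unlist(tetrads[i, cols])))
  })
  complete <- vapply(cls, `[[`, TRUE, "complete")
  if (!any(complete)) {
    stop("no fully viable tetrads: segregation analysis undefined",
         call. = FALSE)
  }
  full <- cls[complete]
  patterns <- vapply(full, `[[`, "", "pattern")
  levelsP <- c("4:0", "3:1", "2:2", "1:3", "0:4")
  pc <- table(factor(patterns, levels = levelsP))
  nPos <- sum(vapply(full, `[[`, 1L, "nPos"))
  nNeg <- sum(vapply(full, `[[`, 1L, "nNeg"))
  p <- stats::binom.test(nPos, nPos + nNeg, p = 0.5,
                         alternative = "two.sided")$p.value
  deviant <- mean(patterns != "2:2")
  methods::new("SegregationResult",
    nTetrads = length(full),
    nIncomplete = sum(!complete),
    patternCounts = stats::setNames(as.integer(pc), levelsP),
    nPosSpores = as.integer(nPos), nNegSpores = as.integer(nNeg),
    binomialP = p,
    consistentSingleLocus = deviant <= deviantThreshold,
    deviantFraction = deviant)
}

#' Expected phenotype-category counts under a single dominant locus
#'
#' A heterozygous single locus segregates 2:2 in every tetrad, so
#' \code{n} fully viable tetrads yield \code{2n} trait-positive and
#' \code{2n} trait-negative spores.
#'
#' @param nTetrads Number of fully viable tetrads.
#' @return Named integer vector \code{c(positive=, negative=)}.
#' @examples
#' expectedCategoryCounts(15)  # 30 positive, 30 negative
#' @export
expectedCategoryCounts <- function(nTetrads) {
  nTetrads <- as.integer(nTetrads)
  if (is.na(nTetrads) || nTetrads < 0L) {
    stop("nTetrads must be a non-negative integer", call. = FALSE)
  }
  c(positive = 2L * nTetrads, negative = 2L * nTetrads)
}

#' Division budget of a serial-passaging evolution experiment
#'
#' Total cell divisions across an experiment in which lineages are diluted
#' into fresh medium every few days and divide at an average daily rate:
#' \code{nPassages * mean(daysPerPassage) * divisionsPerDay * nLineages}.
#' The default passage interval is the 3-4 day range used when cultures
#' grow slowly on a poorly utilized carbon source, averaged at its
#' midpoint; the default division rate is one division per day, the
#' average for strains that cannot consume the primary carbon source.
#'
#' @param nPassages Number of passages.
#' @param daysPerPassage Length-2 \code{c(min, max)} days between passages
#'   (default \code{c(3, 4)}), averaged at the midpoint.
#' @param divisionsPerDay Average divisions per day (default 1).
#' @param nLineages Number of independent lineages
#'   (strains x replicates).
#' @return Exact estimate (numeric), with the value rounded to the nearest
#'   10 in the \code{rounded} attribute.
#' @examples
#' estimateDivisions(100, c(3, 4), 1, 3)  # 1050
#' @export
estimateDivisions <- function(nPassages, daysPerPassage = c(3, 4),
                              divisionsPerDay = 1, nLineages = 1) {
  if (length(daysPerPassage) != 2L || daysPerPassage[1] > daysPerPassage[2]) {
    stop("daysPerPassage must be c(min, max) with min <= max",
         call. = FALSE)
  }
  if (nPassages < 0 || any(daysPerPassage <= 0) || divisionsPerDay <= 0 ||
      nLineages <= 0) {
    stop("regime parameters must be positive (nPassages >= 0)",
         call. = FALSE)
  }
  exact <- nPassages * mean(daysPerPassage) * divisionsPerDay * nLineages
  structure(exact, rounded = round(exact, -1))
}
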