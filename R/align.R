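## Pairwise global alignment and identity tracks.

## Substitution matrix over {A,C,G,T,N}: N never matches anything,
## including another N, so ambiguous runs cannot inflate identity.
nwSubstitutionMatrix <- function(match, mismatch) {
  b <- c(BASES, "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

#' Needleman-Wunsch global alignment of two nucleotide sequences
#'
#' Optimal global alignment under a match/mismatch/linear-gap scheme
#' (defaults +1/-1/-2). The dynamic programming is delegated to
#' \code{\link[Biostrings]{pairwiseAlignment}} with a custom substitution
#' matrix in which \code{N} never scores as a match; output is
#' deterministic for a given input and scoring scheme.
#'
#' @param a,b Sequences (character, \code{DNAString}, or length-1
#'   \code{DNAStringSet}).
#' @param match,mismatch,gap Scoring parameters; \code{gap} is the (negative)
#'   per-column linear gap score.
#' @param idA,idB Identifiers recorded in the result.
#' @return An \linkS4class{AlignedPair}.
#' @examples
#' aln <- globalAlign("ACGT", "AGT")
#' alignmentScore(aln)  # 3 matches - 1 gap = 1
#' @export
globalAlign <- function(a, b, match = 1, mismatch = -1, gap = -2,
                        idA = "a", idB = "b") {
  ca <- seqToChar(a, "sequence a")
  cb <- seqToChar(b, "sequence b")
  if (gap >= 0) stop("gap score must be negative", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ca), Biostrings::DNAString(cb),
    type = "global",
    substitutionMatrix = nwSubstitutionMatrix(match, mismatch),
    gapOpening = 0, gapExtension = abs(gap))
  out <- methods::new("AlignedPair",
    idA = idA, idB = idB,
    alnA = as.character(Biostrings::alignedPattern(aln)),
    alnB = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln))
  if (ungap(out@alnA) != ca || ungap(out@alnB) != cb) {
    stop("alignment round-trip failed", call. = FALSE)  # should not happen
  }
  out
}

## Column-level comparison of two aligned rows (character vectors).
## A match requires equal non-gap, non-N characters.
columnMatches <- function(ca, cb) {
  (ca == cb) & ca != "-" & ca != "N" & cb != "N"
}

#' Percent identity of an alignment
#'
#' At the nucleotide level, identity is the fraction of matching columns.
#' With \code{gaps = "exclude"} (the default, the common p-identity
#' convention) columns gapped in either row are dropped from the
#' denominator; with \code{gaps = "mismatch"} they stay in the denominator
#' and count as mismatches. \code{N} never counts as a match under either
#' convention. At the amino-acid level the rows must ungap to in-frame
#' coding sequences with whole-codon gaps; codon columns are translated and
#' residues compared.
#'
#' @param x An \linkS4class{AlignedPair} or \linkS4class{CodonAlignment}.
#' @param level \code{"nt"} or \code{"aa"}.
#' @param gaps Gap-column convention, \code{"exclude"} or \code{"mismatch"}.
#' @param which For a \code{CodonAlignment} with more than two rows, the two
#'   row names (or indices) to compare.
#' @return Percent identity in [0,100].
#' @examples
#' percentIdentity(globalAlign("ACGT", "ACGA"))  # 75
#' @export
percentIdentity <- function(x, level = c("nt", "aa"),
                            gaps = c("exclude", "mismatch"),
                            which = c(1L, 2L)) {
  level <- match.arg(level)
  gaps <- match.arg(gaps)
  if (methods::is(x, "AlignedPair")) {
    rows <- alignedRows(x)
  } else if (methods::is(x, "CodonAlignment")) {
    rows <- codonRows(x)[which]
  } else {
    stop("x must be an AlignedPair or CodonAlignment", call. = FALSE)
  }
  if (level == "aa") rows <- translateAlignedRows(rows)
  ca <- chars(rows[[1L]])
  cb <- chars(rows[[2L]])
  m <- columnMatches(ca, cb)
  denom <- if (gaps == "exclude") sum(ca != "-" & cb != "-") else length(ca)
  if (denom == 0L) {
    stop("no comparable columns: identity undefined", call. = FALSE)
  }
  100 * sum(m) / denom
}

## Translate gap-padded CDS rows codon-column-wise to gap-padded protein
## rows. Requires whole-codon gaps in frame; gap codons become "-".
translateAlignedRows <- function(rows) {
  vapply(rows, function(row) {
    n <- nchar(row)
    if (n %% 3L != 0L) {
      stop("row length not divisible by 3: not a codon alignment",
           call. = FALSE)
    }
    cods <- substring(row, seq(1L, n, 3L), seq(3L, n, 3L))
    if (any(grepl("-", cods) & cods != "---")) {
      stop("gaps not in whole-codon units; use codonAlign() first",
           call. = FALSE)
    }
    aa <- character(length(cods))
    gapc <- cods == "---"
    aa[gapc] <- "-"
    if (any(!gapc)) aa[!gapc] <- translateCodons(cods[!gapc])
    paste(aa, collapse = "")
  }, "")
}

#' Sliding-window identity track along an alignment
#'
#' Percent identity in windows of \code{window} alignment columns advanced
#' by \code{step}. Inside windows, gap columns count as mismatches by
#' default so that indel-rich windows score low rather than disappear
#' (\code{gaps = "exclude"} switches to a per-window p-identity). Windows in
#' which more than \code{maskN} of columns involve \code{N} are masked to
#' \code{NA}. Window positions are reported at the centre column, 1-based.
#'
#' @param x An \linkS4class{AlignedPair}.
#' @param window Window width in alignment columns (default 10).
#' @param step Step between window starts (default 1).
#' @param gaps In-window gap convention, \code{"mismatch"} (default) or
#'   \code{"exclude"}.
#' @param maskN Mask windows whose fraction of N-involving columns exceeds
#'   this value (default 0.5).
#' @return An \linkS4class{IdentityTrack}.
#' @examples
#' aln <- globalAlign(strrep("ACGT", 5), strrep("ACGT", 5))
#' all(trackValues(slidingIdentity(aln)) == 100)
#' @export
slidingIdentity <- function(x, window = 10L, step = 1L,
                            gaps = c("mismatch", "exclude"), maskN = 0.5) {
  stopifnot(methods::is(x, "AlignedPair"))
  gaps <- match.arg(gaps)
  window <- as.integer(window)
  step <- as.integer(step)
  if (window < 1L || step < 1L) {
    stop("window and step must be positive", call. = FALSE)
  }
  ca <- chars(x@alnA)
  cb <- chars(x@alnB)
  L <- length(ca)
  if (window > L) {
    stop("window (", window, ") exceeds alignment length (", L, ")",
         call. = FALSE)
  }
  m <- columnMatches(ca, cb)
  isGap <- ca == "-" | cb == "-"
  isN <- (ca == "N" | cb == "N") & !isGap
  starts <- seq.int(1L, L - window + 1L, by = step)
  ends <- starts + window - 1L
  cm <- c(0L, cumsum(m))
  cg <- c(0L, cumsum(isGap))
  cn <- c(0L, cumsum(isN))
  nMatch <- cm[ends + 1L] - cm[starts]
  nGap <- cg[ends + 1L] - cg[starts]
  nN <- cn[ends + 1L] - cn[starts]
  denom <- if (gaps == "mismatch") rep(window, length(starts))
           else window - nGap
  vals <- ifelse(denom > 0L, 100 * nMatch / denom, NA_real_)
  vals[nN / window > maskN] <- NA_real_
  methods::new("IdentityTrack",
    window = window, step = step,
    centers = as.integer(floor((starts + ends) / 2)),
    values = as.numeric(vals))
}

#' Export an identity track as a data frame
#'
#' @param x An \linkS4class{IdentityTrack}.
#' @return Data frame with columns \code{center} (1-based alignment column)
#'   and \code{identity} (percent).
#' @export
trackAsDataFrame <- function(x) {
  stopifnot(methods::is(x, "IdentityTrack"))
  data.frame(center = trackCenters(x), identity = trackValues(x))
}
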