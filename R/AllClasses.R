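#' @import methods
#' @importFrom S4Vectors metadata
NULL

#' Pairwise global alignment of two nucleotide sequences
#'
#' Holds two gap-padded rows in register plus the alignment score. Rows
#' contain only \code{A,C,G,T,N,-}; removing the gaps reproduces the input
#' sequences exactly and no column is gapped in both rows.
#'
#' @slot idA,idB Sequence identifiers.
#' @slot alnA,alnB Gap-padded aligned rows of equal length.
#' @slot score Alignment score (match/mismatch/linear-gap units).
#' @exportClass AlignedPair
setClass("AlignedPair",
  representation(idA = "character", idB = "character",
                 alnA = "character", alnB = "character",
                 score = "numeric"))

setValidity("AlignedPair", function(object) {
  msg <- character()
  if (nchar(object@alnA) != nchar(object@alnB)) {
    msg <- c(msg, "aligned rows differ in length")
  }
  if (grepl("[^ACGTN-]", object@alnA) || grepl("[^ACGTN-]", object@alnB)) {
    msg <- c(msg, "rows contain characters outside {A,C,G,T,N,-}")
  }
  ca <- chars(object@alnA); cb <- chars(object@alnB)
  if (length(ca) && any(ca == "-" & cb == "-")) {
    msg <- c(msg, "column gapped in both rows")
  }
  if (length(msg)) msg else TRUE
})

#' Sliding-window percent-identity track along an alignment
#'
#' @slot window,step Window width and step in alignment columns (bp).
#' @slot centers 1-based alignment-column index of each window centre.
#' @slot values Percent identity per window in [0,100]; \code{NA} for
#'   windows masked as mostly ambiguous (N).
#' @exportClass IdentityTrack
setClass("IdentityTrack",
  representation(window = "integer", step = "integer",
                 centers = "integer", values = "numeric"))

setValidity("IdentityTrack", function(object) {
  msg <- character()
  if (length(object@centers) != length(object@values)) {
    msg <- c(msg, "centers and values differ in length")
  }
  v <- object@values[!is.na(object@values)]
  if (length(v) && (any(v < 0) || any(v > 100))) {
    msg <- c(msg, "values outside [0,100]")
  }
  if (object@window < 1L || object@step < 1L) {
    msg <- c(msg, "window and step must be positive")
  }
  if (is.unsorted(object@centers, strictly = TRUE)) {
    msg <- c(msg, "centers must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Codon-aware nucleotide alignment
#'
#' Gap-padded CDS rows whose gaps come in whole-codon units (\code{---}),
#' typically produced by threading coding sequences through a protein
#' alignment (back-translation). Ungapping any row reproduces its CDS.
#'
#' @slot aln Named character vector of gap-padded rows, equal lengths
#'   divisible by 3.
#' @exportClass CodonAlignment
setClass("CodonAlignment", representation(aln = "character"))

setValidity("CodonAlignment", function(object) {
  msg <- character()
  n <- nchar(object@aln)
  if (length(unique(n)) > 1L) msg <- c(msg, "rows differ in length")
  if (length(n) && n[1L] %% 3L != 0L) {
    msg <- c(msg, "column count not divisible by 3")
  }
  if (is.null(names(object@aln)) || anyDuplicated(names(object@aln))) {
    msg <- c(msg, "rows must have unique names")
  }
  for (row in object@aln) {
    cods <- substring(row, seq(1L, nchar(row), 3L), seq(3L, nchar(row), 3L))
    bad <- grepl("-", cods) & cods != "---"
    if (any(bad)) {
      msg <- c(msg, "gaps do not come in whole-codon units")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Inferred gene-conversion tract
#'
#' A donor-derived segment inside a recipient gene, delimited two ways:
#' the \emph{minimal} span covers the first to last donor-supporting
#' informative site, while the \emph{maximal} span extends to just inside
#' the nearest flanking recipient-supporting sites (the breakpoint interval).
#' Substitution tallies are filled in by \code{\link{tractStatistics}} and
#' are \code{NA} until then.
#'
#' @slot recipientId,donorId Parental paralog identifiers.
#' @slot minimalSpan,maximalSpan Integer \code{c(start, end)}, 1-based
#'   inclusive positions in the ungapped candidate sequence.
#' @slot nSupportSites Number of donor-supporting informative sites.
#' @slot nSnpsVsRecipient SNPs between candidate and recipient within the
#'   maximal span.
#' @slot nNonsynonymous,nSynonymous Codon-level substitution tallies within
#'   the maximal span (multi-hit codons classified by net amino-acid effect).
#' @exportClass ConversionTract
setClass("ConversionTract",
  representation(recipientId = "character", donorId = "character",
                 minimalSpan = "integer", maximalSpan = "integer",
                 nSupportSites = "integer", nSnpsVsRecipient = "integer",
                 nNonsynonymous = "integer", nSynonymous = "integer"),
  prototype(nSnpsVsRecipient = NA_integer_, nNonsynonymous = NA_integer_,
            nSynonymous = NA_integer_))

setValidity("ConversionTract", function(object) {
  msg <- character()
  mi <- object@minimalSpan; ma <- object@maximalSpan
  if (length(mi) != 2L || length(ma) != 2L) {
    msg <- c(msg, "spans must be length-2 integer vectors")
  } else {
    if (mi[1L] > mi[2L]) msg <- c(msg, "minimal span start > end")
    if (ma[1L] > mi[1L] || ma[2L] < mi[2L]) {
      msg <- c(msg, "minimal span not nested within maximal span")
    }
  }
  counts <- c(object@nSnpsVsRecipient, object@nNonsynonymous,
              object@nSynonymous)
  if (!anyNA(counts)) {
    if (counts[1L] < object@nSupportSites) {
      msg <- c(msg, "fewer SNPs than support sites")
    }
    if (counts[2L] + counts[3L] > counts[1L]) {
      msg <- c(msg, "classified codons exceed SNP count")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Chimera scan report for one candidate gene
#'
#' @slot candidateId Candidate gene identifier.
#' @slot recipientId,donorId Best-scoring parental pair.
#' @slot tracts List of \linkS4class{ConversionTract}.
#' @slot residualUnexplained Informative sites matching neither parent under
#'   the chosen pair.
#' @slot nInformative Total informative sites for the chosen pair.
#' @slot nSkipped Candidate positions excluded from assignment because a
#'   projected parent row was gapped or ambiguous there.
#' @slot pointConversions Data frame of isolated donor-supporting sites in
#'   runs shorter than \code{minRun} (candidate position and run length).
#' @slot tie \code{TRUE} when another ordered parental pair scored equally
#'   under all tie-break keys before the lexicographic one.
#' @exportClass ChimeraReport
setClass("ChimeraReport",
  representation(candidateId = "character", recipientId = "character",
                 donorId = "character", tracts = "list",
                 residualUnexplained = "integer", nInformative = "integer",
                 nSkipped = "integer", pointConversions = "data.frame",
                 tie = "logical"))

#' Per-site pooled allele counts for two phenotype pools
#'
#' One row per biallelic site: reference/alternative read counts in the
#' trait-positive and trait-negative segregant pools. Positions are 1-based
#' and strictly increasing within each contig.
#'
#' @slot sites Data frame with columns \code{contig, pos, ref, alt, posRef,
#'   posAlt, negRef, negAlt} (counts are non-negative integers) and
#'   optionally \code{multiallelic} (logical).
#' @slot meta List of provenance fields (seed, coverage, thresholds...).
#' @exportClass PoolCounts
setClass("PoolCounts",
  representation(sites = "data.frame", meta = "list"),
  prototype(meta = list()))

setValidity("PoolCounts", function(object) {
  s <- object@sites
  need <- c("contig", "pos", "ref", "alt",
            "posRef", "posAlt", "negRef", "negAlt")
  if (!all(need %in% names(s))) {
    return(paste("missing columns:",
                 paste(setdiff(need, names(s)), collapse = ", ")))
  }
  msg <- character()
  cnt <- as.matrix(s[, c("posRef", "posAlt", "negRef", "negAlt")])
  if (nrow(s)) {
    if (any(cnt < 0)) msg <- c(msg, "negative counts")
    if (any(nchar(s$ref) != 1L) || any(nchar(s$alt) != 1L)) {
      msg <- c(msg, "ref/alt must be single characters")
    }
    bad <- tapply(s$pos, s$contig, function(p) is.unsorted(p, strictly = TRUE))
    if (any(unlist(bad))) {
      msg <- c(msg, "positions not strictly increasing within contig")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Tetrad segregation analysis result
#'
#' @slot nTetrads Number of fully viable tetrads analysed.
#' @slot nIncomplete Tetrads excluded for containing dead spores.
#' @slot patternCounts Named integer vector over patterns
#'   \code{4:0, 3:1, 2:2, 1:3, 0:4} for fully viable tetrads.
#' @slot nPosSpores,nNegSpores Spore tallies over fully viable tetrads.
#' @slot binomialP Two-sided exact binomial p-value for the spore counts
#'   against a 1:1 ratio.
#' @slot consistentSingleLocus \code{TRUE} when the deviation from uniform
#'   2:2 segregation stays within the tolerated fraction.
#' @slot deviantFraction Fraction of fully viable tetrads that are not 2:2.
#' @exportClass SegregationResult
setClass("SegregationResult",
  representation(nTetrads = "integer", nIncomplete = "integer",
                 patternCounts = "integer", nPosSpores = "integer",
                 nNegSpores = "integer", binomialP = "numeric",
                 consistentSingleLocus = "logical",
                 deviantFraction = "numeric"))

#' Ground truth for a simulated mapping scenario
#'
#' Everything \code{\link{makeScenario}} generated, sufficient to score any
#' downstream call: the paralog family and ancestor, the chimeric candidate
#' and its true tract, marker table, per-spore genotypes and phenotypes,
#' tetrad phenotype table, and pooled allele counts.
#'
#' @slot seed Scenario seed.
#' @slot config Fully resolved configuration list.
#' @slot family Named \code{DNAStringSet} of paralogs.
#' @slot ancestor Ancestral CDS (character).
#' @slot candidateId,candidate Chimeric candidate id and sequence.
#' @slot recipientId,donorId True conversion parents.
#' @slot tract True tract \code{c(start, end)}, 1-based inclusive in
#'   recipient coordinates.
#' @slot markers Data frame \code{contig, pos, ref, alt} of segregating
#'   sites.
#' @slot causalIndex Row of \code{markers} carrying the causal allele
#'   (\code{NA} for null scenarios).
#' @slot causalWindow 1-kb tile \code{c(start, end)} containing the causal
#'   site (\code{NA} for null scenarios).
#' @slot genotypes Spore-by-marker 0/1 matrix of derived-allele carriage.
#' @slot phenotypes Character vector (\code{positive}/\code{negative}) per
#'   spore.
#' @slot tetrads Tetrad phenotype data frame.
#' @slot counts \linkS4class{PoolCounts} simulated from the pools.
#' @slot contigLengths Named integer vector of contig lengths.
#' @exportClass ScenarioTruth
setClass("ScenarioTruth",
  representation(seed = "integer", config = "list", family = "ANY",
                 ancestor = "character", candidateId = "character",
                 candidate = "character", recipientId = "character",
                 donorId = "character", tract = "integer",
                 markers = "data.frame", causalIndex = "integer",
                 causalWindow = "integer", genotypes = "matrix",
                 phenotypes = "character", tetrads = "data.frame",
                 counts = "PoolCounts", contigLengths = "integer"))

setMethod("show", "AlignedPair", function(object) {
  n <- nchar(object@alnA)
  cat("AlignedPair: ", object@idA, " / ", object@idB,
      " (", n, " columns, score ", object@score, ")\n", sep = "")
  w <- min(n, 60L)
  cat(" ", substr(object@alnA, 1L, w), if (n > w) "...", "\n", sep = "")
  cat(" ", substr(object@alnB, 1L, w), if (n > w) "...", "\n", sep = "")
})

setMethod("show", "IdentityTrack", function(object) {
  cat("IdentityTrack: ", length(object@values), " windows (window=",
      object@window, ", step=", object@step, ")\n", sep = "")
  v <- object@values[!is.na(object@values)]
  if (length(v)) {
    cat(sprintf("  identity: min %.1f / mean %.1f / max %.1f%%\n",
                min(v), mean(v), max(v)))
  }
})

setMethod("show", "ConversionTract", function(object) {
  cat("ConversionTract: ", object@donorId, " -> ", object@recipientId, "\n",
      "  minimal span ", object@minimalSpan[1L], "-", object@minimalSpan[2L],
      ", maximal span ", object@maximalSpan[1L], "-", object@maximalSpan[2L],
      " (1-based inclusive)\n",
      "  support sites: ", object@nSupportSites, sep = "")
  if (!is.na(object@nSnpsVsRecipient)) {
    cat("; SNPs vs recipient: ", object@nSnpsVsRecipient,
        " (", object@nNonsynonymous, " nonsynonymous, ",
        object@nSynonymous, " synonymous codons)", sep = "")
  }
  cat("\n")
})

setMethod("show", "ChimeraReport", function(object) {
  cat("ChimeraReport for ", object@candidateId, "\n",
      "  best pair: recipient=", object@recipientId,
      ", donor=", object@donorId,
      if (object@tie) "  [tie-broken]", "\n",
      "  informative sites: ", object@nInformative,
      " (", object@residualUnexplained, " unexplained, ",
      object@nSkipped, " skipped)\n",
      "  tracts: ", length(object@tracts), "\n", sep = "")
  for (tr in object@tracts) show(tr)
})

setMethod("show", "PoolCounts", function(object) {
  s <- object@sites
  cat("PoolCounts: ", nrow(s), " sites on ",
      length(unique(s$contig)), " contig(s)\n", sep = "")
  if (nrow(s)) {
    dp <- s$posRef + s$posAlt + s$negRef + s$negAlt
    cat(sprintf("  mean total depth %.1f\n", mean(dp)))
  }
})

setMethod("show", "SegregationResult", function(object) {
  cat("SegregationResult: ", object@nTetrads, " fully viable tetrads (",
      object@nIncomplete, " incomplete excluded)\n", sep = "")
  pc <- object@patternCounts
  cat("  patterns:",
      paste(names(pc)[pc > 0], pc[pc > 0], sep = "=", collapse = ", "), "\n")
  cat("  spores: ", object@nPosSpores, " positive / ", object@nNegSpores,
      " negative; exact binomial p = ",
      format(object@binomialP, digits = 3), "\n", sep = "")
  cat("  consistent with a single dominant locus: ",
      object@consistentSingleLocus, "\n", sep = "")
})

setMethod("show", "ScenarioTruth", function(object) {
  cat("ScenarioTruth (seed ", object@seed, ")\n",
      "  family: ", length(object@family), " genes of ",
      nchar(object@ancestor), " bp; candidate ", object@candidateId,
      " = ", object@recipientId, " with ", object@donorId,
      " tract ", object@tract[1L], "-", object@tract[2L], "\n",
      "  markers: ", nrow(object@markers), "; causal index: ",
      object@causalIndex, "\n",
      "  spores: ", length(object@phenotypes), " in ",
      nrow(object@tetrads), " tetrads\n", sep = "")
})
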