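## Gene-conversion chimera detection: informative-site assignment,
## run-based tract inference, tract statistics, family scan.
##
## The three-way register is candidate-anchored: each parent is globally
## aligned to the candidate and its bases projected onto ungapped candidate
## coordinates. Candidate positions whose projection is gapped (or involves
## N) in any row are skipped and tallied, never silently dropped.

## Project a parent sequence onto candidate coordinates via global
## alignment. Returns a character vector of length nchar(candidate) holding
## the parent base aligned to each candidate position ("-" where the parent
## is gapped; parent insertions relative to the candidate have no candidate
## coordinate and are not represented).
##
## The projection uses a stiff gap penalty: paralogous CDSs compared here
## are expected to be co-linear, and under the mild default penalty the
## optimal alignment of 20%-diverged sequences occasionally buys a
## micro-indel detour that converts a few mismatches, corrupting the
## register. A detour must now rescue >= 8 mismatches to pay off.
projectOntoCandidate <- function(candidate, parent, idParent = "p") {
  aln <- globalAlign(candidate, parent, gap = -8,
                     idA = "candidate", idB = idParent)
  ca <- chars(aln@alnA)
  cp <- chars(aln@alnB)
  keep <- ca != "-"
  out <- cp[keep]
  names(out) <- NULL
  out
}

## Site assignment from projected parent tracks (character vectors in
## candidate coordinates). Shared by informativeSites() and
## scanGeneFamily(), which reuses projections across parent pairs.
assignSites <- function(candChars, projA, projB, idA, idB) {
  L <- length(candChars)
  gapped <- projA == "-" | projB == "-"
  hasN <- candChars == "N" | projA == "N" | projB == "N"
  skip <- gapped | hasN
  informative <- !skip & projA != projB
  pos <- which(informative)
  state <- character(length(pos))
  isA <- candChars[pos] == projA[pos]
  isB <- candChars[pos] == projB[pos]
  state[isA] <- "matches_A"
  state[isB] <- "matches_B"
  state[!isA & !isB] <- "matches_neither"
  out <- data.frame(
    column = pos,
    posCandidate = pos,
    baseCandidate = candChars[pos],
    baseA = projA[pos],
    baseB = projB[pos],
    state = factor(state,
                   levels = c("matches_A", "matches_B", "matches_neither")),
    stringsAsFactors = FALSE)
  attr(out, "idA") <- idA
  attr(out, "idB") <- idB
  attr(out, "nSkipped") <- sum(skip)
  out
}

#' Assign informative sites of a candidate gene to two parental paralogs
#'
#' Builds a candidate-anchored three-way register (each parent globally
#' aligned to the candidate) and, at every position where the parents
#' differ (an informative site), records which parent the candidate
#' matches. Positions gapped in any projection, or involving \code{N}, are
#' skipped and counted in the \code{nSkipped} attribute.
#'
#' @param candidate,parentA,parentB Nucleotide sequences.
#' @param idA,idB Parent identifiers recorded in the result.
#' @return Data frame with columns \code{column}, \code{posCandidate}
#'   (1-based position in the ungapped candidate), \code{baseCandidate},
#'   \code{baseA}, \code{baseB} and \code{state} (factor over
#'   \code{matches_A, matches_B, matches_neither}); attributes \code{idA},
#'   \code{idB}, \code{nSkipped}.
#' @examples
#' s <- informativeSites("AATA", "AAAA", "AATA")
#' s$state  # matches_B at position 3
#' @export
informativeSites <- function(candidate, parentA, parentB,
                             idA = "parentA", idB = "parentB") {
  candChars <- chars(seqToChar(candidate, "candidate"))
  projA <- projectOntoCandidate(candidate, parentA, idA)
  projB <- projectOntoCandidate(candidate, parentB, idB)
  assignSites(candChars, projA, projB, idA, idB)
}

#' Infer conversion tracts from ordered site assignments
#'
#' Scans the informative sites (ordered by candidate position, states
#' \code{matches_A}/\code{matches_B}) for maximal runs of at least
#' \code{minRun} consecutive donor-supporting sites. Sites matching neither
#' parent are ignored for run construction (they neither support nor break
#' a run). Each qualifying run becomes a tract whose minimal span covers
#' its first to last supporting site and whose maximal span extends to just
#' inside the nearest flanking recipient-supporting sites (or the gene
#' ends). Donor runs shorter than \code{minRun} are reported separately as
#' point conversions / homoplasy, not as tracts.
#'
#' @param assignments Data frame from \code{\link{informativeSites}}.
#' @param minRun Minimum run length of donor-supporting sites (default 3).
#' @param geneLength Candidate gene length, used when a tract reaches an
#'   end of the gene.
#' @param donorState Which state is treated as donor-supporting
#'   (\code{"matches_B"} by default; the other state is the recipient's).
#' @return List of \linkS4class{ConversionTract} (statistics unset), with a
#'   \code{pointConversions} attribute (data frame of sub-threshold runs:
#'   first position and length).
#' @export
inferTracts <- function(assignments, minRun = 3L, geneLength = NULL,
                        donorState = "matches_B") {
  stopifnot(donorState %in% c("matches_A", "matches_B"))
  recipState <- setdiff(c("matches_A", "matches_B"), donorState)
  recipientId <- attr(assignments, if (recipState == "matches_A") "idA"
                      else "idB")
  donorIdv <- attr(assignments, if (donorState == "matches_A") "idA"
                   else "idB")
  if (is.null(recipientId)) recipientId <- "recipient"
  if (is.null(donorIdv)) donorIdv <- "donor"
  empty <- list()
  attr(empty, "pointConversions") <-
    data.frame(posStart = integer(), runLength = integer())
  if (is.null(assignments) || nrow(assignments) == 0L) return(empty)
  keep <- assignments$state %in% c(donorState, recipState)
  a <- assignments[keep, , drop = FALSE]
  if (nrow(a) == 0L) return(empty)
  if (is.unsorted(a$posCandidate, strictly = TRUE)) {
    stop("assignments must be ordered by candidate position", call. = FALSE)
  }
  if (is.null(geneLength)) geneLength <- max(a$posCandidate)
  st <- as.character(a$state)
  pos <- a$posCandidate
  r <- rle(st)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths + 1L
  tractsOut <- list()
  points <- data.frame(posStart = integer(), runLength = integer())
  for (i in seq_along(r$values)) {
    if (r$values[i] != donorState) next
    len <- r$lengths[i]
    first <- pos[runStart[i]]
    last <- pos[runEnd[i]]
    if (len < minRun) {
      points <- rbind(points,
                      data.frame(posStart = first, runLength = len))
      next
    }
    prevRecip <- if (runStart[i] > 1L) pos[runStart[i] - 1L] else 0L
    nextRecip <- if (runEnd[i] < length(pos)) pos[runEnd[i] + 1L]
                 else geneLength + 1L
    tractsOut[[length(tractsOut) + 1L]] <- methods::new("ConversionTract",
      recipientId = recipientId, donorId = donorIdv,
      minimalSpan = as.integer(c(first, last)),
      maximalSpan = as.integer(c(prevRecip + 1L, nextRecip - 1L)),
      nSupportSites = as.integer(len))
  }
  attr(tractsOut, "pointConversions") <- points
  tractsOut
}

#' Complete tract substitution statistics
#'
#' Counts, within the tract's maximal span, the per-site substitutions
#' between candidate and recipient, and classifies affected codons as
#' synonymous or nonsynonymous with \code{\link{classifyCodonChange}}.
#' Multi-hit codons are classified once by their net amino-acid effect;
#' codon pairs involving a stop count as nonsynonymous. Candidate and
#' recipient must be in-frame coding sequences in direct register (equal
#' length, as produced by the simulator or by projection onto candidate
#' coordinates); projected positions holding a gap are excluded.
#'
#' @param tract A \linkS4class{ConversionTract} from
#'   \code{\link{inferTracts}}.
#' @param candidate,recipient Sequences in candidate register.
#' @return The tract with \code{nSnpsVsRecipient}, \code{nNonsynonymous}
#'   and \code{nSynonymous} filled in.
#' @export
tractStatistics <- function(tract, candidate, recipient) {
  stopifnot(methods::is(tract, "ConversionTract"))
  cc <- if (is.character(candidate) && length(candidate) > 1L) candidate
        else chars(seqToChar(candidate, "candidate"))
  rc <- if (is.character(recipient) && length(recipient) > 1L) recipient
        else chars(toupper(paste(recipient, collapse = "")))
  if (length(cc) != length(rc)) {
    stop("candidate and recipient are not in register", call. = FALSE)
  }
  span <- maximalSpan(tract)
  if (span[1L] < 1L || span[2L] > length(cc)) {
    stop("tract lies outside candidate coordinates", call. = FALSE)
  }
  idx <- span[1L]:span[2L]
  comparable <- cc[idx] != "-" & rc[idx] != "-" &
                cc[idx] != "N" & rc[idx] != "N"
  diffPos <- idx[comparable & cc[idx] != rc[idx]]
  nSnps <- length(diffPos)
  nNon <- 0L; nSyn <- 0L
  if (nSnps) {
    codIdx <- sort(unique((diffPos - 1L) %/% 3L))
    for (ci in codIdx) {
      cpos <- (ci * 3L + 1L):(ci * 3L + 3L)
      if (max(cpos) > length(cc)) next
      refCod <- paste(rc[cpos], collapse = "")
      altCod <- paste(cc[cpos], collapse = "")
      if (grepl("[^ACGT]", refCod) || grepl("[^ACGT]", altCod)) next
      if (netCodonEffect(refCod, altCod) == "nonsynonymous") {
        nNon <- nNon + 1L
      } else {
        nSyn <- nSyn + 1L
      }
    }
  }
  methods::initialize(tract, nSnpsVsRecipient = nSnps,
                      nNonsynonymous = nNon, nSynonymous = nSyn)
}

#' Scan a paralog panel for the best gene-conversion explanation
#'
#' Evaluates every ordered (recipient, donor) pair from the panel and
#' returns the pair that best explains the candidate as a recipient
#' backbone carrying donor-derived conversion tracts. Pairs are ranked by
#' (1) fewest informative sites matching neither parent (residual), then
#' (2) fewest tracts, then (3) smallest total donor-attributed span
#' (parsimony: the donor should explain a tract, not the backbone), then
#' (4) lexicographic (recipient, donor) ids; a tie at keys 1-3 sets the
#' \code{tie} flag.
#'
#' @param candidate Candidate gene sequence.
#' @param panel Named sequences of the paralog panel (\code{DNAStringSet},
#'   named character vector or named list), at least 2.
#' @param minRun Minimum donor-site run per tract (default 3).
#' @param candidateId Identifier recorded in the report.
#' @return A \linkS4class{ChimeraReport} with completed tract statistics.
#' @export
scanGeneFamily <- function(candidate, panel, minRun = 3L,
                           candidateId = "candidate") {
  panel <- panelToChars(panel)
  if (length(panel) < 2L) {
    stop("panel must contain at least 2 sequences", call. = FALSE)
  }
  candChars <- chars(seqToChar(candidate, "candidate"))
  L <- length(candChars)
  ids <- names(panel)
  proj <- lapply(ids, function(id) {
    projectOntoCandidate(paste(candChars, collapse = ""), panel[[id]], id)
  })
  names(proj) <- ids

  best <- NULL
  bestKey <- NULL
  tie <- FALSE
  ord <- expand.grid(recipient = ids, donor = ids,
                     stringsAsFactors = FALSE)
  ord <- ord[ord$recipient != ord$donor, , drop = FALSE]
  ord <- ord[order(ord$recipient, ord$donor), , drop = FALSE]
  for (k in seq_len(nrow(ord))) {
    rid <- ord$recipient[k]; did <- ord$donor[k]
    sites <- assignSites(candChars, proj[[rid]], proj[[did]], rid, did)
    trs <- inferTracts(sites, minRun = minRun, geneLength = L,
                       donorState = "matches_B")
    residual <- sum(sites$state == "matches_neither")
    spanTotal <- if (length(trs)) {
      sum(vapply(trs, function(t) diff(minimalSpan(t)) + 1L, 1L))
    } else 0L
    key <- c(residual, length(trs), spanTotal)
    if (is.null(bestKey) ||
        isTRUE(compareKeys(key, bestKey) < 0)) {
      bestKey <- key
      tie <- FALSE
      best <- list(rid = rid, did = did, sites = sites, tracts = trs,
                   residual = residual)
    } else if (compareKeys(key, bestKey) == 0) {
      tie <- TRUE
    }
  }
  completed <- lapply(best$tracts, function(t) {
    tractStatistics(t, candChars, proj[[best$rid]])
  })
  methods::new("ChimeraReport",
    candidateId = candidateId,
    recipientId = best$rid, donorId = best$did,
    tracts = completed,
    residualUnexplained = as.integer(best$residual),
    nInformative = nrow(best$sites),
    nSkipped = as.integer(attr(best$sites, "nSkipped")),
    pointConversions = attr(best$tracts, "pointConversions"),
    tie = tie)
}

## Lexicographic comparison of numeric key vectors: -1/0/1.
compareKeys <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  0L
}
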