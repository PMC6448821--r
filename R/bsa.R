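## Bulk-segregant scan: fixed-difference calling, 1-kb window tiling,
## collapsed-paralog artifact flagging.

#' Construct a PoolCounts object
#'
#' @param sites Data frame with columns \code{contig, pos, ref, alt,
#'   posRef, posAlt, negRef, negAlt} (counts for the trait-positive and
#'   trait-negative pools).
#' @param meta Optional provenance list.
#' @return A \linkS4class{PoolCounts}.
#' @export
PoolCounts <- function(sites, meta = list()) {
  sites <- sites[order(sites$contig, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  sites$pos <- as.integer(sites$pos)
  for (col in c("posRef", "posAlt", "negRef", "negAlt")) {
    sites[[col]] <- as.integer(sites[[col]])
  }
  methods::new("PoolCounts", sites = sites, meta = meta)
}

#' Call fixed differences between phenotype pools
#'
#' A site is a fixed difference when the alternative-allele frequencies in
#' the two pools are at opposite near-fixation extremes
#' (\code{freqPos >= fixHi} and \code{freqNeg <= fixLo}, or the reverse)
#' and both pools reach \code{minDepth}. Near-fixation thresholds rather
#' than strict 1/0 tolerate sequencing error and an occasional
#' mis-phenotyped segregant in the pools.
#'
#' @param counts A \linkS4class{PoolCounts}.
#' @param minDepth Minimum per-pool depth (default 10).
#' @param fixHi,fixLo Fixation thresholds (defaults 0.95 / 0.05).
#' @return Data frame with columns \code{contig, pos, freqPos, freqNeg,
#'   depthPos, depthNeg, status} (factor over \code{fixed_difference,
#'   not_fixed, low_depth}); thresholds attached as attributes.
#' @examples
#' pc <- PoolCounts(data.frame(contig = "chrI", pos = 100,
#'                             ref = "A", alt = "T",
#'                             posRef = 0, posAlt = 30,
#'                             negRef = 30, negAlt = 0))
#' callFixedSites(pc)$status  # fixed_difference
#' @export
callFixedSites <- function(counts, minDepth = 10L, fixHi = 0.95,
                           fixLo = 0.05) {
  stopifnot(methods::is(counts, "PoolCounts"))
  if (fixHi <= fixLo) stop("fixHi must exceed fixLo", call. = FALSE)
  s <- poolSites(counts)
  depthPos <- s$posRef + s$posAlt
  depthNeg <- s$negRef + s$negAlt
  freqPos <- ifelse(depthPos > 0L, s$posAlt / depthPos, NA_real_)
  freqNeg <- ifelse(depthNeg > 0L, s$negAlt / depthNeg, NA_real_)
  lowDepth <- depthPos < minDepth | depthNeg < minDepth
  fixed <- !lowDepth &
    ((freqPos >= fixHi & freqNeg <= fixLo) |
     (freqPos <= fixLo & freqNeg >= fixHi))
  status <- rep("not_fixed", nrow(s))
  status[fixed] <- "fixed_difference"
  status[lowDepth] <- "low_depth"
  out <- data.frame(contig = s$contig, pos = s$pos,
                    freqPos = freqPos, freqNeg = freqNeg,
                    depthPos = depthPos, depthNeg = depthNeg,
                    status = factor(status,
                      levels = c("fixed_difference", "not_fixed",
                                 "low_depth")),
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(minDepth = minDepth, fixHi = fixHi,
                               fixLo = fixLo)
  out
}

#' Tile the genome and report candidate windows of fixed differences
#'
#' Tiles each contig with non-overlapping windows (default 1 kb; the last
#' tile per contig may be shorter) and reports every window containing at
#' least \code{minFixed} fixed-difference calls. Adjacent candidate windows
#' are merged into regions, available via
#' \code{S4Vectors::metadata(x)$regions}, so a locus spanning a tile
#' boundary is a single region in the companion report.
#'
#' @param calls Data frame from \code{\link{callFixedSites}}.
#' @param contigLengths Named integer vector of contig lengths.
#' @param window Tile width in bp (default 1000).
#' @param minFixed Minimum fixed differences per reported window
#'   (default 1).
#' @return A \code{GRanges} of candidate windows (1-based inclusive) with
#'   metadata column \code{nFixed}; merged regions and scan parameters in
#'   \code{metadata()}.
#' @export
windowScan <- function(calls, contigLengths, window = 1000L,
                       minFixed = 1L) {
  window <- as.integer(window)
  if (is.na(window) || window <= 0L) {
    stop("window must be a positive integer", call. = FALSE)
  }
  if (is.null(names(contigLengths))) {
    stop("contigLengths must be named", call. = FALSE)
  }
  seqlen <- stats::setNames(as.integer(contigLengths),
                            names(contigLengths))
  tiles <- GenomicRanges::tileGenome(seqlen, tilewidth = window,
                                     cut.last.tile.in.chrom = TRUE)
  fixed <- calls[calls$status == "fixed_difference", , drop = FALSE]
  if (nrow(fixed)) {
    sitesGr <- GenomicRanges::GRanges(
      fixed$contig,
      IRanges::IRanges(fixed$pos, fixed$pos))
    GenomeInfoDb::seqlevels(sitesGr) <- names(seqlen)
    n <- GenomicRanges::countOverlaps(tiles, sitesGr)
  } else {
    n <- integer(length(tiles))
  }
  cand <- tiles[n >= minFixed]
  S4Vectors::mcols(cand)$nFixed <- n[n >= minFixed]
  meta <- list(window = window, minFixed = minFixed,
               regions = GenomicRanges::reduce(cand),
               nSites = nrow(calls), nFixedSites = nrow(fixed))
  S4Vectors::metadata(cand) <- meta
  cand
}

#' Flag candidate windows with collapsed-paralog depth signatures
#'
#' Regions where closely related paralogs collapse onto a single locus in
#' the reference show inflated depth and spurious "fixed" differences.
#' For each window the mean per-site total depth is divided by the genome
#' median site depth; windows whose ratio exceeds \code{ratioThreshold}
#' (default 1.8, i.e. approaching twice the median, as expected when two
#' copies map to one) are flagged. Flagging only annotates; no window is
#' removed.
#'
#' @param windows \code{GRanges} from \code{\link{windowScan}}.
#' @param counts The \linkS4class{PoolCounts} the scan was run on.
#' @param ratioThreshold Depth-ratio threshold (default 1.8).
#' @return \code{windows} with added metadata columns
#'   \code{meanDepthRatio} and \code{artifactFlag}.
#' @export
flagArtifacts <- function(windows, counts, ratioThreshold = 1.8) {
  stopifnot(methods::is(counts, "PoolCounts"))
  s <- poolSites(counts)
  totalDepth <- s$posRef + s$posAlt + s$negRef + s$negAlt
  medDepth <- stats::median(totalDepth)
  ratio <- rep(NA_real_, length(windows))
  if (nrow(s) && length(windows)) {
    sitesGr <- GenomicRanges::GRanges(
      s$contig, IRanges::IRanges(s$pos, s$pos))
    hits <- GenomicRanges::findOverlaps(windows, sitesGr)
    if (length(hits)) {
      mean_by <- tapply(totalDepth[S4Vectors::subjectHits(hits)],
                        S4Vectors::queryHits(hits), mean)
      ratio[as.integer(names(mean_by))] <- mean_by / medDepth
    }
  }
  S4Vectors::mcols(windows)$meanDepthRatio <- as.numeric(ratio)
  S4Vectors::mcols(windows)$artifactFlag <-
    !is.na(ratio) & ratio > ratioThreshold
  md <- S4Vectors::metadata(windows)
  md$ratioThreshold <- ratioThreshold
  md$medianDepth <- medDepth
  S4Vectors::metadata(windows) <- md
  windows
}
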