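## Readers and writers for the standard formats touched by the pipeline.
## Coordinates are 1-based inclusive everywhere except BED output, which is
## 0-based half-open per the format; every writer states its convention and
## thresholds in header comments.

headerComments <- function(extra = character()) {
  c(paste0("tractScan ", pkgVersionString()),
    "coordinates: 1-based inclusive unless stated otherwise",
    extra)
}

#' Read gene sequences from a FASTA file
#'
#' Duplicate identifiers are rejected; lowercase residues are uppercased
#' with a warning; an empty file yields an empty set with a warning.
#'
#' @param path FASTA file.
#' @return Named \code{DNAStringSet}.
#' @export
readGeneFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(Biostrings::DNAStringSet())
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    warning("no records in FASTA file: ", path, call. = FALSE)
    return(Biostrings::DNAStringSet())
  }
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  txt <- as.character(raw)
  if (any(grepl("[a-z]", txt))) {
    warning("lowercase residues in ", path, " uppercased", call. = FALSE)
    txt <- toupper(txt)
  }
  bad <- grepl("[^ACGTN]", txt)
  if (any(bad)) {
    stop("record ", ids[which(bad)[1L]], " in ", path,
         " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(txt)
  names(out) <- ids
  out
}

#' Write gene sequences to FASTA
#'
#' @param seqs Named \code{DNAStringSet} (or named character vector).
#' @param path Output file; sequence lines wrap at 60 columns.
#' @return Invisibly, \code{path}.
#' @export
writeGeneFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

poolCountsTsvColumns <- c("contig", "pos", "ref", "alt",
                          "pos_ref", "pos_alt", "neg_ref", "neg_alt")

#' Read per-site pooled allele counts
#'
#' Two dialects are accepted. \code{tsv}: columns \code{contig, pos, ref,
#' alt, pos_ref, pos_alt, neg_ref, neg_alt} (header required, \code{#}
#' comment lines ignored). \code{vcf}: a minimal VCF whose first two
#' samples are the trait-positive and trait-negative pools carrying
#' \code{AD} (allelic depth) fields; only CHROM/POS/REF/ALT and AD are
#' used. Multiallelic records are collapsed to reference versus the
#' highest-depth alternative and flagged in the \code{multiallelic}
#' column. Positions must be strictly increasing within each contig.
#'
#' @param path Input file.
#' @param dialect \code{"tsv"} or \code{"vcf"}.
#' @return A \linkS4class{PoolCounts}.
#' @export
readPoolCounts <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "tsv") readPoolCountsTsv(path) else readPoolCountsVcf(path)
}

readPoolCountsTsv <- function(path) {
  ## ref/alt must stay character: a column of bare "T"s would otherwise
  ## be read as logical
  d <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = c(contig = "character",
                                        ref = "character",
                                        alt = "character"))
  missing <- setdiff(poolCountsTsvColumns, names(d))
  if (length(missing)) {
    stop("pool-count TSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sites <- data.frame(contig = as.character(d$contig),
                      pos = as.integer(d$pos),
                      ref = toupper(d$ref), alt = toupper(d$alt),
                      posRef = as.integer(d$pos_ref),
                      posAlt = as.integer(d$pos_alt),
                      negRef = as.integer(d$neg_ref),
                      negAlt = as.integer(d$neg_alt),
                      stringsAsFactors = FALSE)
  bad <- unlist(tapply(sites$pos, sites$contig,
                       function(p) is.unsorted(p, strictly = TRUE)))
  if (any(bad)) {
    stop("positions not strictly increasing within contig(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  PoolCounts(sites, meta = list(source = path, dialect = "tsv"))
}

readPoolCountsVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (!is.null(ad) && is.null(dim(ad))) {
    ad <- matrix(ad, nrow = 1L)
  }
  if (is.null(ad) || ncol(ad) < 2L) {
    stop("VCF ", path, " must carry AD for two pool samples",
         call. = FALSE)
  }
  n <- nrow(fix)
  parseAD <- function(x, record) {
    if (is.na(x) || x == ".") {
      stop("missing AD at record ", record, call. = FALSE)
    }
    as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
  }
  ref <- character(n); alt <- character(n)
  posRef <- integer(n); posAlt <- integer(n)
  negRef <- integer(n); negAlt <- integer(n)
  multi <- logical(n)
  for (i in seq_len(n)) {
    rec <- paste0(fix[i, "CHROM"], ":", fix[i, "POS"])
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    adP <- parseAD(ad[i, 1L], rec)
    adN <- parseAD(ad[i, 2L], rec)
    if (length(adP) != length(alts) + 1L ||
        length(adN) != length(alts) + 1L) {
      stop("AD length does not match allele count at record ", rec,
           call. = FALSE)
    }
    multi[i] <- length(alts) > 1L
    ai <- which.max(adP[-1L] + adN[-1L])  # highest-depth alternative
    ref[i] <- fix[i, "REF"]
    alt[i] <- alts[ai]
    posRef[i] <- adP[1L]; posAlt[i] <- adP[ai + 1L]
    negRef[i] <- adN[1L]; negAlt[i] <- adN[ai + 1L]
  }
  nMulti <- sum(multi)
  if (nMulti) {
    message(nMulti, " multiallelic record(s) collapsed to the ",
            "highest-depth alternative")
  }
  sites <- data.frame(contig = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      ref = ref, alt = alt,
                      posRef = posRef, posAlt = posAlt,
                      negRef = negRef, negAlt = negAlt,
                      multiallelic = multi,
                      stringsAsFactors = FALSE)
  bad <- unlist(tapply(sites$pos, sites$contig,
                       function(p) is.unsorted(p, strictly = TRUE)))
  if (any(bad)) {
    stop("positions not strictly increasing within contig(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  PoolCounts(sites, meta = list(source = path, dialect = "vcf",
                                nMultiallelic = nMulti))
}

#' Write pooled allele counts as TSV
#'
#' @param counts A \linkS4class{PoolCounts}.
#' @param path Output file.
#' @param comments Extra header-comment lines.
#' @return Invisibly, \code{path}.
#' @export
writePoolCounts <- function(counts, path, comments = character()) {
  stopifnot(methods::is(counts, "PoolCounts"))
  s <- poolSites(counts)
  out <- data.frame(contig = s$contig, pos = s$pos, ref = s$ref,
                    alt = s$alt, pos_ref = s$posRef, pos_alt = s$posAlt,
                    neg_ref = s$negRef, neg_alt = s$negAlt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", headerComments(comments)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a tetrad phenotype table
#'
#' TSV with columns \code{tetrad, spore1, spore2, spore3, spore4};
#' phenotypes \code{positive}, \code{negative} or \code{dead}.
#'
#' @param path File path.
#' @return For the reader, a data frame.
#' @export
readTetradTable <- function(path) {
  d <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("tetrad", paste0("spore", 1:4))
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("tetrad table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in paste0("spore", 1:4)) {
    d[[col]] <- tolower(d[[col]])
    bad <- !d[[col]] %in% TETRAD_PHENOTYPES
    if (any(bad)) {
      stop("invalid phenotype '", d[[col]][which(bad)[1L]],
           "' in ", path, call. = FALSE)
    }
  }
  d[, need]
}

#' @rdname readTetradTable
#' @param tetrads Data frame with columns \code{tetrad, spore1..spore4}.
#' @export
writeTetradTable <- function(tetrads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", headerComments()), con)
  utils::write.table(tetrads, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write candidate windows as BED
#'
#' Internal 1-based inclusive windows are converted to the BED convention
#' (0-based half-open): a window 1001-2000 emits start 1000, end 2000.
#' Scan thresholds are echoed as \code{#} header comments; an empty
#' candidate set yields a header-only file.
#'
#' @param windows \code{GRanges} from \code{\link{windowScan}} (optionally
#'   annotated by \code{\link{flagArtifacts}}).
#' @param path Output file.
#' @param comments Extra header-comment lines.
#' @return Invisibly, \code{path}.
#' @export
writeWindowsBed <- function(windows, path, comments = character()) {
  md <- S4Vectors::metadata(windows)
  hdr <- c("coordinates: BED 0-based half-open",
           if (!is.null(md$window)) paste0("window=", md$window),
           if (!is.null(md$minFixed)) paste0("minFixed=", md$minFixed),
           if (!is.null(md$ratioThreshold))
             paste0("ratioThreshold=", md$ratioThreshold),
           comments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c(headerComments()[1L], hdr)), con)
  if (length(windows)) {
    mc <- S4Vectors::mcols(windows)
    flagged <- if (!is.null(mc$artifactFlag)) mc$artifactFlag
               else rep(FALSE, length(windows))
    lines <- sprintf("%s\t%d\t%d\t%s\t%d",
                     as.character(GenomicRanges::seqnames(windows)),
                     GenomicRanges::start(windows) - 1L,
                     GenomicRanges::end(windows),
                     ifelse(flagged, "candidate_artifact", "candidate"),
                     mc$nFixed)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a chimera report as JSON
#'
#' @param report A \linkS4class{ChimeraReport}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeChimeraReport <- function(report, path) {
  stopifnot(methods::is(report, "ChimeraReport"))
  trs <- lapply(tracts(report), function(t) {
    list(recipient = recipientId(t), donor = donorId(t),
         minimal_span = minimalSpan(t), maximal_span = maximalSpan(t),
         n_support_sites = nSupportSites(t),
         n_snps_vs_recipient = t@nSnpsVsRecipient,
         n_nonsynonymous = t@nNonsynonymous,
         n_synonymous = t@nSynonymous)
  })
  obj <- list(schema_version = "1.0",
              tool = paste0("tractScan ", pkgVersionString()),
              coordinates = "1-based inclusive",
              candidate = report@candidateId,
              recipient = recipientId(report),
              donor = donorId(report),
              n_informative_sites = report@nInformative,
              residual_unexplained_sites = residualUnexplained(report),
              n_skipped_columns = report@nSkipped,
              tie_broken = report@tie,
              tracts = trs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write site assignments as TSV
#'
#' @param assignments Data frame from \code{\link{informativeSites}}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeSiteAssignments <- function(assignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", headerComments(c(
    paste0("parent_A=", attr(assignments, "idA")),
    paste0("parent_B=", attr(assignments, "idB")),
    paste0("skipped_columns=", attr(assignments, "nSkipped"))))), con)
  utils::write.table(assignments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a segregation result as JSON
#'
#' @param result A \linkS4class{SegregationResult}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeSegregationResult <- function(result, path) {
  stopifnot(methods::is(result, "SegregationResult"))
  obj <- list(schema_version = "1.0",
              tool = paste0("tractScan ", pkgVersionString()),
              n_tetrads = result@nTetrads,
              n_incomplete = result@nIncomplete,
              pattern_counts = as.list(result@patternCounts),
              n_pos_spores = result@nPosSpores,
              n_neg_spores = result@nNegSpores,
              binomial_p = result@binomialP,
              deviant_fraction = result@deviantFraction,
              consistent_single_locus = result@consistentSingleLocus)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
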