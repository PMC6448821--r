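## End-to-end scenario generation with ground truth.

scenarioDefaults <- function() {
  list(
    contig = "chrI",
    genomeLength = 100000L,   # 100-kb genome for the BSA scan
    nGenes = 4L,              # MALT-like four-member paralog family
    cdsLength = 1848L,        # ~616 codons, MFS transporter scale
    targetIdentity = 0.8,     # pairwise nucleotide identity of the family
    titv = 2,
    tractLength = 230L,       # single conversion tract length
    nTetrads = 15L,
    nMarkers = 200L,          # segregating sites across the genome
    coverage = 100,           # mean per-pool sequencing depth
    errorRate = 0.005,
    causal = TRUE,            # FALSE gives a null (no causal locus)
    dupRegion = NULL,         # c(start, end) of a collapsed-duplicate region
    dupFactor = 2             # depth inflation inside dupRegion
  )
}

#' Generate a complete simulated mapping scenario with ground truth
#'
#' Produces every input the pipeline consumes, mirroring an experiment in
#' which a paralog family member acquires a gene-conversion tract that
#' confers a dominant phenotype: a paralog family at the target identity,
#' a chimeric candidate (random recipient/donor pair, one tract of the
#' configured length at a random position), backcross tetrads, and pooled
#' allele counts over a set of segregating markers with one causal site.
#' In a null scenario (\code{causal = FALSE}) phenotypes are a random
#' 50:50 split independent of genotype. If \code{dupRegion} is set, counts
#' inside it are inflated by \code{dupFactor}, emulating a collapsed
#' paralogous repeat. If \code{dir} is given, FASTA/TSV inputs and a truth
#' JSON are written there.
#'
#' @param seed Integer seed; the scenario is a pure function of
#'   \code{(config, seed)}.
#' @param config Named list overriding any default (see Details in the
#'   package vignette); unknown names raise a configuration error.
#' @param dir Optional output directory.
#' @return A \linkS4class{ScenarioTruth}.
#' @examples
#' sc <- makeScenario(seed = 1, config = list(cdsLength = 300L,
#'                    tractLength = 60L, nMarkers = 20L))
#' scenarioTruth(sc)
#' @export
makeScenario <- function(seed, config = list(), dir = NULL) {
  defaults <- scenarioDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown scenario config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (cfg$tractLength < 1L || cfg$tractLength > cfg$cdsLength) {
    stop("tractLength must lie in 1..cdsLength", call. = FALSE)
  }
  if (cfg$nMarkers > cfg$genomeLength) {
    stop("more markers than genome positions", call. = FALSE)
  }
  if (!is.null(cfg$dupRegion) &&
      (length(cfg$dupRegion) != 2L || cfg$dupRegion[1] > cfg$dupRegion[2])) {
    stop("dupRegion must be c(start, end)", call. = FALSE)
  }
  seed <- as.integer(seed)

  out <- withSeed(seed, {
    fam <- simulateGeneFamily(nGenes = cfg$nGenes,
                              cdsLength = cfg$cdsLength,
                              targetIdentity = cfg$targetIdentity,
                              seed = NULL, titv = cfg$titv)
    ids <- names(fam$genes)
    pick <- sample(ids, 2L)
    recipientId <- pick[1L]
    donorId <- pick[2L]
    tractStart <- sample.int(cfg$cdsLength - cfg$tractLength + 1L, 1L)
    tract <- c(tractStart, tractStart + cfg$tractLength - 1L)
    candidate <- applyGeneConversion(
      as.character(fam$genes[[recipientId]]),
      as.character(fam$genes[[donorId]]), tract)
    candidateId <- paste0(recipientId, "_chimera")

    markerPos <- sort(sample.int(cfg$genomeLength, cfg$nMarkers))
    refAllele <- sample(BASES, cfg$nMarkers, replace = TRUE)
    altAllele <- vapply(refAllele, function(b) {
      sample(setdiff(BASES, b), 1L)
    }, "")
    markers <- data.frame(contig = cfg$contig, pos = markerPos,
                          ref = refAllele, alt = unname(altAllele),
                          stringsAsFactors = FALSE)
    causalIndex <- if (cfg$causal) sample.int(cfg$nMarkers, 1L)
                   else NA_integer_

    bx <- simulateBackcrossTetrads(
      nTetrads = cfg$nTetrads, nMarkers = cfg$nMarkers,
      causalIndex = if (cfg$causal) causalIndex else 1L, seed = NULL)
    phen <- if (cfg$causal) {
      bx$phenotypes
    } else {
      sample(rep(c("positive", "negative"), each = 2L * cfg$nTetrads))
    }
    tetrads <- if (cfg$causal) {
      bx$tetrads
    } else {
      data.frame(tetrad = seq_len(cfg$nTetrads),
                 matrix(phen, nrow = cfg$nTetrads, ncol = 4L, byrow = TRUE,
                        dimnames = list(NULL, paste0("spore", 1:4))),
                 stringsAsFactors = FALSE)
    }
    counts <- simulatePoolCounts(bx$genotypes, phen, markers,
                                 coverage = cfg$coverage,
                                 errorRate = cfg$errorRate, seed = NULL)
    if (!is.null(cfg$dupRegion)) {
      s <- poolSites(counts)
      inDup <- s$pos >= cfg$dupRegion[1] & s$pos <= cfg$dupRegion[2]
      for (col in c("posRef", "posAlt", "negRef", "negAlt")) {
        s[[col]][inDup] <- as.integer(round(s[[col]][inDup] * cfg$dupFactor))
      }
      counts <- PoolCounts(s, meta = counts@meta)
    }
    causalWindow <- if (cfg$causal) {
      tile <- (markers$pos[causalIndex] - 1L) %/% 1000L
      c(tile * 1000L + 1L,
        min((tile + 1L) * 1000L, cfg$genomeLength))
    } else {
      c(NA_integer_, NA_integer_)
    }
    methods::new("ScenarioTruth",
      seed = seed, config = cfg,
      family = fam$genes, ancestor = fam$ancestor,
      candidateId = candidateId, candidate = candidate,
      recipientId = recipientId, donorId = donorId,
      tract = as.integer(tract),
      markers = markers, causalIndex = causalIndex,
      causalWindow = as.integer(causalWindow),
      genotypes = bx$genotypes, phenotypes = phen,
      tetrads = tetrads, counts = counts,
      contigLengths = stats::setNames(as.integer(cfg$genomeLength),
                                      cfg$contig))
  })

  if (!is.null(dir)) writeScenario(out, dir)
  out
}

#' Write a scenario's pipeline inputs and truth to a directory
#'
#' Emits \code{candidate.fasta}, \code{panel.fasta},
#' \code{pool_counts.tsv}, \code{tetrads.tsv} and \code{truth.json}.
#' Outputs are byte-deterministic for a given scenario.
#'
#' @param scenario A \linkS4class{ScenarioTruth}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeScenario <- function(scenario, dir) {
  stopifnot(methods::is(scenario, "ScenarioTruth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("candidate.fasta", "panel.fasta",
                            "pool_counts.tsv", "tetrads.tsv",
                            "truth.json"))
  names(paths) <- c("candidate", "panel", "counts", "tetrads", "truth")
  cand <- Biostrings::DNAStringSet(scenario@candidate)
  names(cand) <- scenario@candidateId
  writeGeneFasta(cand, paths["candidate"])
  writeGeneFasta(scenario@family, paths["panel"])
  writePoolCounts(scenario@counts, paths["counts"],
                  comments = paste0("seed=", scenario@seed))
  writeTetradTable(scenario@tetrads, paths["tetrads"])
  truth <- list(
    schema_version = "1.0",
    coordinates = "1-based inclusive",
    seed = scenario@seed,
    recipient = scenario@recipientId,
    donor = scenario@donorId,
    tract = scenario@tract,
    causal_index = scenario@causalIndex,
    causal_pos = if (is.na(scenario@causalIndex)) NA else
      scenario@markers$pos[scenario@causalIndex],
    causal_window = scenario@causalWindow,
    contig_lengths = as.list(scenario@contigLengths))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       pretty = TRUE, na = "null", digits = NA)
  invisible(paths)
}
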