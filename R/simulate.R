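## Seeded synthetic-data generators with ground truth.

## Random in-frame CDS (character vector of single bases): an ATG start
## followed by random sense codons, no internal or terminal stop.
randomCdsChars <- function(len) {
  if (len %% 3L != 0L) stop("cdsLength must be a multiple of 3",
                            call. = FALSE)
  cods <- c("ATG", sample(SENSE_CODONS, len / 3L - 1L, replace = TRUE))
  chars(paste(cods, collapse = ""))
}

## Apply n accepted codon-aware point mutations to a CDS character vector.
## Transition:transversion ratio kappa; mutations creating a stop codon
## are rejected and redrawn, so divergence accumulates without nonsense
## changes, keeping amino-acid identity tracking nucleotide identity.
mutateCdsChars <- function(seq, n, kappa = 2) {
  L <- length(seq)
  pTransition <- kappa / (kappa + 2)
  done <- 0L
  while (done < n) {
    k <- n - done
    pos <- sample.int(L, k, replace = TRUE)
    u <- stats::runif(k)
    for (i in seq_len(k)) {
      p <- pos[i]
      old <- seq[p]
      new <- if (u[i] < pTransition) {
        TRANSITIONS[[old]]
      } else {
        tv <- setdiff(BASES, c(old, TRANSITIONS[[old]]))
        tv[sample.int(2L, 1L)]
      }
      seq[p] <- new
      c0 <- (p - 1L) %/% 3L
      codon <- paste(seq[(c0 * 3L + 1L):(c0 * 3L + 3L)], collapse = "")
      if (codon %in% STOP_CODONS) {
        seq[p] <- old
        next
      }
      done <- done + 1L
      if (done >= n) break
    }
  }
  seq
}

pairIdentityPct <- function(a, b) 100 * mean(a == b)

#' Simulate a paralogous gene family at target nucleotide identity
#'
#' Derives \code{nGenes} coding sequences from a common random ancestor by
#' codon-aware point mutation (stop codons rejected, transition bias
#' \code{titv}) until every realized pairwise nucleotide identity falls
#' within \code{tol} of its target. Mutations are applied greedily to the
#' pair currently farthest above target, so a scalar target yields an
#' (approximately) exchangeable family and a matrix target is honoured
#' pair by pair; targets a star-shaped family cannot realize raise a
#' configuration error. Deterministic per seed.
#'
#' @param nGenes Number of paralogs (default 4).
#' @param cdsLength CDS length in bp, multiple of 3 (default 1848,
#'   ~616 codons, the scale of an MFS sugar transporter).
#' @param targetIdentity Scalar in (0,1), or an \code{nGenes x nGenes}
#'   matrix of pairwise targets (default 0.8).
#' @param seed Integer seed (required for reproducibility; \code{NULL}
#'   uses the current RNG stream).
#' @param titv Transition/transversion ratio (default 2).
#' @param tol Tolerance on realized identity, as a fraction (default 0.02,
#'   i.e. 2 percentage points).
#' @return List with \code{genes} (named \code{DNAStringSet}
#'   \code{gene1..geneN}), \code{ancestor} (character), and
#'   \code{identity} (realized pairwise identity matrix, percent).
#' @examples
#' fam <- simulateGeneFamily(nGenes = 3, cdsLength = 300,
#'                           targetIdentity = 0.9, seed = 1)
#' fam$identity
#' @export
simulateGeneFamily <- function(nGenes = 4L, cdsLength = 1848L,
                               targetIdentity = 0.8, seed = NULL,
                               titv = 2, tol = 0.02) {
  nGenes <- as.integer(nGenes)
  if (nGenes < 2L) stop("nGenes must be at least 2", call. = FALSE)
  tgt <- targetIdentity
  if (is.matrix(tgt)) {
    if (!all(dim(tgt) == nGenes)) {
      stop("targetIdentity matrix must be nGenes x nGenes", call. = FALSE)
    }
    if (!isSymmetric(unname(tgt))) {
      stop("targetIdentity matrix must be symmetric", call. = FALSE)
    }
  } else {
    tgt <- matrix(targetIdentity, nGenes, nGenes)
  }
  diag(tgt) <- NA_real_
  offDiag <- tgt[upper.tri(tgt)]
  if (any(offDiag <= 0 | offDiag > 1)) {
    stop("identity targets must lie in (0,1]", call. = FALSE)
  }
  pairs <- utils::combn(nGenes, 2L)
  tgtPct <- tgt * 100
  tolPct <- tol * 100

  ## One divergence attempt from a fresh ancestor. Greedy: always push the
  ## pair currently farthest above target, mutating only the member whose
  ## other pairs have the most slack above their lower bounds, with a step
  ## sized to the excess. Returns NULL when the 1-mutation granularity
  ## (100/L points at short lengths) drops some pair below target - tol;
  ## the caller then retries with a fresh ancestor.
  familyAttempt <- function() {
    anc <- randomCdsChars(cdsLength)
    genes <- replicate(nGenes, anc, simplify = FALSE)
    nPair <- ncol(pairs)
    repeat {
      idm <- vapply(seq_len(nPair), function(j) {
        pairIdentityPct(genes[[pairs[1L, j]]], genes[[pairs[2L, j]]])
      }, 0)
      excess <- idm - tgtPct[t(pairs)]
      if (any(excess < -tolPct)) return(NULL)
      if (max(excess) <= 0) break
      w <- which.max(excess)
      slackOf <- function(g) {
        other <- which(apply(pairs == g, 2L, any))
        other <- setdiff(other, w)
        if (!length(other)) return(Inf)
        min(idm[other] - (tgtPct[t(pairs)][other] - tolPct))
      }
      cand2 <- pairs[, w]
      g <- cand2[which.max(vapply(cand2, slackOf, 0))]
      nMut <- max(1L, min(as.integer(ceiling(excess[w] * cdsLength / 200)),
                          as.integer(ceiling(0.012 * cdsLength))))
      genes[[g]] <- mutateCdsChars(genes[[g]], nMut, kappa = titv)
    }
    list(anc = anc, genes = genes, idm = idm)
  }

  withSeed(seed, {
    res <- NULL
    for (attempt in 1:5) {
      res <- familyAttempt()
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      stop("unreachable identity targets: some pairwise identity fell ",
           "more than ", tolPct, " points below target in every attempt; ",
           "the target matrix is inconsistent with a star-shaped family",
           call. = FALSE)
    }
    realized <- matrix(NA_real_, nGenes, nGenes)
    for (j in seq_len(ncol(pairs))) {
      realized[pairs[1L, j], pairs[2L, j]] <- res$idm[j]
      realized[pairs[2L, j], pairs[1L, j]] <- res$idm[j]
    }
    ids <- paste0("gene", seq_len(nGenes))
    dimnames(realized) <- list(ids, ids)
    genesSet <- Biostrings::DNAStringSet(
      vapply(res$genes, paste, "", collapse = ""))
    names(genesSet) <- ids
    list(genes = genesSet,
         ancestor = paste(res$anc, collapse = ""),
         identity = realized)
  })
}

#' Apply a gene-conversion tract to a recipient sequence
#'
#' Replaces the recipient segment \code{tract[1]..tract[2]} (1-based
#' inclusive) with the corresponding donor segment; outside the tract the
#' output equals the recipient. Sequences must be the same length (in
#' direct register, as simulator families are).
#'
#' @param recipient,donor Equal-length nucleotide sequences.
#' @param tract Integer \code{c(start, end)}, 1-based inclusive,
#'   within the gene.
#' @return Chimeric sequence (character scalar).
#' @examples
#' applyGeneConversion("AAAAAA", "CCCCCC", c(3, 4))  # "AACCAA"
#' @export
applyGeneConversion <- function(recipient, donor, tract) {
  r <- seqToChar(recipient, "recipient")
  d <- seqToChar(donor, "donor")
  if (nchar(r) != nchar(d)) {
    stop("recipient and donor must be the same length", call. = FALSE)
  }
  tract <- as.integer(tract)
  if (length(tract) != 2L || anyNA(tract) || tract[1L] > tract[2L]) {
    stop("tract must be c(start, end) with start <= end", call. = FALSE)
  }
  if (tract[1L] < 1L || tract[2L] > nchar(r)) {
    stop("tract lies outside the gene (length ", nchar(r), ")",
         call. = FALSE)
  }
  out <- r
  substr(out, tract[1L], tract[2L]) <- substr(d, tract[1L], tract[2L])
  out
}

#' Simulate backcross tetrads segregating a dominant single locus
#'
#' Models meiosis of an F1 heterozygote: at every marker, exactly two of
#' the four spores in a tetrad receive the derived allele (2:2
#' segregation), and unlinked markers assort independently. Spore
#' phenotype is \code{positive} iff it carries the derived allele at the
#' causal marker (full penetrance), giving 2:2 phenotype segregation in
#' every tetrad.
#'
#' @param nTetrads Number of tetrads (default 15).
#' @param nMarkers Number of segregating markers (default 1).
#' @param causalIndex Which marker is causal (default 1).
#' @param seed Integer seed, or \code{NULL}.
#' @return List with \code{tetrads} (data frame \code{tetrad,
#'   spore1..spore4} of phenotypes), \code{genotypes} (spore-by-marker 0/1
#'   matrix, rows \code{t<t>s<s>}), and \code{phenotypes} (character
#'   vector aligned with genotype rows).
#' @examples
#' bx <- simulateBackcrossTetrads(15, seed = 1)
#' table(bx$phenotypes)  # 30 positive, 30 negative
#' @export
simulateBackcrossTetrads <- function(nTetrads = 15L, nMarkers = 1L,
                                     causalIndex = 1L, seed = NULL) {
  nTetrads <- as.integer(nTetrads)
  nMarkers <- as.integer(nMarkers)
  causalIndex <- as.integer(causalIndex)
  if (nTetrads < 1L || nMarkers < 1L) {
    stop("nTetrads and nMarkers must be positive", call. = FALSE)
  }
  if (causalIndex < 1L || causalIndex > nMarkers) {
    stop("causalIndex must lie in 1..nMarkers", call. = FALSE)
  }
  withSeed(seed, {
    geno <- matrix(0L, nrow = 4L * nTetrads, ncol = nMarkers)
    rownames(geno) <- paste0("t", rep(seq_len(nTetrads), each = 4L),
                             "s", rep(1:4, nTetrads))
    for (t in seq_len(nTetrads)) {
      rows <- (t - 1L) * 4L + 1:4
      for (m in seq_len(nMarkers)) {
        geno[rows[sample.int(4L, 2L)], m] <- 1L
      }
    }
    phen <- ifelse(geno[, causalIndex] == 1L, "positive", "negative")
    tetrads <- data.frame(
      tetrad = seq_len(nTetrads),
      matrix(phen, nrow = nTetrads, ncol = 4L, byrow = TRUE,
             dimnames = list(NULL, paste0("spore", 1:4))),
      stringsAsFactors = FALSE)
    list(tetrads = tetrads, genotypes = geno,
         phenotypes = unname(phen))
  })
}

#' Simulate pooled sequencing allele counts for two phenotype pools
#'
#' Emulates pooled whole-genome sequencing at the allele-count level: for
#' each pool and site, read depth is Poisson around the mean coverage and
#' the alternative-read count is binomial with success probability
#' \code{f*(1-e) + (1-f)*e}, where \code{f} is the pool's true
#' derived-allele frequency and \code{e} the per-read error rate.
#'
#' @param genotypes Spore-by-marker 0/1 matrix of derived-allele carriage.
#' @param phenotypes Character vector (\code{positive}/\code{negative})
#'   assigning spores to pools; both pools must be non-empty.
#' @param markers Data frame \code{contig, pos, ref, alt}, one row per
#'   genotype column, positions sorted within contig.
#' @param coverage Mean per-pool depth (default 100).
#' @param errorRate Per-read error rate (default 0.005).
#' @param seed Integer seed, or \code{NULL}.
#' @return A \linkS4class{PoolCounts}.
#' @export
simulatePoolCounts <- function(genotypes, phenotypes, markers,
                               coverage = 100, errorRate = 0.005,
                               seed = NULL) {
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  if (errorRate < 0 || errorRate >= 0.5) {
    stop("errorRate must lie in [0, 0.5)", call. = FALSE)
  }
  if (nrow(markers) != ncol(genotypes)) {
    stop("markers must have one row per genotype column", call. = FALSE)
  }
  pos <- phenotypes == "positive"
  if (!any(pos) || all(pos)) {
    stop("both pools must be non-empty", call. = FALSE)
  }
  fPos <- colMeans(genotypes[pos, , drop = FALSE])
  fNeg <- colMeans(genotypes[!pos, , drop = FALSE])
  m <- nrow(markers)
  withSeed(seed, {
    depthPos <- stats::rpois(m, coverage)
    depthNeg <- stats::rpois(m, coverage)
    pAltPos <- fPos * (1 - errorRate) + (1 - fPos) * errorRate
    pAltNeg <- fNeg * (1 - errorRate) + (1 - fNeg) * errorRate
    altPos <- stats::rbinom(m, depthPos, pAltPos)
    altNeg <- stats::rbinom(m, depthNeg, pAltNeg)
    PoolCounts(
      data.frame(contig = markers$contig, pos = markers$pos,
                 ref = markers$ref, alt = markers$alt,
                 posRef = depthPos - altPos, posAlt = altPos,
                 negRef = depthNeg - altNeg, negAlt = altNeg,
                 stringsAsFactors = FALSE),
      meta = list(coverage = coverage, errorRate = errorRate,
                  seed = seed,
                  nPosSpores = sum(pos), nNegSpores = sum(!pos)))
  })
}
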