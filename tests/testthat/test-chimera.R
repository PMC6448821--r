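## Helper: build an assignments data frame in the shape informativeSites
## produces, for direct inferTracts tests.
makeAssignments <- function(pos, states, idA = "R", idB = "D") {
  d <- data.frame(column = pos, posCandidate = pos,
                  baseCandidate = "A", baseA = "A", baseB = "C",
                  state = factor(states,
                    levels = c("matches_A", "matches_B", "matches_neither")),
                  stringsAsFactors = FALSE)
  attr(d, "idA") <- idA
  attr(d, "idB") <- idB
  attr(d, "nSkipped") <- 0L
  d
}

test_that("informativeSites assigns candidate bases to the right parent", {
  s <- informativeSites("AATA", "AAAA", "AATA", idA = "pA", idB = "pB")
  expect_equal(nrow(s), 1)
  expect_equal(s$posCandidate, 3)
  expect_equal(as.character(s$state), "matches_B")

  s2 <- informativeSites("AAAA", "AAAA", "AATA")
  expect_true(all(s2$state == "matches_A"))
})

test_that("candidate identical to both parents yields no informative sites", {
  s <- informativeSites("ACGT", "ACGT", "ACGT")
  expect_equal(nrow(s), 0)
})

test_that("inferTracts delimits minimal and maximal spans as defined", {
  a <- makeAssignments(c(10, 20, 30, 40, 50, 60),
                       c("matches_A", "matches_A", "matches_B",
                         "matches_B", "matches_B", "matches_A"))
  trs <- inferTracts(a, minRun = 3, geneLength = 100)
  expect_length(trs, 1)
  expect_equal(minimalSpan(trs[[1]]), c(30L, 50L))
  expect_equal(maximalSpan(trs[[1]]), c(21L, 59L))
  expect_equal(nSupportSites(trs[[1]]), 3L)
  expect_equal(recipientId(trs[[1]]), "R")
  expect_equal(donorId(trs[[1]]), "D")
})

test_that("inferTracts returns no tracts for all-recipient assignments", {
  a <- makeAssignments(c(5, 10, 15), rep("matches_A", 3))
  expect_length(inferTracts(a, geneLength = 20), 0)
  expect_length(inferTracts(a[0, ], geneLength = 20), 0)
})

test_that("sub-threshold donor runs are reported as point conversions", {
  a <- makeAssignments(c(10, 20, 30, 40),
                       c("matches_A", "matches_B", "matches_B",
                         "matches_A"))
  trs <- inferTracts(a, minRun = 3, geneLength = 50)
  expect_length(trs, 0)
  pts <- attr(trs, "pointConversions")
  expect_equal(pts$posStart, 20)
  expect_equal(pts$runLength, 2)
})

test_that("tracts touching a gene end extend to the boundary", {
  a <- makeAssignments(c(10, 20, 30, 40),
                       c("matches_B", "matches_B", "matches_B",
                         "matches_A"))
  trs <- inferTracts(a, minRun = 3, geneLength = 100)
  expect_equal(maximalSpan(trs[[1]]), c(1L, 39L))
})

test_that("tractStatistics counts SNPs and classifies codons", {
  rec <- strrep("GAAACC", 10)                   # 60 bp
  cand <- rec
  substr(cand, 21, 21) <- "T"                   # GAA -> GAT: Glu -> Asp
  substr(cand, 30, 30) <- "G"                   # GAA -> GAG: synonymous
  tr <- methods::new("ConversionTract", recipientId = "R", donorId = "D",
                     minimalSpan = c(21L, 30L), maximalSpan = c(19L, 30L),
                     nSupportSites = 2L)
  done <- tractStatistics(tr, cand, rec)
  cnt <- tractCounts(done)
  expect_equal(unname(cnt["nSnpsVsRecipient"]), 2L)
  expect_equal(unname(cnt["nSynonymous"]), 1L)
  expect_equal(unname(cnt["nNonsynonymous"]), 1L)

  trEmpty <- methods::new("ConversionTract", recipientId = "R",
                          donorId = "D", minimalSpan = c(21L, 30L),
                          maximalSpan = c(19L, 30L), nSupportSites = 0L)
  same <- tractStatistics(trEmpty, rec, rec)
  expect_equal(unname(tractCounts(same)["nSnpsVsRecipient"]), 0L)
})

test_that("tractStatistics rejects spans outside the candidate", {
  tr <- methods::new("ConversionTract", recipientId = "R", donorId = "D",
                     minimalSpan = c(5L, 8L), maximalSpan = c(5L, 999L),
                     nSupportSites = 3L)
  expect_error(tractStatistics(tr, "ACGTACGT", "ACGTACGT"), "outside")
})

test_that("multi-hit codons are classified by net amino-acid effect", {
  rec <- "ATGGAAACC"
  cand <- "ATGGAGACC"
  substr(cand, 4, 6) <- "CGT"   # GAA -> CGT, 3 hits, Glu -> Arg
  tr <- methods::new("ConversionTract", recipientId = "R", donorId = "D",
                     minimalSpan = c(4L, 6L), maximalSpan = c(1L, 9L),
                     nSupportSites = 3L)
  done <- tractStatistics(tr, cand, rec)
  cnt <- tractCounts(done)
  expect_equal(unname(cnt["nSnpsVsRecipient"]), 3L)
  expect_equal(unname(cnt["nNonsynonymous"]), 1L)
  expect_equal(unname(cnt["nSynonymous"]), 0L)
})

test_that("scanGeneFamily recovers a simulated conversion exactly", {
  for (seed in c(41, 42, 43)) {
    sc <- makeScenario(seed = seed)
    rep <- scanGeneFamily(sc@candidate, sc@family,
                          candidateId = sc@candidateId)
    expect_equal(recipientId(rep), sc@recipientId)
    expect_equal(donorId(rep), sc@donorId)
    expect_length(tracts(rep), 1)
    span <- maximalSpan(tracts(rep)[[1]])
    expect_lte(span[1], sc@tract[1])
    expect_gte(span[2], sc@tract[2])
    # SNP count against a brute-force positional diff within the span
    rec <- as.character(sc@family[[sc@recipientId]])
    d <- diffPositionsOracle(sc@candidate, rec)
    expect_equal(tractCounts(tracts(rep)[[1]])[["nSnpsVsRecipient"]],
                 sum(d >= span[1] & d <= span[2]))
  }
})

test_that("a candidate identical to a panel member has no tracts", {
  fam <- simulateGeneFamily(nGenes = 3, cdsLength = 300,
                            targetIdentity = 0.8, seed = 44)
  rep <- scanGeneFamily(as.character(fam$genes[[2]]), fam$genes)
  expect_equal(recipientId(rep), "gene2")
  expect_length(tracts(rep), 0)
  expect_equal(residualUnexplained(rep), 0L)
})

test_that("equidistant identical panel members tie-break deterministically", {
  fam <- simulateGeneFamily(nGenes = 2, cdsLength = 300,
                            targetIdentity = 0.8, seed = 45)
  g <- as.character(fam$genes[[1]])
  panel <- c(zz_twin = as.character(fam$genes[[2]]),
             aa_twin = as.character(fam$genes[[2]]))
  rep <- scanGeneFamily(g, panel)
  expect_true(rep@tie)
  expect_equal(recipientId(rep), "aa_twin")  # lexicographic
})

test_that("reports are invariant under panel reordering", {
  sc <- makeScenario(seed = 46, config = list(cdsLength = 900L,
                                              tractLength = 150L))
  fwd <- scanGeneFamily(sc@candidate, sc@family)
  revp <- scanGeneFamily(sc@candidate, rev(as.character(sc@family)))
  expect_equal(recipientId(fwd), recipientId(revp))
  expect_equal(donorId(fwd), donorId(revp))
  expect_equal(lapply(tracts(fwd), maximalSpan),
               lapply(tracts(revp), maximalSpan))
})

test_that("scanGeneFamily rejects panels smaller than two", {
  expect_error(scanGeneFamily("ACGTAA", c(one = "ACGTAA")), "at least 2")
})
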