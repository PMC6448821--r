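test_that("simulated families realize their target identity", {
  for (seed in 71:73) {
    fam <- simulateGeneFamily(nGenes = 4, cdsLength = 1848,
                              targetIdentity = 0.8, seed = seed)
    off <- fam$identity[upper.tri(fam$identity)]
    expect_true(all(off >= 78 & off <= 82))
  }
})

test_that("a target of 1 leaves the family identical to the ancestor", {
  fam <- simulateGeneFamily(nGenes = 3, cdsLength = 300,
                            targetIdentity = 1, seed = 74)
  expect_true(all(as.character(fam$genes) == fam$ancestor))
})

test_that("matrix identity targets are honoured pair by pair", {
  tgt <- matrix(c(NA, 0.90, 0.80,
                  0.90, NA, 0.80,
                  0.80, 0.80, NA), 3, 3)
  diag(tgt) <- 1
  fam <- simulateGeneFamily(nGenes = 3, cdsLength = 1200,
                            targetIdentity = tgt, seed = 75)
  expect_true(abs(fam$identity[1, 2] - 90) <= 2)
  expect_true(abs(fam$identity[1, 3] - 80) <= 2)
  expect_true(abs(fam$identity[2, 3] - 80) <= 2)
})

test_that("family simulation is deterministic per seed and codon-clean", {
  f1 <- simulateGeneFamily(nGenes = 3, cdsLength = 300,
                           targetIdentity = 0.8, seed = 76)
  f2 <- simulateGeneFamily(nGenes = 3, cdsLength = 300,
                           targetIdentity = 0.8, seed = 76)
  expect_identical(as.character(f1$genes), as.character(f2$genes))
  tmp1 <- tempfile(fileext = ".fasta"); tmp2 <- tempfile(fileext = ".fasta")
  writeGeneFasta(f1$genes, tmp1)
  writeGeneFasta(f2$genes, tmp2)
  expect_identical(readBin(tmp1, "raw", file.size(tmp1)),
                   readBin(tmp2, "raw", file.size(tmp2)))
  # no internal stops anywhere in the family
  for (g in as.character(f1$genes)) {
    expect_silent(p <- translateCds(g))
    expect_false(grepl("\\*", as.character(p)))
  }
})

test_that("invalid family configurations are rejected", {
  expect_error(simulateGeneFamily(cdsLength = 100, seed = 1), "multiple of 3")
  expect_error(simulateGeneFamily(targetIdentity = 1.2, seed = 1), "\\(0,1]")
  expect_error(simulateGeneFamily(nGenes = 1, seed = 1), "at least 2")
})

test_that("applyGeneConversion edits exactly the tract", {
  rec <- "AAAAAA"; don <- "CCCCCC"
  expect_equal(applyGeneConversion(rec, don, c(3, 4)), "AACCAA")
  expect_equal(applyGeneConversion(rec, don, c(1, 6)), don)
  one <- applyGeneConversion(rec, don, c(2, 2))
  expect_lte(length(diffPositionsOracle(one, rec)), 1)
  expect_error(applyGeneConversion(rec, don, c(0, 3)), "outside")
  expect_error(applyGeneConversion(rec, don, c(4, 3)), "start <= end")
  expect_error(applyGeneConversion(rec, "CCC", c(1, 2)), "same length")
})

test_that("conversion differences are confined to the tract", {
  set.seed(81)
  for (i in 1:10) {
    fam <- simulateGeneFamily(nGenes = 2, cdsLength = 300,
                              targetIdentity = 0.8,
                              seed = sample.int(1e6, 1))
    rec <- as.character(fam$genes[[1]])
    don <- as.character(fam$genes[[2]])
    s <- sample(300, 1); e <- min(300, s + sample(5:60, 1))
    out <- applyGeneConversion(rec, don, c(s, e))
    expect_true(all(diffPositionsOracle(out, rec) %in% s:e))
    expect_true(all(!diffPositionsOracle(out, don) %in% s:e))
    # idempotent for a fixed tract and donor
    expect_identical(applyGeneConversion(out, don, c(s, e)), out)
  }
})

test_that("backcross tetrads segregate 2:2 at the causal locus", {
  bx <- simulateBackcrossTetrads(nTetrads = 15, seed = 82)
  expect_equal(sum(bx$phenotypes == "positive"), 30)
  expect_equal(sum(bx$phenotypes == "negative"), 30)
  one <- simulateBackcrossTetrads(nTetrads = 1, seed = 83)
  expect_equal(classifyTetrad(unlist(one$tetrads[1, -1]))$pattern, "2:2")
})

test_that("markers unlinked to the causal locus show no association", {
  bx <- simulateBackcrossTetrads(nTetrads = 1000, nMarkers = 2,
                                 causalIndex = 1, seed = 84)
  pheno <- as.integer(bx$phenotypes == "positive")
  r <- stats::cor(pheno, bx$genotypes[, 2])
  expect_lt(abs(r), 0.1)
})

test_that("pooled counts follow the error-convolved binomial model", {
  geno <- matrix(c(1, 1, 0, 0), ncol = 1)
  phen <- c("positive", "positive", "negative", "negative")
  mk <- data.frame(contig = "chrI", pos = 100L, ref = "A", alt = "T")
  pc <- simulatePoolCounts(geno, phen, mk, coverage = 50, errorRate = 0,
                           seed = 85)
  s <- poolSites(pc)
  expect_equal(s$posRef, 0L)            # f = 1, no error: every read alt
  expect_gt(s$posAlt, 0L)
  expect_equal(s$negAlt, 0L)            # f = 0

  ## pool at true frequency 0.5, deep coverage: concentration within 0.02
  geno3 <- matrix(rep(c(1, 0), 30), ncol = 1)
  phen3 <- rep(c("positive", "negative"), each = 30)
  pc3 <- simulatePoolCounts(geno3, phen3, mk, coverage = 10000,
                            errorRate = 0, seed = 87)
  s3 <- poolSites(pc3)
  fobs <- s3$posAlt / (s3$posRef + s3$posAlt)
  expect_lt(abs(fobs - 0.5), 0.02)

  expect_identical(poolSites(simulatePoolCounts(geno, phen, mk, seed = 88)),
                   poolSites(simulatePoolCounts(geno, phen, mk, seed = 88)))
  expect_error(simulatePoolCounts(geno, phen, mk, coverage = 0), "positive")
})

test_that("scanning an unconverted family member reports no tracts", {
  sc <- makeScenario(seed = 89, config = list(cdsLength = 900L,
                                              tractLength = 150L))
  pure <- as.character(sc@family[[sc@recipientId]])
  rep <- scanGeneFamily(pure, sc@family)
  expect_equal(recipientId(rep), sc@recipientId)
  expect_length(tracts(rep), 0)
})

test_that("scenario outputs are byte-reproducible per seed", {
  d1 <- file.path(tempdir(), "sc1"); d2 <- file.path(tempdir(), "sc2")
  cfg <- list(cdsLength = 300L, tractLength = 60L, nMarkers = 30L)
  makeScenario(seed = 90, config = cfg, dir = d1)
  makeScenario(seed = 90, config = cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     label = f)
  }
  expect_error(makeScenario(seed = 1, config = list(bogus = 1)), "unknown")
})

test_that("scenario truth is sufficient to score downstream calls", {
  sc <- makeScenario(seed = 91, config = list(cdsLength = 600L,
                                              tractLength = 120L))
  tr <- scenarioTruth(sc)
  expect_true(all(c("recipientId", "donorId", "tract", "causalIndex",
                    "causalWindow") %in% names(tr)))
  expect_equal(sc@markers$pos[tr$causalIndex] >= tr$causalWindow[1], TRUE)
  expect_equal(sc@markers$pos[tr$causalIndex] <= tr$causalWindow[2], TRUE)
})
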