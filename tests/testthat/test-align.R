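test_that("globalAlign handles the identity and single-gap cases", {
  aln <- globalAlign("ACGT", "ACGT")
  rows <- alignedRows(aln)
  expect_false(any(grepl("-", rows)))
  expect_equal(alignmentScore(aln), 4)

  aln2 <- globalAlign("ACGT", "AGT")
  rows2 <- alignedRows(aln2)
  expect_equal(sum(strsplit(rows2[[2]], "")[[1]] == "-"), 1)
  expect_equal(alignmentScore(aln2), 3 * 1 + 1 * (-2))
})

test_that("globalAlign rejects empty input and non-negative gap scores", {
  expect_error(globalAlign("", "ACGT"), "empty")
  expect_error(globalAlign("ACGT", "ACG", gap = 1), "gap")
})

test_that("alignment scores match the dynamic-programming oracle", {
  set.seed(11)
  for (i in 1:20) {
    a <- randomDna(50)
    b <- randomDna(50)
    expect_equal(alignmentScore(globalAlign(a, b)), nwScoreOracle(a, b))
  }
  # non-default scoring
  for (i in 1:5) {
    a <- randomDna(30)
    b <- randomDna(35)
    expect_equal(
      alignmentScore(globalAlign(a, b, match = 2, mismatch = -3, gap = -4)),
      nwScoreOracle(a, b, match = 2, mismatch = -3, gap = -4))
  }
})

test_that("alignment rows ungap back to the inputs byte-for-byte", {
  set.seed(12)
  for (i in 1:10) {
    a <- randomDna(sample(20:60, 1))
    b <- randomDna(sample(20:60, 1))
    rows <- alignedRows(globalAlign(a, b))
    expect_identical(gsub("-", "", rows[[1]]), a)
    expect_identical(gsub("-", "", rows[[2]]), b)
    expect_false(any(strsplit(rows[[1]], "")[[1]] == "-" &
                     strsplit(rows[[2]], "")[[1]] == "-"))
  }
})

test_that("percentIdentity counts matching columns", {
  expect_equal(percentIdentity(globalAlign("ACGT", "ACGA")), 75)
  expect_equal(percentIdentity(globalAlign("ACGTACGT", "ACGTACGT")), 100)
})

test_that("percentIdentity is symmetric and matches the column oracle", {
  set.seed(13)
  for (i in 1:8) {
    a <- randomDna(40)
    b <- randomDna(45)
    ab <- globalAlign(a, b)
    ba <- globalAlign(b, a)
    expect_equal(percentIdentity(ab), percentIdentity(ba))
    rows <- alignedRows(ab)
    expect_equal(percentIdentity(ab), pidOracle(rows[[1]], rows[[2]]))
    expect_equal(percentIdentity(ab, gaps = "mismatch"),
                 pidOracle(rows[[1]], rows[[2]], gaps = "mismatch"))
  }
})

test_that("percentIdentity reflects a known mutated fraction", {
  set.seed(14)
  a <- strsplit(randomDna(200), "")[[1]]
  mask <- sample(200, 30)
  b <- a
  for (p in mask) b[p] <- setdiff(c("A", "C", "G", "T"), a[p])[1]
  aln <- globalAlign(paste(a, collapse = ""), paste(b, collapse = ""))
  if (!any(grepl("-", alignedRows(aln)))) {
    expect_equal(percentIdentity(aln), 100 * (1 - 30 / 200))
  }
})

test_that("percentIdentity errors when no columns are comparable", {
  aln <- methods::new("AlignedPair", idA = "a", idB = "b",
                      alnA = "A-", alnB = "-A", score = 0)
  expect_error(percentIdentity(aln), "no comparable columns")
})

test_that("N never counts as a match", {
  aln <- globalAlign("ANGT", "ANGT")
  expect_equal(percentIdentity(aln), 75)
})

test_that("slidingIdentity gives 100 on self-alignment and forced values", {
  s <- randomDna(50)
  expect_true(all(trackValues(slidingIdentity(globalAlign(s, s))) == 100))

  a <- strsplit(strrep("A", 20), "")[[1]]
  b <- a
  b[c(5, 15)] <- "C"
  aln <- globalAlign(paste(a, collapse = ""), paste(b, collapse = ""))
  tr <- slidingIdentity(aln, window = 10, step = 10)
  expect_equal(trackValues(tr), c(90, 90))
  expect_equal(trackCenters(tr), c(5L, 15L))
})

test_that("slidingIdentity matches the per-window oracle", {
  set.seed(15)
  a <- randomDna(120)
  b <- randomDna(120)
  aln <- globalAlign(a, b)
  rows <- alignedRows(aln)
  tr <- slidingIdentity(aln, window = 10, step = 3)
  expect_equal(trackValues(tr), windowIdOracle(rows[[1]], rows[[2]], 10, 3))
})

test_that("full-length window equals percentIdentity under gap-as-mismatch", {
  set.seed(16)
  a <- randomDna(40)
  b <- randomDna(44)
  aln <- globalAlign(a, b)
  L <- nchar(alignedRows(aln)[[1]])
  tr <- slidingIdentity(aln, window = L)
  expect_length(trackValues(tr), 1)
  expect_equal(trackValues(tr), percentIdentity(aln, gaps = "mismatch"))
})

test_that("slidingIdentity rejects oversized windows and masks N-rich ones", {
  aln <- globalAlign("ACGTACGT", "ACGTACGT")
  expect_error(slidingIdentity(aln, window = 100), "exceeds")

  alnN <- globalAlign("NNNNNNACGT", "NNNNNNACGT")
  tr <- slidingIdentity(alnN, window = 6, step = 1)
  expect_true(is.na(trackValues(tr)[1]))     # all-N window masked
  expect_false(is.na(trackValues(tr)[5]))    # 2/6 N kept
})

test_that("identity track inside a conversion tract exceeds the outside", {
  fam <- simulateGeneFamily(nGenes = 2, cdsLength = 600,
                            targetIdentity = 0.8, seed = 21)
  rec <- as.character(fam$genes[[1]])
  don <- as.character(fam$genes[[2]])
  tract <- c(201, 380)
  cand <- applyGeneConversion(rec, don, tract)
  aln <- globalAlign(cand, don)
  tr <- slidingIdentity(aln, window = 10, step = 1)
  centers <- trackCenters(tr)
  inside <- centers >= tract[1] & centers <= tract[2]
  expect_gt(mean(trackValues(tr)[inside]),
            mean(trackValues(tr)[!inside]))
  rows <- alignedRows(aln)
  expect_equal(trackValues(tr), windowIdOracle(rows[[1]], rows[[2]], 10, 1))
})
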