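test_that("normalization uppercases and rejects illegal characters", {
  expect_equal(normalizeSequence("acgt"), "ACGT")
  expect_equal(normalizeSequence("ACGT"), "ACGT")
  expect_error(normalizeSequence("ACXT"), "position 3")
  expect_error(normalizeSequence(""), "non-empty")
  expect_equal(normalizeSequence("acgtn"), "ACGTN")
})

test_that("reverse complement follows Watson-Crick with N self-complement", {
  expect_equal(reverseComplementDna("ACGT"), "ACGT")
  expect_equal(reverseComplementDna("AAAC"), "GTTT")
  expect_equal(reverseComplementDna("ACGTN"), "NACGT")
})

test_that("non-overlapping split is forced when kmin == kmax", {
  expect_equal(splitVariableKmers("ACGTACGT", segmentationConfig(2, 2)),
               c("AC", "GT", "AC", "GT"))
  expect_equal(splitVariableKmers("ACGT", segmentationConfig(4, 12)),
               "ACGT")
})

test_that("non-overlapping splits reconstruct the source with in-range lengths", {
  set.seed(42)
  for (i in 1:300) {
    len <- sample(1:2000, 1)
    s <- randomDna(len)
    toks <- splitVariableKmers(s, segmentationConfig(4, 12, seed = i))
    expect_identical(paste(toks, collapse = ""), s)
    nl <- nchar(toks)
    if (length(nl) > 1)
      expect_true(all(nl[-length(nl)] >= 4 & nl[-length(nl)] <= 12))
    expect_lte(nl[length(nl)], 12)
  }
})

test_that("token lengths follow the discrete uniform on {kmin..kmax}", {
  set.seed(7)
  s <- randomDna(120000)
  toks <- splitVariableKmers(s, segmentationConfig(4, 12, seed = 99))
  lens <- nchar(toks)
  lens <- lens[-length(lens)]
  expect_gt(length(lens), 1e4)
  p <- chisq.test(table(factor(lens, levels = 4:12)))$p.value
  expect_gt(p, 0.001)
})

test_that("overlapping split slides by one and truncates at the end", {
  expect_equal(splitOverlappingKmers("ACGTA", segmentationConfig(2, 2)),
               c("AC", "CG", "GT", "TA"))
  expect_equal(splitOverlappingKmers("ACGT", segmentationConfig(4, 4)),
               "ACGT")
  s <- randomDna(50)
  toks <- splitOverlappingKmers(s, segmentationConfig(3, 3, seed = 1))
  expect_length(toks, 50 - 3 + 1)
  expect_error(splitOverlappingKmers("AC", segmentationConfig(4, 12)),
               "shorter than kmin")
})

test_that("fixed-k split honors k and stride", {
  expect_equal(splitFixedKmers("ACGTAC", 2, 2), c("AC", "GT", "AC"))
  expect_equal(splitFixedKmers("ACGTAC", 3, 1), c("ACG", "CGT", "GTA", "TAC"))
  expect_equal(splitFixedKmers("ACG", 3, 5), "ACG")
  expect_error(splitFixedKmers("AC", 3), "shorter than k")
})

test_that("augmentation yields 2N cognate sentences sharing id and label", {
  cfg <- segmentationConfig(4, 12, nReplicates = 3, seed = 5)
  corp <- augmentSequence(randomDna(80), id = "x1", label = 1L, cfg = cfg)
  info <- corpusInfo(corp)
  expect_length(corp, 6L)
  expect_equal(sum(info$origin == "forward"), 3L)
  expect_equal(sum(info$origin == "reverse_complement"), 3L)
  expect_true(all(info$source_id == "x1"))
  expect_true(all(info$label == 1L))
})

test_that("augmentation is deterministic in the seed and degenerate when kmin == kmax", {
  s <- randomDna(60)
  cfg <- segmentationConfig(4, 12, nReplicates = 4, seed = 9)
  a <- augmentSequence(s, cfg = cfg)
  b <- augmentSequence(s, cfg = cfg)
  expect_identical(sentences(a), sentences(b))
  d <- augmentSequence(s, cfg = segmentationConfig(5, 5, nReplicates = 2))
  expect_identical(sentences(d)[[1]], sentences(d)[[2]])
  # replicates draw from independent substreams
  expect_false(identical(sentences(a)[[1]], sentences(a)[[2]]))
})

test_that("forward sentences reconstruct the source, reverse ones its complement", {
  s <- randomDna(150)
  corp <- augmentSequence(s, cfg = segmentationConfig(4, 12, 5, seed = 3))
  info <- corpusInfo(corp)
  rc <- reverseComplementDna(s)
  for (i in seq_along(sentences(corp))) {
    joined <- paste(sentences(corp)[[i]], collapse = "")
    expect_identical(joined, if (info$origin[i] == "forward") s else rc)
  }
})

test_that("sequences containing N are segmented verbatim", {
  toks <- splitVariableKmers("ACGTNNACGT", segmentationConfig(2, 2))
  expect_identical(paste(toks, collapse = ""), "ACGTNNACGT")
})

test_that("mean tokens per sentence matches the expected length law", {
  # expected token length is (4 + 12) / 2 = 8, so a 500 bp sequence
  # yields about 62.5 tokens per sentence
  s <- randomDna(500)
  corp <- augmentSequence(s, cfg = segmentationConfig(4, 12, 200, seed = 11))
  m <- mean(lengths(sentences(corp)))
  expect_lt(abs(m - 62.5) / 62.5, 0.02)
})
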