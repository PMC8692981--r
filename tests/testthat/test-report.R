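test_that("base composition percentages follow the reporting convention", {
  row <- baseComposition("ATGC")
  expect_equal(unname(c(row$A, row$C, row$G, row$T)), rep(25, 4))
  expect_equal(row$GC, 50)
  expect_error(baseComposition(""), "empty")
  # ambiguity codes are excluded from percentages but counted
  amb <- baseComposition("AATTNN")
  expect_equal(amb$A + amb$C + amb$G + amb$T, 100)
  expect_identical(unname(amb$ambiguous), 2L)
  # A+C+G+T sums to 100 within rounding for arbitrary sequences
  set.seed(91)
  comp <- baseComposition(Biostrings::DNAStringSet(
    vapply(1:10, function(i) randomSeq(sample(500:5000, 1)),
           character(1))))
  expect_true(all(abs(comp$A + comp$C + comp$G + comp$T - 100) <= 0.02))
  expect_true(all(abs(comp$GC - (comp$C + comp$G)) <= 0.02))
})

test_that("the published composition rows satisfy the closure invariant", {
  tab <- maramaSubgenomeTable()
  expect_identical(nrow(tab), 7L)
  expect_true(all(abs(tab$A + tab$C + tab$G + tab$T - 100) <= 0.02))
  expect_true(all(abs(tab$GC - (tab$C + tab$G)) <= 0.02))
})

test_that("summary statistics use the midpoint median convention", {
  scaff <- maramaScaffoldTable()
  mols <- maramaSubgenomeTable()
  five <- mols$length[1:5]
  rep <- summaryStats(scaff$length, five,
                      repeats = maramaRepeatTable()$length,
                      mtptFragments = maramaMtptTable()$length)
  s <- rep@scaffoldStats
  expect_equal(unname(s["count"]), 16)
  expect_equal(unname(s["min"]), 2351)
  expect_equal(unname(s["max"]), 56817)
  expect_equal(unname(s["median"]), 27406)
  expect_equal(rep@totalLength, 399572)
  expect_identical(rep@repeatFraction, 8.2)
  expect_identical(rep@mtptFraction, 2.8)
  one <- summaryStats(1234, 1234)
  expect_identical(unname(one@scaffoldStats["min"]),
                   unname(one@scaffoldStats["median"]))
  expect_error(summaryStats(numeric(0), 100), "non-empty")
})

test_that("sequence records round-trip through FASTA and FASTQ", {
  set.seed(92)
  recs <- Biostrings::DNAStringSet(c(m1 = randomSeq(123),
                                     m2 = randomSeq(456)))
  fa <- tempfile(fileext = ".fa")
  back <- roundtripSequences(fa, recs)
  expect_identical(names(back), names(recs))
  expect_identical(as.character(back), as.character(recs))
  # FASTA wraps at 70 columns
  lines <- readLines(fa)
  expect_lte(max(nchar(lines)), 70L)
  fq <- tempfile(fileext = ".fq")
  backq <- roundtripSequences(fq, recs)
  expect_identical(as.character(backq), as.character(recs))
  # circularity is recorded in the description
  writeSequences(recs, fa, circular = TRUE)
  expect_true(all(grepl("circular=true", names(readSequences(fa)))))
})

test_that("degenerate and malformed sequence files are diagnosed", {
  empty <- tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_warning(res <- readSequences(empty), "empty")
  expect_length(res, 0L)
  bad <- tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">s1", "ACGT"), bad)
  expect_error(readSequences(bad), "line 1")
  bad2 <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT", "AC#T"), bad2)
  expect_error(readSequences(bad2), "line 3")
})

test_that("a ten-thousand-record stress file preserves identifier order", {
  set.seed(93)
  ids <- sprintf("rec%05d", 1:10000)
  recs <- setNames(vapply(1:10000, function(i) randomSeq(30),
                          character(1)), ids)
  path <- tempfile(fileext = ".fa")
  back <- roundtripSequences(path, recs)
  expect_identical(names(back), ids)
})

test_that("graph and truth tables serialize to portable text", {
  g <- makeGraph(c("A:tail--B:head", "B:tail--A:head"),
                 c(A = 1L, B = 1L))
  tsv <- tempfile(fileext = ".tsv")
  gfa <- tempfile(fileext = ".gfa")
  writeJunctionGraphTSV(g, tsv, gfaPath = gfa,
                        scaffoldLengths = c(A = 1000, B = 2000))
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), 2L)
  lines <- readLines(gfa)
  expect_identical(sum(startsWith(lines, "S")), 2L)
  expect_identical(sum(startsWith(lines, "L")), 2L)
  cfg <- topologyDemoConfig(seed = 94)
  cfg@longReadParams$n <- 5L
  mg <- buildMasterGenome(cfg)
  rs <- simulateLongReads(mg, cfg)
  tpath <- tempfile(fileext = ".tsv")
  writeTruthTSV(rs, tpath)
  tt <- read.delim(tpath)
  expect_identical(nrow(tt), 5L)
  expect_true(all(c("read", "state", "molecule", "start", "strand") %in%
                  names(tt)))
})

test_that("the reconstructed marama topology reproduces the published molecule lengths", {
  top <- maramaTopology()
  lens <- vapply(molecules(top$state), moleculeLength, numeric(1),
                 unitLengths = top$unitLengths)
  expect_setequal(lens, c(169330, 44455, 39474, 32520, 113793))
  expect_equal(sum(lens), 399572)
})
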