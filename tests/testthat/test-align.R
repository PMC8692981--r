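test_that("seed index postings match a naive sliding-window enumeration", {
  set.seed(41)
  seqs <- c(s1 = "ACGTACGTACGTA", s2 = randomSeq(60), s3 = randomSeq(60))
  idx <- kmerSeedIndex(seqs, k = 13)
  naive <- list()
  for (i in seq_along(seqs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[i]] else rcSeq(seqs[[i]])
      if (nchar(s) < 13) next
      for (p in 0:(nchar(s) - 13))
        naive[[length(naive) + 1L]] <- data.frame(
          kmer = substr(s, p + 1, p + 13), seq = i, pos = p,
          strand = strand, stringsAsFactors = FALSE)
    }
  }
  naive <- do.call(rbind, naive)
  post <- as.data.frame(idx@postings)
  o <- function(d) d[order(d$seq, d$strand, d$pos), c("kmer", "seq",
                                                      "pos", "strand")]
  expect_equal(o(post), o(naive), ignore_attr = TRUE)
  # a 13 bp sequence yields one forward and one reverse posting
  one <- kmerSeedIndex(c(a = "ACGTACGTACGTA"), 13)
  expect_identical(nrow(one@postings), 2L)
  # duplicated sequences duplicate every posting
  two <- kmerSeedIndex(c(a = seqs[["s2"]], b = seqs[["s2"]]), 13)
  expect_true(all(table(two@postings$kmer) >= 2L))
})

test_that("seed index rejects unusable word sizes", {
  expect_error(kmerSeedIndex(c(a = "ACGT"), 13), "empty index")
  expect_error(kmerSeedIndex(c(a = randomSeq(50)), 8), "k must be")
  expect_error(kmerSeedIndex(c(a = randomSeq(50)), 35), "k must be")
})

test_that("identical sequences align end to end at full identity", {
  set.seed(42)
  s <- randomSeq(1000)
  aln <- localAlign(c(q = s), c(t = s), minIdentity = 90,
                    minLength = 500)
  expect_identical(nrow(aln), 1L)
  expect_equal(aln$identity, 100)
  expect_identical(aln$length, 1000L)
  expect_identical(c(aln$qstart, aln$qend), c(0L, 1000L))
  expect_identical(aln$strand, "+")
})

test_that("reverse-complement homology is reported on the minus strand", {
  set.seed(43)
  seg <- randomSeq(600)
  target <- paste0(randomSeq(400), seg, randomSeq(300))
  query <- rcSeq(seg)
  aln <- localAlign(c(q = query), c(t = target), minIdentity = 90,
                    minLength = 400)
  expect_identical(nrow(aln), 1L)
  expect_identical(aln$strand, "-")
  # reported target interval covers the planted segment
  expect_lte(aln$tstart, 410L)
  expect_gte(aln$tend, 990L)
})

test_that("x-drop identity tracks the full dynamic-programming oracle", {
  set.seed(44)
  for (div in c(0.02, 0.05, 0.08)) {
    a <- randomSeq(1200)
    b <- mutateSeq(a, div, nIndel = 3L)
    aln <- localAlign(c(q = a), c(t = b), minIdentity = 60,
                      minLength = 300)
    expect_gte(nrow(aln), 1L)
    best <- aln[which.max(aln$score), ]
    expect_lt(abs(best$identity - dpLocalIdentity(a, b)), 1)
  }
})

test_that("alignment score is symmetric under query/target swap", {
  set.seed(45)
  for (i in 1:8) {
    a <- randomSeq(500)
    b <- mutateSeq(a, 0.04)
    f <- localAlign(c(q = a), c(t = b), minIdentity = 60,
                    minLength = 200)
    r <- localAlign(c(q = b), c(t = a), minIdentity = 60,
                    minLength = 200)
    expect_identical(max(f$score), max(r$score))
  }
})

test_that("contigs are classified by their best reference gene hit", {
  set.seed(46)
  mito <- Biostrings::DNAStringSet(c(atp1 = randomSeq(1500),
                                     cox1 = randomSeq(1500),
                                     nad5 = randomSeq(1200)))
  plast <- Biostrings::DNAStringSet(c(psaA = randomSeq(1500),
                                      psaB = randomSeq(1400),
                                      psbC = randomSeq(1200)))
  contigs <- Biostrings::DNAStringSet(c(
    c1 = paste0(randomSeq(2000), as.character(mito[["atp1"]]),
                randomSeq(1500)),
    c2 = paste0(randomSeq(1000), as.character(plast[["psaA"]]),
                randomSeq(800)),
    c3 = randomSeq(10000)))
  lab <- classifyContigs(contigs, mito, plast)
  res <- setNames(lab$label, lab$contig)
  expect_identical(unname(res["c1"]), "mitochondrial")
  expect_identical(unname(res["c2"]), "plastid")
  expect_identical(unname(res["c3"]), "unassigned")
  expect_identical(lab$bestGene[lab$contig == "c1"], "atp1")
})

test_that("classification is perfectly sensitive and specific on clean contigs", {
  set.seed(47)
  mito <- Biostrings::DNAStringSet(c(g1 = randomSeq(1200),
                                     g2 = randomSeq(1000)))
  plast <- Biostrings::DNAStringSet(c(p1 = randomSeq(1200)))
  n <- 100L
  hasGene <- rep(c(TRUE, FALSE), length.out = n)
  contigs <- character(n)
  for (i in seq_len(n)) {
    bg <- randomSeq(sample(2000:6000, 1))
    contigs[i] <- if (hasGene[i]) {
      g <- as.character(mito[[sample(2, 1)]])
      p <- sample(nchar(bg), 1)
      paste0(substr(bg, 1, p), g, substr(bg, p + 1, nchar(bg)))
    } else bg
  }
  names(contigs) <- sprintf("c%03d", seq_len(n))
  lab <- classifyContigs(Biostrings::DNAStringSet(contigs), mito, plast)
  called <- lab$label == "mitochondrial"
  expect_identical(sum(called & hasGene), sum(hasGene))   # recall 1
  expect_identical(sum(called & !hasGene), 0L)            # precision 1
})
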