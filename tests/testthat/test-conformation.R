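test_that("canonical forms are idempotent and rotation/strand invariant", {
  set.seed(11)
  for (i in 1:25) {
    st <- randomTestConformation(sample(3:7, 1), sample(0:2, 1),
                                 sample(1:3, 1))
    for (m in molecules(st)) {
      key <- canonicalMolecule(m)
      # idempotence: canonical of the canonical token string
      expect_identical(canonicalMolecule(
        circularMolecule(strsplit(key, ",")[[1]])), key)
      # rotation invariance
      n <- length(m@units)
      r <- sample(n, 1)
      rot <- new("CircularMolecule",
                 units = m@units[c(r:n, seq_len(r - 1))[seq_len(n)]],
                 strands = m@strands[c(r:n, seq_len(r - 1))[seq_len(n)]])
      expect_identical(canonicalMolecule(rot), key)
      # strand-flip invariance
      flip <- new("CircularMolecule", units = rev(m@units),
                  strands = -rev(m@strands))
      expect_identical(canonicalMolecule(flip), key)
    }
  }
})

test_that("fusion and fission are exact inverses and conserve length", {
  s <- conformationSet(list(c("A", "R", "B"), c("C", "R")))
  lens <- c(A = 10000, B = 5000, C = 7000, R = 2000)
  fused <- applyRecombination(s, recombinationEvent("R", "fusion",
                                                    c(1, 2), "direct"))
  expect_length(molecules(fused), 1L)
  expect_equal(moleculeLength(molecules(fused)[[1]], lens),
               sum(lens[c("A", "B", "C")]) + 2 * lens[["R"]],
               ignore_attr = TRUE)
  back <- applyRecombination(fused, recombinationEvent("R", "fission", 1,
                                                       "direct"))
  expect_identical(canonicalState(back), canonicalState(s))
})

test_that("inverted-repeat flip-flop exchanges the successors of the copies", {
  # before: contexts A-I-D and K-I-F; after: A-I-F and K-I-D
  before <- conformationSet(list(c("A", "I", "D", "X", "-F", "-I", "-K",
                                   "Y")))
  after <- applyRecombination(before,
                              recombinationEvent("I", "inversion", 1,
                                                 "inverted"))
  expected <- circularMolecule(c("A", "I", "F", "-X", "-D", "-I", "-K",
                                 "Y"))
  expect_identical(canonicalMolecule(molecules(after)[[1]]),
                   canonicalMolecule(expected))
  # and the transformation is reversible
  back <- applyRecombination(after,
                             recombinationEvent("I", "inversion", 1,
                                                "inverted"))
  expect_identical(canonicalState(back), canonicalState(before))
})

test_that("mechanism and repeat configuration must agree", {
  direct <- conformationSet(list(c("A", "R", "B", "R")))
  inverted <- conformationSet(list(c("A", "R", "B", "-R")))
  expect_error(applyRecombination(direct,
    recombinationEvent("R", "inversion", 1, "inverted")),
    "mismatch")
  expect_error(applyRecombination(inverted,
    recombinationEvent("R", "fission", 1, "direct")),
    "mismatch")
  expect_error(recombinationEvent("R", "fusion", c(1, 2), "inverted"))
  expect_error(recombinationEvent("R", "inversion", 1, "direct"))
})

test_that("conformation space enumerates the recombination closure", {
  base <- conformationSet(list(c("A", "B"), c("C")))
  expect_length(conformationSpace(base, data.frame(id = character(0),
                                                   kind = character(0))),
                1L)
  # one inverted pair within one circle: two states, same circle count
  # and identical molecule lengths
  inv <- conformationSet(list(c("A", "I", "B", "-I"), c("C")))
  lens <- c(A = 5000, B = 3000, C = 4000, I = 1500)
  sp <- conformationSpace(inv, data.frame(id = "I", kind = "inverted"))
  expect_length(sp, 2L)
  for (s in sp) {
    expect_length(molecules(s), 2L)
    expect_setequal(
      vapply(molecules(s), moleculeLength, numeric(1), unitLengths = lens),
      vapply(molecules(inv), moleculeLength, numeric(1),
             unitLengths = lens))
  }
  # two independent direct pairs: 2 x 2 states
  two <- conformationSet(list(c("A", "R1"), c("B", "R1"),
                              c("C", "R2"), c("D", "R2")))
  sp2 <- conformationSpace(two, data.frame(id = c("R1", "R2"),
                                           kind = "direct"))
  expect_length(sp2, 4L)
  # reachability is symmetric: the base is recoverable from every state
  baseKey <- canonicalState(two)
  for (s in sp2) {
    back <- conformationSpace(s, data.frame(id = c("R1", "R2"),
                                            kind = "direct"))
    expect_true(baseKey %in% vapply(back, canonicalState, character(1)))
  }
})

test_that("total length is conserved exactly across the conformation space", {
  top <- maramaTopology()
  sp <- conformationSpace(top$state, top$repeats)
  totals <- vapply(sp, mitomosaic:::stateTotalLength, numeric(1),
                   unitLengths = top$unitLengths)
  expect_true(all(totals == totals[1]))
  expect_equal(unname(totals[1]), 399572)
  # the closure contains a two-master-ring state
  nmol <- vapply(sp, function(s) length(molecules(s)), integer(1))
  expect_true(2L %in% nmol)
})

test_that("molecule length and sequence reconstruction validate inputs", {
  m <- circularMolecule(c("A", "-B"))
  expect_error(moleculeLength(new("CircularMolecule",
                                  units = character(0),
                                  strands = integer(0)), c(A = 1)))
  expect_error(moleculeLength(m, c(A = 10)), "unknown unit")
  expect_identical(moleculeLength(circularMolecule("A"), c(A = 42)), 42)
  units <- Biostrings::DNAStringSet(c(A = "ACGTT", B = "GGCAT"))
  expect_identical(as.character(moleculeSequence(m, units)),
                   paste0("ACGTT", rcSeq("GGCAT")))
})

test_that("GC content is invariant under inversion events", {
  set.seed(5)
  units <- Biostrings::DNAStringSet(c(A = randomSeq(3000),
                                      I = randomSeq(1200),
                                      B = randomSeq(2500)))
  st <- conformationSet(list(c("A", "I", "B", "-I")))
  flip <- applyRecombination(st, recombinationEvent("I", "inversion", 1,
                                                    "inverted"))
  gc <- function(s) sum(Biostrings::alphabetFrequency(s)[c("C", "G")])
  expect_identical(gc(moleculeSequence(molecules(st)[[1]], units)),
                   gc(moleculeSequence(molecules(flip)[[1]], units)))
})

test_that("circle decomposition handles canonical small graphs", {
  # a single node with a tail-head self edge forms one circle
  g1 <- makeGraph("A:head--A:tail", c(A = 1L))
  d1 <- decomposeCircles(g1)
  expect_length(d1, 1L)
  expect_length(molecules(d1[[1]]), 1L)
  # a 3-cycle decomposes uniquely
  tri <- conformationSet(list(c("A", "B", "C")))
  g3 <- graphFromStates(list(tri))
  d3 <- decomposeCircles(g3)
  expect_length(d3, 1L)
  expect_identical(canonicalState(d3[[1]]), canonicalState(tri))
})

test_that("decomposition recovers both fused and split repeat routings", {
  split <- conformationSet(list(c("A", "R"), c("B", "R")))
  fused <- applyRecombination(split,
    recombinationEvent("R", "fusion", c(1, 2), "direct"))
  g <- graphFromStates(list(split))  # fused shares the same edge set
  dec <- decomposeCircles(g)
  keys <- vapply(dec, canonicalState, character(1))
  expect_true(canonicalState(split) %in% keys)
  expect_true(canonicalState(fused) %in% keys)
})

test_that("structural problems are reported, not mis-decomposed", {
  bad <- makeGraph(c("A:tail--B:head", "B:tail--A:head",
                     "C:tail--A:head"),
                   c(A = 1L, B = 1L, C = 1L))
  expect_error(decomposeCircles(bad), "C")
  # a node without junction evidence leaves no decomposition
  iso <- makeGraph("A:head--A:tail", c(A = 1L, B = 1L))
  expect_length(decomposeCircles(iso), 0L)
})

test_that("decomposition agrees with the brute-force oracle on small graphs", {
  set.seed(21)
  for (i in 1:10) {
    st <- randomTestConformation(sample(3:6, 1), sample(0:2, 1),
                                 sample(1:3, 1))
    g <- graphFromStates(list(st))
    mine <- sort(vapply(decomposeCircles(g), canonicalState,
                        character(1)))
    expect_identical(mine, oracleDecompose(g))
    expect_true(canonicalState(st) %in% mine)
  }
})

test_that("component separation detects bridged master rings", {
  top <- maramaTopology()
  sp <- conformationSpace(top$state, top$repeats)
  g <- graphFromStates(sp)
  sep <- checkComponentSeparation(g, sp)
  expect_true(sep$separated)
  expect_identical(sep$nComponents, 2L)
  # a repeat shared across the two components destroys separation
  bridged <- conformationSet(list(c("S1", "I", "H", "-I", "J", "Z"),
                                  c("S2", "H"), c("S3", "J"),
                                  c("S4", "O", "Z"), c("S5", "O")))
  spb <- conformationSpace(bridged,
                           rbind(top$repeats,
                                 data.frame(id = "Z", kind = "direct",
                                            length = 1500)))
  gb <- graphFromStates(spb)
  sepb <- checkComponentSeparation(gb, spb)
  expect_false(sepb$separated)
  # a single-component graph holds vacuously
  one <- conformationSet(list(c("A", "B")))
  g1 <- graphFromStates(list(one))
  expect_identical(checkComponentSeparation(g1, list(one))$nComponents,
                   1L)
})

test_that("mixture estimation handles degenerate counts", {
  split <- conformationSet(list(c("A", "R"), c("B", "R")))
  fused <- applyRecombination(split,
    recombinationEvent("R", "fusion", c(1, 2), "direct"))
  g <- graphFromStates(list(split))
  # no observations at all: flagged estimate
  est <- estimateMixture(g, list(split, fused))
  expect_true(est@flagged)
  expect_true(all(is.na(est@frequencies)))
  expect_error(estimateMixture(g, list(split)), "at least two")
  expect_error(estimateMixture(g, list(split, split)), "do not differ")
})
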