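test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(conformationFrequencies = c(0.6, 0.6)),
               "sum to 1")
  expect_error(simulationConfig(longReadParams = list(
    n = 10L, meanLength = 1000, sdlog = 0.2, errorRate = 1.0,
    errorMix = c(1, 0, 0))), "error rate")
  expect_error(simulationConfig(shortReadParams = list(
    coverage = 10, readLength = 150L, insertMean = 250, insertSd = 20,
    errorRate = 0)), "insert mean")
  expect_error(simulationConfig(repeatSpecs = data.frame(
    length = 2000, kind = "tandem")), "direct")
  expect_error(simulationConfig(plastidSpecs = data.frame(
    length = 500, divergence = 1.0)), "divergence")
})

test_that("master genomes honour layout, seeding and repeat placement", {
  # no recombination substrate: a single truth state
  cfg0 <- simulationConfig(nSingleCopyUnits = 4L, nCircles = 2L,
                           unitLengthRange = c(2000L, 4000L),
                           repeatSpecs = data.frame(length = numeric(0),
                                                    kind = character(0)),
                           seed = 3L)
  mg0 <- buildMasterGenome(cfg0)
  expect_length(truthSpace(mg0), 1L)
  # one direct repeat shared by two circles: fused and split states
  cfg1 <- simulationConfig(
    nSingleCopyUnits = 2L, nCircles = 2L,
    unitLengthRange = c(5000L, 5000L),
    layout = list(c("U01", "R1"), c("U02", "R1")),
    unitLengths = c(U01 = 5000, U02 = 5000),
    repeatSpecs = data.frame(id = "R1", length = 1500,
                             kind = "direct"),
    seed = 4L)
  mg1 <- buildMasterGenome(cfg1)
  expect_length(truthSpace(mg1), 2L)
  info <- unitInfo(mg1)
  expect_identical(info$kind[info$id == "R1"], "direct")
  # determinism: same seed reproduces the genome, another seed differs
  mgA <- buildMasterGenome(cfg1)
  expect_identical(as.character(genomeUnits(mg1)),
                   as.character(genomeUnits(mgA)))
  cfgB <- cfg1
  cfgB@seed <- 5L
  mgB <- buildMasterGenome(cfgB)
  expect_false(identical(as.character(genomeUnits(mg1)),
                         as.character(genomeUnits(mgB))))
  # a repeat dominating its host circle is rejected
  expect_error(buildMasterGenome(simulationConfig(
    nSingleCopyUnits = 1L, nCircles = 1L,
    layout = list(c("U01", "R1"), c("U02", "R1")),
    unitLengths = c(U01 = 1000, U02 = 5000),
    repeatSpecs = data.frame(id = "R1", length = 3000, kind = "direct"),
    seed = 1L)), "sizing")
  # random placement keeps every repeat at exactly two copies
  cfgR <- simulationConfig(nSingleCopyUnits = 8L, nCircles = 3L,
                           unitLengthRange = c(4000L, 9000L), seed = 9L)
  mgR <- buildMasterGenome(cfgR)
  expect_true(validObject(mgR))
  occ <- table(unlist(lapply(molecules(baseConformation(mgR)),
                             function(m) m@units)))
  infoR <- unitInfo(mgR)
  expect_true(all(occ[infoR$id[infoR$role == "repeat"]] == 2L))
  expect_true(all(occ[infoR$id[infoR$role == "single"]] == 1L))
})

test_that("zero-error long reads are exact substrings of their source circle", {
  cfg <- topologyDemoConfig(seed = 6)
  cfg@longReadParams$n <- 40L
  cfg@longReadParams$errorRate <- 0
  mg <- buildMasterGenome(cfg)
  rs <- simulateLongReads(mg, cfg)
  expect_identical(nrow(rs@truth), length(rs@reads))
  states <- truthSpace(mg)
  for (i in seq_len(20)) {
    tr <- rs@truth[i, ]
    mol <- molecules(states[[tr$state]])[[tr$molecule]]
    circ <- as.character(moleculeSequence(mol, genomeUnits(mg)))
    doubled <- paste0(circ, circ)
    r <- as.character(rs@reads[[i]])
    if (tr$strand == "-") r <- rcSeq(r)
    expect_identical(substr(doubled, tr$start + 1, tr$start + tr$length),
                     r)
  }
})

test_that("long-read totals and mixture frequencies follow the parameters", {
  # two large circles, no repeats, so no truncation distorts totals
  cfg <- simulationConfig(
    nSingleCopyUnits = 2L, nCircles = 2L,
    layout = list("U01", "U02"),
    unitLengths = c(U01 = 30000, U02 = 30000),
    repeatSpecs = data.frame(length = numeric(0), kind = character(0)),
    longReadParams = list(n = 2000L, meanLength = 8000, sdlog = 0.3,
                          errorRate = 0, errorMix = c(1, 0, 0)),
    seed = 8L)
  mg <- buildMasterGenome(cfg)
  rs <- simulateLongReads(mg, cfg)
  total <- sum(Biostrings::width(rs@reads))
  expect_lt(abs(total - 1.6e7) / 1.6e7, 0.05)
  # a degenerate mixture concentrates every read on one state
  cfg1 <- topologyDemoConfig(seed = 2)
  cfg1@longReadParams$n <- 100L
  mg1 <- buildMasterGenome(cfg1)
  cfg1@conformationFrequencies <-
    c(1, rep(0, length(truthSpace(mg1)) - 1L))
  rs1 <- simulateLongReads(mg1, cfg1)
  expect_true(all(rs1@truth$state == 1L))
})

test_that("reads longer than every circle trigger the truncation warning", {
  cfg <- simulationConfig(
    nSingleCopyUnits = 1L, nCircles = 1L,
    layout = list("U01"), unitLengths = c(U01 = 3000),
    repeatSpecs = data.frame(length = numeric(0), kind = character(0)),
    longReadParams = list(n = 20L, meanLength = 8000, sdlog = 0.3,
                          errorRate = 0, errorMix = c(1, 0, 0)),
    seed = 2L)
  mg <- buildMasterGenome(cfg)
  expect_warning(rs <- simulateLongReads(mg, cfg), "truncated")
  expect_true(all(Biostrings::width(rs@reads) <= 3000L))
})

test_that("short-read pair counts, inserts and mates follow the model", {
  cfg <- simulationConfig(
    nSingleCopyUnits = 2L, nCircles = 1L,
    layout = list(c("U01", "U02")),
    unitLengths = c(U01 = 50000, U02 = 50000),
    repeatSpecs = data.frame(length = numeric(0), kind = character(0)),
    shortReadParams = list(coverage = 50, readLength = 150L,
                           insertMean = 400, insertSd = 40,
                           errorRate = 0),
    seed = 12L)
  mg <- buildMasterGenome(cfg)
  rs <- simulateShortReads(mg, cfg)
  expect_true(rs@paired)
  nPairs <- length(rs@reads)
  expect_lt(abs(nPairs - 50 * 100000 / 300) / (50 * 100000 / 300), 0.02)
  # zero-error mates are exact substrings (mate 2 on the other strand)
  circ <- as.character(moleculeSequence(
    molecules(baseConformation(mg))[[1]], genomeUnits(mg)))
  doubled <- paste0(circ, circ)
  for (i in seq_len(10)) {
    tr <- rs@truth[i, ]
    expect_identical(substr(doubled, tr$start + 1, tr$start + 150),
                     as.character(rs@reads[[i]]))
    expect_identical(
      substr(doubled, tr$start + tr$insert - 150 + 1,
             tr$start + tr$insert),
      rcSeq(as.character(rs@mates[[i]])))
  }
})

test_that("identical configuration and seed give byte-identical outputs", {
  run <- function() {
    cfg <- topologyDemoConfig(seed = 33)
    cfg@longReadParams$n <- 50L
    mg <- buildMasterGenome(cfg)
    rs <- simulateLongReads(mg, cfg)
    fa <- tempfile(fileext = ".fa")
    fq <- tempfile(fileext = ".fq")
    writeSequences(genomeUnits(mg), fa)
    writeSequences(rs@reads, fq)
    c(tools::md5sum(fa), tools::md5sum(fq))
  }
  h1 <- unname(run())
  h2 <- unname(run())
  expect_identical(h1, h2)
})

test_that("plastid insertion grows hosts by the fragment length at the stated divergence", {
  cfg <- simulationConfig(
    nSingleCopyUnits = 2L, nCircles = 2L,
    layout = list("U01", "U02"),
    unitLengths = c(U01 = 12000, U02 = 12000),
    repeatSpecs = data.frame(length = numeric(0), kind = character(0)),
    plastidSpecs = data.frame(length = c(9798, 2000),
                              divergence = c(0, 0.05)),
    seed = 14L)
  mg <- buildMasterGenome(cfg)
  cp <- simulatePlastidGenome(20000, seed = 14)
  before <- sum(unitInfo(mg)$length)
  mg2 <- insertPlastidFragments(mg, cp)
  truth <- plastidTruth(mg2)
  expect_identical(nrow(truth), 2L)
  expect_identical(sum(unitInfo(mg2)$length) - before,
                   as.integer(9798 + 2000))
  expect_identical(truth$identity[truth$length == 9798], 100)
  id5 <- truth$identity[truth$length == 2000]
  expect_lt(abs(id5 - 95), 1)
  # host interval matches the spliced sequence
  for (i in seq_len(nrow(truth))) {
    u <- as.character(genomeUnits(mg2)[[truth$unit[i]]])
    frag <- substr(u, truth$unitStart[i] + 1, truth$unitEnd[i])
    donor <- substr(as.character(cp[[1]]), truth$cpStart[i] + 1,
                    truth$cpEnd[i])
    same <- mapply(identical, strsplit(frag, "")[[1]],
                   strsplit(donor, "")[[1]])
    expect_equal(100 * mean(same), truth$identity[i], tolerance = 1e-9)
  }
  # an empty specification leaves the master untouched
  mg3 <- insertPlastidFragments(mg, cp,
                                specs = data.frame(length = numeric(0),
                                                   divergence = numeric(0)))
  expect_identical(as.character(genomeUnits(mg3)),
                   as.character(genomeUnits(mg)))
  expect_error(insertPlastidFragments(mg, cp,
    specs = data.frame(length = 30000, divergence = 0)), "donor")
})

test_that("the YAML round trip preserves configuration fields", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "nSingleCopyUnits: 6",
    "nCircles: 3",
    "seed: 99",
    "gc: 0.41",
    "longReadParams:",
    "  n: 123",
    "  errorRate: 0.02"), path)
  cfg <- readSimulationConfig(path)
  expect_identical(cfg@nSingleCopyUnits, 6L)
  expect_identical(cfg@nCircles, 3L)
  expect_identical(cfg@seed, 99L)
  expect_equal(cfg@gc, 0.41)
  expect_identical(cfg@longReadParams$n, 123L)
  expect_equal(cfg@longReadParams$errorRate, 0.02)
  expect_equal(cfg@longReadParams$meanLength, 8000)  # default retained
})
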