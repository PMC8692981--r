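#' @include conformation.R
NULL

defaultRepeatSpecs <- function() {
  data.frame(id = c("R1", "R2", "R3", "R4"),
             length = c(5212, 2351, 3908, 4926),
             kind = c("direct", "inverted", "direct", "direct"),
             stringsAsFactors = FALSE)
}

#' Create a simulation configuration
#'
#' Defaults emulate a multipartite plant mitochondrial genome at the
#' scale observed for marama: 12 single-copy units of 2.3--57 kb on five
#' circles, four two-copy repeats (5,212 / 2,351 / 3,908 / 4,926 bp;
#' three direct, one inverted), ~44.7\% GC, long reads of 8 kb mean
#' length at 10\% error and 50x paired 150 bp short reads with a 400 bp
#' insert. The conformation mixture defaults to an equal split between
#' the base (most-fissioned) state and the most-fused state, the
#' coexistence regime reported for such genomes.
#'
#' @param nSingleCopyUnits number of single-copy units.
#' @param unitLengthRange min/max single-copy unit length (bp).
#' @param nCircles number of circles in the base conformation.
#' @param layout optional list of signed unit-token vectors fixing the
#'   base conformation (see \code{\link{circularMolecule}}); unit ids
#'   appearing twice are repeats.
#' @param unitLengths optional named lengths used with \code{layout}.
#' @param repeatSpecs data.frame: id (optional), length, kind.
#' @param plastidSpecs data.frame: length, divergence.
#' @param conformationFrequencies optional numeric over the truth states.
#' @param longReadParams,shortReadParams parameter lists, see
#'   \linkS4class{SimulationConfig}.
#' @param gc background G+C fraction.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nSingleCopyUnits = 12L,
                             unitLengthRange = c(2351L, 56817L),
                             nCircles = 5L,
                             layout = NULL,
                             unitLengths = NULL,
                             repeatSpecs = defaultRepeatSpecs(),
                             plastidSpecs = data.frame(
                               length = numeric(0),
                               divergence = numeric(0)),
                             conformationFrequencies = NULL,
                             longReadParams = list(
                               n = 1000L, meanLength = 8000,
                               sdlog = 0.3, errorRate = 0.1,
                               errorMix = c(sub = 0.5, ins = 0.3,
                                            del = 0.2)),
                             shortReadParams = list(
                               coverage = 50, readLength = 150L,
                               insertMean = 400, insertSd = 40,
                               errorRate = 0.002),
                             gc = 0.447,
                             seed = 1L) {
  cfg <- new("SimulationConfig",
             nSingleCopyUnits = as.integer(nSingleCopyUnits),
             unitLengthRange = as.integer(unitLengthRange),
             nCircles = as.integer(nCircles),
             layout = layout,
             unitLengths = unitLengths,
             repeatSpecs = repeatSpecs,
             plastidSpecs = plastidSpecs,
             conformationFrequencies = conformationFrequencies,
             longReadParams = longReadParams,
             shortReadParams = shortReadParams,
             gc = gc, seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Accepts a YAML file whose top-level keys mirror the arguments of
#' \code{\link{simulationConfig}}; missing keys fall back to the
#' defaults.
#'
#' @param path YAML file path.
#' @return A \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  scal <- c("nSingleCopyUnits", "nCircles", "gc", "seed",
            "conformationFrequencies", "unitLengthRange")
  for (k in scal) if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$layout)) args$layout <- lapply(y$layout, as.character)
  if (!is.null(y$unitLengths)) args$unitLengths <- unlist(y$unitLengths)
  if (!is.null(y$repeatSpecs))
    args$repeatSpecs <- do.call(rbind.data.frame, y$repeatSpecs)
  if (!is.null(y$plastidSpecs))
    args$plastidSpecs <- do.call(rbind.data.frame, y$plastidSpecs)
  for (k in c("longReadParams", "shortReadParams"))
    if (!is.null(y[[k]])) {
      def <- formals(simulationConfig)[[k]]
      merged <- eval(def)
      v <- y[[k]]
      # YAML 1.1 reads a bare key "n" as boolean FALSE; map it back
      names(v)[names(v) == "FALSE"] <- "n"
      merged[names(v)] <- v
      args[[k]] <- merged
    }
  do.call(simulationConfig, args)
}

#' Compact five-circle validation genome configuration
#'
#' A desk-scale analogue of the five-molecule topology resolved for
#' marama: five circles built from eight single-copy units and four 2 kb
#' repeats -- three direct repeats each shared between two circles (the
#' fusion substrate that merges the five circles into two master rings)
#' and one inverted repeat with both copies on the largest circle (the
#' flip-flop substrate). Total genome 67 kb with every circle (10.5--25
#' kb) comfortably longer than the 8 kb mean long read, so that reads
#' rarely wrap a full circle (which keeps repeat-traversal counting
#' unbiased between states) while 1,000 long reads still yield several
#' hundred full repeat traversals for mixture estimation.
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed on to \code{\link{simulationConfig}}.
#' @return A \linkS4class{SimulationConfig}.
#' @export
topologyDemoConfig <- function(seed = 1L, ...) {
  layout <- list(
    c("U01", "RI", "U02", "RH", "U03", "-RI", "U04", "RJ"),
    c("U05", "RH"),
    c("U06", "RJ"),
    c("U07", "RO"),
    c("U08", "RO"))
  unitLengths <- c(U01 = 4250, U02 = 4250, U03 = 4250, U04 = 4250,
                   U05 = 8500, U06 = 8500, U07 = 8500, U08 = 8500,
                   RH = 2000, RI = 2000, RJ = 2000, RO = 2000)
  repeatSpecs <- data.frame(id = c("RH", "RI", "RJ", "RO"),
                            length = 2000,
                            kind = c("direct", "inverted", "direct",
                                     "direct"),
                            stringsAsFactors = FALSE)
  simulationConfig(nSingleCopyUnits = 8L, nCircles = 5L,
                   unitLengthRange = c(4250L, 8500L),
                   layout = layout, unitLengths = unitLengths,
                   repeatSpecs = repeatSpecs, seed = seed, ...)
}

# resolve unit lengths for a set of ids: explicit > repeatSpecs > sampled
resolveLengths <- function(ids, config, repeatIds, repeatSpecLens) {
  lens <- setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(config@unitLengths)) {
    shared <- intersect(ids, names(config@unitLengths))
    lens[shared] <- config@unitLengths[shared]
  }
  stillRep <- intersect(repeatIds, ids[is.na(lens)])
  lens[stillRep] <- repeatSpecLens[stillRep]
  todo <- is.na(lens)
  if (any(todo)) {
    r <- config@unitLengthRange
    lens[todo] <- sample(seq(r[1], r[2]), sum(todo), replace = TRUE)
  }
  lens
}

#' Build a multipartite master genome with ground truth
#'
#' Draws single-copy units with lengths in the configured range, places
#' each specified repeat so that it has exactly two copies (direct
#' repeats shared between two circles when possible, inverted repeats as
#' two opposite-strand copies on one circle), assembles the base
#' conformation of circular molecules, generates i.i.d. background
#' sequence at the configured GC, and enumerates the truth conformation
#' space as the recombination closure of the base state. Deterministic
#' for a fixed seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{MasterGenome}.
#' @export
buildMasterGenome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  reps <- config@repeatSpecs
  nRep <- nrow(reps)
  specRepIds <- if (nRep && !is.null(reps$id)) as.character(reps$id)
    else if (nRep) sprintf("R%d", seq_len(nRep)) else character(0)
  specRepLens <- setNames(if (nRep) as.numeric(reps$length) else
    numeric(0), specRepIds)
  specRepKind <- setNames(if (nRep) as.character(reps$kind) else
    character(0), specRepIds)

  if (is.null(config@layout)) {
    nS <- config@nSingleCopyUnits
    nC <- min(config@nCircles, nS)
    singleIds <- sprintf("U%02d", seq_len(nS))
    assign <- c(seq_len(nC), sample(nC, nS - nC, replace = TRUE))
    assign <- assign[sample(nS)]
    layout <- lapply(seq_len(nC), function(ci) singleIds[assign == ci])
    for (ri in seq_len(nRep)) {
      r <- specRepIds[ri]
      if (specRepKind[r] == "inverted" || nC < 2L) {
        ci <- sample(nC, 1L)
        toks <- layout[[ci]]
        pos <- sort(sample(0:length(toks), 2L, replace = TRUE))
        s2 <- if (specRepKind[r] == "inverted") paste0("-", r) else r
        toks <- append(toks, r, after = pos[1])
        toks <- append(toks, s2, after = pos[2] + 1L)
        layout[[ci]] <- toks
      } else {
        cc <- sample(nC, 2L)
        for (ci in cc) {
          toks <- layout[[ci]]
          layout[[ci]] <- append(toks, r,
                                 after = sample(0:length(toks), 1L))
        }
      }
    }
  } else {
    layout <- config@layout
  }

  allTokens <- unlist(layout)
  parsed <- parseSignedTokens(allTokens)
  occ <- table(parsed$units)
  if (any(occ > 2L))
    stop("unit(s) appearing more than twice: ",
         paste(names(occ)[occ > 2L], collapse = ", "))
  repeatIds <- names(occ)[occ == 2L]
  singleIds <- names(occ)[occ == 1L]
  kinds <- setNames(rep(NA_character_, length(repeatIds)), repeatIds)
  known <- intersect(repeatIds, specRepIds)
  kinds[known] <- specRepKind[known]

  base <- conformationSet(layout)
  # infer kinds for unannotated repeats from the base configuration
  for (r in repeatIds[is.na(kinds)]) {
    holders <- which(vapply(base@molecules,
                            function(m) any(m@units == r), logical(1)))
    if (length(holders) == 1L) {
      m <- base@molecules[[holders]]
      cp <- which(m@units == r)
      kinds[r] <- if (m@strands[cp[1]] * m@strands[cp[2]] == -1L)
        "inverted" else "direct"
    } else kinds[r] <- "direct"
  }

  lens <- resolveLengths(c(singleIds, repeatIds), config, repeatIds,
                         specRepLens)
  # sizing check: a repeat may not dominate its host circle
  for (ci in seq_along(layout)) {
    toks <- parseSignedTokens(layout[[ci]])$units
    circleLen <- sum(lens[toks])
    for (r in intersect(unique(toks), repeatIds)) {
      inCircle <- sum(toks == r) * lens[r]
      if (lens[r] > circleLen - inCircle)
        stop("sizing error: repeat '", r, "' (", lens[r],
             " bp) is longer than the rest of its host circle")
    }
  }

  ids <- c(singleIds, repeatIds)
  seqs <- DNAStringSet(vapply(ids, function(id)
    randomDNA(lens[id], config@gc), character(1)))
  names(seqs) <- ids
  info <- DataFrame(
    id = ids,
    length = as.integer(lens[ids]),
    role = c(rep("single", length(singleIds)),
             rep("repeat", length(repeatIds))),
    kind = unname(c(rep(NA_character_, length(singleIds)),
                    kinds[repeatIds])))
  repTab <- data.frame(id = repeatIds, kind = kinds[repeatIds],
                       stringsAsFactors = FALSE)
  truth <- conformationSpace(base, repTab)
  new("MasterGenome", units = seqs, unitInfo = info,
      baseConformation = base, truthSpace = truth,
      plastidTruth = DataFrame(fragment = character(0),
                               unit = character(0),
                               unitStart = integer(0),
                               unitEnd = integer(0),
                               molecule = integer(0),
                               cpStart = integer(0), cpEnd = integer(0),
                               length = integer(0),
                               divergence = numeric(0),
                               identity = numeric(0)),
      config = config)
}

#' Enumerate the true conformation space of a master genome
#'
#' The closure of the base conformation under all single recombination
#' events on the annotated repeats (see \code{\link{conformationSpace}}).
#'
#' @param master a \linkS4class{MasterGenome}.
#' @return A list of \linkS4class{ConformationSet}.
#' @export
enumerateTrueConformations <- function(master) {
  info <- master@unitInfo
  reps <- data.frame(id = info$id[info$role == "repeat"],
                     kind = info$kind[info$role == "repeat"],
                     stringsAsFactors = FALSE)
  conformationSpace(master@baseConformation, reps)
}

#' Simulate a plastid genome donor sequence
#'
#' An i.i.d. random donor at plastid-like GC, used as the source for
#' simulated plastid-to-mitochondrion insertions.
#'
#' @param length donor length in bp.
#' @param gc G+C fraction (plastid genomes are AT-rich; default 0.36).
#' @param seed integer RNG seed.
#' @return A \code{DNAStringSet} of length 1 named "plastid".
#' @export
simulatePlastidGenome <- function(length = 20000L, gc = 0.36,
                                  seed = 1L) {
  set.seed(seed)
  DNAStringSet(c(plastid = randomDNA(length, gc)))
}

#' Insert plastid-derived fragments into a master genome
#'
#' Copies each configured fragment from the donor plastid genome,
#' mutates it by substitution to the stated divergence, and inserts it
#' at a uniform position inside a single-copy unit. All fragments land
#' on units of one (randomly chosen) base molecule, emulating the
#' observation that plastid-derived fragments cluster on one molecule.
#' Host circle lengths increase by exactly the fragment lengths, and
#' truth intervals are recorded in both coordinate systems together with
#' the realized identity.
#'
#' @param master a \linkS4class{MasterGenome}.
#' @param cpGenome the donor plastid genome (any single sequence).
#' @param specs data.frame with columns length and divergence; defaults
#'   to the master's configured plastid specs.
#' @return The updated \linkS4class{MasterGenome} with
#'   \code{plastidTruth} filled in.
#' @export
insertPlastidFragments <- function(master, cpGenome,
                                   specs = master@config@plastidSpecs) {
  if (is.null(specs) || nrow(specs) == 0L) return(master)
  if (any(specs$divergence >= 1) || any(specs$divergence < 0))
    stop("divergence must be in [0, 1)")
  cp <- asCharSeqs(cpGenome)[[1]]
  cpLen <- nchar(cp)
  if (any(specs$length >= cpLen))
    stop("fragment longer than the donor plastid genome")
  set.seed(master@config@seed + 3L)
  info <- master@unitInfo
  base <- master@baseConformation
  singleByMol <- lapply(base@molecules, function(m)
    intersect(m@units, info$id[info$role == "single"]))
  cand <- which(lengths(singleByMol) > 0L)
  hostMol <- cand[sample.int(length(cand), 1L)]
  hostUnits <- singleByMol[[hostMol]]
  units <- as.character(master@units)
  n <- nrow(specs)
  rows <- vector("list", n)
  ins <- data.frame(unit = hostUnits[sample.int(length(hostUnits), n,
                                                replace = TRUE)],
                    pos = NA_integer_, frag = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    L <- as.integer(specs$length[i])
    cpStart <- sample.int(cpLen - L + 1L, 1L) - 1L
    frag <- substr(cp, cpStart + 1L, cpStart + L)
    mut <- mutateBySubstitution(frag, specs$divergence[i])
    ins$pos[i] <- sample.int(nchar(units[[ins$unit[i]]]) + 1L, 1L) - 1L
    ins$frag[i] <- mut$seq
    rows[[i]] <- data.frame(
      fragment = sprintf("mtpt%d", i), unit = ins$unit[i],
      unitStart = NA_integer_, unitEnd = NA_integer_,
      molecule = hostMol, cpStart = cpStart, cpEnd = cpStart + L,
      length = L, divergence = specs$divergence[i],
      identity = 100 * (1 - mut$nChanged / L),
      stringsAsFactors = FALSE)
  }
  # splice fragments; within a unit, apply in ascending position and
  # shift later coordinates by the accumulated inserted length
  for (u in unique(ins$unit)) {
    ii <- which(ins$unit == u)
    ii <- ii[order(ins$pos[ii])]
    offset <- 0L
    s <- units[[u]]
    for (i in ii) {
      p <- ins$pos[i] + offset
      s <- paste0(substr(s, 1L, p), ins$frag[i],
                  substr(s, p + 1L, nchar(s)))
      rows[[i]]$unitStart <- p
      rows[[i]]$unitEnd <- p + nchar(ins$frag[i])
      offset <- offset + nchar(ins$frag[i])
    }
    units[[u]] <- s
  }
  newUnits <- DNAStringSet(units)
  names(newUnits) <- names(master@units)
  info$length <- as.integer(nchar(units[info$id]))
  truth <- DataFrame(do.call(rbind, rows))
  initialize(master, units = newUnits, unitInfo = info,
             plastidTruth = truth)
}

# resolve mixture frequencies over the truth space
resolveFrequencies <- function(config, states) {
  f <- config@conformationFrequencies
  if (!is.null(f)) {
    if (length(f) != length(states))
      stop("conformationFrequencies must have one entry per truth state (",
           length(states), ")")
    return(f)
  }
  if (length(states) == 1L) return(1)
  nm <- vapply(states, function(s) length(s@molecules), integer(1))
  f <- numeric(length(states))
  fusedIdx <- which.min(replace(nm, 1L, Inf))
  f[1L] <- 0.5
  f[fusedIdx] <- f[fusedIdx] + 0.5
  f
}

#' Simulate long reads from a conformation mixture
#'
#' Read source states are multinomial at the mixture frequencies, source
#' circles are drawn proportional to circle length, start positions are
#' uniform on circular coordinates (reads may wrap the origin, handled by
#' sampling on the doubled sequence), lengths are log-normal at the
#' configured mean and dispersion (truncated to the source circle
#' length), strands are uniform, and errors are injected at the
#' configured per-base rate and substitution:insertion:deletion mix.
#' Full per-read truth is recorded.
#'
#' @param master a \linkS4class{MasterGenome}.
#' @param config a \linkS4class{SimulationConfig}; defaults to the
#'   master's own.
#' @return A \linkS4class{SimulatedReadSet} (unpaired).
#' @export
simulateLongReads <- function(master, config = master@config) {
  set.seed(config@seed + 1L)
  states <- master@truthSpace
  freqs <- resolveFrequencies(config, states)
  lp <- config@longReadParams
  n <- lp$n
  stateMols <- lapply(states, function(s)
    lapply(s@molecules, moleculeSequence, units = master@units))
  stateLens <- lapply(stateMols, function(m) vapply(m, length, integer(1)))
  if (lp$meanLength > max(unlist(stateLens)))
    warning("mean read length exceeds the longest circle; ",
            "reads are truncated to circle length")
  doubled <- lapply(stateMols, function(mols)
    vapply(mols, function(x) {
      s <- as.character(x); paste0(s, s)
    }, character(1)))
  stateIdx <- sample.int(length(states), n, replace = TRUE, prob = freqs)
  molIdx <- integer(n)
  for (si in unique(stateIdx)) {
    w <- which(stateIdx == si)
    molIdx[w] <- sample.int(length(stateLens[[si]]), length(w),
                            replace = TRUE, prob = stateLens[[si]])
  }
  circleLen <- mapply(function(si, mi) stateLens[[si]][mi],
                      stateIdx, molIdx)
  meanlog <- log(lp$meanLength) - lp$sdlog^2 / 2
  len <- pmin(pmax(100L, as.integer(round(stats::rlnorm(
    n, meanlog, lp$sdlog)))), circleLen)
  start <- as.integer(floor(runif(n) * circleLen))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- character(n)
  for (si in unique(stateIdx)) {
    for (mi in unique(molIdx[stateIdx == si])) {
      w <- which(stateIdx == si & molIdx == mi)
      seqs[w] <- substring(doubled[[si]][mi], start[w] + 1L,
                           start[w] + len[w])
    }
  }
  neg <- strand == "-"
  if (any(neg)) {
    rc <- as.character(reverseComplement(DNAStringSet(seqs[neg])))
    seqs[neg] <- rc
  }
  names(seqs) <- sprintf("lr%05d", seq_len(n))
  mix <- lp$errorMix
  seqs <- cpp_mutate_reads(seqs, lp$errorRate, mix[1], mix[2], mix[3])
  truth <- DataFrame(read = names(seqs), state = stateIdx,
                     molecule = molIdx, start = start, strand = strand,
                     length = len)
  new("SimulatedReadSet", reads = DNAStringSet(seqs), mates = NULL,
      truth = truth, paired = FALSE)
}

#' Simulate paired short reads over the base conformation
#'
#' Pair count is coverage x total length / (2 x read length); fragment
#' positions are uniform on circular coordinates; insert sizes are
#' normal at the configured mean/sd (clamped to at least twice the read
#' length); mates are reported on opposite strands (forward/reverse).
#' Errors are substitution-only at the configured rate. The base
#' conformation is used as the template: per-position depth is invariant
#' across conformation states, so the mixture does not affect short-read
#' coverage.
#'
#' @param master a \linkS4class{MasterGenome}.
#' @param config a \linkS4class{SimulationConfig}; defaults to the
#'   master's own.
#' @return A paired \linkS4class{SimulatedReadSet}.
#' @export
simulateShortReads <- function(master, config = master@config) {
  sp <- config@shortReadParams
  if (sp$insertMean < 2 * sp$readLength)
    stop("insert mean must be >= 2 x read length")
  set.seed(config@seed + 2L)
  mols <- lapply(master@baseConformation@molecules, moleculeSequence,
                 units = master@units)
  lens <- vapply(mols, length, integer(1))
  total <- sum(lens)
  rl <- as.integer(sp$readLength)
  nPairs <- as.integer(round(sp$coverage * total / (2 * rl)))
  doubled <- vapply(mols, function(x) {
    s <- as.character(x); paste0(s, s)
  }, character(1))
  molIdx <- sample.int(length(mols), nPairs, replace = TRUE, prob = lens)
  insert <- as.integer(round(rnorm(nPairs, sp$insertMean, sp$insertSd)))
  insert <- pmax(insert, 2L * rl)
  insert <- pmin(insert, lens[molIdx])
  start <- as.integer(floor(runif(nPairs) * lens[molIdx]))
  m1 <- substring(doubled[molIdx], start + 1L, start + rl)
  m2 <- substring(doubled[molIdx], start + insert - rl + 1L,
                  start + insert)
  m2 <- as.character(reverseComplement(DNAStringSet(m2)))
  ids <- sprintf("sr%06d", seq_len(nPairs))
  names(m1) <- ids
  names(m2) <- ids
  m1 <- cpp_mutate_reads(m1, sp$errorRate, 1, 0, 0)
  m2 <- cpp_mutate_reads(m2, sp$errorRate, 1, 0, 0)
  truth <- DataFrame(read = ids, state = 1L, molecule = molIdx,
                     start = start, strand = "+",
                     insert = insert)
  new("SimulatedReadSet", reads = DNAStringSet(m1),
      mates = DNAStringSet(m2), truth = truth, paired = TRUE)
}
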