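# shared fixture builders (all fixtures are generated in code)

randomSeq <- function(n, gc = 0.45) {
  at <- (1 - gc) / 2
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at, gc / 2, gc / 2, at)), collapse = "")
}

rcSeq <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substitute a fraction of positions (exact count), optional indels
mutateSeq <- function(x, div = 0, nIndel = 0L) {
  ch <- strsplit(x, "")[[1]]
  nmut <- round(div * length(ch))
  if (nmut > 0) {
    pos <- sample(length(ch), nmut)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  if (nIndel > 0) {
    for (i in seq_len(nIndel)) {
      p <- sample(length(ch), 1)
      if (runif(1) < 0.5) {
        ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = p)
      } else {
        ch <- ch[-p]
      }
    }
  }
  paste(ch, collapse = "")
}

# junction graph assembled directly from edge keys and node capacities
makeGraph <- function(edgeKeys, caps) {
  halves <- strsplit(edgeKeys, "--", fixed = TRUE)
  edges <- S4Vectors::DataFrame(
    end1 = vapply(halves, `[`, character(1), 1L),
    end2 = vapply(halves, `[`, character(1), 2L),
    count = rep(1L, length(edgeKeys)),
    readIds = rep("r1", length(edgeKeys)))
  nodes <- S4Vectors::DataFrame(id = names(caps),
                                copyNumber = as.integer(caps),
                                repeatFlag = caps >= 2L)
  new("JunctionGraph", nodes = nodes, edges = edges,
      observations = S4Vectors::DataFrame(
        read = character(0), end1 = character(0), end2 = character(0),
        orient1 = character(0), orient2 = character(0),
        gap = integer(0), qstart = integer(0)))
}

graphFromStates <- function(states, extraEdges = character(0)) {
  adj <- unique(c(unlist(lapply(states, mitomosaic:::stateAdjacency)),
                  extraEdges))
  occ <- table(unlist(lapply(states[[1]]@molecules,
                             function(m) m@units)))
  caps <- setNames(as.integer(occ), names(occ))
  makeGraph(adj, caps)
}

# random circular conformation over <= nNodes units with some two-copy
# repeats; guaranteed well-formed
randomTestConformation <- function(nNodes, nRepeats, nCircles) {
  ids <- LETTERS[seq_len(nNodes)]
  reps <- if (nRepeats > 0) sample(ids, nRepeats) else character(0)
  tokens <- c(ids, reps)
  tokens <- sample(tokens)
  neg <- runif(length(tokens)) < 0.3
  tokens[neg] <- paste0("-", tokens[neg])
  nCircles <- min(nCircles, length(tokens))
  cut <- sort(sample(length(tokens) - 1L, nCircles - 1L))
  groups <- split(tokens, findInterval(seq_along(tokens) - 1L, cut))
  conformationSet(unname(groups))
}

demoPipeline <- function(seed, nReads = NULL, freqs = NULL) {
  cfg <- topologyDemoConfig(seed = seed)
  if (!is.null(nReads)) cfg@longReadParams$n <- nReads
  if (!is.null(freqs)) cfg@conformationFrequencies <- freqs
  mg <- buildMasterGenome(cfg)
  lr <- simulateLongReads(mg, cfg)
  an <- extractAnchors(genomeUnits(mg), 500)
  obs <- callSpanning(mapReadsToAnchors(lr, an))
  g <- buildJunctionGraph(obs, scaffolds = genomeUnits(mg))
  list(cfg = cfg, mg = mg, lr = lr, an = an, obs = obs, graph = g)
}

fusedStateIndex <- function(mg) {
  nm <- vapply(truthSpace(mg), function(s) length(molecules(s)),
               integer(1))
  which.min(replace(nm, 1L, Inf))
}
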