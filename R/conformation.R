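#' @include utils.R AllGenerics.R
NULL

# ---- canonical forms -------------------------------------------------------

rotateTokens <- function(tokens, i) {
  n <- length(tokens)
  if (i == 0L) tokens else tokens[c((i + 1L):n, seq_len(i))]
}

flipMolecule <- function(mol) {
  new("CircularMolecule", units = rev(mol@units),
      strands = -rev(mol@strands))
}

#' Canonical form of a circular molecule
#'
#' The rotation- and strand-invariant representative: among all rotations
#' of the signed unit sequence and of its reverse complement, the
#' lexicographically smallest comma-joined token string. Used to
#' deduplicate circular isomorphs.
#'
#' @param mol a \linkS4class{CircularMolecule}.
#' @return A character scalar.
#' @examples
#' canonicalMolecule(circularMolecule(c("B", "A")))  # "A,B"
#' @export
canonicalMolecule <- function(mol) {
  t1 <- signedTokens(mol)
  t2 <- signedTokens(flipMolecule(mol))
  n <- length(t1)
  cand <- character(2L * n)
  for (i in seq_len(n)) {
    cand[i] <- paste(rotateTokens(t1, i - 1L), collapse = ",")
    cand[n + i] <- paste(rotateTokens(t2, i - 1L), collapse = ",")
  }
  min(cand)
}

#' Canonical form of a conformation set
#'
#' Sorted canonical molecule strings joined by ";". Two conformation sets
#' are the same genome state iff their canonical state strings are equal.
#'
#' @param state a \linkS4class{ConformationSet}.
#' @return A character scalar.
#' @export
canonicalState <- function(state) {
  paste(sort(vapply(state@molecules, canonicalMolecule, character(1))),
        collapse = ";")
}

# rotate (flipping first if necessary) so the copy at index `i` sits at
# position 1 with + strand
normalizeToCopy <- function(mol, i) {
  if (mol@strands[i] < 0) {
    n <- length(mol@units)
    mol <- flipMolecule(mol)
    i <- n - i + 1L
  }
  new("CircularMolecule",
      units = rotateTokens(mol@units, i - 1L),
      strands = rotateTokens(mol@strands, i - 1L))
}

# ---- recombination events --------------------------------------------------

#' Construct a recombination event
#'
#' @param repeatId id of the mediating repeat unit.
#' @param mechanism "fusion", "fission" or "inversion".
#' @param molecules integer indices of the operand molecule(s) within the
#'   conformation set: two for fusion, one for fission/inversion.
#' @param kind repeat kind ("direct"/"inverted"), checked against the
#'   mechanism when given.
#' @return A \linkS4class{RecombinationEvent}.
#' @export
recombinationEvent <- function(repeatId, mechanism, molecules,
                               kind = NA_character_) {
  new("RecombinationEvent", repeatId = repeatId, mechanism = mechanism,
      kind = kind, operands = list(molecules = as.integer(molecules)))
}

#' Apply one repeat-mediated recombination event to a conformation
#'
#' Direct-repeat fusion joins two circles that each carry one copy of the
#' repeat into one circle carrying both copies; fission is the exact
#' inverse split of a circle carrying both copies in the same orientation;
#' inverted-repeat inversion (flip-flop) reverse-complements the segment
#' between the two oppositely oriented copies, exchanging the successors
#' of the two copies while conserving length. All mechanisms are
#' reversible and conserve total genome length exactly.
#'
#' @param state a \linkS4class{ConformationSet}.
#' @param event a \linkS4class{RecombinationEvent} valid against
#'   \code{state}.
#' @return The transformed \linkS4class{ConformationSet}, with the event
#'   appended to its provenance.
#' @examples
#' s <- conformationSet(list(c("A", "R", "B"), c("C", "R")))
#' fused <- applyRecombination(s, recombinationEvent("R", "fusion", c(1, 2)))
#' length(molecules(fused))  # 1
#' @export
applyRecombination <- function(state, event) {
  validObject(event)
  r <- event@repeatId
  idx <- event@operands$molecules
  mols <- state@molecules
  if (event@mechanism == "fusion") {
    if (length(idx) != 2L || idx[1] == idx[2])
      stop("fusion needs two distinct operand molecules")
    a <- mols[[idx[1]]]; b <- mols[[idx[2]]]
    ca <- which(a@units == r); cb <- which(b@units == r)
    if (length(ca) != 1L || length(cb) != 1L)
      stop("fusion operands must each hold exactly one copy of repeat '",
           r, "'")
    a <- normalizeToCopy(a, ca)
    b <- normalizeToCopy(b, cb)
    fused <- new("CircularMolecule",
                 units = c(a@units, b@units),
                 strands = c(a@strands, b@strands))
    mols <- c(mols[-idx], list(fused))
  } else {
    if (length(idx) != 1L)
      stop(event@mechanism, " operates on a single molecule")
    m <- mols[[idx]]
    cp <- which(m@units == r)
    if (length(cp) != 2L)
      stop(event@mechanism, " requires both copies of repeat '", r,
           "' on one molecule")
    m <- normalizeToCopy(m, cp[1])
    j <- which(m@units == r)[2]
    n <- length(m@units)
    if (event@mechanism == "fission") {
      if (m@strands[j] != 1L)
        stop("mechanism/kind mismatch: copies of '", r,
             "' are inverted; fission needs a direct configuration")
      m1 <- new("CircularMolecule", units = m@units[seq_len(j - 1L)],
                strands = m@strands[seq_len(j - 1L)])
      m2 <- new("CircularMolecule", units = m@units[j:n],
                strands = m@strands[j:n])
      mols <- c(mols[-idx], list(m1, m2))
    } else {  # inversion
      if (m@strands[j] != -1L)
        stop("mechanism/kind mismatch: copies of '", r,
             "' are direct; inversion needs an inverted configuration")
      seg <- if (j > 2L) (2L):(j - 1L) else integer(0)
      units <- m@units; strands <- m@strands
      if (length(seg)) {
        units[seg] <- rev(units[seg])
        strands[seg] <- -rev(strands[seg])
      }
      mols <- c(mols[-idx],
                list(new("CircularMolecule", units = units,
                         strands = strands)))
    }
  }
  new("ConformationSet", molecules = mols,
      provenance = c(state@provenance, list(event)))
}

# enumerate every single recombination event applicable to `state` given a
# repeat table (columns id, kind)
applicableEvents <- function(state, repeats) {
  out <- list()
  for (ri in seq_len(nrow(repeats))) {
    r <- repeats$id[ri]; kind <- repeats$kind[ri]
    holders <- which(vapply(state@molecules,
                            function(m) sum(m@units == r) > 0L, logical(1)))
    counts <- vapply(state@molecules[holders],
                     function(m) sum(m@units == r), integer(1))
    if (length(holders) == 2L && all(counts == 1L)) {
      if (kind == "direct")
        out <- c(out, list(recombinationEvent(r, "fusion", holders, kind)))
    } else if (length(holders) == 1L && counts == 2L) {
      m <- state@molecules[[holders]]
      cp <- which(m@units == r)
      rel <- m@strands[cp[1]] * m@strands[cp[2]]
      if (rel == 1L && kind == "direct")
        out <- c(out, list(recombinationEvent(r, "fission", holders, kind)))
      if (rel == -1L && kind == "inverted")
        out <- c(out, list(recombinationEvent(r, "inversion", holders,
                                              kind)))
    }
  }
  out
}

#' Closure of a conformation under repeat-mediated recombination
#'
#' Breadth-first closure of the base state under all single recombination
#' events on the annotated repeats, deduplicated by canonical state form.
#' Every returned state conserves the total genome length of the base
#' state exactly, and reachability is symmetric because every mechanism is
#' reversible.
#'
#' @param base the starting \linkS4class{ConformationSet}.
#' @param repeats data.frame (or DataFrame) with columns \code{id} and
#'   \code{kind} describing the two-copy repeat units.
#' @return A list of \linkS4class{ConformationSet}; the base state first,
#'   then in breadth-first discovery order.
#' @examples
#' base <- conformationSet(list(c("A", "R", "B"), c("C", "R")))
#' length(conformationSpace(base, data.frame(id = "R", kind = "direct")))
#' @export
conformationSpace <- function(base, repeats) {
  repeats <- as.data.frame(repeats)
  if (nrow(repeats) == 0L) return(list(base))
  seen <- canonicalState(base)
  queue <- list(base)
  out <- list(base)
  while (length(queue)) {
    s <- queue[[1]]; queue <- queue[-1]
    for (ev in applicableEvents(s, repeats)) {
      s2 <- applyRecombination(s, ev)
      key <- canonicalState(s2)
      if (!key %in% seen) {
        seen <- c(seen, key)
        out <- c(out, list(s2))
        queue <- c(queue, list(s2))
      }
    }
  }
  out
}

# ---- lengths and sequences -------------------------------------------------

#' Length of a circular molecule from unit lengths
#'
#' Sum of constituent unit lengths, each traversal occurrence counted once
#' (so a fused circle carrying both copies of a repeat counts the repeat
#' twice).
#'
#' @param molecule a \linkS4class{CircularMolecule}.
#' @param unitLengths named numeric of unit lengths (bp).
#' @return Length in bp.
#' @export
moleculeLength <- function(molecule, unitLengths) {
  if (length(molecule@units) == 0L)
    stop("empty molecule has no length")
  missing <- setdiff(molecule@units, names(unitLengths))
  if (length(missing))
    stop("unknown unit(s): ", paste(missing, collapse = ", "))
  sum(unitLengths[molecule@units])
}

stateTotalLength <- function(state, unitLengths) {
  sum(vapply(state@molecules, moleculeLength, numeric(1),
             unitLengths = unitLengths))
}

#' Reconstitute the sequence of a circular molecule
#'
#' Concatenates unit sequences in circular order, reverse-complementing
#' reverse-strand units. The returned linear sequence starts at the
#' molecule's first unit (the rotation is arbitrary for a circle).
#'
#' @param molecule a \linkS4class{CircularMolecule}.
#' @param units named \code{DNAStringSet} of unit sequences.
#' @return A \code{DNAString}.
#' @export
moleculeSequence <- function(molecule, units) {
  missing <- setdiff(molecule@units, names(units))
  if (length(missing))
    stop("unknown unit(s): ", paste(missing, collapse = ", "))
  parts <- character(length(molecule@units))
  for (i in seq_along(molecule@units)) {
    s <- as.character(units[[molecule@units[i]]])
    parts[i] <- if (molecule@strands[i] < 0) revcompChar(s) else s
  }
  DNAString(paste(parts, collapse = ""))
}

# adjacency edge-key set of a conformation state
stateAdjacency <- function(state) {
  keys <- character(0)
  for (m in state@molecules) {
    n <- length(m@units)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      exit <- endKey(m@units[i], if (m@strands[i] > 0) "tail" else "head")
      entry <- endKey(m@units[j], if (m@strands[j] > 0) "head" else "tail")
      keys <- c(keys, edgeKey(exit, entry))
    }
  }
  unique(keys)
}

# ---- circle decomposition of a junction graph ------------------------------

#' Enumerate circular-molecule decompositions of a junction graph
#'
#' Enumerates every way of decomposing the junction graph into circular
#' walks that traverse each single-copy scaffold exactly once and each
#' two-copy (repeat) scaffold exactly twice, using only observed edges. A
#' traversal entering a scaffold's head exits its tail (forward strand)
#' and vice versa. Decompositions are deduplicated by canonical state
#' form; enumeration is exhaustive backtracking with a fixed start rule
#' (each walk starts at the smallest remaining scaffold id on the forward
#' strand), practical for graphs up to a few dozen nodes.
#'
#' @param graph a \linkS4class{JunctionGraph}; node copy numbers (set by
#'   \code{\link{flagRepeatNodes}}, default 1) give traversal capacities.
#' @return A list of \linkS4class{ConformationSet}, sorted by number of
#'   molecules then canonical form; empty if no decomposition exists.
#' @export
decomposeCircles <- function(graph) {
  nodes <- graph@nodes
  edges <- graph@edges
  cap <- nodes$copyNumber
  cap[is.na(cap)] <- 1L
  cap <- as.integer(pmax(1L, cap))
  names(cap) <- nodes$id
  # adjacency: end key -> vector of partner end keys
  adj <- list()
  addAdj <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
  }
  for (i in seq_len(nrow(edges))) {
    addAdj(edges$end1[i], edges$end2[i])
    if (edges$end1[i] != edges$end2[i])
      addAdj(edges$end2[i], edges$end1[i])
  }
  touched <- unique(endScaffold(c(edges$end1, edges$end2)))
  for (v in nodes$id) {
    hasH <- !is.null(adj[[endKey(v, "head")]])
    hasT <- !is.null(adj[[endKey(v, "tail")]])
    if (xor(hasH, hasT))
      stop("structural error: scaffold '", v,
           "' has junction evidence on only one end")
  }
  if (!all(nodes$id %in% touched)) return(list())  # unplaceable node(s)
  ids <- sort(nodes$id[nodes$id %in% touched])
  if (!length(ids)) return(list())
  rem <- cap[ids]
  results <- new.env(parent = emptyenv())
  circles <- list()          # completed circles (lists of units/strands)
  walkU <- character(0); walkS <- integer(0)
  firstEntry <- NA_character_
  recurse <- function(exitEnd) {
    if (is.na(exitEnd)) {
      # no open walk
      open <- names(rem)[rem > 0L]
      if (!length(open)) {
        st <- new("ConformationSet",
                  molecules = lapply(circles, function(cc)
                    new("CircularMolecule", units = cc$u,
                        strands = cc$s)),
                  provenance = list())
        results[[canonicalState(st)]] <- st
        return(invisible())
      }
      v <- open[1]
      rem[v] <<- rem[v] - 1L
      walkU <<- v; walkS <<- 1L
      firstEntry <<- endKey(v, "head")
      recurse(endKey(v, "tail"))
      rem[v] <<- rem[v] + 1L
      walkU <<- character(0); walkS <<- integer(0)
      firstEntry <<- NA_character_
      return(invisible())
    }
    partners <- adj[[exitEnd]]
    if (is.null(partners)) return(invisible())
    savedU <- walkU; savedS <- walkS; savedFirst <- firstEntry
    for (F in unique(partners)) {
      if (F == firstEntry) {
        # close the walk
        circles[[length(circles) + 1L]] <<- list(u = walkU, s = walkS)
        walkU <<- character(0); walkS <<- integer(0)
        firstEntry <<- NA_character_
        recurse(NA_character_)
        circles[[length(circles)]] <<- NULL
        walkU <<- savedU; walkS <<- savedS; firstEntry <<- savedFirst
      }
      w <- endScaffold(F)
      if (!w %in% names(rem) || rem[w] <= 0L) next
      strand <- if (endSide(F) == "head") 1L else -1L
      rem[w] <<- rem[w] - 1L
      walkU <<- c(walkU, w); walkS <<- c(walkS, strand)
      recurse(endKey(w, otherSide(endSide(F))))
      rem[w] <<- rem[w] + 1L
      walkU <<- savedU; walkS <<- savedS
    }
    invisible()
  }
  recurse(NA_character_)
  out <- as.list(results)
  if (!length(out)) return(list())
  keys <- names(out)
  nmol <- vapply(out, function(s) length(s@molecules), integer(1))
  out <- out[order(nmol, keys)]
  names(out) <- NULL
  out
}

# ---- mixture estimation ----------------------------------------------------

#' Conformation mixture estimate from repeat-spanning reads
#'
#' @slot frequencies numeric per-state frequency (sums to 1 when defined).
#' @slot ratio character ratio string from rounded frequencies.
#' @slot diagnosticCounts \code{DataFrame} of per-repeat diagnostic read
#'   counts per state.
#' @slot diagnosticReads integer, total reads used.
#' @slot flagged logical, TRUE when a comparison had zero diagnostic
#'   reads.
#' @export
setClass("MixtureEstimate",
  slots = c(frequencies = "numeric", ratio = "character",
            diagnosticCounts = "DataFrame", diagnosticReads = "integer",
            flagged = "logical"))

setMethod("show", "MixtureEstimate", function(object) {
  cat("MixtureEstimate (", object@diagnosticReads, " diagnostic reads):\n",
      sep = "")
  print(round(object@frequencies, 3))
  cat("  ratio ~", object@ratio, if (object@flagged) " [flagged]", "\n")
})

# pairing set of repeat `r` in a state: per traversal, the (head-side
# edge, tail-side edge) pair in the + reading of the repeat
repeatPairings <- function(state, r) {
  pairs <- character(0)
  for (m in state@molecules) {
    n <- length(m@units)
    for (p in which(m@units == r)) {
      prv <- if (p == 1L) n else p - 1L
      nxt <- if (p == n) 1L else p + 1L
      entry <- endKey(r, if (m@strands[p] > 0) "head" else "tail")
      exit <- endKey(r, if (m@strands[p] > 0) "tail" else "head")
      ePrev <- edgeKey(
        endKey(m@units[prv], if (m@strands[prv] > 0) "tail" else "head"),
        entry)
      eNext <- edgeKey(
        exit,
        endKey(m@units[nxt], if (m@strands[nxt] > 0) "head" else "tail"))
      # normalize to (+ reading): head-side edge first
      pr <- if (m@strands[p] > 0) c(ePrev, eNext) else c(eNext, ePrev)
      pairs <- c(pairs, paste(pr, collapse = "|"))
    }
  }
  unique(pairs)
}

# extract one vote per full repeat traversal from the stored junction
# observations: consecutive observations X--r and r--Y on the same read
repeatVotes <- function(observations, repeatIds) {
  votes <- data.frame(read = character(0), rep = character(0),
                      pair = character(0), stringsAsFactors = FALSE)
  if (nrow(observations) == 0L) return(votes)
  obs <- observations[order(observations$read, observations$qstart), ]
  n <- nrow(obs)
  if (n < 2L) return(votes)
  i <- seq_len(n - 1L)
  same <- obs$read[i] == obs$read[i + 1L]
  s2 <- endScaffold(obs$end2[i])
  s1n <- endScaffold(obs$end1[i + 1L])
  isRep <- s2 %in% repeatIds & s1n == s2 &
    endSide(obs$end2[i]) == otherSide(endSide(obs$end1[i + 1L]))
  hit <- which(same & isRep)
  for (h in hit) {
    r <- endScaffold(obs$end2[h])
    e1 <- edgeKey(obs$end1[h], obs$end2[h])
    e2 <- edgeKey(obs$end1[h + 1L], obs$end2[h + 1L])
    pr <- if (endSide(obs$end2[h]) == "head") c(e1, e2) else c(e2, e1)
    votes <- rbind(votes, data.frame(read = obs$read[h], rep = r,
                                     pair = paste(pr, collapse = "|"),
                                     stringsAsFactors = FALSE))
  }
  votes
}

#' Estimate the conformation mixture from spanning-read counts
#'
#' For every repeat whose flank pairings distinguish the candidate states,
#' long-read traversals that cross the repeat completely (flank to flank)
#' are counted as votes for the states whose pairing they match. A state's
#' frequency at one repeat is its exclusive vote count over all exclusive
#' votes; the overall per-state frequency is the mean over distinguishing
#' repeats, renormalized to sum to 1. The ratio string is formed from the
#' rounded frequencies (e.g. "1:1").
#'
#' @param graph a \linkS4class{JunctionGraph} whose observations were kept
#'   by \code{\link{buildJunctionGraph}}.
#' @param states list of candidate \linkS4class{ConformationSet} (>= 2),
#'   differing in at least one repeat pairing.
#' @return A \linkS4class{MixtureEstimate}.
#' @export
estimateMixture <- function(graph, states) {
  if (length(states) < 2L)
    stop("mixture estimation needs at least two candidate states")
  occ <- table(unlist(lapply(states[[1]]@molecules, function(m) m@units)))
  repeatIds <- names(occ)[occ == 2L]
  pairings <- lapply(states, function(s)
    lapply(setNames(repeatIds, repeatIds), function(r)
      repeatPairings(s, r)))
  distinguishing <- Filter(function(r) {
    sets <- lapply(pairings, `[[`, r)
    length(unique(vapply(sets, function(x)
      paste(sort(x), collapse = "&"), character(1)))) > 1L
  }, repeatIds)
  if (!length(distinguishing))
    stop("candidate states do not differ at any repeat pairing")
  votes <- repeatVotes(graph@observations, distinguishing)
  ns <- length(states)
  perRepeat <- matrix(0L, nrow = length(distinguishing), ncol = ns,
                      dimnames = list(distinguishing, NULL))
  for (ri in seq_along(distinguishing)) {
    r <- distinguishing[ri]
    v <- votes[votes$rep == r, ]
    for (k in seq_len(nrow(v))) {
      consistent <- which(vapply(seq_len(ns), function(si)
        v$pair[k] %in% pairings[[si]][[r]], logical(1)))
      if (length(consistent) == 1L)
        perRepeat[ri, consistent] <- perRepeat[ri, consistent] + 1L
    }
  }
  totals <- rowSums(perRepeat)
  flagged <- any(totals == 0L)
  freq <- rep(NA_real_, ns)
  if (any(totals > 0L)) {
    props <- perRepeat[totals > 0L, , drop = FALSE] /
      totals[totals > 0L]
    freq <- colMeans(props)
    freq <- freq / sum(freq)
  }
  names(freq) <- paste0("state", seq_len(ns))
  pos <- freq[!is.na(freq) & freq > 0]
  ratio <- if (length(pos))
    paste(pmax(1L, round(freq / min(pos))), collapse = ":")
  else NA_character_
  new("MixtureEstimate", frequencies = freq, ratio = ratio,
      diagnosticCounts = DataFrame(repeatId = rownames(perRepeat),
                                   as.data.frame(perRepeat)),
      diagnosticReads = as.integer(sum(perRepeat)), flagged = flagged)
}

# ---- component separation --------------------------------------------------

#' Check separation of master-ring components
#'
#' Units are grouped by connectivity: two units fall in the same component
#' when a junction edge links them or when any candidate state places them
#' on one circular molecule (which includes sharing a two-copy repeat).
#' The genome is "separated" when more than one component remains, i.e. no
#' junction evidence and no recombination event can merge the component
#' molecules into one circle.
#'
#' @param graph a \linkS4class{JunctionGraph}.
#' @param states list of \linkS4class{ConformationSet} to audit.
#' @return A list: \code{separated} (logical), \code{nComponents},
#'   \code{membership} (named integer of component ids per unit).
#' @export
checkComponentSeparation <- function(graph, states) {
  ids <- unique(c(graph@nodes$id,
                  unlist(lapply(states, function(s)
                    unlist(lapply(s@molecules, function(m) m@units))))))
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(match(a, ids)); rb <- find(match(b, ids))
    if (ra != rb) parent[rb] <<- ra
  }
  e <- graph@edges
  for (i in seq_len(nrow(e)))
    unite(endScaffold(e$end1[i]), endScaffold(e$end2[i]))
  for (s in states)
    for (m in s@molecules) {
      u <- unique(m@units)
      if (length(u) > 1L)
        for (k in 2:length(u)) unite(u[1], u[k])
    }
  roots <- vapply(seq_along(ids), find, numeric(1))
  membership <- setNames(as.integer(factor(roots)), ids)
  list(separated = length(unique(membership)) > 1L,
       nComponents = length(unique(membership)),
       membership = membership)
}
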