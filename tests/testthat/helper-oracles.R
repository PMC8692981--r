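# independent oracles used to validate the package's own algorithms

# ---- full dynamic-programming local alignment identity ---------------------

dpLocalIdentity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  Biostrings::pid(aln, type = "PID1")
}

# ---- per-base interval-union coverage --------------------------------------

markingCoverage <- function(starts, ends, genomeLength) {
  covered <- logical(genomeLength)
  for (i in seq_along(starts))
    if (ends[i] > starts[i])
      covered[(starts[i] + 1):ends[i]] <- TRUE
  sum(covered)
}

# ---- maximal exact shared segments by diagonal scan ------------------------

exactSharedSegments <- function(a, b, minLen) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  out <- list()
  for (off in (-(nb - 1)):(na - 1)) {
    i0 <- max(1L, 1L + off)
    j0 <- i0 - off
    len <- min(na - i0, nb - j0) + 1L
    if (len < minLen) next
    eq <- av[i0:(i0 + len - 1L)] == bv[j0:(j0 + len - 1L)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= minLen))
      out[[length(out) + 1L]] <- c(aStart = i0 + starts[k] - 2L,
                                   bStart = j0 + starts[k] - 2L,
                                   len = r$lengths[k])
  }
  out
}

# ---- brute-force circle-decomposition enumeration --------------------------
# Model: pick an integer multiplicity for every edge such that the uses
# incident to each scaffold end sum to the node capacity, then pair the
# head-side and tail-side edge-use plugs at every node into visits in all
# possible ways and trace the resulting closed walks. Entirely
# independent of the package's backtracking walk construction.

oracleDecompose <- function(graph) {
  nodes <- graphNodes(graph)
  edges <- as.data.frame(graphEdges(graph))
  cap <- nodes$copyNumber
  cap[is.na(cap)] <- 1L
  cap <- pmax(1L, as.integer(cap))
  names(cap) <- nodes$id
  endCap <- integer(0)
  for (id in nodes$id) {
    endCap[paste0(id, ":head")] <- cap[[id]]
    endCap[paste0(id, ":tail")] <- cap[[id]]
  }
  ne <- nrow(edges)
  if (ne == 0L) return(character(0))
  selfSame <- edges$end1 == edges$end2
  maxMult <- pmin(endCap[edges$end1], endCap[edges$end2])
  maxMult[selfSame] <- endCap[edges$end1[selfSame]] %/% 2L
  # suffix potential per end for pruning
  incWeight <- function(i, e) (edges$end1[i] == e) + (edges$end2[i] == e)
  pot <- matrix(0L, nrow = ne + 1L, ncol = length(endCap),
                dimnames = list(NULL, names(endCap)))
  for (i in ne:1)
    pot[i, ] <- pot[i + 1L, ] + vapply(names(endCap), function(e)
      as.integer(maxMult[i] * incWeight(i, e)), integer(1))
  states <- new.env(parent = emptyenv())
  endSide2 <- function(e) sub("^.*:", "", e)
  endNode2 <- function(e) sub(":(head|tail)$", "", e)
  tryMatchings <- function(mult) {
    inst <- rep(seq_len(ne), mult)
    if (!length(inst)) return(invisible())
    plugEnd <- as.vector(rbind(edges$end1[inst], edges$end2[inst]))
    nPlug <- length(plugEnd)
    p2 <- as.vector(rbind(seq(2, nPlug, by = 2), seq(1, nPlug, by = 2)))
    plugNode <- endNode2(plugEnd)
    plugSide <- endSide2(plugEnd)
    perNode <- lapply(nodes$id, function(v) {
      list(h = which(plugNode == v & plugSide == "head"),
           t = which(plugNode == v & plugSide == "tail"))
    })
    names(perNode) <- nodes$id
    # all visit pairings per node (capacity <= 2 here)
    options <- lapply(perNode, function(p) {
      if (length(p$h) == 0L) return(list(cbind(integer(0), integer(0))))
      if (length(p$h) == 1L) return(list(cbind(p$h, p$t)))
      list(cbind(p$h, p$t), cbind(p$h, rev(p$t)))
    })
    combo <- function(i, p1) {
      if (i > length(options)) {
        # trace closed walks
        visited <- logical(nPlug)
        circles <- list()
        for (p0 in seq_len(nPlug)) {
          if (visited[p0]) next
          u <- character(0); s <- integer(0)
          p <- p0
          repeat {
            visited[p] <- TRUE
            q <- p2[p]
            visited[q] <- TRUE
            u <- c(u, plugNode[q])
            s <- c(s, if (plugSide[q] == "head") 1L else -1L)
            r <- p1[q]
            visited[r] <- TRUE
            p <- r
            if (p == p0) break
          }
          circles[[length(circles) + 1L]] <-
            new("CircularMolecule", units = u, strands = s)
        }
        st <- new("ConformationSet", molecules = circles,
                  provenance = list())
        states[[canonicalState(st)]] <- TRUE
        return(invisible())
      }
      for (m in options[[i]]) {
        p1b <- p1
        for (r in seq_len(nrow(m))) {
          p1b[m[r, 1]] <- m[r, 2]
          p1b[m[r, 2]] <- m[r, 1]
        }
        combo(i + 1L, p1b)
      }
      invisible()
    }
    combo(1L, integer(nPlug))
    invisible()
  }
  endSum <- setNames(rep(0L, length(endCap)), names(endCap))
  recurse <- function(i, mult) {
    if (i > ne) {
      if (all(endSum == endCap)) tryMatchings(mult)
      return(invisible())
    }
    for (m in 0:maxMult[i]) {
      ok <- TRUE
      if (m > 0) {
        endSum[edges$end1[i]] <<- endSum[edges$end1[i]] + m
        endSum[edges$end2[i]] <<- endSum[edges$end2[i]] + m
      }
      if (any(endSum > endCap) ||
          any(endSum + pot[i + 1L, names(endCap)] < endCap))
        ok <- FALSE
      if (ok) recurse(i + 1L, c(mult, m))
      if (m > 0) {
        endSum[edges$end1[i]] <<- endSum[edges$end1[i]] - m
        endSum[edges$end2[i]] <<- endSum[edges$end2[i]] - m
      }
    }
    invisible()
  }
  recurse(1L, integer(0))
  sort(ls(states))
}
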