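#' @include align.R
NULL

#' Extract terminal anchors from scaffolds
#'
#' Takes the fixed-length window at both ends of each scaffold (head
#' \code{[0, a)} and tail \code{[L-a, L)}) used to detect junction-spanning
#' long reads. Scaffolds shorter than twice the anchor length yield
#' overlapping anchors flagged \code{short}.
#'
#' @param scaffolds non-empty named \code{DNAStringSet}.
#' @param anchorLen anchor window length (bp), >= 50; default 500.
#' @return A \code{DataFrame}: scaffold, side ("head"/"tail"), start, end
#'   (0-based half-open on the scaffold), short flag and anchor
#'   \code{seq}; anchor length recorded in \code{metadata()}.
#' @examples
#' s <- Biostrings::DNAStringSet(c(A = paste(rep("ACGT", 300), collapse = "")))
#' extractAnchors(s, 500)
#' @export
extractAnchors <- function(scaffolds, anchorLen = 500L) {
  if (length(scaffolds) == 0L) stop("empty scaffold set")
  anchorLen <- as.integer(anchorLen)
  if (anchorLen < 50L) stop("anchorLen must be >= 50")
  if (is.null(names(scaffolds)))
    names(scaffolds) <- paste0("scaffold", seq_along(scaffolds))
  L <- Biostrings::width(scaffolds)
  a <- pmin(anchorLen, L)
  headStart <- rep(0L, length(scaffolds))
  tailStart <- pmax(0L, L - a)
  df <- DataFrame(
    scaffold = rep(names(scaffolds), each = 2L),
    side = rep(c("head", "tail"), length(scaffolds)),
    start = as.integer(rbind(headStart, tailStart)),
    end = as.integer(rbind(headStart + a, tailStart + a)),
    short = rep(L < 2L * anchorLen, each = 2L))
  df$seq <- vapply(seq_len(nrow(df)), function(i)
    as.character(subseq(scaffolds[[df$scaffold[i]]],
                        start = df$start[i] + 1L, end = df$end[i])),
    character(1))
  metadata(df)$anchorLen <- anchorLen
  df
}

#' Map long reads onto scaffold terminal anchors
#'
#' Aligns each long read against all terminal anchors with the seed-and-
#' extend aligner and returns, per read, the ordered chain of anchor hits
#' along the read. Hits below \code{minIdentity} or covering less than
#' half the anchor are discarded.
#'
#' @param reads \code{DNAStringSet} of long reads (or a long-read
#'   \linkS4class{SimulatedReadSet}).
#' @param anchors anchor table from \code{\link{extractAnchors}}.
#' @param minIdentity minimum percent identity (default 80, tolerant of
#'   ~10\% long-read error).
#' @param k,xdrop aligner parameters, see \code{\link{localAlign}}.
#' @return A \code{DataFrame} ordered by read then read coordinate:
#'   read, scaffold, side, strand, qstart, qend, identity.
#' @export
mapReadsToAnchors <- function(reads, anchors, minIdentity = 80,
                              k = 13L, xdrop = 30) {
  if (is(reads, "SimulatedReadSet")) reads <- reads@reads
  targets <- DNAStringSet(anchors$seq)
  names(targets) <- paste(anchors$scaffold, anchors$side, sep = "|")
  widths <- setNames(anchors$end - anchors$start, names(targets))
  aln <- localAlign(reads, targets, minIdentity = minIdentity,
                    minLength = as.integer(ceiling(0.5 * min(widths))),
                    k = k, xdrop = xdrop)
  if (nrow(aln) == 0L)
    return(DataFrame(read = character(0), scaffold = character(0),
                     side = character(0), strand = character(0),
                     qstart = integer(0), qend = integer(0),
                     identity = numeric(0)))
  tspan <- aln$tend - aln$tstart
  aln <- aln[tspan >= 0.5 * widths[aln$target], , drop = FALSE]
  parts <- strsplit(aln$target, "|", fixed = TRUE)
  out <- DataFrame(read = aln$query,
                   scaffold = vapply(parts, `[`, character(1), 1L),
                   side = vapply(parts, `[`, character(1), 2L),
                   strand = aln$strand,
                   qstart = aln$qstart, qend = aln$qend,
                   identity = aln$identity)
  out[order(out$read, out$qstart), ]
}

#' Call junction-spanning observations from anchor hit chains
#'
#' Each consecutive pair of anchor hits on a read that joins two scaffold
#' ends in orientation-consistent order, with a gap of at most
#' \code{maxGap} bp (negative for overlap), yields one junction
#' observation. A read exiting a scaffold passes its tail on the forward
#' strand (or its head on the reverse strand); within-scaffold head-tail
#' pairs are interior traversals, not junctions.
#'
#' @param hits anchor hit table from \code{\link{mapReadsToAnchors}}.
#' @param maxGap maximum junction gap in bp (default 500: abutting
#'   contigs are expected within anchor-scale distances).
#' @return A \code{DataFrame} of observations: read, end1, end2 (scaffold
#'   end keys), orient1, orient2, gap, qstart.
#' @export
callSpanning <- function(hits, maxGap = 500L) {
  empty <- DataFrame(read = character(0), end1 = character(0),
                     end2 = character(0), orient1 = character(0),
                     orient2 = character(0), gap = integer(0),
                     qstart = integer(0))
  n <- nrow(hits)
  if (n < 2L) return(empty)
  i <- seq_len(n - 1L)
  j <- i + 1L
  sameRead <- hits$read[i] == hits$read[j]
  gap <- hits$qstart[j] - hits$qend[i]
  # the left hit must present its outgoing end, the right hit its
  # incoming end
  outSide <- ifelse(hits$strand[i] == "+", "tail", "head")
  inSide <- ifelse(hits$strand[j] == "+", "head", "tail")
  consistent <- hits$side[i] == outSide & hits$side[j] == inSide
  interior <- hits$scaffold[i] == hits$scaffold[j]
  ok <- sameRead & consistent & !interior & abs(gap) <= maxGap
  if (!any(ok)) return(empty)
  i <- i[ok]; j <- j[ok]
  DataFrame(read = hits$read[i],
            end1 = endKey(hits$scaffold[i], hits$side[i]),
            end2 = endKey(hits$scaffold[j], hits$side[j]),
            orient1 = hits$strand[i], orient2 = hits$strand[j],
            gap = as.integer(gap[ok]), qstart = hits$qstart[i])
}

#' Build the weighted junction graph from spanning observations
#'
#' Aggregates observations into undirected edges between oriented
#' scaffold ends; edge support is the set of distinct spanning read ids,
#' and edges with fewer than \code{minSupport} supporting reads are
#' dropped (so a single chimeric long read cannot create an edge). The
#' raw observations are retained on the graph for downstream mixture
#' estimation.
#'
#' @param observations observation table from \code{\link{callSpanning}}.
#' @param minSupport minimum distinct spanning reads per edge (default 2).
#' @param scaffolds optional character vector (or named
#'   \code{DNAStringSet}) declaring the node set; defaults to scaffolds
#'   seen in the observations.
#' @return A \linkS4class{JunctionGraph} with unit copy numbers unset
#'   (see \code{\link{flagRepeatNodes}}).
#' @export
buildJunctionGraph <- function(observations, minSupport = 2L,
                               scaffolds = NULL) {
  if (nrow(observations)) {
    key <- edgeKey(observations$end1, observations$end2)
    splitReads <- split(observations$read, key)
    readSets <- lapply(splitReads, unique)
    counts <- lengths(readSets)
    keep <- counts >= minSupport
    keys <- names(readSets)[keep]
    halves <- strsplit(keys, "--", fixed = TRUE)
    edges <- DataFrame(
      end1 = vapply(halves, `[`, character(1), 1L),
      end2 = vapply(halves, `[`, character(1), 2L),
      count = as.integer(counts[keep]),
      readIds = vapply(readSets[keep], paste, character(1),
                       collapse = ","))
  } else {
    edges <- DataFrame(end1 = character(0), end2 = character(0),
                       count = integer(0), readIds = character(0))
  }
  ids <- if (!is.null(scaffolds)) {
    if (is.character(scaffolds)) scaffolds else names(scaffolds)
  } else {
    sort(unique(endScaffold(c(observations$end1, observations$end2))))
  }
  nodes <- DataFrame(id = ids,
                     copyNumber = rep(NA_integer_, length(ids)),
                     repeatFlag = rep(NA, length(ids)))
  rownames(edges) <- NULL
  new("JunctionGraph", nodes = nodes, edges = edges,
      observations = observations)
}

#' Flag two-copy repeat scaffolds from depth doubling
#'
#' Sets each node's copy number to its depth ratio against the
#' single-copy baseline, rounded half-up with a floor of 1. The baseline
#' is first taken as the median of per-scaffold median depths, then
#' re-estimated over nodes at copy number 1. Nodes at copy number >= 2
#' are flagged as repeats (collapsed two-copy sequence shows doubled
#' coverage); the number of distinct orientation-consistent neighbors on
#' each end is recorded as corroborating evidence, since a two-copy
#' repeat typically shows two alternative neighbors per end.
#'
#' @param graph a \linkS4class{JunctionGraph}.
#' @param depthTable a \linkS4class{DepthTable} covering every node.
#' @return The graph with node copyNumber, repeatFlag, depthRatio and
#'   per-end neighbor counts filled in.
#' @export
flagRepeatNodes <- function(graph, depthTable) {
  nodes <- graph@nodes
  st <- depthTable@stats
  missing <- setdiff(nodes$id, st$scaffold)
  if (length(missing))
    stop("no depth entry for scaffold(s): ",
         paste(missing, collapse = ", "))
  med <- setNames(st$median, st$scaffold)[nodes$id]
  baseline <- median(med)
  ratio <- med / baseline
  copy <- pmax(1L, as.integer(floor(ratio + 0.5)))
  if (any(copy == 1L)) {
    baseline <- median(med[copy == 1L])
    ratio <- med / baseline
    copy <- pmax(1L, as.integer(floor(ratio + 0.5)))
  }
  e <- graph@edges
  nbrs <- function(id, side) {
    k <- endKey(id, side)
    partners <- c(e$end2[e$end1 == k], e$end1[e$end2 == k])
    length(unique(partners))
  }
  nodes$copyNumber <- copy
  nodes$repeatFlag <- copy >= 2L
  nodes$depthRatio <- as.numeric(ratio)
  nodes$nNbrHead <- vapply(nodes$id, nbrs, integer(1), side = "head")
  nodes$nNbrTail <- vapply(nodes$id, nbrs, integer(1), side = "tail")
  initialize(graph, nodes = nodes)
}
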