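#' @include utils.R
NULL

asCharSeqs <- function(x) {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- as.character(seq_along(out))
    return(out)
  }
  if (is(x, "XString")) return(c(seq1 = as.character(x)))
  nm <- names(x)
  x <- as.character(x)
  names(x) <- if (is.null(nm)) as.character(seq_along(x)) else nm
  x
}

#' Build an exact k-mer seed index
#'
#' Indexes every k-mer of the input sequences on both strands; postings on
#' the minus strand carry positions on the reverse complement of the
#' sequence. This is the seeding structure behind
#' \code{\link{localAlign}}; it is exposed so that seeding behaviour can
#' be inspected and verified directly.
#'
#' @param sequences \code{DNAStringSet} (or named character vector).
#' @param k integer word size, 11--31 (default 13, sensitive for >= 200 bp
#'   segments at up to ~10\% divergence).
#' @return A \linkS4class{SeedIndex}.
#' @examples
#' idx <- kmerSeedIndex(Biostrings::DNAStringSet(c(s1 = "ACGTACGTACGTA")), 13)
#' nrow(idx@postings)
#' @export
kmerSeedIndex <- function(sequences, k = 13L) {
  k <- as.integer(k)
  if (k < 11L || k > 31L) stop("k must be in [11, 31]")
  seqs <- asCharSeqs(sequences)
  if (all(nchar(seqs) < k))
    stop("empty index: k = ", k, " is larger than every sequence")
  post <- cpp_kmer_postings(unname(seqs), k)
  new("SeedIndex", postings = DataFrame(post), k = k,
      sequences = DNAStringSet(seqs))
}

# cluster seed hits into diagonal-band chains and pick one anchor per chain
chainSeeds <- function(hits, band = 30L, maxSeedGap = 5000L) {
  hits$diag <- hits$qpos - hits$tpos
  o <- order(hits$query, hits$target, hits$strand, hits$diag, hits$qpos)
  hits <- hits[o, , drop = FALSE]
  grp <- paste(hits$query, hits$target, hits$strand)
  newGroup <- c(TRUE, grp[-1] != grp[-length(grp)])
  dd <- c(0L, diff(hits$diag))
  newChain <- newGroup | dd > band
  chain <- cumsum(newChain)
  # split chains with large positional gaps
  oo <- order(chain, hits$qpos)
  hits <- hits[oo, , drop = FALSE]
  chain <- chain[oo]
  qgap <- c(0L, diff(hits$qpos))
  chain <- cumsum(c(TRUE, chain[-1] != chain[-length(chain)]) |
                    qgap > maxSeedGap)
  hits$chain <- chain
  # anchor: the median seed of each chain
  idx <- unlist(lapply(split(seq_len(nrow(hits)), chain), function(ii)
    ii[(length(ii) + 1L) %/% 2L]), use.names = FALSE)
  hits[idx, , drop = FALSE]
}

#' Seed-and-extend local alignment
#'
#' Finds local alignments between query and target sequences by exact
#' k-mer seeding on both strands, merging of seeds on the same diagonal
#' band, and two-sided x-drop extension under unit costs (match +1,
#' mismatch -1, gap -2). Identity is the percentage of matching columns
#' over all alignment columns. With the default k = 13 any shared segment
#' of at least \code{minLength} bp diverging by up to ~10\% is seeded with
#' near certainty.
#'
#' @param query,target \code{DNAStringSet} (or character vectors).
#' @param index optional \linkS4class{SeedIndex} of the target set built
#'   with \code{\link{kmerSeedIndex}}; when omitted, seeds are computed
#'   directly.
#' @param minIdentity minimum percent identity to report.
#' @param minLength minimum alignment length (columns) to report.
#' @param k seed word size.
#' @param xdrop x-drop extension threshold.
#' @param band diagonal band (bp) within which seeds are merged into one
#'   chain before extension.
#' @param excludeSelf drop the trivial identity diagonal (for aligning a
#'   sequence set against itself).
#' @return A \code{DataFrame} with one row per alignment: query, target,
#'   qstart/qend, tstart/tend (0-based half-open, target coordinates on
#'   its forward strand), strand, identity, score, length (columns) and
#'   matches. Empty when nothing meets the thresholds.
#' @export
localAlign <- function(query, target, index = NULL, minIdentity = 70,
                       minLength = 100L, k = 13L, xdrop = 30,
                       band = 30L, excludeSelf = FALSE) {
  qs <- asCharSeqs(query)
  if (!is.null(index)) {
    stopifnot(is(index, "SeedIndex"))
    target <- index@sequences
    k <- index@k
  }
  ts <- asCharSeqs(target)
  empty <- DataFrame(query = character(0), target = character(0),
                     qstart = integer(0), qend = integer(0),
                     tstart = integer(0), tend = integer(0),
                     strand = character(0), identity = numeric(0),
                     score = numeric(0), length = integer(0),
                     matches = integer(0))
  hits <- cpp_seed_hits(unname(qs), unname(ts), as.integer(k),
                        excludeSelf)
  if (nrow(hits) == 0L) return(empty)
  anchors <- chainSeeds(hits, band = band)
  tsRC <- vapply(ts, revcompChar, character(1))
  out <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    tstr <- if (a$strand == "+") ts[[a$target]] else tsRC[[a$target]]
    e <- cpp_xdrop_extend(qs[[a$query]], tstr, a$qpos, a$tpos, xdrop)
    if (e$cols < minLength) next
    identity <- 100 * e$matches / e$cols
    if (identity < minIdentity) next
    tlen <- nchar(ts[[a$target]])
    if (a$strand == "+") {
      tstart <- e$tstart; tend <- e$tend
    } else {
      tstart <- tlen - e$tend; tend <- tlen - e$tstart
    }
    out[[i]] <- data.frame(
      query = names(qs)[a$query], target = names(ts)[a$target],
      qstart = e$qstart, qend = e$qend, tstart = tstart, tend = tend,
      strand = a$strand, identity = identity, score = e$score,
      length = e$cols, matches = e$matches, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  aln <- do.call(rbind, out)
  # deduplicate near-identical alignments within each (query, target,
  # strand) group, keeping the best-scoring representative
  aln <- aln[order(aln$query, aln$target, aln$strand, -aln$score), ,
             drop = FALSE]
  grp <- paste(aln$query, aln$target, aln$strand)
  keepIdx <- unlist(lapply(split(seq_len(nrow(aln)), grp), function(ii) {
    kept <- integer(0)
    for (i in ii) {
      dup <- FALSE
      for (j in kept) {
        qov <- min(aln$qend[j], aln$qend[i]) -
          max(aln$qstart[j], aln$qstart[i])
        tov <- min(aln$tend[j], aln$tend[i]) -
          max(aln$tstart[j], aln$tstart[i])
        if (qov > 0.5 * (aln$qend[i] - aln$qstart[i]) && tov > 0) {
          dup <- TRUE; break
        }
      }
      if (!dup) kept <- c(kept, i)
    }
    kept
  }), use.names = FALSE)
  aln <- aln[sort(keepIdx), , drop = FALSE]
  rownames(aln) <- NULL
  DataFrame(aln)
}

#' Classify contigs by homology to reference organelle gene sets
#'
#' Mirrors gene-seeded retrieval of organelle contigs from a mixed
#' assembly: each contig is aligned against reference mitochondrial and
#' plastid gene coding sequences and labeled by the gene set producing its
#' best-scoring alignment above the thresholds. Score ties are broken
#' toward the mitochondrial label (the pipeline's focus) and recorded.
#'
#' @param contigs \code{DNAStringSet} of assembly contigs.
#' @param mitoGenes,plastidGenes non-empty \code{DNAStringSet} of
#'   reference gene coding sequences.
#' @param minIdentity,minLength alignment acceptance thresholds.
#' @return A \code{DataFrame}: contig, label
#'   ("mitochondrial"/"plastid"/"unassigned"), bestGene, identity,
#'   length, score, tie.
#' @export
classifyContigs <- function(contigs, mitoGenes, plastidGenes,
                            minIdentity = 70, minLength = 200L) {
  if (length(mitoGenes) == 0L || length(plastidGenes) == 0L)
    stop("gene sets must be non-empty")
  cs <- asCharSeqs(contigs)
  bestOf <- function(genes) {
    aln <- localAlign(cs, genes, minIdentity = minIdentity,
                      minLength = minLength)
    if (nrow(aln) == 0L) return(NULL)
    aln <- aln[order(-aln$score), , drop = FALSE]
    aln[!duplicated(aln$query), , drop = FALSE]
  }
  mt <- bestOf(mitoGenes)
  cp <- bestOf(plastidGenes)
  res <- lapply(names(cs), function(id) {
    m <- if (!is.null(mt) && id %in% mt$query)
      mt[mt$query == id, ][1, ] else NULL
    p <- if (!is.null(cp) && id %in% cp$query)
      cp[cp$query == id, ][1, ] else NULL
    sm <- if (is.null(m)) -Inf else m$score
    sp <- if (is.null(p)) -Inf else p$score
    if (is.infinite(sm) && is.infinite(sp))
      return(data.frame(contig = id, label = "unassigned",
                        bestGene = NA_character_, identity = NA_real_,
                        length = NA_integer_, score = NA_real_,
                        tie = FALSE, stringsAsFactors = FALSE))
    tie <- is.finite(sm) && is.finite(sp) && sm == sp
    hit <- if (sm >= sp) m else p   # ties toward mitochondrial
    data.frame(contig = id,
               label = if (sm >= sp) "mitochondrial" else "plastid",
               bestGene = hit$target, identity = hit$identity,
               length = hit$length, score = hit$score, tie = tie,
               stringsAsFactors = FALSE)
  })
  DataFrame(do.call(rbind, res))
}
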