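#' @include align.R
NULL

#' Short-read depth profiling by exact k-mer assignment
#'
#' Computes per-position depth of coverage for each scaffold by assigning
#' read k-mers to scaffold positions via exact matching (both read
#' strands against the scaffold forward strand). A k-mer matching n
#' positions contributes 1/n to each, so reads from a collapsed two-copy
#' repeat split their weight across the copies and the repeat scaffold
#' retains its doubled depth signal instead of losing multi-mapping
#' reads.
#'
#' @param reads a \linkS4class{SimulatedReadSet} (both mates are used),
#'   \code{DNAStringSet} or character vector of reads.
#' @param scaffolds non-empty named \code{DNAStringSet}.
#' @param k k-mer size (default 21); must not exceed the read length.
#' @return A \linkS4class{DepthTable} with per-scaffold median and mean
#'   depth, the single-copy baseline (median of per-scaffold medians) and
#'   the positional depth vectors.
#' @export
depthProfile <- function(reads, scaffolds, k = 21L) {
  if (is(reads, "SimulatedReadSet")) {
    r <- reads@reads
    if (!is.null(reads@mates)) r <- c(r, reads@mates)
    reads <- r
  }
  rs <- asCharSeqs(reads)
  ss <- asCharSeqs(scaffolds)
  if (length(rs) == 0L || length(ss) == 0L)
    stop("reads and scaffolds must be non-empty")
  k <- as.integer(k)
  if (k > max(nchar(rs)))
    stop("k = ", k, " exceeds the read length")
  depth <- cpp_kmer_depth(unname(ss), unname(rs), k)
  names(depth) <- names(ss)
  # calibrate window-spread k-mer counts to read depth: an interior
  # position is covered by up to k windows, and a read of length r
  # contributes r-k+1 k-mers over r positions
  meanRl <- mean(nchar(rs))
  corr <- meanRl / (meanRl - k + 1)
  depth <- lapply(depth, function(d) {
    L <- length(d)
    w <- pmin(pmin(seq_len(L), k), rev(seq_len(L)))
    d / w * corr
  })
  med <- vapply(depth, median, numeric(1))
  mn <- vapply(depth, mean, numeric(1))
  new("DepthTable",
      stats = DataFrame(scaffold = names(ss), median = unname(med),
                        mean = unname(mn)),
      baseline = median(med), depth = depth)
}

#' Find long two-copy repeats by self-homology
#'
#' Reports all maximal pairs of segments of at least \code{minRepeatLen}
#' bp at \code{minIdentity} percent identity or better, within and
#' between the given molecules, classified direct or inverted by the
#' relative strand of the two copies. These long near-identical repeats
#' are the substrate of repeat-mediated recombination. Overlapping hits
#' of the same copy pair are merged to their maximal extent.
#'
#' @param molecules named \code{DNAStringSet} of (circular) molecule
#'   sequences; coordinates are reported on the given rotation.
#' @param minRepeatLen minimum repeat length (default 1000 bp, the
#'   conventional "long repeat" threshold).
#' @param minIdentity minimum percent identity (default 98: repeats that
#'   support recombination are near-identical).
#' @param k seed word size.
#' @return A \code{DataFrame}: id, length, kind ("direct"/"inverted"),
#'   identity, mol1, start1, end1, mol2, start2, end2, strand2
#'   (coordinates 0-based half-open).
#' @export
findLongRepeats <- function(molecules, minRepeatLen = 1000L,
                            minIdentity = 98, k = 13L) {
  aln <- localAlign(molecules, molecules, minIdentity = minIdentity,
                    minLength = minRepeatLen, k = k, xdrop = 50,
                    excludeSelf = TRUE)
  empty <- DataFrame(id = character(0), length = integer(0),
                     kind = character(0), identity = numeric(0),
                     mol1 = character(0), start1 = integer(0),
                     end1 = integer(0), mol2 = character(0),
                     start2 = integer(0), end2 = integer(0),
                     strand2 = character(0))
  if (nrow(aln) == 0L) return(empty)
  # normalize each alignment to an ordered copy pair
  df <- as.data.frame(aln)
  swap <- df$target < df$query |
    (df$target == df$query & df$tstart < df$qstart)
  tmp <- df
  df$query[swap] <- tmp$target[swap]; df$qstart[swap] <- tmp$tstart[swap]
  df$qend[swap] <- tmp$tend[swap]
  df$target[swap] <- tmp$query[swap]; df$tstart[swap] <- tmp$qstart[swap]
  df$tend[swap] <- tmp$qend[swap]
  df <- df[order(-df$length), , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(df))) {
    merged <- FALSE
    for (j in seq_along(kept)) {
      kp <- kept[[j]]
      if (kp$query == df$query[i] && kp$target == df$target[i] &&
          kp$strand == df$strand[i] &&
          min(kp$qend, df$qend[i]) > max(kp$qstart, df$qstart[i]) &&
          min(kp$tend, df$tend[i]) > max(kp$tstart, df$tstart[i])) {
        kp$qstart <- min(kp$qstart, df$qstart[i])
        kp$qend <- max(kp$qend, df$qend[i])
        kp$tstart <- min(kp$tstart, df$tstart[i])
        kp$tend <- max(kp$tend, df$tend[i])
        kp$identity <- max(kp$identity, df$identity[i])
        kept[[j]] <- kp
        merged <- TRUE
        break
      }
    }
    if (!merged) kept[[length(kept) + 1L]] <- df[i, ]
  }
  df <- do.call(rbind, kept)
  len <- pmax(df$qend - df$qstart, df$tend - df$tstart)
  o <- order(-len)
  df <- df[o, , drop = FALSE]; len <- len[o]
  DataFrame(id = paste0("rep", seq_len(nrow(df))),
            length = as.integer(len),
            kind = ifelse(df$strand == "+", "direct", "inverted"),
            identity = df$identity,
            mol1 = df$query, start1 = df$qstart, end1 = df$qend,
            mol2 = df$target, start2 = df$tstart, end2 = df$tend,
            strand2 = df$strand)
}

#' Fraction of the genome occupied by two-copy repeats
#'
#' Both copies of each repeat count toward the numerator:
#' \code{100 * sum(2 * length) / totalLength}, rounded half-up to one
#' decimal (the conventional reporting precision).
#'
#' @param repeats numeric repeat lengths (one per repeat pair) or a
#'   table with a \code{length} column such as from
#'   \code{\link{findLongRepeats}}.
#' @param totalLength total genome length in bp (> 0).
#' @return Percent of the genome, one decimal.
#' @examples
#' repeatGenomeFraction(c(5212, 2351, 3908, 4926), 399572)  # 8.2
#' @export
repeatGenomeFraction <- function(repeats, totalLength) {
  if (totalLength <= 0) stop("totalLength must be > 0")
  lens <- if (is.numeric(repeats)) repeats else repeats$length
  if (length(lens) == 0L) return(0)
  roundHalfUp(100 * sum(2 * lens) / totalLength, 1)
}
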