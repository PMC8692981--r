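#' @include align.R
NULL

#' Detect plastid-derived fragments (MTPT) in mitochondrial molecules
#'
#' Finds all local alignments between mitochondrial molecules and a
#' plastid genome meeting the length and identity thresholds. The default
#' identity floor of 70 sits below the weakest identities typically
#' observed for real mitochondrial plastid DNA (~74\%), so the oldest
#' detectable transfer class is retained. Overlapping mitochondrial
#' intervals on the same molecule are merged, keeping the
#' best-identity representative; results are sorted by length
#' descending.
#'
#' @param mtMolecules named \code{DNAStringSet} of mitochondrial
#'   molecules.
#' @param cpGenome plastid genome (\code{DNAString},
#'   \code{DNAStringSet} of length 1, or character).
#' @param minLength minimum fragment length (default 200 bp).
#' @param minIdentity minimum percent identity (default 70).
#' @param k seed word size.
#' @return A \code{DataFrame}: molecule, mtStart, mtEnd, cpStart, cpEnd,
#'   strand, identity, length (0-based half-open coordinates).
#' @export
findMTPT <- function(mtMolecules, cpGenome, minLength = 200L,
                     minIdentity = 70, k = 13L) {
  cp <- asCharSeqs(cpGenome)
  if (length(cp) != 1L || nchar(cp) == 0L)
    stop("cpGenome must be a single non-empty sequence")
  names(cp) <- "plastid"
  aln <- localAlign(mtMolecules, cp, minIdentity = minIdentity,
                    minLength = minLength, k = k, xdrop = 50)
  empty <- DataFrame(molecule = character(0), mtStart = integer(0),
                     mtEnd = integer(0), cpStart = integer(0),
                     cpEnd = integer(0), strand = character(0),
                     identity = numeric(0), length = integer(0))
  if (nrow(aln) == 0L) return(empty)
  df <- as.data.frame(aln)
  df <- df[order(df$query, -df$identity, -df$length), , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(df))) {
    dup <- FALSE
    for (j in seq_along(kept)) {
      kp <- kept[[j]]
      if (kp$query == df$query[i] &&
          min(kp$qend, df$qend[i]) > max(kp$qstart, df$qstart[i])) {
        kept[[j]]$qstart <- min(kp$qstart, df$qstart[i])
        kept[[j]]$qend <- max(kp$qend, df$qend[i])
        dup <- TRUE
        break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- df[i, ]
  }
  df <- do.call(rbind, kept)
  len <- df$qend - df$qstart
  o <- order(-len)
  df <- df[o, , drop = FALSE]
  DataFrame(molecule = df$query, mtStart = df$qstart, mtEnd = df$qend,
            cpStart = df$tstart, cpEnd = df$tend, strand = df$strand,
            identity = df$identity, length = as.integer(len[o]))
}

#' Fractional genome coverage of MTPT fragments
#'
#' Computes \code{100 * union(intervals) / genomeLength}, rounded
#' half-up to one decimal, in either the mitochondrial or the plastid
#' coordinate space. The two spaces can differ when several
#' mitochondrial fragments derive from overlapping donor regions.
#' Overlapping intervals are counted once (union semantics).
#'
#' @param fragments a fragment table from \code{\link{findMTPT}}, or a
#'   numeric vector of fragment lengths (then assumed disjoint).
#' @param genomeLength length (bp) of the genome in the chosen space.
#' @param space "mt" or "cp": which coordinate system to measure.
#' @return Percent covered, one decimal.
#' @examples
#' coverageFraction(c(9798, 859, 342, 273), 399572)  # 2.8
#' coverageFraction(9798, 399572)                    # 2.5
#' @export
coverageFraction <- function(fragments, genomeLength,
                             space = c("mt", "cp")) {
  space <- match.arg(space)
  if (genomeLength <= 0) stop("genomeLength must be > 0")
  if (is.numeric(fragments)) {
    if (any(fragments > genomeLength))
      stop("fragment longer than the genome")
    covered <- sum(fragments)
  } else if (nrow(fragments) == 0L) {
    covered <- 0
  } else {
    if (space == "mt") {
      start <- fragments$mtStart; end <- fragments$mtEnd
      grp <- fragments$molecule
    } else {
      start <- fragments$cpStart; end <- fragments$cpEnd
      grp <- rep("cp", nrow(fragments))
    }
    if (any(end > genomeLength) || any(start < 0))
      stop("interval beyond genome bounds")
    covered <- sum(vapply(split(seq_along(start), grp), function(ii)
      sum(width(reduce(IRanges(start = start[ii] + 1L, end = end[ii])))),
      numeric(1)))
  }
  roundHalfUp(100 * covered / genomeLength, 1)
}
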