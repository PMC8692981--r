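#' @include AllClasses.R
NULL

# round half away from zero at `digits` decimals (the reporting convention
# for printed percentages; base round() is round-half-even)
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# random DNA of length n at the configured GC fraction
randomDNA <- function(n, gc = 0.447) {
  at <- (1 - gc) / 2
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at, gc / 2, gc / 2, at)), collapse = "")
}

# substitute exactly round(divergence * L) distinct positions; returns the
# mutated string and the realized number of changes
mutateBySubstitution <- function(seq, divergence) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  nmut <- round(divergence * length(chars))
  if (nmut > 0) {
    pos <- sample(length(chars), nmut)
    for (p in pos) {
      alt <- setdiff(c("A", "C", "G", "T"), chars[p])
      chars[p] <- sample(alt, 1)
    }
  }
  list(seq = paste(chars, collapse = ""), nChanged = nmut)
}

revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# ---- signed unit tokens ("U01" / "-U01") ----------------------------------

parseSignedTokens <- function(tokens) {
  neg <- startsWith(tokens, "-")
  list(units = sub("^-", "", tokens),
       strands = ifelse(neg, -1L, 1L))
}

signedTokens <- function(mol) {
  paste0(ifelse(mol@strands < 0, "-", ""), mol@units)
}

#' Build a circular molecule from signed unit tokens
#'
#' @param tokens character vector of unit ids, a leading "-" marking
#'   reverse-strand traversal (e.g. \code{c("A", "R1", "-B")}).
#' @return A \linkS4class{CircularMolecule}.
#' @examples
#' circularMolecule(c("A", "R1", "-B"))
#' @export
circularMolecule <- function(tokens) {
  p <- parseSignedTokens(tokens)
  new("CircularMolecule", units = p$units, strands = p$strands)
}

#' Build a conformation set from a list of signed-token circles
#'
#' @param circles list of signed unit-token character vectors, one per
#'   circular molecule (see \code{\link{circularMolecule}}).
#' @return A \linkS4class{ConformationSet}.
#' @examples
#' conformationSet(list(c("A", "R1", "B"), c("C", "R1")))
#' @export
conformationSet <- function(circles) {
  new("ConformationSet",
      molecules = lapply(circles, circularMolecule),
      provenance = list())
}

moleculeString <- function(mol) paste(signedTokens(mol), collapse = ",")

# ---- scaffold end keys -----------------------------------------------------

endKey <- function(scaffold, side) paste0(scaffold, ":", side)

endScaffold <- function(key) sub(":(head|tail)$", "", key)

endSide <- function(key) sub("^.*:", "", key)

otherSide <- function(side) ifelse(side == "head", "tail", "head")

edgeKey <- function(end1, end2) {
  a <- pmin(end1, end2)
  b <- pmax(end1, end2)
  paste(a, b, sep = "--")
}
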