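#' @include depth.R mtpt.R
NULL

#' Base composition of a sequence
#'
#' Percentages of A, C, G and T to two decimals (half-up), with GC as
#' the sum of the C and G percentages. Ambiguity codes are counted
#' separately and excluded from the percentages.
#'
#' @param sequence a \code{DNAString}, \code{DNAStringSet} or character
#'   vector (one row per sequence in the result).
#' @return A \code{DataFrame}: id, A, C, G, T, GC (percent), length,
#'   ambiguous (count of non-ACGT letters).
#' @examples
#' baseComposition("ATGC")
#' @export
baseComposition <- function(sequence) {
  seqs <- asCharSeqs(sequence)
  if (length(seqs) == 0L || any(nchar(seqs) == 0L))
    stop("empty sequence")
  freq <- alphabetFrequency(DNAStringSet(seqs), baseOnly = TRUE)
  acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
  tot <- rowSums(acgt)
  if (any(tot == 0L)) stop("sequence contains no unambiguous bases")
  pct <- roundHalfUp(100 * acgt / tot, 2)
  DataFrame(id = names(seqs),
            A = unname(pct[, "A"]), C = unname(pct[, "C"]),
            G = unname(pct[, "G"]), T = unname(pct[, "T"]),
            GC = unname(pct[, "C"] + pct[, "G"]),
            length = unname(nchar(seqs)),
            ambiguous = unname(freq[, "other"]))
}

#' Genome summary statistics
#'
#' Scaffold count/min/max/median (median as the mean of the two central
#' values for even counts), molecule lengths and total, and the repeat
#' and MTPT genome fractions (delegated to
#' \code{\link{repeatGenomeFraction}} and
#' \code{\link{coverageFraction}}).
#'
#' @param scaffoldLengths non-empty numeric scaffold lengths (bp).
#' @param moleculeLengths non-empty numeric circular molecule lengths
#'   (bp).
#' @param repeats repeat lengths or table (see
#'   \code{\link{repeatGenomeFraction}}); NULL for none.
#' @param mtptFragments MTPT fragment lengths or table (see
#'   \code{\link{coverageFraction}}); NULL for none.
#' @return A \linkS4class{SummaryReport}.
#' @export
summaryStats <- function(scaffoldLengths, moleculeLengths,
                         repeats = NULL, mtptFragments = NULL) {
  if (length(scaffoldLengths) == 0L || length(moleculeLengths) == 0L)
    stop("length lists must be non-empty")
  total <- as.numeric(sum(moleculeLengths))
  repFrac <- if (is.null(repeats)) 0 else
    repeatGenomeFraction(repeats, total)
  mtptFrac <- if (is.null(mtptFragments)) 0 else
    coverageFraction(mtptFragments, total, space = "mt")
  new("SummaryReport",
      scaffoldStats = c(count = as.numeric(length(scaffoldLengths)),
                        min = as.numeric(min(scaffoldLengths)),
                        median = as.numeric(median(scaffoldLengths)),
                        max = as.numeric(max(scaffoldLengths))),
      moleculeLengths = as.numeric(moleculeLengths),
      totalLength = total,
      repeatFraction = repFrac,
      mtptFraction = mtptFrac)
}

sniffFormat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty)) return(list(format = "empty", lines = lines))
  first <- substr(lines[nonEmpty[1]], 1, 1)
  if (first == ">") list(format = "fasta", lines = lines)
  else if (first == "@") list(format = "fastq", lines = lines)
  else stop("parse error at line ", nonEmpty[1],
            ": not a FASTA ('>') or FASTQ ('@') record")
}

validateFasta <- function(lines) {
  inRecord <- FALSE
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l)) next
    if (startsWith(l, ">")) inRecord <- TRUE
    else {
      if (!inRecord)
        stop("parse error at line ", i, ": sequence before any header")
      if (grepl("[^A-Za-z.*-]", l))
        stop("parse error at line ", i, ": invalid sequence characters")
    }
  }
  invisible(TRUE)
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is sniffed from the first record character; structural
#' problems are reported with a line number. An empty file returns an
#' empty set with a warning.
#'
#' @param path input file.
#' @return A \code{DNAStringSet} (names carry the full description
#'   line).
#' @export
readSequences <- function(path) {
  sn <- sniffFormat(path)
  if (sn$format == "empty") {
    warning("empty sequence file: ", path)
    return(DNAStringSet())
  }
  if (sn$format == "fasta") {
    validateFasta(sn$lines)
    readDNAStringSet(path, format = "fasta")
  } else {
    readDNAStringSet(path, format = "fastq")
  }
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTA is wrapped at 70 columns; FASTQ uses a constant placeholder
#' quality (the pipeline never consumes qualities). Circular molecules
#' can be marked with \code{circular=true} in the description.
#'
#' @param records named \code{DNAStringSet} (or character vector).
#' @param path output file; format from extension (.fq/.fastq for
#'   FASTQ, FASTA otherwise) unless \code{format} is given.
#' @param format "fasta" or "fastq", overriding the extension.
#' @param circular logical (recycled): append " circular=true" to the
#'   description of the corresponding records.
#' @return Invisibly, \code{path}.
#' @export
writeSequences <- function(records, path, format = NULL,
                           circular = FALSE) {
  seqs <- DNAStringSet(asCharSeqs(records))
  if (is.null(format))
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  circular <- rep_len(circular, length(seqs))
  if (any(circular))
    names(seqs)[circular] <- paste(names(seqs)[circular],
                                   "circular=true")
  if (format == "fasta") {
    writeXStringSet(seqs, path, format = "fasta", width = 70L)
  } else {
    quals <- Biostrings::BStringSet(vapply(Biostrings::width(seqs),
      function(w) paste(rep("I", w), collapse = ""), character(1)))
    writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  }
  invisible(path)
}

#' Round-trip sequence records through a file
#'
#' Writes the records to \code{path} and reads them back; identifiers
#' and sequences are preserved exactly.
#'
#' @param path file to write and re-read.
#' @param records named \code{DNAStringSet} or character vector.
#' @param ... passed to \code{\link{writeSequences}}.
#' @return The re-read \code{DNAStringSet}.
#' @export
roundtripSequences <- function(path, records, ...) {
  writeSequences(records, path, ...)
  readSequences(path)
}

#' Write a read-truth table
#'
#' Tab-separated ground truth of a simulated read set (read id, source
#' state, source circle, start, strand).
#'
#' @param readSet a \linkS4class{SimulatedReadSet}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeTruthTSV <- function(readSet, path) {
  write.table(as.data.frame(readSet@truth), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a junction graph as a TSV edge list
#'
#' Columns end1, end2, count, readIds (comma-joined); a GFA-style
#' companion (segments and links) can be produced for external viewers.
#'
#' @param graph a \linkS4class{JunctionGraph}.
#' @param path output TSV path.
#' @param gfaPath optional path for GFA-style segment/link text.
#' @param scaffoldLengths optional named lengths written as segment LN
#'   tags.
#' @return Invisibly, \code{path}.
#' @export
writeJunctionGraphTSV <- function(graph, path, gfaPath = NULL,
                                  scaffoldLengths = NULL) {
  write.table(as.data.frame(graph@edges), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(gfaPath)) {
    con <- file(gfaPath, "w")
    on.exit(close(con))
    writeLines("H\tVN:Z:1.0", con)
    for (id in graph@nodes$id) {
      ln <- if (!is.null(scaffoldLengths) && id %in%
                names(scaffoldLengths))
        paste0("\tLN:i:", scaffoldLengths[[id]]) else ""
      writeLines(paste0("S\t", id, "\t*", ln), con)
    }
    e <- graph@edges
    for (i in seq_len(nrow(e))) {
      # a link leaves via a tail on +, enters via a head on +
      o1 <- if (endSide(e$end1[i]) == "tail") "+" else "-"
      o2 <- if (endSide(e$end2[i]) == "head") "+" else "-"
      writeLines(paste("L", endScaffold(e$end1[i]), o1,
                       endScaffold(e$end2[i]), o2, "0M",
                       paste0("RC:i:", e$count[i]), sep = "\t"), con)
    }
  }
  invisible(path)
}

# ---- packaged reference tables --------------------------------------------

maramaTable <- function(file) {
  read.delim(system.file("extdata", file, package = "mitomosaic"),
             stringsAsFactors = FALSE)
}

#' Reference tables for the marama mitogenome
#'
#' Published summary tables for the multipartite mitochondrial genome of
#' marama (Tylosema esculentum), shipped as plain TSV so that the
#' package's bookkeeping arithmetic can be exercised without any
#' download: the 16 primary scaffold lengths, the subgenome feature
#' table (five circular molecules plus the two fused master rings, with
#' base composition and lengths), the four long two-copy repeats, and
#' the four plastid-derived (MTPT) fragment lengths.
#'
#' @return \code{maramaScaffoldTable}: data.frame of unit labels and
#'   lengths (bp).
#' @export
maramaScaffoldTable <- function() maramaTable("marama_scaffolds.tsv")

#' @rdname maramaScaffoldTable
#' @return \code{maramaSubgenomeTable}: data.frame with molecule, A, C,
#'   G, T, GC percentages and length (bp).
#' @export
maramaSubgenomeTable <- function() maramaTable("marama_subgenomes.tsv")

#' @rdname maramaScaffoldTable
#' @return \code{maramaRepeatTable}: data.frame with repeat label,
#'   length and kind.
#' @export
maramaRepeatTable <- function() maramaTable("marama_repeats.tsv")

#' @rdname maramaScaffoldTable
#' @return \code{maramaMtptTable}: data.frame with fragment label and
#'   length.
#' @export
maramaMtptTable <- function() maramaTable("marama_mtpt.tsv")

#' Topology-level reconstruction of the marama base conformation
#'
#' The five-molecule base conformation with its four repeats placed per
#' the published merge topology: repeat H shared between molecules M1
#' and M2, J between M1 and M3, O between M4 and M5, and the inverted
#' repeat I with both copies on M1. The exact single-copy scaffold
#' composition of each molecule is not fully recoverable from the
#' published tables, so each molecule's single-copy content is
#' aggregated into one filler unit whose length makes the molecule
#' lengths match the published values exactly. Fusing M1+M2 via H and
#' then +M3 via J yields the 253,259 bp master ring LS1; fusing M4+M5
#' via O yields the 146,313 bp LS2.
#'
#' @return A list: \code{state} (the base \linkS4class{ConformationSet}),
#'   \code{unitLengths} (named bp), \code{repeats} (data.frame id, kind,
#'   length).
#' @export
maramaTopology <- function() {
  mol <- maramaSubgenomeTable()
  rep <- maramaRepeatTable()
  repLen <- setNames(rep$length, rep$label)
  lenOf <- function(m) mol$length[mol$molecule == m]
  unitLengths <- c(
    S1 = lenOf("M1") - repLen[["H"]] - repLen[["J"]] -
      2 * repLen[["I"]],
    S2 = lenOf("M2") - repLen[["H"]],
    S3 = lenOf("M3") - repLen[["J"]],
    S4 = lenOf("M4") - repLen[["O"]],
    S5 = lenOf("M5") - repLen[["O"]],
    H = repLen[["H"]], I = repLen[["I"]], J = repLen[["J"]],
    O = repLen[["O"]])
  state <- conformationSet(list(
    c("S1", "I", "H", "-I", "J"),
    c("S2", "H"),
    c("S3", "J"),
    c("S4", "O"),
    c("S5", "O")))
  list(state = state, unitLengths = unitLengths,
       repeats = data.frame(id = c("H", "I", "J", "O"),
                            kind = rep$kind[match(c("H", "I", "J", "O"),
                                                  rep$label)],
                            length = repLen[c("H", "I", "J", "O")],
                            stringsAsFactors = FALSE))
}
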