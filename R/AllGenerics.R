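#' @include AllClasses.R
NULL

#' Accessors for mitomosaic objects
#'
#' Small accessor generics for the package's S4 containers: unit sequences
#' and unit metadata of a \linkS4class{MasterGenome}, the molecules of a
#' \linkS4class{ConformationSet}, and the node/edge tables of a
#' \linkS4class{JunctionGraph}.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot content (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeUnits", function(x) standardGeneric("genomeUnits"))

#' @rdname accessors
#' @export
setGeneric("unitInfo", function(x) standardGeneric("unitInfo"))

#' @rdname accessors
#' @export
setGeneric("baseConformation",
           function(x) standardGeneric("baseConformation"))

#' @rdname accessors
#' @export
setGeneric("truthSpace", function(x) standardGeneric("truthSpace"))

#' @rdname accessors
#' @export
setGeneric("plastidTruth", function(x) standardGeneric("plastidTruth"))

#' @rdname accessors
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("depthStats", function(x) standardGeneric("depthStats"))

#' @rdname accessors
#' @export
setGeneric("depthBaseline", function(x) standardGeneric("depthBaseline"))

#' @rdname accessors
#' @export
setMethod("genomeUnits", "MasterGenome", function(x) x@units)

#' @rdname accessors
#' @export
setMethod("unitInfo", "MasterGenome", function(x) x@unitInfo)

#' @rdname accessors
#' @export
setMethod("baseConformation", "MasterGenome",
          function(x) x@baseConformation)

#' @rdname accessors
#' @export
setMethod("truthSpace", "MasterGenome", function(x) x@truthSpace)

#' @rdname accessors
#' @export
setMethod("plastidTruth", "MasterGenome", function(x) x@plastidTruth)

#' @rdname accessors
#' @export
setMethod("molecules", "ConformationSet", function(x) x@molecules)

#' @rdname accessors
#' @export
setMethod("graphNodes", "JunctionGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("graphEdges", "JunctionGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("depthStats", "DepthTable", function(x) x@stats)

#' @rdname accessors
#' @export
setMethod("depthBaseline", "DepthTable", function(x) x@baseline)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSingleCopyUnits, "single-copy units,",
      nrow(object@repeatSpecs), "repeat(s),",
      object@nCircles, "circles, seed", object@seed, "\n")
  cat("  long reads : n=", object@longReadParams$n, ", mean=",
      object@longReadParams$meanLength, " bp, error=",
      object@longReadParams$errorRate, "\n", sep = "")
  cat("  short reads: ", object@shortReadParams$coverage, "x, ",
      object@shortReadParams$readLength, " bp\n", sep = "")
})

setMethod("show", "CircularMolecule", function(object) {
  cat("CircularMolecule (", length(object@units), " units): ",
      moleculeString(object), "\n", sep = "")
})

setMethod("show", "ConformationSet", function(object) {
  cat("ConformationSet of", length(object@molecules), "circular",
      "molecule(s)\n")
  for (m in object@molecules)
    cat("  ", moleculeString(m), "\n", sep = "")
  if (length(object@provenance))
    cat("  provenance:", length(object@provenance), "event(s)\n")
})

setMethod("show", "RecombinationEvent", function(object) {
  cat("RecombinationEvent:", object@mechanism, "via repeat",
      object@repeatId, "\n")
})

setMethod("show", "MasterGenome", function(object) {
  info <- object@unitInfo
  cat("MasterGenome:", sum(info$role == "single"), "single-copy +",
      sum(info$role == "repeat"), "repeat unit(s);",
      length(object@baseConformation@molecules), "base circle(s);",
      length(object@truthSpace), "conformation state(s);",
      "total", sum(info$length[info$role == "single"]) +
        2L * sum(info$length[info$role == "repeat"]), "bp\n")
  if (nrow(object@plastidTruth))
    cat("  plastid insertions:", nrow(object@plastidTruth), "\n")
})

setMethod("show", "SimulatedReadSet", function(object) {
  cat("SimulatedReadSet:", length(object@reads),
      if (object@paired) "pairs" else "reads", "with truth\n")
})

setMethod("show", "SeedIndex", function(object) {
  cat("SeedIndex: k=", object@k, ", ", nrow(object@postings),
      " postings over ", length(object@sequences), " sequence(s)\n",
      sep = "")
})

setMethod("show", "JunctionGraph", function(object) {
  cat("JunctionGraph:", nrow(object@nodes), "node(s),",
      nrow(object@edges), "edge(s),",
      nrow(object@observations), "spanning observation(s)\n")
})

setMethod("show", "DepthTable", function(object) {
  cat("DepthTable over", nrow(object@stats), "scaffold(s); single-copy",
      "baseline", round(object@baseline, 2), "x\n")
})

setMethod("show", "SummaryReport", function(object) {
  s <- object@scaffoldStats
  cat("SummaryReport\n")
  cat("  scaffolds : n=", s["count"], ", min=", s["min"], ", median=",
      s["median"], ", max=", s["max"], " bp\n", sep = "")
  cat("  molecules :", paste(format(object@moleculeLengths, big.mark = ","),
                             collapse = ", "), "bp\n")
  cat("  total     :", format(object@totalLength, big.mark = ","), "bp\n")
  cat("  repeats   :", object@repeatFraction, "% of genome\n")
  cat("  MTPT      :", object@mtptFraction, "% of genome\n")
})
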