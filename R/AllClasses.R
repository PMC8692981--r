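#' @include mitomosaic-package.R
NULL

setClassUnion("DataFrameOrNULL", c("DataFrame", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))
setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' Simulation configuration for multipartite mitogenome emulation
#'
#' Holds every tunable of the synthetic-genome and read generator: unit
#' counts and length ranges, repeat specifications, plastid-insertion
#' specifications, conformation mixture frequencies, long- and short-read
#' parameters, background GC content and the RNG seed. Defaults emulate a
#' multipartite plant mitogenome at the scale observed for marama: 12
#' single-copy units of 2.3--57 kb arranged on 5 circles, four repeats
#' (three direct, one inverted) of 2--5.3 kb each present in two copies,
#' long reads of ~8 kb mean at 10% error, and 50x paired short reads.
#'
#' @slot nSingleCopyUnits integer, number of single-copy units.
#' @slot unitLengthRange integer(2), min/max single-copy unit length (bp).
#' @slot nCircles integer, number of circles in the base conformation.
#' @slot layout optional list of signed unit-id character vectors (one per
#'   circle, e.g. \code{c("U01","R1","-U02")}); when supplied it fixes the
#'   base conformation instead of random placement.
#' @slot unitLengths optional named numeric of unit lengths used with
#'   \code{layout}.
#' @slot repeatSpecs data.frame with columns \code{length} (bp) and
#'   \code{kind} ("direct"/"inverted"), optionally \code{id}.
#' @slot plastidSpecs data.frame with columns \code{length} (bp) and
#'   \code{divergence} (fraction in [0,1)).
#' @slot conformationFrequencies optional numeric mixture over the truth
#'   conformation space; \code{NULL} means an equal split between the base
#'   state and the most-fused state (the 1:1 regime).
#' @slot longReadParams list: \code{n}, \code{meanLength} (bp),
#'   \code{sdlog} (log-normal dispersion), \code{errorRate},
#'   \code{errorMix} numeric(3) substitution:insertion:deletion.
#' @slot shortReadParams list: \code{coverage} (x), \code{readLength} (bp),
#'   \code{insertMean} (bp), \code{insertSd} (bp), \code{errorRate}.
#' @slot gc numeric, background G+C fraction of simulated sequence.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  slots = c(
    nSingleCopyUnits = "integer",
    unitLengthRange = "integer",
    nCircles = "integer",
    layout = "listOrNULL",
    unitLengths = "numericOrNULL",
    repeatSpecs = "data.frame",
    plastidSpecs = "data.frame",
    conformationFrequencies = "numericOrNULL",
    longReadParams = "list",
    shortReadParams = "list",
    gc = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSingleCopyUnits < 1L)
    msg <- c(msg, "nSingleCopyUnits must be >= 1")
  if (length(object@unitLengthRange) != 2L ||
      any(object@unitLengthRange <= 0L))
    msg <- c(msg, "unitLengthRange must be two positive lengths")
  if (nrow(object@repeatSpecs) > 0) {
    if (!all(c("length", "kind") %in% names(object@repeatSpecs)))
      msg <- c(msg, "repeatSpecs needs 'length' and 'kind' columns")
    else {
      if (any(object@repeatSpecs$length <= 0))
        msg <- c(msg, "repeat lengths must be > 0")
      if (!all(object@repeatSpecs$kind %in% c("direct", "inverted")))
        msg <- c(msg, "repeat kind must be 'direct' or 'inverted'")
    }
  }
  if (nrow(object@plastidSpecs) > 0) {
    if (!all(c("length", "divergence") %in% names(object@plastidSpecs)))
      msg <- c(msg, "plastidSpecs needs 'length' and 'divergence' columns")
    else {
      if (any(object@plastidSpecs$length <= 0))
        msg <- c(msg, "plastid fragment lengths must be > 0")
      if (any(object@plastidSpecs$divergence < 0 |
              object@plastidSpecs$divergence >= 1))
        msg <- c(msg, "plastid divergence must be in [0, 1)")
    }
  }
  if (!is.null(object@conformationFrequencies)) {
    f <- object@conformationFrequencies
    if (abs(sum(f) - 1) > 1e-9)
      msg <- c(msg, "conformationFrequencies must sum to 1 (tol 1e-9)")
    if (any(f < 0)) msg <- c(msg, "conformation frequencies must be >= 0")
  }
  lr <- object@longReadParams
  if (!all(c("n", "meanLength", "sdlog", "errorRate", "errorMix") %in%
           names(lr)))
    msg <- c(msg, "longReadParams incomplete")
  else if (lr$errorRate < 0 || lr$errorRate >= 1)
    msg <- c(msg, "long-read error rate must be in [0, 1)")
  sr <- object@shortReadParams
  if (!all(c("coverage", "readLength", "insertMean", "insertSd",
             "errorRate") %in% names(sr)))
    msg <- c(msg, "shortReadParams incomplete")
  else {
    if (sr$errorRate < 0 || sr$errorRate >= 1)
      msg <- c(msg, "short-read error rate must be in [0, 1)")
    if (sr$insertMean < 2 * sr$readLength)
      msg <- c(msg, "insert mean must be >= 2 x read length")
  }
  if (object@gc <= 0 || object@gc >= 1)
    msg <- c(msg, "gc must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' A circular molecule as a signed ordering of assembly units
#'
#' Units are scaffold identifiers; strands are +1/-1 for forward/reverse
#' traversal along the circle. Two circular molecules are compared through
#' their canonical form, which is invariant under rotation and under
#' reading the circle from the opposite strand.
#'
#' @slot units character vector of unit ids, in circular order.
#' @slot strands integer vector of +1/-1, one per unit.
#' @export
setClass("CircularMolecule",
  slots = c(units = "character", strands = "integer"))

setValidity("CircularMolecule", function(object) {
  msg <- character()
  if (length(object@units) < 1L)
    msg <- c(msg, "a circular molecule needs at least one unit")
  if (length(object@units) != length(object@strands))
    msg <- c(msg, "units and strands must have equal length")
  if (!all(object@strands %in% c(-1L, 1L)))
    msg <- c(msg, "strands must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' A genome-wide set of circular molecules (one conformation)
#'
#' One conformation of a multipartite genome: a list of
#' \linkS4class{CircularMolecule} objects that jointly contain every
#' single-copy unit once and every two-copy repeat unit twice, plus the
#' provenance of recombination events that produced it from a base state.
#'
#' @slot molecules list of \linkS4class{CircularMolecule}.
#' @slot provenance list of \linkS4class{RecombinationEvent}.
#' @export
setClass("ConformationSet",
  slots = c(molecules = "list", provenance = "list"))

setValidity("ConformationSet", function(object) {
  ok <- vapply(object@molecules, is, logical(1), class2 = "CircularMolecule")
  if (!all(ok)) "molecules must all be CircularMolecule objects" else TRUE
})

#' A repeat-mediated recombination event
#'
#' Fusion joins two circles each carrying one copy of a direct repeat;
#' fission is its exact inverse on a circle carrying both copies; inversion
#' (flip-flop) reverse-complements the segment between the two copies of an
#' inverted repeat within one circle.
#'
#' @slot repeatId character, the repeat unit mediating the event.
#' @slot mechanism "fusion", "fission" or "inversion".
#' @slot kind repeat kind, "direct" or "inverted".
#' @slot operands list of molecule indices (and copy positions) acted on.
#' @export
setClass("RecombinationEvent",
  slots = c(repeatId = "character", mechanism = "character",
            kind = "character", operands = "list"))

setValidity("RecombinationEvent", function(object) {
  msg <- character()
  if (!object@mechanism %in% c("fusion", "fission", "inversion"))
    msg <- c(msg, "mechanism must be fusion, fission or inversion")
  if (length(object@kind) == 1L && !is.na(object@kind)) {
    if (object@mechanism == "inversion" && object@kind != "inverted")
      msg <- c(msg, "inversion requires an inverted repeat")
    if (object@mechanism %in% c("fusion", "fission") &&
        object@kind != "direct")
      msg <- c(msg, "fusion/fission require a direct repeat")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated multipartite master genome with full ground truth
#'
#' @slot units \code{DNAStringSet} of unit sequences (one copy per unit).
#' @slot unitInfo \code{DataFrame}: id, length, role ("single"/"repeat"),
#'   kind (NA, "direct" or "inverted").
#' @slot baseConformation \linkS4class{ConformationSet}, the generating
#'   state.
#' @slot truthSpace list of \linkS4class{ConformationSet}: closure of the
#'   base state under single recombination events.
#' @slot plastidTruth \code{DataFrame} of inserted plastid fragments (mt
#'   and cp coordinates, realized identity); empty until
#'   \code{\link{insertPlastidFragments}} is applied.
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @export
setClass("MasterGenome",
  slots = c(units = "DNAStringSet", unitInfo = "DataFrame",
            baseConformation = "ConformationSet", truthSpace = "list",
            plastidTruth = "DataFrame", config = "SimulationConfig"))

setValidity("MasterGenome", function(object) {
  msg <- character()
  occ <- unlist(lapply(object@baseConformation@molecules,
                       function(m) m@units))
  tab <- table(occ)
  info <- object@unitInfo
  singles <- info$id[info$role == "single"]
  reps <- info$id[info$role == "repeat"]
  if (!all(singles %in% names(tab)) || any(tab[singles] != 1L))
    msg <- c(msg, "every single-copy unit must appear exactly once")
  if (length(reps) && (!all(reps %in% names(tab)) || any(tab[reps] != 2L)))
    msg <- c(msg, "every repeat unit must appear exactly twice")
  if (!all(info$id %in% names(object@units)))
    msg <- c(msg, "unitInfo ids must match unit sequences")
  if (length(msg)) msg else TRUE
})

#' Simulated reads with per-read ground truth
#'
#' @slot reads \code{DNAStringSet}; first mates for paired data.
#' @slot mates \code{DNAStringSet} of second mates, or NULL for long reads.
#' @slot truth \code{DataFrame}: one row per read/pair giving source
#'   conformation state, source circle, start coordinate and strand.
#' @slot paired logical.
#' @export
setClass("SimulatedReadSet",
  slots = c(reads = "DNAStringSet", mates = "DNAStringSetOrNULL",
            truth = "DataFrame", paired = "logical"))

setValidity("SimulatedReadSet", function(object) {
  msg <- character()
  if (nrow(object@truth) != length(object@reads))
    msg <- c(msg, "truth must cover every read exactly once")
  if (object@paired && (is.null(object@mates) ||
      length(object@mates) != length(object@reads)))
    msg <- c(msg, "paired read set needs mates matching reads")
  if (length(msg)) msg else TRUE
})

#' Exact k-mer seed index
#'
#' Postings of every k-mer of a sequence set on both strands; positions on
#' the minus strand are coordinates on the reverse complement. Built by
#' \code{\link{kmerSeedIndex}} and consumed by \code{\link{localAlign}}.
#'
#' @slot postings \code{DataFrame}: kmer, seq (index), pos (0-based),
#'   strand.
#' @slot k integer word size.
#' @slot sequences the indexed \code{DNAStringSet}.
#' @export
setClass("SeedIndex",
  slots = c(postings = "DataFrame", k = "integer",
            sequences = "DNAStringSet"))

#' Weighted scaffold-junction graph
#'
#' Nodes are scaffolds (with copy-number attributes); edges are unordered
#' pairs of oriented scaffold ends ("scaffold:head" / "scaffold:tail"),
#' supported by the identifiers of long reads spanning the junction. The
#' spanning observations themselves are retained so that repeat-crossing
#' traversals can later be counted for mixture estimation.
#'
#' @slot nodes \code{DataFrame}: id, copyNumber, repeatFlag, plus neighbor
#'   counts per end once \code{\link{flagRepeatNodes}} has run.
#' @slot edges \code{DataFrame}: end1, end2, count, readIds (comma-joined).
#' @slot observations \code{DataFrame} of raw junction observations.
#' @export
setClass("JunctionGraph",
  slots = c(nodes = "DataFrame", edges = "DataFrame",
            observations = "DataFrame"))

setValidity("JunctionGraph", function(object) {
  e <- object@edges
  if (nrow(e) == 0) return(TRUE)
  n <- vapply(strsplit(e$readIds, ",", fixed = TRUE),
              function(x) length(unique(x)), integer(1))
  if (!all(n == e$count))
    "edge count must equal the number of distinct supporting read ids"
  else TRUE
})

#' Per-scaffold short-read depth-of-coverage table
#'
#' @slot stats \code{DataFrame}: scaffold, median, mean depth (x).
#' @slot baseline numeric, single-copy baseline depth (median of
#'   per-scaffold medians over scaffolds not flagged repeat).
#' @slot depth list of per-position depth vectors, one per scaffold.
#' @export
setClass("DepthTable",
  slots = c(stats = "DataFrame", baseline = "numeric", depth = "list"))

#' Genome summary statistics
#'
#' @slot scaffoldStats named numeric: count, min, max, median (bp).
#' @slot moleculeLengths numeric, circular molecule lengths (bp).
#' @slot totalLength numeric, genome total (bp).
#' @slot repeatFraction numeric, percent of genome in two-copy repeats.
#' @slot mtptFraction numeric, percent of genome of plastid origin.
#' @export
setClass("SummaryReport",
  slots = c(scaffoldStats = "numeric", moleculeLengths = "numeric",
            totalLength = "numeric", repeatFraction = "numeric",
            mtptFraction = "numeric"))

setValidity("SummaryReport", function(object) {
  msg <- character()
  s <- object@scaffoldStats
  if (all(c("min", "median", "max") %in% names(s)) &&
      !(s["min"] <= s["median"] && s["median"] <= s["max"]))
    msg <- c(msg, "min <= median <= max must hold")
  if (length(object@moleculeLengths) &&
      object@totalLength != sum(object@moleculeLengths))
    msg <- c(msg, "total length must equal the sum of molecule lengths")
  if (length(msg)) msg else TRUE
})
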