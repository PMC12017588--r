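## S4 containers for the package.  All sets are parallel-slot classes in the
## Bioconductor style: vectors of equal length, subsettable with `[`, with
## accessors instead of direct slot access.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' DotBracketSet: a collection of dot-bracket structures
#'
#' Holds named pseudoknot-free secondary structures in dot-bracket notation,
#' optionally with their nucleotide sequences.  Validity requires balanced
#' parentheses, characters restricted to \code{(}, \code{)} and \code{.},
#' and, where a sequence is present, equal sequence and bracket lengths.
#'
#' @slot names character vector of structure identifiers.
#' @slot brackets character vector of dot-bracket strings.
#' @slot sequence character vector of nucleotide sequences (NA when absent).
#'
#' @seealso [DotBracketSet()] for construction, [annotateStructures()] to
#'   convert to structure arrays.
#' @aliases DotBracketSet-class
#' @exportClass DotBracketSet
setClass("DotBracketSet",
    representation(names = "character", brackets = "character",
                   sequence = "character"))

setValidity("DotBracketSet", function(object) {
    n <- length(object@brackets)
    if (length(object@names) != n || length(object@sequence) != n)
        return("'names', 'brackets' and 'sequence' must have equal length")
    for (i in seq_len(n)) {
        b <- object@brackets[i]
        if (is.na(b) || nchar(b) == 0L)
            return(sprintf("record %s: empty bracket string", object@names[i]))
        chk <- .checkBrackets(b)
        if (!is.null(chk))
            return(sprintf("record %s: %s", object@names[i], chk))
        s <- object@sequence[i]
        if (!is.na(s) && nchar(s) != nchar(b))
            return(sprintf(
                "record %s: sequence length (%d) != bracket length (%d)",
                object@names[i], nchar(s), nchar(b)))
    }
    TRUE
})

#' StructureArraySet: a collection of structure arrays
#'
#' Per-nucleotide structure-code strings over the eight-letter alphabet
#' returned by [structAlphabet()].  This is the input representation for all
#' k-mer operations.
#'
#' @slot names character vector of identifiers.
#' @slot codes character vector of structure-array strings.
#'
#' @seealso [StructureArraySet()], [annotateStructures()], [readST()].
#' @aliases StructureArraySet-class
#' @exportClass StructureArraySet
setClass("StructureArraySet",
    representation(names = "character", codes = "character"))

setValidity("StructureArraySet", function(object) {
    if (length(object@names) != length(object@codes))
        return("'names' and 'codes' must have equal length")
    for (i in seq_along(object@codes)) {
        a <- object@codes[i]
        if (is.na(a) || nchar(a) < 1L)
            return(sprintf("record %s: empty structure array",
                           object@names[i]))
        bad <- .firstBadCode(a)
        if (!is.null(bad))
            return(sprintf(
                "record %s: invalid structure code '%s' at position %d",
                object@names[i], bad$char, bad$pos))
    }
    TRUE
})

#' KmerCountVector: counts of structural k-mers over a fixed vocabulary
#'
#' An ordered vocabulary of k-mers together with aligned non-negative
#' counts.  Plain vectors extracted from one structure have integer counts
#' summing to \eqn{L - k + 1}; fuzzified vectors carry fractional
#' pseudo-counts and set \code{fuzzy = TRUE}.
#'
#' @slot k k-mer length.
#' @slot vocabulary ordered character vector of distinct k-mers.
#' @slot counts numeric vector aligned to \code{vocabulary}, all >= 0.
#' @slot fuzzy logical; TRUE after pseudo-count expansion.
#'
#' @seealso [countVector()], [fuzzify()], [cosineSimilarity()].
#' @aliases KmerCountVector-class
#' @exportClass KmerCountVector
setClass("KmerCountVector",
    representation(k = "integer", vocabulary = "character",
                   counts = "numeric", fuzzy = "logical"))

setValidity("KmerCountVector", function(object) {
    if (length(object@counts) != length(object@vocabulary))
        return("'counts' and 'vocabulary' must have equal length")
    if (anyDuplicated(object@vocabulary))
        return("vocabulary must not contain duplicates")
    if (length(object@vocabulary) &&
        any(nchar(object@vocabulary) != object@k))
        return("all vocabulary k-mers must have length k")
    if (any(is.na(object@counts)) || any(object@counts < 0))
        return("counts must be non-negative")
    TRUE
})

#' NeighborTable: edit distances between close k-mer pairs
#'
#' Symmetric table of exact unit-cost edit distances \code{d} for all
#' unordered k-mer pairs with \code{1 <= d <= maxDist}.  Each pair is stored
#' once; no self-pairs.  Drives both fuzzy pseudo-counts and the k-mer
#' network.
#'
#' @slot k k-mer length.
#' @slot maxDist distance threshold.
#' @slot pairs data.frame with columns \code{a}, \code{b} (k-mers) and
#'   \code{d} (integer distance).
#'
#' @seealso [neighborTable()], [fuzzify()], [buildKmerNetwork()].
#' @aliases NeighborTable-class
#' @exportClass NeighborTable
setClass("NeighborTable",
    representation(k = "integer", maxDist = "integer", pairs = "data.frame"))

setValidity("NeighborTable", function(object) {
    p <- object@pairs
    if (!all(c("a", "b", "d") %in% names(p)))
        return("'pairs' must have columns a, b, d")
    if (nrow(p)) {
        if (any(p$a == p$b)) return("self-pairs are not allowed")
        if (any(p$d < 1L) || any(p$d > object@maxDist))
            return("all stored distances must lie in [1, maxDist]")
        key <- paste(pmin(p$a, p$b), pmax(p$a, p$b))
        if (anyDuplicated(key))
            return("each unordered pair must be stored once")
    }
    TRUE
})

#' KmerNetwork: the edit-distance network over observed k-mer space
#'
#' Nodes are observed unique k-mers carrying their occurrence count,
#' dominant structure-code label and degree; edges join k-mer pairs at edit
#' distance \code{d <= maxDist}.
#'
#' @slot k k-mer length.
#' @slot maxDist edge distance threshold.
#' @slot nodes data.frame with columns \code{kmer}, \code{count},
#'   \code{dominant}, \code{degree}.
#' @slot edges data.frame with columns \code{a}, \code{b}, \code{d}.
#'
#' @seealso [buildKmerNetwork()], [topHubs()], [exportGraphML()].
#' @aliases KmerNetwork-class
#' @exportClass KmerNetwork
setClass("KmerNetwork",
    representation(k = "integer", maxDist = "integer",
                   nodes = "data.frame", edges = "data.frame"))

setValidity("KmerNetwork", function(object) {
    nd <- object@nodes; ed <- object@edges
    if (!all(c("kmer", "count", "dominant", "degree") %in% names(nd)))
        return("'nodes' must have columns kmer, count, dominant, degree")
    if (!all(c("a", "b", "d") %in% names(ed)))
        return("'edges' must have columns a, b, d")
    if (nrow(ed)) {
        if (!all(ed$a %in% nd$kmer) || !all(ed$b %in% nd$kmer))
            return("edge endpoints must be nodes")
        if (any(ed$a == ed$b)) return("self-loops are not allowed")
    }
    deg <- integer(nrow(nd))
    names(deg) <- nd$kmer
    if (nrow(ed)) {
        t1 <- table(ed$a); t2 <- table(ed$b)
        deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
        deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
    }
    if (!identical(unname(deg), as.integer(nd$degree)))
        return("node degrees must equal incident edge counts")
    TRUE
})

#' ClusterResult: affinity-propagation clustering of a score matrix
#'
#' @slot ids ordered item identifiers.
#' @slot labels integer cluster index per item (1..nClusters).
#' @slot exemplars identifier of the representative item of each cluster.
#' @slot converged logical; FALSE when message passing hit the iteration
#'   cap without a stable exemplar set.
#' @slot iterations number of message-passing iterations run.
#'
#' @seealso [affinityCluster()], [evaluateClustering()].
#' @aliases ClusterResult-class
#' @exportClass ClusterResult
setClass("ClusterResult",
    representation(ids = "character", labels = "integer",
                   exemplars = "character", converged = "logical",
                   iterations = "integer"))

setValidity("ClusterResult", function(object) {
    if (length(object@labels) != length(object@ids))
        return("one label per id required")
    k <- length(object@exemplars)
    if (length(object@labels) && !setequal(unique(object@labels), seq_len(k)))
        return("labels must cover 1..nClusters")
    for (j in seq_len(k)) {
        ex <- object@exemplars[j]
        if (!(ex %in% object@ids[object@labels == j]))
            return(sprintf("exemplar '%s' does not belong to cluster %d",
                           ex, j))
    }
    TRUE
})

#' SynthConfig: parameters of the synthetic structure generator
#'
#' @slot seed RNG seed.
#' @slot nFamilies number of planted families.
#' @slot membersPerFamily structures per family.
#' @slot lengthRange min/max base-structure length (nucleotides).
#' @slot minHairpin minimum unpaired positions in a hairpin loop.
#' @slot branchProb probability of branching during recursive generation.
#' @slot mutationOps validity-preserving edits applied per family member.
#'
#' @seealso [synthConfig()], [plantedDataset()].
#' @aliases SynthConfig-class
#' @exportClass SynthConfig
setClass("SynthConfig",
    representation(seed = "integer", nFamilies = "integer",
                   membersPerFamily = "integer", lengthRange = "integer",
                   minHairpin = "integer", branchProb = "numeric",
                   mutationOps = "integer"))

setValidity("SynthConfig", function(object) {
    if (length(object@lengthRange) != 2L ||
        object@lengthRange[1] > object@lengthRange[2])
        return("'lengthRange' must be c(min, max) with min <= max")
    if (object@lengthRange[1] < 2L + object@minHairpin)
        return("minimum length must admit one helix plus a hairpin")
    if (object@branchProb < 0 || object@branchProb > 1)
        return("'branchProb' must lie in [0, 1]")
    if (object@nFamilies < 1L || object@membersPerFamily < 1L ||
        object@minHairpin < 0L || object@mutationOps < 0L)
        return("counts must be non-negative (families/members >= 1)")
    TRUE
})
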