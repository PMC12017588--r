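## Constructors, accessors, show and subsetting for the S4 containers.

#' Construct a DotBracketSet
#'
#' @param brackets character vector of dot-bracket strings.
#' @param names identifiers; defaults to names of \code{brackets} or
#'   \code{structure_1..n}.
#' @param sequence optional nucleotide sequences (NA where absent).
#' @return A [DotBracketSet-class] object.
#' @examples
#' DotBracketSet(c(hp = "(((...)))"))
#' @export
DotBracketSet <- function(brackets, names = NULL, sequence = NA_character_) {
    nms <- base::names(brackets)
    brackets <- as.character(brackets)
    if (is.null(names)) {
        names <- if (!is.null(nms)) nms
                 else paste0("structure_", seq_along(brackets))
    }
    sequence <- rep_len(as.character(sequence), length(brackets))
    new("DotBracketSet", names = as.character(names),
        brackets = unname(brackets), sequence = sequence)
}

#' Construct a StructureArraySet
#'
#' @param codes character vector of structure-array strings over the
#'   alphabet returned by [structAlphabet()].
#' @param names identifiers; defaults to names of \code{codes} or
#'   \code{structure_1..n}.
#' @return A [StructureArraySet-class] object.
#' @examples
#' StructureArraySet(c(toy = "LLLHHHRRR"))
#' @export
StructureArraySet <- function(codes, names = NULL) {
    nms <- base::names(codes)
    codes <- as.character(codes)
    if (is.null(names)) {
        names <- if (!is.null(nms)) nms
                 else paste0("structure_", seq_along(codes))
    }
    new("StructureArraySet", names = as.character(names),
        codes = unname(codes))
}

#' @describeIn DotBracketSet-class number of structures.
#' @param x a set object.
#' @export
setMethod("length", "DotBracketSet", function(x) length(x@brackets))

#' @describeIn StructureArraySet-class number of structures.
#' @param x a set object.
#' @export
setMethod("length", "StructureArraySet", function(x) length(x@codes))

#' @describeIn DotBracketSet-class structure identifiers.
#' @export
setMethod("names", "DotBracketSet", function(x) x@names)

#' @describeIn StructureArraySet-class structure identifiers.
#' @export
setMethod("names", "StructureArraySet", function(x) x@names)

#' Dot-bracket strings of a set
#'
#' @param x a [DotBracketSet-class].
#' @return Named character vector of bracket strings.
#' @export
dotBrackets <- function(x) {
    stopifnot(is(x, "DotBracketSet"))
    stats::setNames(x@brackets, x@names)
}

#' Structure-array strings of a set
#'
#' @param x a [StructureArraySet-class].
#' @return Named character vector of structure-code strings.
#' @export
structureCodes <- function(x) {
    stopifnot(is(x, "StructureArraySet"))
    stats::setNames(x@codes, x@names)
}

#' Structure lengths
#'
#' Number of nucleotide positions of each structure in a set; for a
#' structure array this is the quantity entering the length penalty.
#'
#' @param x a [DotBracketSet-class] or [StructureArraySet-class].
#' @return Named integer vector.
#' @export
structureLengths <- function(x) {
    if (is(x, "DotBracketSet")) stats::setNames(nchar(x@brackets), x@names)
    else if (is(x, "StructureArraySet"))
        stats::setNames(nchar(x@codes), x@names)
    else stop("'x' must be a DotBracketSet or StructureArraySet")
}

#' @describeIn DotBracketSet-class subset by index or name.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "DotBracketSet", function(x, i, j, ..., drop = TRUE) {
    idx <- .resolveIndex(i, x@names)
    new("DotBracketSet", names = x@names[idx], brackets = x@brackets[idx],
        sequence = x@sequence[idx])
})

#' @describeIn StructureArraySet-class subset by index or name.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "StructureArraySet", function(x, i, j, ..., drop = TRUE) {
    idx <- .resolveIndex(i, x@names)
    new("StructureArraySet", names = x@names[idx], codes = x@codes[idx])
})

.resolveIndex <- function(i, nms) {
    if (is.character(i)) {
        idx <- match(i, nms)
        if (anyNA(idx))
            stop("unknown identifier(s): ",
                 paste(i[is.na(idx)], collapse = ", "))
        idx
    } else {
        seq_along(nms)[i]
    }
}

setMethod("show", "DotBracketSet", function(object) {
    n <- length(object)
    cat("DotBracketSet with", n, if (n == 1) "structure\n" else "structures\n")
    .previewStrings(object@names, object@brackets)
})

setMethod("show", "StructureArraySet", function(object) {
    n <- length(object)
    cat("StructureArraySet with", n,
        if (n == 1) "structure\n" else "structures\n")
    .previewStrings(object@names, object@codes)
})

.previewStrings <- function(nms, strs, max_show = 6L) {
    n <- length(nms)
    show <- seq_len(min(n, max_show))
    for (i in show) {
        s <- strs[i]
        disp <- if (nchar(s) > 50) paste0(substr(s, 1, 47), "...") else s
        cat(sprintf("  %s [%d nt] %s\n", nms[i], nchar(s), disp))
    }
    if (n > max_show) cat("  ...", n - max_show, "more\n")
}

#' Construct a KmerCountVector
#'
#' @param vocabulary ordered character vector of distinct k-mers.
#' @param counts numeric counts aligned to \code{vocabulary}.
#' @param fuzzy logical; TRUE for pseudo-count-expanded vectors.
#' @return A [KmerCountVector-class].
#' @export
KmerCountVector <- function(vocabulary, counts, fuzzy = FALSE) {
    k <- if (length(vocabulary)) nchar(vocabulary[1]) else 0L
    new("KmerCountVector", k = as.integer(k),
        vocabulary = as.character(vocabulary),
        counts = as.numeric(counts), fuzzy = isTRUE(fuzzy))
}

#' Vocabulary of a k-mer count vector
#' @param x a [KmerCountVector-class].
#' @return Character vector of k-mers.
#' @export
vocabulary <- function(x) {
    stopifnot(is(x, "KmerCountVector"))
    x@vocabulary
}

#' Counts of a k-mer count vector
#' @param x a [KmerCountVector-class].
#' @return Named numeric vector aligned to the vocabulary.
#' @export
kmerCounts <- function(x) {
    stopifnot(is(x, "KmerCountVector"))
    stats::setNames(x@counts, x@vocabulary)
}

setMethod("show", "KmerCountVector", function(object) {
    cat(sprintf("KmerCountVector: %d %d-mers%s, total mass %.4g\n",
                length(object@vocabulary), object@k,
                if (object@fuzzy) " (fuzzy)" else "", sum(object@counts)))
    nz <- sum(object@counts > 0)
    cat(sprintf("  non-zero entries: %d of %d\n", nz,
                length(object@counts)))
})

#' Neighbor pairs of a NeighborTable
#' @param x a [NeighborTable-class].
#' @return data.frame with columns \code{a}, \code{b}, \code{d}.
#' @export
neighborPairs <- function(x) {
    stopifnot(is(x, "NeighborTable"))
    x@pairs
}

setMethod("show", "NeighborTable", function(object) {
    cat(sprintf("NeighborTable: k = %d, maxDist = %d, %d pair(s)\n",
                object@k, object@maxDist, nrow(object@pairs)))
})

#' Nodes of a k-mer network
#' @param x a [KmerNetwork-class].
#' @return data.frame with columns \code{kmer}, \code{count},
#'   \code{dominant}, \code{degree}.
#' @export
networkNodes <- function(x) {
    stopifnot(is(x, "KmerNetwork"))
    x@nodes
}

#' Edges of a k-mer network
#' @param x a [KmerNetwork-class].
#' @return data.frame with columns \code{a}, \code{b}, \code{d}.
#' @export
networkEdges <- function(x) {
    stopifnot(is(x, "KmerNetwork"))
    x@edges
}

setMethod("show", "KmerNetwork", function(object) {
    cat(sprintf("KmerNetwork: %d node(s), %d edge(s) at d <= %d (k = %d)\n",
                nrow(object@nodes), nrow(object@edges), object@maxDist,
                object@k))
})

#' Cluster labels
#' @param x a [ClusterResult-class].
#' @return Named integer vector of cluster indices.
#' @export
clusterLabels <- function(x) {
    stopifnot(is(x, "ClusterResult"))
    stats::setNames(x@labels, x@ids)
}

#' Cluster exemplars
#' @param x a [ClusterResult-class].
#' @return Character vector: exemplar id of each cluster.
#' @export
clusterExemplars <- function(x) {
    stopifnot(is(x, "ClusterResult"))
    x@exemplars
}

#' Number of clusters
#' @param x a [ClusterResult-class].
#' @return Integer.
#' @export
nClusters <- function(x) {
    stopifnot(is(x, "ClusterResult"))
    length(x@exemplars)
}

#' Did affinity propagation converge?
#' @param x a [ClusterResult-class].
#' @return Logical.
#' @export
hasConverged <- function(x) {
    stopifnot(is(x, "ClusterResult"))
    x@converged
}

setMethod("show", "ClusterResult", function(object) {
    cat(sprintf("ClusterResult: %d item(s) in %d cluster(s)%s\n",
                length(object@ids), length(object@exemplars),
                if (object@converged) "" else " [NOT converged]"))
    cat("  exemplars:", paste(head(object@exemplars, 8), collapse = ", "),
        if (length(object@exemplars) > 8) "..." else "", "\n")
})

setMethod("show", "SynthConfig", function(object) {
    cat(sprintf(paste0(
        "SynthConfig: %d families x %d members, lengths %d-%d,\n",
        "  minHairpin %d, branchProb %.2f, %d mutation op(s), seed %d\n"),
        object@nFamilies, object@membersPerFamily, object@lengthRange[1],
        object@lengthRange[2], object@minHairpin, object@branchProb,
        object@mutationOps, object@seed))
})
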