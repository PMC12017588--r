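## Census of observed unique k-mers across a dataset and the edit-distance
## network over them, with hub ranking and dominant-character node labels.

#' Census of unique structural k-mers across a dataset
#'
#' Tallies every k-mer occurrence over all structures of a set.  Structures
#' shorter than \code{k} are skipped with a warning.  The number of
#' distinct k-mers observed is bounded above both by the total window count
#' and by [possibleKmers()].
#'
#' @param x a [StructureArraySet-class].
#' @param k k-mer length.
#' @return data.frame with columns \code{kmer} and \code{count}, sorted by
#'   decreasing count, ties lexicographic.
#' @examples
#' kmerCensus(StructureArraySet(c(a = "LLLHHHRRR")), k = 3)
#' @export
kmerCensus <- function(x, k) {
    stopifnot(is(x, "StructureArraySet"))
    k <- .checkCount(k, "k")
    keep <- nchar(x@codes) >= k
    if (!all(keep))
        warning("skipping ", sum(!keep), " structure(s) shorter than k = ",
                k, ": ", paste(x@names[!keep], collapse = ", "))
    if (!any(keep)) stop("no structure of length >= k")
    all_kmers <- unlist(lapply(x@codes[keep], extractKmers, k = k),
                        use.names = FALSE)
    tab <- table(all_kmers)
    out <- data.frame(kmer = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$kmer), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Dominant structure code of a k-mer
#'
#' The structure character with the highest multiplicity in the k-mer
#' (e.g. \code{LLLLLLHHH} is L-dominant); ties are broken by the fixed
#' priority order L, R, H, M, X, I, B, E.
#'
#' @param kmer character vector of k-mers.
#' @return Character vector of single structure codes.
#' @examples
#' dominantLabel(c("LLLLLLHHH", "LLLHHHRRR"))
#' @export
dominantLabel <- function(kmer) {
    stopifnot(is.character(kmer), all(nchar(kmer) >= 1L))
    priority <- c("L", "R", "H", "M", "X", "I", "B", "E")
    vapply(strsplit(kmer, "", fixed = TRUE), function(ch) {
        counts <- vapply(priority, function(p) sum(ch == p), integer(1))
        priority[which.max(counts)]  # which.max keeps the first = priority
    }, character(1))
}

#' Build the edit-distance network over a k-mer set
#'
#' Nodes are unique k-mers (with occurrence counts when a census is
#' supplied); edges join all unordered pairs at edit distance
#' \code{1 <= d <= maxDist}.
#'
#' @param x a census data.frame from [kmerCensus()], or a character vector
#'   of unique k-mers (all counts then 1).
#' @param maxDist edge threshold (>= 1).
#' @param method pair-finding strategy passed to [neighborTable()].
#' @return A [KmerNetwork-class].
#' @examples
#' buildKmerNetwork(c("LLL", "LLH", "HHH"), maxDist = 2)
#' @export
buildKmerNetwork <- function(x, maxDist = 2, method = c("dp", "enumerate")) {
    method <- match.arg(method)
    if (is.character(x))
        x <- data.frame(kmer = unique(x),
                        count = 1L, stringsAsFactors = FALSE)
    stopifnot(is.data.frame(x), all(c("kmer", "count") %in% names(x)))
    maxDist <- .checkCount(maxDist, "maxDist")
    k <- nchar(x$kmer[1])
    nt <- neighborTable(x$kmer, maxDist = maxDist, method = method)
    edges <- nt@pairs
    deg <- integer(nrow(x))
    names(deg) <- x$kmer
    if (nrow(edges)) {
        t1 <- table(edges$a); t2 <- table(edges$b)
        deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
        deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
    }
    nodes <- data.frame(kmer = x$kmer, count = as.integer(x$count),
                        dominant = dominantLabel(x$kmer),
                        degree = unname(deg), stringsAsFactors = FALSE)
    new("KmerNetwork", k = as.integer(k), maxDist = maxDist,
        nodes = nodes, edges = edges)
}

#' Top hub k-mers of a network
#'
#' K-mers ranked by decreasing degree (number of incident edges), ties in
#' lexicographic k-mer order.
#'
#' @param network a [KmerNetwork-class].
#' @param n number of hubs to return; \code{n <= 0} gives an empty vector.
#' @return data.frame with columns \code{kmer}, \code{degree},
#'   \code{dominant}, at most \code{n} rows.
#' @export
topHubs <- function(network, n = 20) {
    stopifnot(is(network, "KmerNetwork"))
    if (n <= 0)
        return(data.frame(kmer = character(0), degree = integer(0),
                          dominant = character(0), stringsAsFactors = FALSE))
    nd <- network@nodes
    nd <- nd[order(-nd$degree, nd$kmer), , drop = FALSE]
    out <- head(nd[, c("kmer", "degree", "dominant")], n)
    rownames(out) <- NULL
    out
}

#' Export network edges as TSV
#'
#' Columns \code{kmer_a}, \code{kmer_b}, \code{d}.
#'
#' @param network a [KmerNetwork-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportEdges <- function(network, path) {
    stopifnot(is(network, "KmerNetwork"))
    ed <- network@edges
    names(ed) <- c("kmer_a", "kmer_b", "d")
    write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a k-mer network as GraphML
#'
#' Writes nodes with \code{count}, \code{dominant} and \code{degree}
#' attributes and edges with the distance \code{d}, so any Gephi-class tool
#' can lay the k-mer space out; the package itself does no plotting.
#'
#' @param network a [KmerNetwork-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportGraphML <- function(network, path) {
    g <- asIgraph(network)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

#' Convert a k-mer network to an igraph object
#'
#' @param network a [KmerNetwork-class].
#' @return An \code{igraph} graph with vertex attributes \code{count},
#'   \code{dominant}, \code{degree} and edge attribute \code{d}.
#' @export
asIgraph <- function(network) {
    stopifnot(is(network, "KmerNetwork"))
    igraph::graph_from_data_frame(
        d = network@edges,
        directed = FALSE,
        vertices = network@nodes)
}

#' Read a GraphML k-mer network back
#'
#' Inverse of [exportGraphML()]; node and edge counts and attributes are
#' preserved.
#'
#' @param path GraphML file written by [exportGraphML()].
#' @param maxDist the threshold the network was built with (recorded only
#'   in the object, not the file); defaults to the maximum edge distance.
#' @return A [KmerNetwork-class].
#' @export
readKmerNetwork <- function(path, maxDist = NULL) {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(
        kmer = igraph::vertex_attr(g, "name"),
        count = as.integer(igraph::vertex_attr(g, "count")),
        dominant = igraph::vertex_attr(g, "dominant"),
        degree = as.integer(igraph::vertex_attr(g, "degree")),
        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(a = el[, 1], b = el[, 2],
                        d = as.integer(igraph::edge_attr(g, "d")),
                        stringsAsFactors = FALSE)
    if (is.null(maxDist))
        maxDist <- if (nrow(edges)) max(edges$d) else 1L
    k <- if (nrow(nodes)) nchar(nodes$kmer[1]) else 0L
    new("KmerNetwork", k = as.integer(k), maxDist = as.integer(maxDist),
        nodes = nodes, edges = .orderPairs(edges))
}
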