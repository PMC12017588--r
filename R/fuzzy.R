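## Edit distances between k-mers, neighbor tables, and fuzzy pseudo-count
## expansion of count vectors.
##
## A single structural change (one inserted nucleotide, one grown bulge)
## rewrites every window overlapping it, so two near-identical structures
## can share few exact k-mers.  Fuzzy mode compensates by letting each
## observed k-mer donate exp(-d) pseudo-counts to vocabulary k-mers an edit
## distance d away (d <= maxDist, default 2), which fills zero entries and
## pulls the two count vectors back toward a common direction.

#' Unit-cost edit distance between two k-mers
#'
#' Levenshtein distance (insertion = deletion = mismatch = 1) computed by a
#' banded dynamic program with early exit.  In this package both strings
#' have equal length, where the optimal unit-cost alignment coincides with
#' the minimal count of insertions, deletions and mismatches of any optimal
#' global alignment.
#'
#' @param a,b character vectors of k-mers (recycled to a common length).
#' @return Integer vector of exact distances.
#' @examples
#' kmerEditDistance("LLHHHRRRR", "LLLHHHRRR")  # 2
#' @export
kmerEditDistance <- function(a, b) {
    stopifnot(is.character(a), is.character(b))
    n <- max(length(a), length(b))
    a <- rep_len(a, n); b <- rep_len(b, n)
    .lev_dist_cpp(a, b)
}

#' Neighbor table of a k-mer vocabulary
#'
#' All unordered k-mer pairs with edit distance \code{1 <= d <= maxDist}.
#' Two interchangeable strategies are provided: \code{"dp"} runs the banded
#' dynamic program over all pairs (abandoning a pair as soon as its
#' distance provably exceeds the threshold); \code{"enumerate"} finds
#' candidate pairs by neighborhood enumeration and hashing (Hamming
#' neighborhoods plus shared single-deletion variants, complete for
#' equal-length k-mers at \code{maxDist <= 2}) and then assigns exact
#' distances.  Both must produce the identical table.
#'
#' @param vocab character vector of distinct k-mers of one length.
#' @param maxDist distance threshold; 1 or 2 are the supported operating
#'   points, 3 is allowed with a warning (it over-connects the k-mer space
#'   and blurs the distinction between structural element types).
#' @param method pair-finding strategy, see above.
#' @return A [NeighborTable-class].
#' @examples
#' neighborPairs(neighborTable(c("LLL", "LLH", "HHH"), maxDist = 2))
#' @export
neighborTable <- function(vocab, maxDist = 2,
                          method = c("dp", "enumerate")) {
    method <- match.arg(method)
    maxDist <- .checkCount(maxDist, "maxDist")
    stopifnot(is.character(vocab), !anyDuplicated(vocab))
    if (maxDist >= 3L)
        warning("maxDist >= 3 over-connects the k-mer space; ",
                "d <= 2 is the recommended level of fuzziness")
    k <- if (length(vocab)) nchar(vocab[1]) else 0L
    if (length(vocab) && any(nchar(vocab) != k))
        stop("all vocabulary k-mers must have the same length")
    pairs <- if (method == "dp" || maxDist > 2L) {
        .neighborPairsDP(vocab, maxDist)
    } else {
        .neighborPairsEnum(vocab, maxDist)
    }
    new("NeighborTable", k = as.integer(k), maxDist = maxDist,
        pairs = pairs)
}

.neighborPairsDP <- function(vocab, maxDist) {
    if (length(vocab) < 2L)
        return(data.frame(a = character(0), b = character(0),
                          d = integer(0), stringsAsFactors = FALSE))
    res <- .neighbor_pairs_cpp(vocab, as.integer(maxDist))
    .orderPairs(data.frame(a = vocab[res$i], b = vocab[res$j], d = res$d,
                           stringsAsFactors = FALSE))
}

## Candidate generation for equal-length k-mers, maxDist <= 2:
## d = 1  <=>  Hamming distance 1;
## d = 2  <=>  Hamming distance 2, or one deletion plus one insertion
##             (equivalently: the two k-mers share a (k-1)-mer deletion
##             variant and are not already at d <= 1).
.neighborPairsEnum <- function(vocab, maxDist) {
    n <- length(vocab)
    empty <- data.frame(a = character(0), b = character(0), d = integer(0),
                        stringsAsFactors = FALSE)
    if (n < 2L) return(empty)
    k <- nchar(vocab[1])
    chm <- do.call(rbind, strsplit(vocab, "", fixed = TRUE))
    ## pairwise Hamming distances, counting mismatches column by column
    ham <- matrix(0L, n, n)
    for (j in seq_len(k))
        ham <- ham + outer(chm[, j], chm[, j], "!=")
    cand <- which(upper.tri(ham) & ham >= 1L & ham <= maxDist, arr.ind = TRUE)
    pairs <- data.frame(a = vocab[cand[, 1]], b = vocab[cand[, 2]],
                        d = ham[cand], stringsAsFactors = FALSE)
    if (maxDist == 2L && k >= 2L) {
        ## hash-join on single-deletion variants to catch shift pairs
        del <- vector("list", k)
        for (p in seq_len(k))
            del[[p]] <- paste0(substr(vocab, 1, p - 1L),
                               substr(vocab, p + 1L, k))
        idx <- rep(seq_len(n), times = k)
        variants <- unlist(del)
        groups <- split(idx, variants)
        extra <- unique(do.call(rbind, lapply(groups, function(g) {
            g <- unique(g)
            if (length(g) < 2L) return(NULL)
            t(combn(sort(g), 2L))
        })))
        if (!is.null(extra) && nrow(extra)) {
            h <- ham[extra]
            ## drop pairs already found at Hamming <= 2 and confirm exact d
            extra <- extra[h > 2L, , drop = FALSE]
            if (nrow(extra)) {
                d <- kmerEditDistance(vocab[extra[, 1]], vocab[extra[, 2]])
                keep <- d <= 2L
                pairs <- rbind(pairs, data.frame(
                    a = vocab[extra[keep, 1]], b = vocab[extra[keep, 2]],
                    d = d[keep], stringsAsFactors = FALSE))
            }
        }
    }
    .orderPairs(pairs)
}

## canonical storage: a < b lexicographically, rows sorted
.orderPairs <- function(pairs) {
    if (!nrow(pairs)) return(pairs)
    swap <- pairs$a > pairs$b
    tmp <- pairs$a[swap]; pairs$a[swap] <- pairs$b[swap]
    pairs$b[swap] <- tmp
    pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
    rownames(pairs) <- NULL
    pairs$d <- as.integer(pairs$d)
    pairs
}

#' Fuzzy pseudo-count expansion of a count vector
#'
#' Adds \eqn{e^{-d}} pseudo-counts for k-mers an edit distance \eqn{d}
#' away (\eqn{d \le} the table's threshold), within the vector's own
#' vocabulary.  Two accumulation schemes:
#' \describe{
#'   \item{\code{"linear"} (default)}{per-occurrence smoothing:
#'     \eqn{f_u = \sum_w c_w e^{-d(u, w)}} over vocabulary k-mers \eqn{w}
#'     with \eqn{d(u, w) \le} maxDist, with \eqn{d(u, u) = 0} so original
#'     counts enter with weight 1.}
#'   \item{\code{"flat"}}{each k-mer present in the structure donates a
#'     single \eqn{e^{-d}} to each close vocabulary k-mer, independent of
#'     its count.}
#' }
#' Entries never decrease, and the vocabulary and its order are preserved.
#'
#' @param v a [KmerCountVector-class].
#' @param table a [NeighborTable-class] built on (a superset of) the
#'   vector's vocabulary.
#' @param scheme accumulation scheme, see above.
#' @return A fuzzy [KmerCountVector-class].
#' @examples
#' v <- KmerCountVector(c("LLL", "LLH"), c(2, 0))
#' nt <- neighborTable(c("LLL", "LLH"), maxDist = 2)
#' kmerCounts(fuzzify(v, nt))  # c(LLL = 2, LLH = 2 * exp(-1))
#' @export
fuzzify <- function(v, table, scheme = c("linear", "flat")) {
    scheme <- match.arg(scheme)
    stopifnot(is(v, "KmerCountVector"), is(table, "NeighborTable"))
    p <- table@pairs
    f <- v@counts
    if (nrow(p)) {
        ia <- match(p$a, v@vocabulary)
        ib <- match(p$b, v@vocabulary)
        keep <- !is.na(ia) & !is.na(ib)
        ia <- ia[keep]; ib <- ib[keep]
        w <- exp(-p$d[keep])
        src <- if (scheme == "linear") v@counts else as.numeric(v@counts > 0)
        ## symmetric donation along every stored pair
        f <- f + .sumInto(ia, src[ib] * w, length(f)) +
                 .sumInto(ib, src[ia] * w, length(f))
    }
    new("KmerCountVector", k = v@k, vocabulary = v@vocabulary, counts = f,
        fuzzy = TRUE)
}

.sumInto <- function(idx, val, n) {
    out <- numeric(n)
    if (length(idx)) {
        agg <- rowsum(val, group = idx)
        out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
}
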