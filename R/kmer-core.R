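## Structural k-mer extraction and the cosine / length-weighted scores.
##
## Two structures are compared by sliding a k-wide window over each
## structure array, tallying the k-mers over the union vocabulary of the
## pair, and taking
##     cos(theta) = (V1 . V2) / (|V1| |V2|),
## optionally down-weighted by the relative length penalty
##     D(L1, L2) = 2 |L1 - L2| / (L1 + L2),
##     S = cos(theta) * (1 - D).
## S is deliberately not clamped at zero: a length ratio beyond 3:1 gives
## D > 1 and a negative S, which downstream affinity propagation accepts.

#' Extract structural k-mers from one structure array
#'
#' All length-\code{k} windows in order; the list has \eqn{L - k + 1}
#' elements.
#'
#' @param x structure-array string (or [StructureArraySet-class] of
#'   length 1).
#' @param k window length, \code{1 <= k <= nchar(x)}.
#' @return Character vector of k-mers in positional order.
#' @examples
#' extractKmers("LLLHHHRRR", 3)
#' @export
extractKmers <- function(x, k) {
    x <- .asCodesString(x)
    k <- .checkCount(k, "k")
    L <- nchar(x)
    if (k > L)
        stop(sprintf(
            "k = %d exceeds structure length %d; lower k or skip the record",
            k, L), call. = FALSE)
    n <- L - k + 1L
    substring(x, seq_len(n), seq_len(n) + k - 1L)
}

.asCodesString <- function(x) {
    if (is(x, "StructureArraySet")) {
        if (length(x) != 1L) stop("expected a single structure")
        x@codes
    } else {
        stopifnot(is.character(x), length(x) == 1L, !is.na(x))
        bad <- .firstBadCode(x)
        if (!is.null(bad))
            stop(sprintf("invalid structure code '%s' at position %d",
                         bad$char, bad$pos), call. = FALSE)
        x
    }
}

#' Union vocabulary of two k-mer lists
#'
#' Distinct k-mers of both lists in first-appearance order (list a, then
#' list b).  The per-pair union is the vocabulary over which both count
#' vectors are laid out; k-mers outside it would contribute zeros to both
#' vectors and so cannot affect the cosine.
#'
#' @param kmersA,kmersB character vectors of k-mers of a common length.
#' @return Character vector of distinct k-mers.
#' @examples
#' pairVocabulary(c("LLL", "LLH"), c("LLH", "HHH"))
#' @export
pairVocabulary <- function(kmersA, kmersB) {
    stopifnot(length(kmersA) >= 1L, length(kmersB) >= 1L)
    if (nchar(kmersA[1]) != nchar(kmersB[1]))
        stop("both k-mer lists must share the same k")
    unique(c(kmersA, kmersB))
}

#' Count vector of a k-mer list over a fixed vocabulary
#'
#' @param kmers character vector of k-mers (a structure's sliding-window
#'   list).
#' @param vocab ordered vocabulary; k-mers of \code{kmers} absent from it
#'   are not permitted, k-mers of the vocabulary absent from \code{kmers}
#'   get count 0.
#' @return A [KmerCountVector-class] with integer counts summing to
#'   \code{length(kmers)}.
#' @examples
#' v <- pairVocabulary(extractKmers("LLLHHHRRR", 3),
#'                     extractKmers("LLLLHHHHRRRR", 3))
#' countVector(extractKmers("LLLLHHHHRRRR", 3), v)
#' @export
countVector <- function(kmers, vocab) {
    idx <- match(kmers, vocab)
    if (anyNA(idx))
        stop("k-mer(s) absent from the vocabulary: ",
             paste(unique(kmers[is.na(idx)]), collapse = ", "))
    KmerCountVector(vocab, tabulate(idx, nbins = length(vocab)))
}

#' Cosine similarity of two k-mer count vectors
#'
#' Dot product over the product of Euclidean norms.  Counts are
#' non-negative, so the result lies in \eqn{[0, 1]}.
#'
#' @param v1,v2 [KmerCountVector-class] objects over identical
#'   vocabularies.
#' @return Numeric scalar in \eqn{[0, 1]}.
#' @export
cosineSimilarity <- function(v1, v2) {
    stopifnot(is(v1, "KmerCountVector"), is(v2, "KmerCountVector"))
    if (!identical(sort(v1@vocabulary), sort(v2@vocabulary)))
        stop("count vectors must share an identical vocabulary")
    ## accumulate in canonical vocabulary order so the score is exactly
    ## symmetric in its arguments, and take a single square root of the
    ## norm product so self-similarity is exactly 1
    c1 <- v1@counts[order(v1@vocabulary)]
    c2 <- v2@counts[order(v2@vocabulary)]
    sq1 <- sum(c1^2)
    sq2 <- sum(c2^2)
    if (sq1 == 0 || sq2 == 0)
        stop("undefined score: zero-norm count vector ",
             "(empty or too-short structure)")
    sum(c1 * c2) / sqrt(sq1 * sq2)
}

#' Relative length penalty
#'
#' Absolute length difference divided by the average length,
#' \eqn{D(L_1, L_2) = 2 |L_1 - L_2| / (L_1 + L_2)}.  Symmetric, zero iff
#' the lengths agree, and always below 2.
#'
#' @param L1,L2 positive structure lengths.
#' @return Numeric scalar in \eqn{[0, 2)}.
#' @examples
#' lengthPenalty(9, 12)   # 6/21
#' @export
lengthPenalty <- function(L1, L2) {
    L1 <- .checkCount(L1, "L1"); L2 <- .checkCount(L2, "L2")
    2 * abs(L1 - L2) / (L1 + L2)
}

#' Length-weighted similarity score
#'
#' \eqn{S = \cos(\theta) (1 - D(L_1, L_2))}.  Not clamped below at zero:
#' length ratios beyond 3:1 give \eqn{D > 1} and a negative S, preserving
#' the monotone ordering passed on to clustering.
#'
#' @param cosine cosine similarity in \eqn{[0, 1]}.
#' @param L1,L2 structure lengths.
#' @return Numeric scalar, equal to \code{cosine} when the lengths agree.
#' @examples
#' weightedScore(0.5, 90, 110)  # 0.4
#' @export
weightedScore <- function(cosine, L1, L2) {
    stopifnot(is.numeric(cosine), length(cosine) == 1L,
              cosine >= 0, cosine <= 1)
    cosine * (1 - lengthPenalty(L1, L2))
}

#' Score one pair of structures
#'
#' Full scoring pipeline: extract k-mers, form the pair-union vocabulary,
#' tally count vectors, optionally expand both with fuzzy pseudo-counts,
#' take the cosine, and (unless disabled) apply the length weighting.
#'
#' @param a,b structure-array strings or [StructureArraySet-class]
#'   objects of length 1.
#' @param k k-mer length (default 10, the plain-mode operating point; use 9
#'   with \code{fuzzy = TRUE}).
#' @param fuzzy logical; add edit-distance-decayed pseudo-counts.
#' @param maxDist pseudo-count edit-distance threshold (default 2).
#' @param lengthWeight logical; apply the length penalty (default TRUE).
#' @param fuzzyScheme pseudo-count accumulation scheme, see [fuzzify()].
#' @param ids optional character(2) of identifiers for the output record.
#' @return One-row data.frame with columns \code{id_a}, \code{id_b},
#'   \code{cosine}, \code{penalty}, \code{score}, \code{k}, \code{fuzzy},
#'   \code{max_dist}; \code{score = cosine * (1 - penalty)}.
#' @examples
#' scorePair("LLLHHHRRR", "LLLLHHHHRRRR", k = 3)
#' @export
scorePair <- function(a, b, k = 10, fuzzy = FALSE, maxDist = 2,
                      lengthWeight = TRUE,
                      fuzzyScheme = c("linear", "flat"), ids = NULL) {
    fuzzyScheme <- match.arg(fuzzyScheme)
    if (is.null(ids)) {
        ids <- c(if (is(a, "StructureArraySet")) names(a) else "a",
                 if (is(b, "StructureArraySet")) names(b) else "b")
    }
    sa <- .asCodesString(a)
    sb <- .asCodesString(b)
    k <- .checkCount(k, "k")
    La <- nchar(sa); Lb <- nchar(sb)
    if (k > min(La, Lb))
        stop(sprintf("k = %d exceeds the shorter structure (length %d)",
                     k, min(La, Lb)), call. = FALSE)
    ka <- extractKmers(sa, k)
    kb <- extractKmers(sb, k)
    vocab <- pairVocabulary(ka, kb)
    va <- countVector(ka, vocab)
    vb <- countVector(kb, vocab)
    if (fuzzy) {
        nt <- .cachedNeighborTable(vocab, maxDist)
        va <- fuzzify(va, nt, scheme = fuzzyScheme)
        vb <- fuzzify(vb, nt, scheme = fuzzyScheme)
    }
    cosine <- cosineSimilarity(va, vb)
    penalty <- if (lengthWeight) lengthPenalty(La, Lb) else 0
    data.frame(id_a = ids[1], id_b = ids[2], cosine = cosine,
               penalty = penalty, score = cosine * (1 - penalty),
               k = k, fuzzy = fuzzy,
               max_dist = if (fuzzy) as.integer(maxDist) else NA_integer_,
               stringsAsFactors = FALSE)
}

#' All-vs-all pair scores in long form
#'
#' Scores every unordered pair of a [StructureArraySet-class].
#' Structures shorter than \code{k} are skipped with a warning rather than
#' failing the whole run.
#'
#' @inheritParams scorePair
#' @param x a [StructureArraySet-class].
#' @return data.frame with one row per unordered pair, columns as in
#'   [scorePair()].
#' @export
scorePairs <- function(x, k = 10, fuzzy = FALSE, maxDist = 2,
                       lengthWeight = TRUE,
                       fuzzyScheme = c("linear", "flat")) {
    stopifnot(is(x, "StructureArraySet"))
    fuzzyScheme <- match.arg(fuzzyScheme)
    k <- .checkCount(k, "k")
    keep <- nchar(x@codes) >= k
    if (!all(keep)) {
        warning("skipping ", sum(!keep), " structure(s) shorter than k = ",
                k, ": ", paste(x@names[!keep], collapse = ", "))
        x <- x[which(keep)]
    }
    n <- length(x)
    if (n < 2L) stop("need at least two structures of length >= k")
    rows <- vector("list", n * (n - 1L) / 2L)
    r <- 0L
    for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
            r <- r + 1L
            rows[[r]] <- scorePair(x@codes[i], x@codes[j], k = k,
                                   fuzzy = fuzzy, maxDist = maxDist,
                                   lengthWeight = lengthWeight,
                                   fuzzyScheme = fuzzyScheme,
                                   ids = c(x@names[i], x@names[j]))
        }
    }
    do.call(rbind, rows)
}

#' All-vs-all similarity matrix
#'
#' Symmetric score matrix over a [StructureArraySet-class] with unit
#' diagonal (self-similarity), suitable as direct input to
#' [affinityCluster()].
#'
#' @inheritParams scorePairs
#' @return Numeric matrix with dimnames set to the structure names.
#' @export
scoreMatrix <- function(x, k = 10, fuzzy = FALSE, maxDist = 2,
                        lengthWeight = TRUE,
                        fuzzyScheme = c("linear", "flat")) {
    pairs <- scorePairs(x, k = k, fuzzy = fuzzy, maxDist = maxDist,
                        lengthWeight = lengthWeight,
                        fuzzyScheme = fuzzyScheme)
    ids <- unique(c(pairs$id_a, pairs$id_b))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 1
    ia <- match(pairs$id_a, ids)
    ib <- match(pairs$id_b, ids)
    m[cbind(ia, ib)] <- pairs$score
    m[cbind(ib, ia)] <- pairs$score
    m
}

## per-session memo of neighbor tables keyed on (vocabulary, maxDist)
.ntCache <- new.env(parent = emptyenv())

.cachedNeighborTable <- function(vocab, maxDist) {
    key <- paste(maxDist, paste(sort(vocab), collapse = "\1"), sep = "\2")
    hit <- .ntCache[[key]]
    if (!is.null(hit)) return(hit)
    nt <- neighborTable(vocab, maxDist)
    if (length(ls(.ntCache)) > 256L) rm(list = ls(.ntCache), envir = .ntCache)
    assign(key, nt, envir = .ntCache)
    nt
}
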