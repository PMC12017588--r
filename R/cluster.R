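## Affinity propagation clustering of similarity matrices and evaluation of
## the resulting partitions against known subclass labels.
##
## Affinity propagation suits score matrices from this package because it
## consumes similarities directly (including negative length-weighted
## scores), requires no preset cluster count and no edge threshold; the
## number of clusters emerges from the preference placed on the diagonal.

#' Affinity propagation clustering
#'
#' Standard responsibility/availability message passing (Frey & Dueck) on a
#' symmetric similarity matrix.  The diagonal is replaced by the
#' \code{preference}; a seeded jitter of magnitude ~1e-10 breaks ties, and
#' is drawn in id-sorted order so that permuting the input rows/columns
#' permutes the labels identically for the same seed.
#'
#' @param S square symmetric numeric matrix with dimnames (ids); e.g. the
#'   output of [scoreMatrix()].
#' @param preference \code{"median"} (median of off-diagonal similarities,
#'   the conventional default) or a numeric scalar; larger values yield
#'   more clusters.
#' @param damping update damping factor in \eqn{[0.5, 1)}.
#' @param maxit maximum number of iterations.
#' @param convits stop once the exemplar set is unchanged this many
#'   iterations.
#' @param seed integer seed for the tie-breaking jitter.
#' @return A [ClusterResult-class]; when the exemplar set never
#'   stabilises the result carries \code{converged = FALSE} and a warning
#'   is issued.
#' @examples
#' S <- rbind(c(1, .9, .1), c(.9, 1, .1), c(.1, .1, 1))
#' dimnames(S) <- list(letters[1:3], letters[1:3])
#' affinityCluster(S)
#' @export
affinityCluster <- function(S, preference = "median", damping = 0.9,
                            maxit = 1000L, convits = 100L, seed = 0L) {
    stopifnot(is.matrix(S), nrow(S) == ncol(S))
    if (max(abs(S - t(S))) > 1e-9)
        stop("similarity matrix must be symmetric")
    if (damping < 0.5 || damping >= 1)
        stop("'damping' must lie in [0.5, 1)")
    n <- nrow(S)
    ids <- rownames(S)
    if (is.null(ids)) ids <- paste0("item_", seq_len(n))
    if (n == 1L)
        return(new("ClusterResult", ids = ids, labels = 1L,
                   exemplars = ids, converged = TRUE, iterations = 0L))

    pref <- if (identical(preference, "median")) {
        median(S[row(S) != col(S)])
    } else {
        stopifnot(is.numeric(preference), length(preference) == 1L)
        preference
    }
    diag(S) <- pref

    ## seeded symmetry-breaking jitter, drawn in id-sorted order so the
    ## result is equivariant under permutations of the input
    scale <- max(abs(S), 1)
    canon <- order(ids)
    E <- matrix(0, n, n)
    E[canon, canon] <- .withSeed(seed,
        matrix(rnorm(n * n), n, n)) * 1e-10 * scale
    S <- S + E

    R <- matrix(0, n, n)
    A <- matrix(0, n, n)
    idx <- cbind(seq_len(n), seq_len(n))
    stable <- 0L
    prev_ex <- rep(FALSE, n)
    converged <- FALSE
    it <- 0L
    while (it < maxit) {
        it <- it + 1L
        ## responsibilities
        AS <- A + S
        imax <- max.col(AS, ties.method = "first")
        first <- AS[cbind(seq_len(n), imax)]
        AS[cbind(seq_len(n), imax)] <- -Inf
        second <- apply(AS, 1, max)
        Rnew <- S - first
        Rnew[cbind(seq_len(n), imax)] <- S[cbind(seq_len(n), imax)] - second
        R <- damping * R + (1 - damping) * Rnew
        ## availabilities
        Rp <- pmax(R, 0)
        Rp[idx] <- R[idx]
        colsum <- colSums(Rp)
        Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
        dAnew <- Anew[idx]
        Anew <- pmin(Anew, 0)
        Anew[idx] <- dAnew
        A <- damping * A + (1 - damping) * Anew

        ex <- (A[idx] + R[idx]) > 0
        if (identical(ex, prev_ex) && any(ex)) {
            stable <- stable + 1L
            if (stable >= convits) { converged <- TRUE; break }
        } else {
            stable <- 0L
        }
        prev_ex <- ex
    }
    if (!converged)
        warning("affinity propagation did not converge in ", maxit,
                " iterations; returning the current exemplar set")

    K <- which((A[idx] + R[idx]) > 0)
    if (length(K) == 0L) K <- which.max(A[idx] + R[idx])
    ## assign and refine exemplars within clusters
    lab <- apply(S[, K, drop = FALSE], 1, which.max)
    lab[K] <- seq_along(K)
    for (j in seq_along(K)) {
        members <- which(lab == j)
        within <- colSums(S[members, members, drop = FALSE])
        K[j] <- members[which.max(within)]
    }
    K <- sort(K)
    lab <- apply(S[, K, drop = FALSE], 1, which.max)
    lab[K] <- seq_along(K)
    new("ClusterResult", ids = ids, labels = as.integer(lab),
        exemplars = ids[K], converged = converged,
        iterations = it)
}

.asLabels <- function(x) {
    if (is(x, "ClusterResult")) x@labels
    else as.integer(factor(x))
}

#' Cluster purity
#'
#' Fraction of items belonging to the majority true class of their
#' predicted cluster: \eqn{(1/N) \sum_c \max_t n_{ct}}.  Invariant under
#' relabeling of cluster indices.
#'
#' @param pred predicted cluster labels (vector or
#'   [ClusterResult-class]).
#' @param truth true class labels, same length.
#' @return Numeric scalar in \eqn{[0, 1]}.
#' @export
clusterPurity <- function(pred, truth) {
    pred <- .asLabels(pred)
    if (length(pred) != length(truth))
        stop("'pred' and 'truth' must have the same length")
    if (length(pred) == 0L) stop("empty label vectors")
    tab <- table(pred, truth)
    sum(apply(tab, 1, max)) / length(pred)
}

#' Pairwise co-clustering precision, recall and accuracy
#'
#' Over all unordered item pairs: a true positive is a pair co-clustered
#' and of the same true class; a false positive is co-clustered across
#' classes; a false negative is a same-class pair split across clusters.
#' \code{accuracy = (TP + TN) / pairs} is the Rand index.  Degenerate 0/0
#' ratios (e.g. recall with no same-class pair) are reported as 1.
#'
#' @inheritParams clusterPurity
#' @return Named numeric vector \code{c(precision, recall, accuracy)}.
#' @export
pairwiseMetrics <- function(pred, truth) {
    pred <- .asLabels(pred)
    if (length(pred) != length(truth))
        stop("'pred' and 'truth' must have the same length")
    n <- length(pred)
    if (n < 2L) stop("need at least two items")
    tab <- table(pred, truth)
    npairs <- choose(n, 2)
    same_both <- sum(choose(tab, 2))                 # TP
    same_pred <- sum(choose(rowSums(tab), 2))        # TP + FP
    same_true <- sum(choose(colSums(tab), 2))        # TP + FN
    tp <- same_both
    fp <- same_pred - same_both
    fn <- same_true - same_both
    tn <- npairs - tp - fp - fn
    precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
    c(precision = precision, recall = recall,
      accuracy = (tp + tn) / npairs)
}

#' Average subclass split
#'
#' Mean over true classes of the number of distinct predicted clusters
#' containing at least one member of that class; 1 when no class is
#' scattered.
#'
#' @inheritParams clusterPurity
#' @return Numeric scalar >= 1.
#' @export
subclassSplit <- function(pred, truth) {
    pred <- .asLabels(pred)
    if (length(pred) != length(truth))
        stop("'pred' and 'truth' must have the same length")
    mean(vapply(split(pred, truth), function(p) length(unique(p)),
                numeric(1)))
}

#' Mapped classification accuracy of a clustering
#'
#' Accuracy under the optimal one-to-one assignment of predicted clusters
#' to true classes (solved exactly with the Hungarian algorithm): the
#' fraction of items whose cluster maps to their class.
#'
#' @inheritParams clusterPurity
#' @return Numeric scalar in \eqn{[0, 1]}.
#' @export
mappedAccuracy <- function(pred, truth) {
    pred <- .asLabels(pred)
    if (length(pred) != length(truth))
        stop("'pred' and 'truth' must have the same length")
    tab <- as.matrix(table(pred, truth))
    n <- max(dim(tab))
    C <- matrix(0, n, n)
    C[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    m <- .solveAssignment(max(C) - C)   # minimize cost = maximize matches
    sum(C[cbind(seq_len(n), m)]) / length(pred)
}

## Exact linear assignment (Hungarian algorithm with potentials, O(n^3));
## square cost matrix, returns the column matched to each row.
.solveAssignment <- function(cost) {
    n <- nrow(cost)
    stopifnot(ncol(cost) == n)
    u <- numeric(n + 1)
    v <- numeric(n + 1)
    p <- integer(n + 1)     # p[j + 1]: row matched to column j (0 = none)
    way <- integer(n + 1)
    for (i in seq_len(n)) {
        p[1] <- i
        j0 <- 0L
        minv <- rep(Inf, n + 1)
        used <- rep(FALSE, n + 1)
        repeat {
            used[j0 + 1] <- TRUE
            i0 <- p[j0 + 1]
            delta <- Inf
            j1 <- 0L
            for (j in seq_len(n)) {
                if (!used[j + 1]) {
                    cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
                    if (cur < minv[j + 1]) {
                        minv[j + 1] <- cur
                        way[j + 1] <- j0
                    }
                    if (minv[j + 1] < delta) {
                        delta <- minv[j + 1]
                        j1 <- j
                    }
                }
            }
            for (j in 0:n) {
                if (used[j + 1]) {
                    u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
                    v[j + 1] <- v[j + 1] - delta
                } else {
                    minv[j + 1] <- minv[j + 1] - delta
                }
            }
            j0 <- j1
            if (p[j0 + 1] == 0L) break
        }
        repeat {
            j1 <- way[j0 + 1]
            p[j0 + 1] <- p[j1 + 1]
            j0 <- j1
            if (j0 == 0L) break
        }
    }
    match <- integer(n)
    for (j in seq_len(n)) if (p[j + 1] > 0L) match[p[j + 1]] <- j
    match
}

#' Evaluate a clustering against true subclass labels
#'
#' @inheritParams clusterPurity
#' @param style \code{"pairwise"} scores precision/recall/accuracy over
#'   co-clustered item pairs (accuracy = Rand index); \code{"mapped"}
#'   reports [mappedAccuracy()] as the accuracy (precision/recall are then
#'   NA, as they are pair-based notions).
#' @return One-row data.frame with columns \code{purity},
#'   \code{accuracy}, \code{precision}, \code{recall}, \code{n_clusters},
#'   \code{avg_subclass_split}.
#' @examples
#' evaluateClustering(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
evaluateClustering <- function(pred, truth,
                               style = c("pairwise", "mapped")) {
    style <- match.arg(style)
    labs <- .asLabels(pred)
    pm <- pairwiseMetrics(labs, truth)
    acc <- if (style == "pairwise") pm[["accuracy"]]
           else mappedAccuracy(labs, truth)
    data.frame(
        purity = clusterPurity(labs, truth),
        accuracy = acc,
        precision = if (style == "pairwise") pm[["precision"]] else NA_real_,
        recall = if (style == "pairwise") pm[["recall"]] else NA_real_,
        n_clusters = length(unique(labs)),
        avg_subclass_split = subclassSplit(labs, truth))
}
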