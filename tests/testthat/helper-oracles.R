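## Independent reference implementations used to cross-check the package.
## These deliberately use the most naive formulation (explicit loops,
## dictionary tallies, plain recursion) and share no code with the package
## internals.

## full scoring pipeline by dictionary tally and explicit loops
naive_score <- function(a, b, k, length_weight = TRUE) {
    win <- function(s) {
        out <- character(0)
        for (i in seq_len(nchar(s) - k + 1))
            out <- c(out, substr(s, i, i + k - 1))
        out
    }
    ka <- win(a); kb <- win(b)
    vocab <- unique(c(ka, kb))
    ca <- cb <- stats::setNames(numeric(length(vocab)), vocab)
    for (x in ka) ca[x] <- ca[x] + 1
    for (x in kb) cb[x] <- cb[x] + 1
    dot <- na <- nb <- 0
    for (v in vocab) {
        dot <- dot + ca[v] * cb[v]
        na <- na + ca[v]^2
        nb <- nb + cb[v]^2
    }
    cosine <- unname(dot / (sqrt(na) * sqrt(nb)))
    D <- 2 * abs(nchar(a) - nchar(b)) / (nchar(a) + nchar(b))
    list(cosine = cosine, penalty = if (length_weight) D else 0,
         score = cosine * (1 - if (length_weight) D else 0))
}

## plain exhaustive recursion for the unit-cost edit distance
rec_lev <- function(a, b) {
    if (nchar(a) == 0) return(nchar(b))
    if (nchar(b) == 0) return(nchar(a))
    ra <- substr(a, 2, nchar(a))
    rb <- substr(b, 2, nchar(b))
    min(rec_lev(ra, b) + 1,
        rec_lev(a, rb) + 1,
        rec_lev(ra, rb) + (substr(a, 1, 1) != substr(b, 1, 1)))
}

## Rand index by brute force over all unordered item pairs
brute_rand <- function(pred, truth) {
    n <- length(pred)
    agree <- 0
    total <- 0
    for (i in seq_len(n - 1)) {
        for (j in seq.int(i + 1, n)) {
            total <- total + 1
            same_p <- pred[i] == pred[j]
            same_t <- truth[i] == truth[j]
            if (same_p == same_t) agree <- agree + 1
        }
    }
    agree / total
}

## all permutations of 1..n (n small)
all_perms <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (p in all_perms(n - 1)) {
        for (pos in 0:(n - 1)) {
            out[[length(out) + 1L]] <- append(p, n, after = pos)
        }
    }
    out
}

## mapped accuracy by exhaustive search over cluster-to-class assignments
brute_mapped <- function(pred, truth) {
    tab <- as.matrix(table(pred, truth))
    n <- max(dim(tab))
    C <- matrix(0, n, n)
    C[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    best <- 0
    for (p in all_perms(n))
        best <- max(best, sum(C[cbind(seq_len(n), p)]))
    best / length(pred)
}

## random k-mers over the structure alphabet
random_kmers <- function(n, k) {
    vapply(seq_len(n), function(i)
        paste(sample(structAlphabet(), k, replace = TRUE), collapse = ""),
        character(1))
}
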