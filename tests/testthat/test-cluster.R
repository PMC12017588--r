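block_matrix <- function() {
    S <- matrix(0.1, 6, 6)
    S[1:3, 1:3] <- 0.9
    S[4:6, 4:6] <- 0.9
    diag(S) <- 1
    dimnames(S) <- list(letters[1:6], letters[1:6])
    S
}

test_that("affinity propagation recovers a two-block partition", {
    res <- affinityCluster(block_matrix(), seed = 0)
    expect_s4_class(res, "ClusterResult")
    expect_true(hasConverged(res))
    expect_identical(nClusters(res), 2L)
    lab <- clusterLabels(res)
    expect_identical(length(unique(lab[1:3])), 1L)
    expect_identical(length(unique(lab[4:6])), 1L)
    expect_false(lab[1] == lab[4])
    ## exemplars belong to their own clusters (validity-enforced)
    for (j in seq_len(nClusters(res)))
        expect_true(clusterExemplars(res)[j] %in% names(lab)[lab == j])
})

test_that("high preference with no attraction gives all singletons", {
    S <- diag(5)
    dimnames(S) <- list(letters[1:5], letters[1:5])
    res <- affinityCluster(S, preference = 1, seed = 1)
    expect_identical(nClusters(res), 5L)
})

test_that("a single item forms a single cluster", {
    S <- matrix(1, 1, 1, dimnames = list("solo", "solo"))
    res <- affinityCluster(S)
    expect_identical(clusterLabels(res), c(solo = 1L))
    expect_identical(clusterExemplars(res), "solo")
})

test_that("clustering is deterministic given the seed", {
    ds <- plantedDataset(synthConfig(seed = 0, nFamilies = 3,
                                     membersPerFamily = 4))
    m <- scoreMatrix(ds$arrays, k = 10)
    r1 <- affinityCluster(m, seed = 7)
    r2 <- affinityCluster(m, seed = 7)
    expect_identical(clusterLabels(r1), clusterLabels(r2))
})

test_that("permuting the matrix permutes the labels identically", {
    ds <- plantedDataset(synthConfig(seed = 1, nFamilies = 3,
                                     membersPerFamily = 4))
    m <- scoreMatrix(ds$arrays, k = 10)
    res <- affinityCluster(m, seed = 3)
    set.seed(99)
    perm <- sample(nrow(m))
    resp <- affinityCluster(m[perm, perm], seed = 3)
    lab <- clusterLabels(res)
    labp <- clusterLabels(resp)
    ## same partition of the same ids, up to cluster re-indexing
    expect_identical(names(labp), names(lab)[perm])
    for (id1 in names(lab)) {
        for (id2 in names(lab)) {
            expect_identical(lab[[id1]] == lab[[id2]],
                             labp[[id1]] == labp[[id2]])
        }
    }
})

test_that("input matrices must be symmetric and damping in range", {
    S <- block_matrix()
    S[1, 2] <- 0.5
    expect_error(affinityCluster(S), "symmetric")
    expect_error(affinityCluster(block_matrix(), damping = 0.2),
                 "damping")
})

test_that("purity follows the majority-class formula", {
    expect_identical(clusterPurity(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
    expect_identical(clusterPurity(rep(1, 4), c("a", "a", "b", "b")), 0.5)
    expect_equal(clusterPurity(c(1, 1, 2), c("a", "b", "b")), 2 / 3,
                 tolerance = 1e-12)
    expect_error(clusterPurity(1:3, 1:4), "same length")
})

test_that("purity is invariant under cluster relabeling", {
    set.seed(41)
    for (i in 1:20) {
        pred <- sample(1:4, 30, replace = TRUE)
        truth <- sample(letters[1:3], 30, replace = TRUE)
        relab <- sample(10:13)[pred]
        expect_identical(clusterPurity(pred, truth),
                         clusterPurity(relab, truth))
    }
})

test_that("pairwise metrics enumerate co-clustering outcomes", {
    pm <- pairwiseMetrics(c(1, 1, 2), c("A", "A", "A"))
    expect_equal(unname(pm), c(1, 1 / 3, 1 / 3), tolerance = 1e-12)
    perfect <- pairwiseMetrics(c(1, 1, 2, 2), c("a", "a", "b", "b"))
    expect_identical(unname(perfect), c(1, 1, 1))
    ## all singletons: precision 1 by the 0/0 convention, recall 0
    single <- pairwiseMetrics(1:4, c("a", "a", "b", "b"))
    expect_identical(unname(single[c("precision", "recall")]), c(1, 0))
})

test_that("pairwise accuracy equals the brute-force Rand index", {
    set.seed(51)
    for (i in 1:20) {
        n <- sample(5:50, 1)
        pred <- sample(1:5, n, replace = TRUE)
        truth <- sample(1:4, n, replace = TRUE)
        expect_equal(pairwiseMetrics(pred, truth)[["accuracy"]],
                     brute_rand(pred, truth), tolerance = 1e-12)
    }
})

test_that("subclass split counts clusters per true class", {
    expect_identical(subclassSplit(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
    ## one class scattered over 5 clusters, the other intact
    pred <- c(1, 2, 3, 4, 5, 6, 6, 6)
    truth <- c(rep("hh3", 5), rep("glms", 3))
    expect_identical(subclassSplit(pred, truth), 3)
    expect_identical(subclassSplit(1:6, rep("x", 6)), 6)
})

test_that("Hungarian mapped accuracy equals exhaustive permutation search", {
    set.seed(61)
    for (i in 1:15) {
        n <- sample(8:30, 1)
        pred <- sample(1:sample(2:5, 1), n, replace = TRUE)
        truth <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
        expect_equal(mappedAccuracy(pred, truth),
                     brute_mapped(pred, truth), tolerance = 1e-12)
    }
})

test_that("evaluateClustering reports both metric styles", {
    pred <- c(1, 1, 1, 2, 2, 3)
    truth <- c("a", "a", "b", "b", "b", "c")
    ev <- evaluateClustering(pred, truth)
    expect_identical(ev$n_clusters, 3L)
    expect_equal(ev$accuracy, brute_rand(pred, truth), tolerance = 1e-12)
    evm <- evaluateClustering(pred, truth, style = "mapped")
    expect_equal(evm$accuracy, brute_mapped(pred, truth),
                 tolerance = 1e-12)
    expect_true(is.na(evm$precision))
    expect_gte(ev$avg_subclass_split, 1)
})
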