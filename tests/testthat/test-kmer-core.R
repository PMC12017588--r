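test_that("extractKmers slides a k-window in order", {
    expect_identical(extractKmers("LLLHHHRRR", 3),
                     c("LLL", "LLH", "LHH", "HHH", "HHR", "HRR", "RRR"))
    expect_identical(extractKmers("LLLL", 3), c("LLL", "LLL"))
    expect_identical(extractKmers("HHH", 3), "HHH")
    expect_error(extractKmers("HHH", 4), "exceeds structure length")
})

test_that("pair vocabulary is the first-appearance union", {
    expect_identical(pairVocabulary(c("LLL", "LLH"), c("LLH", "HHH")),
                     c("LLL", "LLH", "HHH"))
    expect_identical(pairVocabulary("LLL", "LLL"), "LLL")
    expect_error(pairVocabulary(character(0), "LLL"))
    expect_error(pairVocabulary("LL", "LLL"), "same k")
})

test_that("count vectors tally multiplicities over the union", {
    ka <- extractKmers("LLLHHHRRR", 3)
    kb <- extractKmers("LLLLHHHHRRRR", 3)
    vocab <- pairVocabulary(ka, kb)
    expect_identical(unname(kmerCounts(countVector(ka, vocab))),
                     rep(1, 7))
    expect_identical(unname(kmerCounts(countVector(kb, vocab))),
                     c(2, 1, 1, 2, 1, 1, 2))
    ## vocabulary entries missing from the list get zero
    v <- countVector("LLL", c("LLL", "HHH"))
    expect_identical(unname(kmerCounts(v)), c(1, 0))
    expect_error(countVector("XXX", c("LLL")), "absent from the vocabulary")
})

test_that("cosine matches the hand-worked value and its edge cases", {
    v1 <- KmerCountVector(letters[1:7], rep(1, 7))
    v2 <- KmerCountVector(letters[1:7], c(2, 1, 1, 2, 1, 1, 2))
    expect_equal(cosineSimilarity(v1, v2), 10 / (4 * sqrt(7)),
                 tolerance = 1e-12)
    expect_equal(cosineSimilarity(v2, v2), 1, tolerance = 1e-12)
    d1 <- KmerCountVector(c("a", "b"), c(1, 0))
    d2 <- KmerCountVector(c("a", "b"), c(0, 1))
    expect_equal(cosineSimilarity(d1, d2), 0)
    z <- KmerCountVector(c("a", "b"), c(0, 0))
    expect_error(cosineSimilarity(d1, z), "zero-norm")
    expect_error(cosineSimilarity(d1, KmerCountVector("a", 1)),
                 "identical vocabulary")
})

test_that("length penalty is the relative length difference", {
    expect_identical(lengthPenalty(100, 100), 0)
    expect_identical(lengthPenalty(50, 150), 1)
    expect_equal(lengthPenalty(9, 12), 6 / 21, tolerance = 1e-12)
    expect_identical(lengthPenalty(12, 9), lengthPenalty(9, 12))
    expect_error(lengthPenalty(0, 5), "must be a single integer")
})

test_that("weighted score composes cosine and penalty without clamping", {
    expect_identical(weightedScore(0.8, 200, 200), 0.8)
    expect_equal(weightedScore(0.5, 90, 110), 0.4, tolerance = 1e-12)
    expect_equal(weightedScore(10 / (4 * sqrt(7)), 9, 12), 0.6749366,
                 tolerance = 1e-6)
    ## length ratio beyond 3:1 makes D > 1 and the score negative
    expect_lt(weightedScore(1, 10, 100), 0)
})

test_that("scorePair runs the whole worked pipeline", {
    rec <- scorePair("LLLHHHRRR", "LLLLHHHHRRRR", k = 3)
    expect_equal(rec$cosine, 10 / (4 * sqrt(7)), tolerance = 1e-12)
    expect_equal(rec$penalty, 2 / 7, tolerance = 1e-12)
    expect_equal(rec$score, rec$cosine * (1 - rec$penalty),
                 tolerance = 1e-15)
    same <- scorePair("LLLHHHRRR", "LLLHHHRRR", k = 3)
    expect_identical(c(same$cosine, same$penalty, same$score), c(1, 0, 1))
    ortho <- scorePair(strrep("H", 12), strrep("L", 12), k = 10)
    expect_identical(ortho$score, 0)
    expect_error(scorePair("LLLHHHRRR", "LR", k = 3), "shorter structure")
})

test_that("scorePair is symmetric and self-scores are exactly 1", {
    set.seed(11)
    for (i in 1:20) {
        a <- annotateStructure(randomStructure(sample(40:120, 1)))
        b <- annotateStructure(randomStructure(sample(40:120, 1)))
        for (fz in c(FALSE, TRUE)) {
            k <- if (fz) 9 else 10
            ab <- scorePair(a, b, k = k, fuzzy = fz)
            ba <- scorePair(b, a, k = k, fuzzy = fz)
            expect_identical(ab$score, ba$score)
            self <- scorePair(a, a, k = k, fuzzy = fz)
            expect_identical(self$score, 1)
        }
    }
})

test_that("cosine is invariant under positive scaling of one vector", {
    set.seed(3)
    for (i in 1:10) {
        v <- KmerCountVector(letters[1:5], runif(5, 0, 4))
        w <- KmerCountVector(letters[1:5], runif(5, 0, 4))
        lambda <- runif(1, 0.1, 50)
        scaled <- KmerCountVector(letters[1:5], lambda * w@counts)
        expect_equal(cosineSimilarity(v, scaled), cosineSimilarity(v, w),
                     tolerance = 1e-12)
    }
})

test_that("at fixed total length the score falls as lengths diverge", {
    cosine <- 0.9
    total <- 240
    diffs <- seq(0, 110, by = 10)
    s <- vapply(diffs, function(d)
        weightedScore(cosine, (total - d) / 2, (total + d) / 2), numeric(1))
    expect_true(all(diff(s) <= 0))
})

test_that("plain counts sum to L - k + 1 for every structure", {
    set.seed(5)
    for (i in 1:20) {
        arr <- annotateStructure(randomStructure(sample(30:100, 1)))
        k <- sample(3:10, 1)
        km <- extractKmers(arr, k)
        v <- countVector(km, unique(km))
        expect_identical(sum(v@counts), as.numeric(nchar(arr) - k + 1))
    }
})

test_that("scorePair agrees with the naive oracle on random pairs", {
    set.seed(17)
    for (i in 1:100) {
        a <- annotateStructure(randomStructure(sample(30:80, 1)))
        b <- annotateStructure(randomStructure(sample(30:80, 1)))
        k <- sample(c(3, 6, 10), 1)
        got <- scorePair(a, b, k = k)
        want <- naive_score(a, b, k)
        expect_equal(got$cosine, want$cosine, tolerance = 1e-12)
        expect_equal(got$penalty, want$penalty, tolerance = 1e-12)
        expect_equal(got$score, want$score, tolerance = 1e-12)
    }
})

test_that("scoreMatrix is symmetric with unit diagonal, skipping short", {
    arrs <- StructureArraySet(c(a = "LLLHHHRRR", b = "LLLLHHHHRRRR",
                                c = "EELLLHHHRRREE", short = "LHHHR"))
    expect_warning(m <- scoreMatrix(arrs, k = 6), "skipping 1 structure")
    expect_identical(dim(m), c(3L, 3L))
    expect_identical(unname(diag(m)), rep(1, 3))
    expect_identical(m, t(m))
    expect_equal(m["a", "b"],
                 scorePair("LLLHHHRRR", "LLLLHHHHRRRR", k = 6)$score,
                 tolerance = 1e-15)
})
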