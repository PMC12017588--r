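test_that("edit distance handles the worked cases", {
    expect_identical(kmerEditDistance("HHH", "HHH"), 0L)
    expect_identical(kmerEditDistance("HHHH", "HHHR"), 1L)
    ## equal-length pair where two substitutions tie an indel shift
    expect_identical(kmerEditDistance("LLHHHRRRR", "LLLHHHRRR"), 2L)
    expect_identical(kmerEditDistance("", "HHH"), 3L)
})

test_that("banded DP equals utils::adist on many random 5-mer pairs", {
    set.seed(21)
    vocab <- unique(random_kmers(200, 5))
    idx <- t(combn(length(vocab), 2))
    got <- kmerEditDistance(vocab[idx[, 1]], vocab[idx[, 2]])
    want <- as.integer(adist(vocab)[idx])
    expect_identical(got, want)
})

test_that("banded DP equals plain exhaustive recursion on 5-mers", {
    set.seed(33)
    vocab <- unique(random_kmers(12, 5))
    for (i in seq_len(length(vocab) - 1)) {
        for (j in seq.int(i + 1, length(vocab))) {
            expect_identical(kmerEditDistance(vocab[i], vocab[j]),
                             as.integer(rec_lev(vocab[i], vocab[j])))
        }
    }
})

test_that("edit distance is a metric on random 9-mer triples", {
    set.seed(55)
    a <- random_kmers(1000, 9)
    b <- random_kmers(1000, 9)
    c <- random_kmers(1000, 9)
    dab <- kmerEditDistance(a, b)
    dba <- kmerEditDistance(b, a)
    dac <- kmerEditDistance(a, c)
    dcb <- kmerEditDistance(c, b)
    expect_identical(dab, dba)                       # symmetry
    expect_identical(kmerEditDistance(a, a), rep(0L, 1000))  # identity
    expect_true(all(dab[a != b] >= 1L))
    expect_true(all(dab <= dac + dcb))               # triangle
})

test_that("neighbor tables store exactly the d <= maxDist pairs", {
    nt1 <- neighborTable(c("LLL", "LLH", "HHH"), maxDist = 1)
    expect_identical(neighborPairs(nt1),
                     data.frame(a = "LLH", b = "LLL", d = 1L))
    nt2 <- neighborTable(c("LLL", "LLH", "HHH"), maxDist = 2)
    expect_identical(neighborPairs(nt2),
                     data.frame(a = c("HHH", "LLH"), b = c("LLH", "LLL"),
                                d = c(2L, 1L)))
    expect_identical(nrow(neighborPairs(neighborTable("LLL", 2))), 0L)
    expect_warning(neighborTable(c("LLL", "LLH"), maxDist = 3),
                   "over-connects")
})

test_that("DP and neighborhood-enumeration tables are identical", {
    set.seed(87)
    for (rep in 1:3) {
        vocab <- unique(random_kmers(150, 6))
        for (md in 1:2) {
            dp <- neighborPairs(neighborTable(vocab, md, method = "dp"))
            en <- neighborPairs(neighborTable(vocab, md,
                                              method = "enumerate"))
            expect_identical(dp, en)
        }
    }
    ## also on a realistic structure-derived vocabulary
    arrs <- plantedDataset(synthConfig(seed = 2, nFamilies = 2,
                                       membersPerFamily = 3))$arrays
    vocab <- kmerCensus(arrs, 9)$kmer
    expect_identical(
        neighborPairs(neighborTable(vocab, 2, method = "dp")),
        neighborPairs(neighborTable(vocab, 2, method = "enumerate")))
})

test_that("fuzzify adds exp(-d) pseudo-counts within the vocabulary", {
    v <- KmerCountVector(c("LLL", "LLH"), c(2, 0))
    nt <- neighborTable(c("LLL", "LLH"), maxDist = 2)
    f <- kmerCounts(fuzzify(v, nt))
    expect_equal(unname(f), c(2, 2 * exp(-1)), tolerance = 1e-12)
    ## the only pseudo-count weights at maxDist 2, to printed precision
    expect_lt(abs(exp(-1) - 0.367879), 5e-7)
    expect_lt(abs(exp(-2) - 0.135335), 5e-7)
})

test_that("flat scheme adds exp(-d) once per present neighbor", {
    v <- KmerCountVector(c("LLL", "LLH", "HHH"), c(5, 0, 0))
    nt <- neighborTable(c("LLL", "LLH", "HHH"), maxDist = 2)
    f <- kmerCounts(fuzzify(v, nt, scheme = "flat"))
    ## d(LLL,LLH)=1, d(LLL,HHH)=3 (absent), d(LLH,HHH)=2
    expect_equal(unname(f), c(5, exp(-1), 0), tolerance = 1e-12)
})

test_that("isolated k-mers are untouched by fuzzification", {
    v <- KmerCountVector(c("LLLLL", "HHHHH"), c(3, 0))
    nt <- neighborTable(c("LLLLL", "HHHHH"), maxDist = 2)
    expect_identical(kmerCounts(fuzzify(v, nt)), kmerCounts(v))
})

test_that("fuzzification never decreases an entry and fills zeros only
           near observed k-mers", {
    set.seed(9)
    for (i in 1:10) {
        arr1 <- annotateStructure(randomStructure(60))
        arr2 <- annotateStructure(randomStructure(60))
        ka <- extractKmers(arr1, 9)
        vocab <- pairVocabulary(ka, extractKmers(arr2, 9))
        v <- countVector(ka, vocab)
        nt <- neighborTable(vocab, 2)
        f <- fuzzify(v, nt)
        expect_true(all(f@counts >= v@counts))
        expect_true(f@fuzzy)
        expect_identical(f@vocabulary, v@vocabulary)
        ## new mass only within maxDist of an observed k-mer
        gained <- which(f@counts > 0 & v@counts == 0)
        obs <- vocab[v@counts > 0]
        for (g in gained)
            expect_lte(min(kmerEditDistance(rep(vocab[g], length(obs)),
                                            obs)), 2L)
        ## zero-count elements shrink (the motivation for fuzzy mode)
        expect_lte(sum(f@counts == 0), sum(v@counts == 0))
    }
})

test_that("fuzzy self-score is exactly 1", {
    set.seed(13)
    for (i in 1:5) {
        arr <- annotateStructure(randomStructure(80))
        rec <- scorePair(arr, arr, k = 9, fuzzy = TRUE, maxDist = 2)
        expect_identical(rec$score, 1)
    }
})
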