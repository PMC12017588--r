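test_that("census tallies unique k-mers with total occurrence counts", {
    cen <- kmerCensus(StructureArraySet("LLLHHHRRR"), 3)
    expect_identical(nrow(cen), 7L)
    expect_true(all(cen$count == 1L))
    cen2 <- kmerCensus(StructureArraySet(c("LLLL", "LLLL")), 3)
    expect_identical(cen2, data.frame(kmer = "LLL", count = 4L))
    expect_warning(kmerCensus(StructureArraySet(c(a = "LLLHHHRRR",
                                                  b = "LR")), 3),
                   "skipping 1 structure")
})

test_that("observed k-mer count respects both upper bounds", {
    set.seed(31)
    arrs <- plantedDataset(synthConfig(seed = 3, nFamilies = 3,
                                       membersPerFamily = 4))$arrays
    for (k in c(3, 5, 9)) {
        cen <- kmerCensus(arrs, k)
        windows <- sum(pmax(structureLengths(arrs) - k + 1, 0))
        expect_lte(nrow(cen), windows)
        expect_lte(nrow(cen), possibleKmers(k))
        expect_identical(sum(cen$count), as.integer(windows))
    }
})

test_that("possible k-mer space size is 8^k", {
    expect_identical(possibleKmers(1), 8)
    expect_identical(possibleKmers(10), 1073741824)
})

test_that("dominant label picks the modal character with fixed tie order", {
    expect_identical(dominantLabel("LLLLLLHHH"), "L")
    expect_identical(dominantLabel("HHHHHHHHH"), "H")
    expect_identical(dominantLabel("LLLHHHRRR"), "L")   # 3-way tie
    expect_identical(dominantLabel(c("RRRHHH", "EEEBBB")), c("R", "B"))
})

test_that("network edges follow the neighbor table, degrees match", {
    net1 <- buildKmerNetwork(c("LLL", "LLH", "HHH"), maxDist = 1)
    expect_identical(nrow(networkEdges(net1)), 1L)
    net2 <- buildKmerNetwork(c("LLL", "LLH", "HHH"), maxDist = 2)
    expect_identical(nrow(networkEdges(net2)), 2L)
    deg <- stats::setNames(networkNodes(net2)$degree,
                           networkNodes(net2)$kmer)
    expect_identical(deg[["LLH"]], 2L)
    expect_identical(deg[["LLL"]], 1L)
    net0 <- buildKmerNetwork("LLL", maxDist = 2)
    expect_identical(nrow(networkEdges(net0)), 0L)
})

test_that("edge count is monotone in the distance threshold", {
    set.seed(61)
    arrs <- plantedDataset(synthConfig(seed = 4, nFamilies = 2,
                                       membersPerFamily = 3))$arrays
    cen <- kmerCensus(arrs, 9)
    e1 <- nrow(networkEdges(buildKmerNetwork(cen, maxDist = 1)))
    e2 <- nrow(networkEdges(buildKmerNetwork(cen, maxDist = 2)))
    expect_gte(e2, e1)
})

test_that("top hubs rank by degree then lexicographic k-mer", {
    net <- buildKmerNetwork(c("LLL", "LLH", "LHH", "XXX"), maxDist = 1)
    hubs <- topHubs(net, 2)
    expect_identical(hubs$kmer, c("LLH", "LHH"))
    expect_true(all(diff(hubs$degree) <= 0))
    expect_identical(nrow(topHubs(net, 0)), 0L)
    iso <- buildKmerNetwork(c("XXX", "HHH", "BBB"), maxDist = 1)
    expect_identical(topHubs(iso, 3)$kmer, c("BBB", "HHH", "XXX"))
})

test_that("stem-rich datasets yield stem-dominant hubs", {
    set.seed(71)
    arrs <- plantedDataset(synthConfig(seed = 5))$arrays
    net <- buildKmerNetwork(kmerCensus(arrs, 9), maxDist = 2)
    hubs <- topHubs(net, 20)
    expect_gte(mean(hubs$dominant %in% c("L", "R")), 0.5)
})

test_that("GraphML export re-imports losslessly", {
    arrs <- plantedDataset(synthConfig(seed = 6, nFamilies = 2,
                                       membersPerFamily = 2))$arrays
    net <- buildKmerNetwork(kmerCensus(arrs, 6), maxDist = 2)
    f <- withr::local_tempfile(fileext = ".graphml")
    exportGraphML(net, f)
    back <- readKmerNetwork(f, maxDist = 2)
    expect_identical(nrow(networkNodes(back)), nrow(networkNodes(net)))
    expect_identical(nrow(networkEdges(back)), nrow(networkEdges(net)))
    nd <- networkNodes(net)[order(networkNodes(net)$kmer), ]
    bd <- networkNodes(back)[order(networkNodes(back)$kmer), ]
    rownames(nd) <- rownames(bd) <- NULL
    expect_identical(bd, nd)
    expect_identical(networkEdges(back), networkEdges(net))
})

test_that("edge TSV export carries kmer_a, kmer_b, d", {
    net <- buildKmerNetwork(c("LLL", "LLH", "HHH"), maxDist = 2)
    f <- withr::local_tempfile(fileext = ".tsv")
    exportEdges(net, f)
    ed <- read.delim(f)
    expect_identical(names(ed), c("kmer_a", "kmer_b", "d"))
    expect_identical(nrow(ed), 2L)
})
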