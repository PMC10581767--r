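smallParams <- function(...) {
    simParams(nPedigrees = 2, nGenera = 12, envPoolSize = 30, depth = 10000,
              ...)
}

test_that("generation is deterministic in the seed", {
    a <- simulatePedigreeDataset(smallParams(seed = 5))
    b <- simulatePedigreeDataset(smallParams(seed = 5))
    expect_identical(counts(a$experiment), counts(b$experiment))
    expect_identical(a$truth, b$truth)
    expect_identical(sampleMetadata(a$experiment),
                     sampleMetadata(b$experiment))
    c <- simulatePedigreeDataset(smallParams(seed = 6))
    expect_false(identical(counts(a$experiment), counts(c$experiment)))
})

test_that("every sample sums exactly to the sequencing depth", {
    sim <- simulatePedigreeDataset(smallParams(seed = 2))
    totals <- colSums(counts(sim$experiment))
    md <- sampleMetadata(sim$experiment)
    # founder samples can be shallower only if the whole community dropped out
    expect_true(all(totals == 10000 | totals == 0))
    expect_true(all(totals[md$generation != "founder"] == 10000))
})

test_that("the study design is emulated: tiers, pooling, shared paternal colony", {
    sim <- simulatePedigreeDataset(simParams(seed = 3))
    md <- sampleMetadata(sim$experiment)
    expect_identical(sort(unique(md$pedigree[!is.na(md$pedigree)])),
                     sort(c("red", "yellow", "blue", "green")))
    expect_true(all(md$guts_pooled >= 5 & md$guts_pooled <= 10))
    pat <- md$generation == "parental" & md$parental_role == "paternal"
    expect_identical(length(unique(md$colony_id[pat])), 1L)
    expect_true(all(is.na(md$pedigree[pat])))
    for (pp in c("red", "green")) {
        expect_identical(sum(md$generation == "founder" & md$pedigree == pp &
                                 md$parental_role == "maternal"), 3L)
        expect_identical(sum(md$generation == "offspring" &
                                 md$pedigree == pp), 3L)
    }
})

test_that("planted classes have the promised presence structure", {
    sim <- simulatePedigreeDataset(smallParams(seed = 8))
    pe <- sim$experiment
    pres <- presenceMatrix(pe)
    md <- sampleMetadata(pe)
    truth <- sim$truth
    for (pp in pedigrees(pe)) {
        tr <- truth[truth$pedigree == pp, ]
        herit_m <- tr$asv_id[tr$class %in% c("heritable_maternal",
                                             "heritable_shared")]
        founders_m <- md$generation == "founder" & md$pedigree == pp &
            md$parental_role == "maternal"
        offspring <- md$generation == "offspring" & md$pedigree == pp
        # heritable maternal ASVs in ALL maternal founder samples
        expect_true(all(pres[herit_m, founders_m]))
        # and in at least one offspring sample
        expect_true(all(rowSums(pres[herit_m, offspring, drop = FALSE]) > 0))
        # environmental ASVs never occur outside offspring samples (they can
        # recur in another pedigree's offspring: the env pool is shared)
        env <- tr$asv_id[tr$class == "environmental"]
        expect_true(all(pres[env, md$generation != "offspring"] == 0))
        # parental-only ASVs never reach the offspring
        ponly <- tr$asv_id[tr$class == "parental_only"]
        expect_true(all(pres[ponly, offspring] == 0))
    }
})

test_that("nothing is planted when heritability is off and dropout total", {
    sim <- simulatePedigreeDataset(smallParams(seed = 12, fracHeritable = 0,
                                               founderDropout = 1))
    expect_false(any(startsWith(sim$truth$class, "heritable")))
    pe <- sim$experiment
    calls <- do.call(rbind, lapply(pedigrees(pe), function(pp)
        classifyVertical(pe, pp, "maternal")))
    expect_identical(sum(calls$vertically_transmitted), 0L)
})

test_that("without dropout and at high depth every parental ASV reaches founders", {
    sim <- simulatePedigreeDataset(simParams(
        nPedigrees = 1, nGenera = 6, asvsPerGenusMean = 3, envPoolSize = 10,
        founderDropout = 0, depth = 2e5, overdispersion = 5000, seed = 13))
    pe <- sim$experiment
    calls <- classifyVertical(pe, "red", "maternal")
    tr <- sim$truth
    maternal_comm <- tr$asv_id[tr$pedigree == "red" &
        tr$class != "environmental"]
    in_maternal <- calls$asv_id %in% maternal_comm &
        calls$present_in_parental_workers
    expect_true(all(calls$transmitted_to_founders[in_maternal]))
})

test_that("planted-partition networks have the requested structure", {
    labels <- setNames(rep(c("a", "b"), each = 10), sprintf("N%02d", 1:20))
    sim <- simulateSignedNetwork(labels, pWithinPositive = 0.5,
                                 pBetweenPositive = 0, pNegative = 0.1,
                                 seed = 4)
    pos <- subsetBySign(sim$network, "positive")
    expect_equal(labelAssortativity(pos, labels)$r, 1)

    # determinism and node preservation
    sim2 <- simulateSignedNetwork(labels, 0.5, 0, 0.1, seed = 4)
    expect_identical(networkEdges(sim$network), networkEdges(sim2$network))
    expect_identical(networkNodes(sim$network), names(labels))

    # label-independent connection probabilities: r centred at 0 (within
    # the O(1/edges) finite-size bias of the coefficient)
    biglab <- setNames(rep(c("a", "b"), each = 15), sprintf("B%02d", 1:30))
    rs <- vapply(1:60, function(i) {
        s <- simulateSignedNetwork(biglab, 0.3, 0.3, 0, seed = 1000 + i)
        labelAssortativity(s$network, biglab)$r
    }, 1.0)
    expect_lt(abs(mean(rs, na.rm = TRUE)), 0.05)

    # edge counts concentrate near n * p
    n_pairs_within <- 2 * choose(10, 2)
    n_pairs_between <- 100
    sim3 <- simulateSignedNetwork(labels, 0.4, 0.2, 0, seed = 77)
    n_edges <- nrow(networkEdges(sim3$network))
    expected <- 0.4 * n_pairs_within + 0.2 * n_pairs_between
    expect_lt(abs(n_edges - expected), 4 * sqrt(expected))
})
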