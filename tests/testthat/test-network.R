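test_that("signed-network validity rejects malformed graphs", {
    expect_error(SignedNetwork(data.frame(from = "A", to = "A",
                                          sign = "positive")), "self-loop")
    expect_error(SignedNetwork(data.frame(from = c("A", "B"),
                                          to = c("B", "A"),
                                          sign = "positive")), "duplicate")
    expect_error(SignedNetwork(data.frame(from = "A", to = "B",
                                          sign = "positive"),
                               nodes = "A"), "endpoint")
    expect_error(SignedNetwork(data.frame(from = "A", to = "B",
                                          sign = "up")), "sign")
})

test_that("sign subsetting keeps all nodes and filters edges", {
    net <- SignedNetwork(data.frame(
        from = c("A", "B", "C", "A", "B"),
        to = c("B", "C", "D", "C", "D"),
        sign = c("positive", "positive", "positive", "negative", "negative")))
    pos <- subsetBySign(net, "positive")
    expect_identical(nrow(networkEdges(pos)), 3L)
    expect_setequal(networkNodes(pos), networkNodes(net))
    neg <- subsetBySign(net, "negative")
    expect_identical(nrow(networkEdges(neg)), 2L)
    only_pos <- SignedNetwork(data.frame(from = "A", to = "B",
                                         sign = "positive"))
    expect_warning(empty <- subsetBySign(only_pos, "negative"), "no negative")
    expect_identical(nrow(networkEdges(empty)), 0L)
    expect_identical(networkNodes(empty), c("A", "B"))
})

test_that("assortativity matches hand-derived mixing values", {
    # two uniformly-labeled components, no cross edges
    net1 <- SignedNetwork(data.frame(from = c("A", "C"), to = c("B", "D"),
                                     sign = "positive"))
    lab1 <- c(A = "i", B = "i", C = "n", D = "n")
    expect_equal(labelAssortativity(net1, lab1)$r, 1)

    # A-B, C-D within class, B-C across: e_ii = e_nn = 1/3, cross 1/6 each
    net2 <- SignedNetwork(data.frame(from = c("A", "C", "B"),
                                     to = c("B", "D", "C"),
                                     sign = "positive"))
    expect_equal(labelAssortativity(net2, lab1)$r, 1 / 3)

    # single-class network: undefined and flagged
    res <- labelAssortativity(net1, c(A = "i", B = "i", C = "i", D = "i"))
    expect_false(res$defined)
    expect_true(is.na(res$r))

    expect_error(labelAssortativity(net1, c(A = "i", B = "i", C = "n")),
                 "unlabeled")
    expect_error(labelAssortativity(
        SignedNetwork(nodes = c("A", "B")), c(A = "i", B = "n")), "edge")
})

test_that("assortativity is invariant to class renaming and stays in [-1,1]", {
    set.seed(13)
    for (i in 1:30) {
        n <- sample(5:9, 1)
        sim <- simulateSignedNetwork(
            setNames(sample(c("x", "y"), n, TRUE), paste0("N", 1:n)),
            pWithinPositive = 0.6, pBetweenPositive = 0.4, pNegative = 0,
            seed = i)
        if (!nrow(networkEdges(sim$network))) next
        lab <- sim$labels
        r1 <- labelAssortativity(sim$network, lab)$r
        swapped <- setNames(ifelse(lab == "x", "y", "x"), names(lab))
        r2 <- labelAssortativity(sim$network, swapped)$r
        expect_equal(r1, r2)
        if (!is.na(r1)) expect_true(r1 >= -1 - 1e-12 && r1 <= 1 + 1e-12)
    }
})

test_that("implementation agrees with igraph on random labeled graphs", {
    set.seed(31)
    for (i in 1:40) {
        n <- sample(4:10, 1)
        labels <- setNames(sample(c("i", "n"), n, TRUE), paste0("N", 1:n))
        sim <- simulateSignedNetwork(labels, 0.5, 0.3, 0, seed = 100 + i)
        edges <- networkEdges(sim$network)
        if (nrow(edges) < 1) next
        mine <- labelAssortativity(sim$network, labels)$r
        g <- igraph::graph_from_data_frame(
            edges[, c("from", "to")], directed = FALSE,
            vertices = data.frame(name = networkNodes(sim$network)))
        ref <- igraph::assortativity_nominal(
            g, factor(labels[igraph::V(g)$name]))
        if (is.na(mine) || is.nan(ref)) expect_true(is.na(mine) &&
                                                        is.nan(ref))
        else expect_equal(mine, ref, tolerance = 1e-12)
    }
})

test_that("null assortativity compares the fixed topology across labelings", {
    labels <- setNames(rep(c("i", "n"), each = 6), paste0("N", 1:12))
    sim <- simulateSignedNetwork(labels, 0.9, 0.05, 0, seed = 8)
    inherited <- names(labels)[labels == "i"]

    # degenerate null: every null labeling equals the observed one
    same <- replicate(25, inherited, simplify = FALSE)
    res <- nullAssortativity(sim$network, same, inherited)
    expect_equal(res$p_raw, 1)
    expect_true(all(res$null_r == res$r))

    # random labelings on a label-independent graph: mean null r near 0
    # (graph large enough that the O(1/edges) finite-size bias is small)
    big <- setNames(rep(c("i", "n"), each = 15), paste0("M", 1:30))
    er <- simulateSignedNetwork(big, 0.4, 0.4, 0, seed = 9)
    set.seed(14)
    rand_big <- replicate(300, sample(names(big), 15), simplify = FALSE)
    res2 <- nullAssortativity(er$network, rand_big,
                              names(big)[big == "i"])
    expect_lt(abs(mean(res2$null_r)), 0.05)

    # planted blocks beat random labelings (blocks big enough that a
    # uniform draw essentially never reproduces the planted partition)
    planted <- setNames(rep(c("i", "n"), each = 10), paste0("P", 1:20))
    psim <- simulateSignedNetwork(planted, 0.9, 0.05, 0, seed = 16)
    set.seed(15)
    rand <- replicate(300, sample(names(planted), 10), simplify = FALSE)
    res3 <- nullAssortativity(psim$network, rand,
                              names(planted)[planted == "i"])
    expect_gt(res3$r, max(res3$null_r))
    expect_equal(res3$p_raw, 0)
    expect_gt(res3$p_add_one, 0)

    expect_error(nullAssortativity(sim$network, list(c("N1", "ZZ")),
                                   inherited), "absent")
})

test_that("degree features count incident edges per sign", {
    net <- SignedNetwork(data.frame(
        from = c("A", "A", "A", "B"), to = c("B", "C", "D", "C"),
        sign = c("positive", "positive", "negative", "negative")),
        nodes = c("A", "B", "C", "D", "E"))
    deg <- degreeFeatures(net)
    a <- deg[deg$node == "A", ]
    expect_identical(c(a$positive_degree, a$negative_degree), c(2L, 1L))
    e <- deg[deg$node == "E", ]
    expect_identical(c(e$positive_degree, e$negative_degree), c(0L, 0L))
    expect_identical(sum(deg$positive_degree), 2L * 2L)  # handshake lemma
    expect_identical(sum(deg$negative_degree), 2L * 2L)
})

test_that("edge lists round-trip and the display filter is display-only", {
    net <- SignedNetwork(data.frame(
        from = c("A", "A", "B"), to = c("B", "C", "C"),
        sign = c("positive", "negative", "positive"),
        weight = c(0.5, -0.2, 0.8)))
    path <- tempfile(fileext = ".tsv")
    df <- networkEdges(net)
    names(df)[1:2] <- c("node_a", "node_b")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    back <- readSignedNetwork(path)
    expect_setequal(networkNodes(back), networkNodes(net))
    expect_equal(networkEdges(back)$weight, networkEdges(net)$weight)

    hub <- SignedNetwork(data.frame(
        from = rep("H", 6), to = paste0("N", 1:6), sign = "positive"))
    disp <- displayFilter(hub, minDegree = 6)
    expect_identical(networkNodes(disp), "H")
    expect_identical(nrow(networkEdges(disp)), 0L)
})
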