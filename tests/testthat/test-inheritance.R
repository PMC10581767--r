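test_that("the strict rule needs parental presence, all founders, any offspring", {
    # rows: ASV1 full pattern; ASV2 misses founder F2; ASV3 misses the
    # parental workers; ASV4 founder-transmitted but absent from offspring
    pat <- matrix(c(1, 1, 1, 1, 0,
                    1, 1, 0, 1, 1,
                    0, 1, 1, 1, 1,
                    1, 1, 1, 0, 0) == 1, nrow = 4, byrow = TRUE)
    pe <- patternExperiment(pat)
    calls <- classifyVertical(pe, "A", "maternal")
    expect_identical(calls$vertically_transmitted, c(TRUE, FALSE, FALSE,
                                                     FALSE))
    expect_identical(calls$transmitted_to_founders, c(TRUE, FALSE, FALSE,
                                                      TRUE))
    expect_identical(calls$in_any_offspring, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("missing tiers error with the tier name", {
    pe <- tinyExperiment()
    expect_error(classifyVertical(pe, "A", "paternal"), "parental")
    expect_error(classifyVertical(pe, "B", "maternal"), "founder|parental")
})

test_that("parental presence uses workers only, unless castes are widened", {
    md <- tinyMetadata()
    md$caste[1] <- "queen"  # the only parental sample is now a royal
    pe <- PedigreeExperiment(tinyCounts(), tinyTaxonomy(), md)
    expect_error(classifyVertical(pe, "A", "maternal"), "parental")
    calls <- classifyVertical(pe, "A", "maternal",
                              parentalCastes = c("worker", "queen", "king"))
    expect_identical(calls$asv_id, paste0("ASV", 1:4))
})

test_that("parentage attribution merges lineage calls", {
    mk <- function(vt) data.frame(asv_id = paste0("ASV", 1:4),
                                  pedigree = "A",
                                  vertically_transmitted = vt)
    st <- attributeParentage(mk(c(TRUE, TRUE, FALSE, FALSE)),
                             mk(c(TRUE, FALSE, TRUE, FALSE)))
    expect_identical(st$status, c("shared", "maternal", "paternal", "none"))
    expect_error(attributeParentage(mk(c(TRUE, TRUE, FALSE, FALSE)),
                                    mk(rep(TRUE, 4))[1:3, ]), "universe")
})

test_that("per-sample summaries report inherited fractions and flag empties", {
    cts <- matrix(c(6L, 3L, 1L, 0L,
                    0L, 0L, 0L, 0L), ncol = 2,
                  dimnames = list(paste0("ASV", 1:4), c("O1", "O2")))
    md <- data.frame(sample_id = c("O1", "O2"), pedigree = "A",
                     generation = "offspring", parental_role = "na",
                     caste = "worker", colony_id = "O", guts_pooled = 5L)
    pe <- suppressWarnings(PedigreeExperiment(cts, tinyTaxonomy(), md))
    calls <- data.frame(asv_id = paste0("ASV", 1:4), pedigree = "A",
                        vertically_transmitted = c(TRUE, TRUE, FALSE, FALSE))
    summ <- suppressWarnings(sampleInheritedSummary(pe, calls))
    o1 <- summ[summ$sample_id == "O1", ]
    expect_equal(o1$inherited_relabund_fraction, 0.9)  # (6+3)/10
    expect_equal(o1$inherited_asv_fraction, 2 / 3)     # 2 of 3 present
    o2 <- summ[summ$sample_id == "O2", ]
    expect_false(o2$defined)
    expect_true(is.na(o2$inherited_relabund_fraction))

    none <- calls; none$vertically_transmitted <- FALSE
    s0 <- suppressWarnings(sampleInheritedSummary(pe, none))
    expect_equal(s0$inherited_relabund_fraction[1], 0)
    expect_equal(s0$inherited_asv_fraction[1], 0)
})

test_that("pedigree sharing partitions the inherited union exhaustively", {
    calls <- expand.grid(asv_id = paste0("ASV", 1:6),
                         pedigree = c("A", "B", "C"),
                         stringsAsFactors = FALSE)
    calls$lineage <- "maternal"
    calls$vertically_transmitted <- with(calls, (asv_id == "ASV1") |
        (asv_id == "ASV2" & pedigree %in% c("A", "B")) |
        (asv_id == "ASV3" & pedigree == "C"))
    cells <- pedigreeSharing(calls)
    expect_identical(cells[["A+B+C"]], 1L)
    expect_identical(cells[["A+B"]], 1L)
    expect_identical(cells[["C"]], 1L)
    expect_identical(sum(cells), 3L)  # equals the inherited-ASV union
    expect_error(pedigreeSharing(calls[calls$pedigree == "A", ]), "2")
})

test_that("genus overlap is the intersection over the mean set size", {
    tax <- tinyTaxonomy(asv = paste0("ASV", 1:4),
                        genus = c("a", "b", "b", "c"))
    calls <- rbind(
        data.frame(asv_id = c("ASV1", "ASV2"), pedigree = "P1",
                   vertically_transmitted = TRUE),
        data.frame(asv_id = c("ASV3", "ASV4"), pedigree = "P2",
                   vertically_transmitted = TRUE))
    ov <- genusOverlap(calls, tax)
    expect_equal(ov["P1", "P2"], 0.5)  # {a,b} vs {b,c}
    expect_equal(diag(ov), c(P1 = 1, P2 = 1))
    expect_identical(ov["P1", "P2"], ov["P2", "P1"])

    disj <- calls
    disj$asv_id <- c("ASV1", "ASV1", "ASV4", "ASV4")
    disj$vertically_transmitted <- c(TRUE, TRUE, TRUE, TRUE)
    ov2 <- genusOverlap(disj[c(1, 4), ], tax)
    expect_equal(ov2["P1", "P2"], 0)

    empty <- calls
    empty$vertically_transmitted[3:4] <- FALSE
    expect_warning(ov3 <- genusOverlap(empty, tax), "P2")
    expect_true(is.na(ov3["P1", "P2"]))
})

test_that("retention is vertically transmitted over founder-transmitted", {
    calls <- data.frame(asv_id = sprintf("ASV%02d", 1:10), pedigree = "A",
                        lineage = "maternal",
                        transmitted_to_founders = TRUE,
                        vertically_transmitted = c(rep(TRUE, 8),
                                                   rep(FALSE, 2)))
    ret <- founderRetention(calls)
    expect_equal(ret$retention[ret$pedigree == "A"], 0.8)
    expect_equal(ret$retention[ret$pedigree == "pooled"], 0.8)
    all_kept <- calls; all_kept$vertically_transmitted <- TRUE
    expect_equal(founderRetention(all_kept)$retention[1], 1.0)
    expect_true(all(founderRetention(calls)$retention <= 1))
})

test_that("stage nesting and count monotonicity hold on random tables", {
    set.seed(7)
    for (i in 1:25) {
        cts <- matrix(rbinom(7 * 20, 4, 0.35), nrow = 20,
                      dimnames = list(sprintf("ASV%02d", 1:20), NULL))
        pat <- cts >= 1
        colnames(pat) <- c("PW1", "F1", "F2", "F3", "O1", "O2", "O3")
        pe <- patternExperiment(pat, nFounders = 3, nOffspring = 3)
        calls <- classifyVertical(pe, "A", "maternal")
        expect_true(all(calls$vertically_transmitted <=
                            calls$transmitted_to_founders))
        expect_true(all(calls$transmitted_to_founders <=
                            calls$present_in_parental_workers))

        # adding reads anywhere never revokes a transmitted call
        bumped <- counts(pe)
        idx <- sample(length(bumped), 12)
        bumped[idx] <- bumped[idx] + 5L
        pe2 <- PedigreeExperiment(bumped, taxonomy(pe), sampleMetadata(pe))
        calls2 <- classifyVertical(pe2, "A", "maternal")
        expect_true(all(calls2$vertically_transmitted >=
                            calls$vertically_transmitted))
    }
})
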