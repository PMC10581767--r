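# Small handcrafted pedigree dataset used across tests: one pedigree "A"
# with 1 maternal parental-worker, 2 maternal founder and 2 offspring
# samples (the minimal tier layout), plus a taxonomy of 2 genera.

tinyMetadata <- function() {
    data.frame(
        sample_id = c("PW1", "F1", "F2", "O1", "O2"),
        pedigree = "A",
        generation = c("parental", "founder", "founder", "offspring",
                       "offspring"),
        parental_role = c("maternal", "maternal", "maternal", "na", "na"),
        caste = c("worker", "alate", "alate", "worker", "worker"),
        colony_id = c("M", "C1", "C2", "O", "O"),
        guts_pooled = 5L)
}

tinyTaxonomy <- function(asv = paste0("ASV", 1:4),
                         genus = c("g1", "g1", "g2", "g2")) {
    data.frame(asv_id = asv, phylum = "p", class = "c", order = "o",
               family = "f", genus = genus)
}

tinyCounts <- function() {
    m <- matrix(c(10L, 5L, 0L, 1L,
                  8L, 2L, 1L, 0L,
                  6L, 3L, 2L, 0L,
                  0L, 4L, 5L, 0L,
                  1L, 0L, 6L, 2L), nrow = 5, byrow = TRUE,
                dimnames = list(c("PW1", "F1", "F2", "O1", "O2"),
                                paste0("ASV", 1:4)))
    m
}

tinyExperiment <- function() {
    PedigreeExperiment(tinyCounts(), tinyTaxonomy(), tinyMetadata())
}

# Build a PedigreeExperiment for one pedigree/lineage directly from a
# presence pattern (ASVs x samples logical matrix) using the tiny tier
# layout with `nFounders` founders and `nOffspring` offspring samples.
patternExperiment <- function(pattern, nFounders = 2, nOffspring = 2) {
    n_samp <- 1 + nFounders + nOffspring
    stopifnot(ncol(pattern) == n_samp)
    ids <- c("PW1", paste0("F", seq_len(nFounders)),
             paste0("O", seq_len(nOffspring)))
    colnames(pattern) <- ids
    if (is.null(rownames(pattern)))
        rownames(pattern) <- paste0("ASV", seq_len(nrow(pattern)))
    md <- data.frame(
        sample_id = ids, pedigree = "A",
        generation = c("parental", rep("founder", nFounders),
                       rep("offspring", nOffspring)),
        parental_role = c("maternal", rep("maternal", nFounders),
                          rep("na", nOffspring)),
        caste = c("worker", rep("alate", nFounders),
                  rep("worker", nOffspring)),
        colony_id = "X", guts_pooled = 5L)
    tax <- tinyTaxonomy(asv = rownames(pattern),
                        genus = rep("g1", nrow(pattern)))
    PedigreeExperiment(pattern * 1L, tax, md)
}

writeTinyDataset <- function(dir = tempfile()) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(counts = file.path(dir, "counts.tsv"),
                  taxonomy = file.path(dir, "taxonomy.tsv"),
                  metadata = file.path(dir, "metadata.tsv"))
    cts <- data.frame(sample_id = rownames(tinyCounts()), tinyCounts(),
                      check.names = FALSE)
    write.table(cts, paths$counts, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(tinyTaxonomy(), paths$taxonomy, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(tinyMetadata(), paths$metadata, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths
}
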