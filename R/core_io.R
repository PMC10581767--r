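#' Read an ASV dataset (counts, taxonomy, sample metadata)
#'
#' Reads the three tab-separated tables shared by all downstream stages and
#' cross-checks them: every counts sample must have metadata and every counts
#' ASV a taxonomy row (violations error); metadata samples absent from the
#' counts only warn. The counts table may have samples as rows (first column
#' `sample_id`) or ASVs as rows (first column `asv_id`); the orientation is
#' auto-detected. A BIOM file (`.biom`, JSON or HDF5) is accepted for the
#' counts when the `biomformat` package is available.
#'
#' @param countsPath path to the counts TSV (or `.biom`).
#' @param taxonomyPath path to the taxonomy TSV (`asv_id`, `phylum`, `class`,
#'   `order`, `family`, `genus`).
#' @param metadataPath path to the sample metadata TSV (`sample_id`,
#'   `pedigree`, `generation`, `parental_role`, `caste`, `colony_id`,
#'   `guts_pooled`).
#' @return A [PedigreeExperiment-class].
#' @export
readPedigreeDataset <- function(countsPath, taxonomyPath, metadataPath) {
    for (p in c(countsPath, taxonomyPath, metadataPath))
        if (!file.exists(p)) stop("missing file: ", p)
    counts <- .readCounts(countsPath)
    taxonomy <- read.delim(taxonomyPath, stringsAsFactors = FALSE,
                           check.names = FALSE)
    metadata <- read.delim(metadataPath, stringsAsFactors = FALSE,
                           check.names = FALSE)
    if ("asv_id" %in% colnames(taxonomy) && anyDuplicated(taxonomy$asv_id))
        stop("duplicate ASV ids in taxonomy")
    if ("sample_id" %in% colnames(metadata) &&
        anyDuplicated(metadata$sample_id))
        stop("duplicate sample ids in metadata")
    PedigreeExperiment(counts, taxonomy, metadata)
}

.readCounts <- function(path) {
    if (grepl("\\.biom$", path, ignore.case = TRUE)) {
        if (!requireNamespace("biomformat", quietly = TRUE))
            stop("reading BIOM counts requires the 'biomformat' package")
        b <- biomformat::read_biom(path)
        m <- as.matrix(biomformat::biom_data(b))  # observations x samples
        storage.mode(m) <- "double"
        return(.checkCountValues(m))
    }
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    idcol <- colnames(df)[1]
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    if (anyDuplicated(rownames(m)))
        stop("duplicate ids in counts first column ('", idcol, "')")
    if (!is.numeric(m)) stop("non-numeric values in counts table")
    .checkCountValues(m)
}

.checkCountValues <- function(m) {
    if (any(is.na(m))) stop("missing values in counts table")
    if (any(m < 0)) stop("negative count in counts table")
    if (any(m != round(m))) stop("non-integer count in counts table")
    m
}

#' Drop ASVs with fewer than `threshold` reads across the whole dataset
#'
#' The dataset-level abundance filter: an ASV is removed when its read total
#' over all samples is strictly below the threshold (default 25 reads).
#' Samples are always retained, even if left empty. Idempotent.
#'
#' @param x a [PedigreeExperiment-class].
#' @param threshold minimum dataset-wide read total to keep an ASV.
#' @return The filtered `PedigreeExperiment`.
#' @seealso [prefilterForNetwork()] for the network-specific default of 200.
#' @export
filterMinTotalReads <- function(x, threshold = 25) {
    stopifnot(threshold >= 0)
    keep <- rowSums(counts(x)) >= threshold
    if (!any(keep))
        warning("no ASV meets the ", threshold, "-read threshold")
    x[keep, ]
}

#' Per-sample relative abundances
#'
#' Divides each sample's counts by the sample total. Samples with zero total
#' reads become all-zero columns and are reported in the
#' `"zero_total_samples"` attribute (with a warning).
#'
#' @param x a [PedigreeExperiment-class] or a counts matrix (ASVs x samples).
#' @return Numeric matrix of fractions, same dimensions as the counts, with
#'   attribute `zero_total_samples`.
#' @export
relativeAbundance <- function(x) {
    cts <- if (methods::is(x, "SummarizedExperiment")) counts(x) else
        as.matrix(x)
    totals <- colSums(cts)
    zero <- colnames(cts)[totals == 0]
    if (length(zero))
        warning("zero-total sample(s): ", paste(zero, collapse = ", "))
    totals[totals == 0] <- 1
    out <- sweep(cts, 2, totals, "/")
    attr(out, "zero_total_samples") <- zero
    out
}

#' Presence/absence matrix
#'
#' Entry is `TRUE` when the read count reaches `minCount` (default 1 read;
#' presence means at least one read after dataset-level filtering).
#'
#' @param x a [PedigreeExperiment-class] or counts matrix (ASVs x samples).
#' @param minCount per-sample read threshold for presence, >= 1.
#' @return Logical matrix, ASVs x samples.
#' @export
presenceMatrix <- function(x, minCount = 1) {
    stopifnot(minCount >= 1)
    cts <- if (methods::is(x, "SummarizedExperiment")) counts(x) else
        as.matrix(x)
    cts >= minCount
}

#' Genus-level grouping labels
#'
#' Maps each ASV to its genus; ASVs with an unresolved genus are grouped as
#' `"unclassified_<lowest resolved rank value>"` (falling back through
#' family, order, class, phylum; `"unclassified_unknown"` if nothing is
#' resolved). This keeps genus-level counts exhaustive and disjoint.
#'
#' @param taxonomy data.frame of ranks as in [taxonomy()] (row names are
#'   ASV ids), or a [PedigreeExperiment-class].
#' @return Named character vector, one genus-group label per ASV.
#' @export
genusGroups <- function(taxonomy) {
    if (methods::is(taxonomy, "PedigreeExperiment"))
        taxonomy <- mbInherit::taxonomy(taxonomy)
    taxonomy <- .normalizeTaxonomy(taxonomy)
    out <- taxonomy$genus
    for (rk in rev(.TAXONOMY_RANKS[-length(.TAXONOMY_RANKS)])) {
        fill <- is.na(out) & !is.na(taxonomy[[rk]])
        out[fill] <- paste0("unclassified_", taxonomy[[rk]][fill])
    }
    out[is.na(out)] <- "unclassified_unknown"
    names(out) <- rownames(taxonomy)
    out
}

#' Write the three dataset tables as TSV
#'
#' Writes counts (samples as rows, first column `sample_id`), taxonomy and
#' sample metadata in the dialect accepted by [readPedigreeDataset()].
#'
#' @param x a [PedigreeExperiment-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the three file paths.
#' @export
writePedigreeDataset <- function(x, dir, prefix = "dataset") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, paste0(prefix, "_",
                                   c("counts", "taxonomy", "metadata"),
                                   ".tsv"))
    cts <- data.frame(sample_id = sampleIds(x), t(counts(x)),
                      check.names = FALSE)
    write.table(cts, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
    tax <- data.frame(asv_id = asvIds(x), taxonomy(x), check.names = FALSE)
    write.table(tax, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
    md <- data.frame(sample_id = sampleIds(x), sampleMetadata(x),
                     check.names = FALSE)
    write.table(md, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(stats::setNames(paths, c("counts", "taxonomy", "metadata")))
}
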