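#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rgamma rmultinom rlnorm rbinom runif rnorm rgeom setNames
#' @importFrom utils read.delim write.table combn head
NULL

.GENERATIONS <- c("parental", "founder", "offspring")
.ROLES <- c("maternal", "paternal", "na")
.CASTES <- c("worker", "queen", "king", "larva", "alate")
.METADATA_COLS <- c("pedigree", "generation", "parental_role", "caste",
                    "colony_id", "guts_pooled")
.TAXONOMY_RANKS <- c("phylum", "class", "order", "family", "genus")

#' PedigreeExperiment: ASV counts with taxonomy and pedigree metadata
#'
#' An extension of [SummarizedExperiment::SummarizedExperiment] holding an ASV
#' read-count matrix (`counts` assay, ASVs as rows, samples as columns),
#' per-ASV taxonomy (`rowData`: phylum, class, order, family, genus;
#' unresolved ranks are `NA`) and per-sample pedigree metadata (`colData`:
#' `pedigree`, `generation` in parental/founder/offspring, `parental_role` in
#' maternal/paternal/na, `caste`, `colony_id`, `guts_pooled`).
#'
#' Validity requires non-negative integral counts, unique non-empty ASV and
#' sample identifiers, the metadata columns above with their allowed levels,
#' `guts_pooled >= 1`, and that founder and offspring samples carry a
#' pedigree (founders additionally a maternal/paternal role).
#'
#' @export
setClass("PedigreeExperiment", contains = "SummarizedExperiment")

.validPedigreeExperiment <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(is.na(cts)))
            msg <- c(msg, "counts contain NA")
        else {
            if (any(cts < 0)) msg <- c(msg, "negative count")
            if (any(cts != round(cts))) msg <- c(msg, "non-integer count")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)) ||
        any(!nzchar(rownames(object))))
        msg <- c(msg, "ASV ids must be unique and non-empty")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)) ||
        any(!nzchar(colnames(object))))
        msg <- c(msg, "sample ids must be unique and non-empty")
    cd <- SummarizedExperiment::colData(object)
    missing_cols <- setdiff(.METADATA_COLS, colnames(cd))
    if (length(missing_cols))
        msg <- c(msg, paste0("missing metadata column(s): ",
                             paste(missing_cols, collapse = ", ")))
    else {
        if (!all(cd$generation %in% .GENERATIONS))
            msg <- c(msg, "generation must be parental, founder or offspring")
        if (!all(cd$parental_role %in% .ROLES))
            msg <- c(msg, "parental_role must be maternal, paternal or na")
        if (!all(cd$caste %in% .CASTES))
            msg <- c(msg, paste0("caste must be one of: ",
                                 paste(.CASTES, collapse = ", ")))
        if (any(is.na(cd$guts_pooled)) || any(cd$guts_pooled < 1))
            msg <- c(msg, "guts_pooled must be >= 1")
        fo <- cd$generation == "founder"
        if (any(fo & (is.na(cd$pedigree) | cd$parental_role == "na")))
            msg <- c(msg, "founder samples need a pedigree and a parental_role")
        of <- cd$generation == "offspring"
        if (any(of & is.na(cd$pedigree)))
            msg <- c(msg, "offspring samples need a pedigree")
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!all(.TAXONOMY_RANKS %in% colnames(rd)))
        msg <- c(msg, paste0("missing taxonomy rank column(s): ",
                             paste(setdiff(.TAXONOMY_RANKS, colnames(rd)),
                                   collapse = ", ")))
    if (length(msg)) msg else TRUE
}

setValidity("PedigreeExperiment", .validPedigreeExperiment)

#' Construct a PedigreeExperiment
#'
#' @param counts integer matrix of read counts; orientation is auto-detected
#'   from the dimnames against `metadata` row names (samples may be rows or
#'   columns; stored internally as ASVs x samples).
#' @param taxonomy data.frame with row names (or column `asv_id`) matching
#'   the ASV ids, and columns `phylum`, `class`, `order`, `family`, `genus`.
#'   Unresolved ranks may be `NA` or empty strings (converted to `NA`).
#' @param metadata data.frame with row names (or column `sample_id`) matching
#'   the sample ids, and columns `pedigree`, `generation`, `parental_role`,
#'   `caste`, `colony_id`, `guts_pooled`. A pedigree of `"none"` or `""` is
#'   converted to `NA`.
#' @return A [PedigreeExperiment-class] object.
#' @examples
#' cts <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'               dimnames = list(c("ASV1", "ASV2"), c("S1", "S2")))
#' tax <- data.frame(row.names = c("ASV1", "ASV2"), phylum = "p1",
#'                   class = "c1", order = "o1", family = "f1",
#'                   genus = c("g1", "g2"))
#' md <- data.frame(row.names = c("S1", "S2"),
#'                  pedigree = c("red", "red"),
#'                  generation = c("parental", "offspring"),
#'                  parental_role = c("maternal", "na"),
#'                  caste = "worker", colony_id = c("M1", "O1"),
#'                  guts_pooled = 5L)
#' pe <- PedigreeExperiment(cts, tax, md)
#' @export
PedigreeExperiment <- function(counts, taxonomy, metadata) {
    metadata <- .normalizeMetadata(metadata)
    taxonomy <- .normalizeTaxonomy(taxonomy)
    counts <- .orientCounts(counts, rownames(metadata))

    asv_ids <- rownames(counts)
    sample_ids <- colnames(counts)
    extra_md <- setdiff(sample_ids, rownames(metadata))
    if (length(extra_md))
        stop("count sample(s) absent from metadata: ",
             paste(extra_md, collapse = ", "))
    unused_md <- setdiff(rownames(metadata), sample_ids)
    if (length(unused_md))
        warning("metadata sample(s) absent from counts: ",
                paste(unused_md, collapse = ", "))
    extra_tax <- setdiff(asv_ids, rownames(taxonomy))
    if (length(extra_tax))
        stop("count ASV(s) absent from taxonomy: ",
             paste(head(extra_tax, 5), collapse = ", "))

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(taxonomy[asv_ids, , drop = FALSE]),
        colData = S4Vectors::DataFrame(metadata[sample_ids, , drop = FALSE]))
    methods::new("PedigreeExperiment", se)
}

.normalizeMetadata <- function(metadata) {
    metadata <- as.data.frame(metadata)
    if ("sample_id" %in% colnames(metadata)) {
        rownames(metadata) <- as.character(metadata$sample_id)
        metadata$sample_id <- NULL
    }
    missing_cols <- setdiff(.METADATA_COLS, colnames(metadata))
    if (length(missing_cols))
        stop("missing metadata column(s): ",
             paste(missing_cols, collapse = ", "))
    ped <- as.character(metadata$pedigree)
    ped[!is.na(ped) & (ped == "none" | ped == "")] <- NA_character_
    metadata$pedigree <- ped
    metadata$parental_role <- as.character(metadata$parental_role)
    metadata$parental_role[is.na(metadata$parental_role)] <- "na"
    metadata
}

.normalizeTaxonomy <- function(taxonomy) {
    taxonomy <- as.data.frame(taxonomy)
    if ("asv_id" %in% colnames(taxonomy)) {
        rownames(taxonomy) <- as.character(taxonomy$asv_id)
        taxonomy$asv_id <- NULL
    }
    missing_cols <- setdiff(.TAXONOMY_RANKS, colnames(taxonomy))
    if (length(missing_cols))
        stop("missing taxonomy rank column(s): ",
             paste(missing_cols, collapse = ", "))
    for (rk in .TAXONOMY_RANKS) {
        v <- as.character(taxonomy[[rk]])
        v[!is.na(v) & v == ""] <- NA_character_
        taxonomy[[rk]] <- v
    }
    taxonomy
}

# Decide which axis of `counts` holds samples by matching dimnames against
# the metadata sample ids; ties resolve to samples-as-columns.
.orientCounts <- function(counts, sample_ids) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have row and column names")
    hit_cols <- mean(colnames(counts) %in% sample_ids)
    hit_rows <- mean(rownames(counts) %in% sample_ids)
    if (hit_rows > hit_cols) counts <- t(counts)
    if (is.double(counts)) {
        if (any(is.na(counts)) || any(counts != round(counts)))
            stop("non-integer count")
        storage.mode(counts) <- "integer"
    }
    counts
}

#' @describeIn PedigreeExperiment-class Read-count matrix (ASVs x samples).
#' @param x,object A `PedigreeExperiment`.
#' @param ... ignored.
#' @importFrom BiocGenerics counts
#' @exportMethod counts
setMethod("counts", "PedigreeExperiment",
          function(object, ...) SummarizedExperiment::assay(object, "counts"))

#' @describeIn PedigreeExperiment-class ASV identifiers.
#' @export
asvIds <- function(x) rownames(x)

#' @describeIn PedigreeExperiment-class Sample identifiers.
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn PedigreeExperiment-class Taxonomy table as a data.frame.
#' @export
taxonomy <- function(x)
    as.data.frame(SummarizedExperiment::rowData(x))[, .TAXONOMY_RANKS,
                                                    drop = FALSE]

#' @describeIn PedigreeExperiment-class Sample metadata as a data.frame.
#' @export
sampleMetadata <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn PedigreeExperiment-class Pedigree labels present in the data.
#' @export
pedigrees <- function(x) {
    p <- SummarizedExperiment::colData(x)$pedigree
    sort(unique(p[!is.na(p)]))
}

setMethod("show", "PedigreeExperiment", function(object) {
    cat("class: PedigreeExperiment\n")
    cat("dim:", nrow(object), "ASVs x", ncol(object), "samples\n")
    cd <- SummarizedExperiment::colData(object)
    cat("pedigrees:", paste(pedigrees(object), collapse = ", "), "\n")
    cat("tiers:",
        paste(names(table(cd$generation)), table(cd$generation),
              sep = "=", collapse = ", "), "\n")
    cat("total reads:", sum(counts(object)), "\n")
})

#' SignedNetwork: undirected ASV graph with signed edges
#'
#' Nodes are ASV identifiers; edges are unordered node pairs carrying a sign
#' (`"positive"` for co-occurrence, `"negative"` for co-exclusion) and an
#' optional weight. Self-loops and duplicate pairs are invalid; isolated
#' nodes are allowed (and preserved by [subsetBySign()]).
#'
#' @slot nodes character vector of node (ASV) identifiers.
#' @slot edges data.frame with columns `from`, `to`, `sign`, `weight`.
#' @export
setClass("SignedNetwork",
         representation(nodes = "character", edges = "data.frame"))

.validSignedNetwork <- function(object) {
    msg <- character()
    ed <- object@edges
    if (!all(c("from", "to", "sign", "weight") %in% colnames(ed)))
        return("edges need columns from, to, sign, weight")
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicate node ids")
    if (nrow(ed)) {
        if (!all(ed$sign %in% c("positive", "negative")))
            msg <- c(msg, "edge sign must be 'positive' or 'negative'")
        if (any(ed$from == ed$to))
            msg <- c(msg, "self-loops are not allowed")
        bad <- setdiff(c(ed$from, ed$to), object@nodes)
        if (length(bad))
            msg <- c(msg, paste0("edge endpoint(s) not in nodes: ",
                                 paste(head(bad, 5), collapse = ", ")))
        key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate edge (unordered pair)")
    }
    if (length(msg)) msg else TRUE
}

setValidity("SignedNetwork", .validSignedNetwork)

#' Construct a SignedNetwork
#'
#' @param edges data.frame with columns `from`, `to`, `sign` and optionally
#'   `weight` (defaults to 1).
#' @param nodes optional node id vector; defaults to the union of edge
#'   endpoints. Extra ids give isolated nodes.
#' @return A [SignedNetwork-class].
#' @export
SignedNetwork <- function(edges = data.frame(from = character(),
                                             to = character(),
                                             sign = character()),
                          nodes = NULL) {
    edges <- as.data.frame(edges)
    if (!"weight" %in% colnames(edges))
        edges$weight <- rep(1, nrow(edges))
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$sign <- as.character(edges$sign)
    if (is.null(nodes))
        nodes <- unique(c(edges$from, edges$to))
    methods::new("SignedNetwork", nodes = as.character(nodes),
                 edges = edges[, c("from", "to", "sign", "weight")])
}

#' @describeIn SignedNetwork-class Node identifiers.
#' @param x,object A `SignedNetwork`.
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn SignedNetwork-class Edge table (`from`, `to`, `sign`, `weight`).
#' @export
networkEdges <- function(x) x@edges

setMethod("show", "SignedNetwork", function(object) {
    tab <- table(factor(object@edges$sign, c("positive", "negative")))
    cat("class: SignedNetwork\n")
    cat(length(object@nodes), "nodes,", nrow(object@edges), "edges (",
        tab[["positive"]], "positive /", tab[["negative"]], "negative )\n")
})

#' NullDraws: iterated abundance-weighted ASV selections
#'
#' The resampling null for inheritance: each iteration draws `nSelect`
#' distinct ASVs without replacement, with selection probability at each
#' sequential draw proportional to the supplied weights (mean relative
#' abundance in maternal workers), renormalized over the remaining pool.
#'
#' @slot draws list of character vectors, one ASV-id set per iteration.
#' @slot nSelect integer, set size per draw.
#' @slot iterations integer, number of draws.
#' @slot seed integer seed the draws were generated from.
#' @slot weightSource label recording which abundances weighted the draws.
#' @export
setClass("NullDraws",
         representation(draws = "list", nSelect = "integer",
                        iterations = "integer", seed = "integer",
                        weightSource = "character"))

.validNullDraws <- function(object) {
    msg <- character()
    if (length(object@draws) != object@iterations)
        msg <- c(msg, "length(draws) must equal iterations")
    sizes <- lengths(object@draws)
    if (length(sizes) && any(sizes != object@nSelect))
        msg <- c(msg, "every draw must have exactly nSelect ASVs")
    if (any(vapply(object@draws, anyDuplicated, 1L) > 0))
        msg <- c(msg, "draws must contain distinct ASVs")
    if (length(msg)) msg else TRUE
}

setValidity("NullDraws", .validNullDraws)

setMethod("show", "NullDraws", function(object) {
    cat("class: NullDraws\n")
    cat(object@iterations, "iterations of", object@nSelect,
        "ASVs (seed", paste0(object@seed, ","), "weights:",
        object@weightSource, ")\n")
})

#' @describeIn NullDraws-class The list of drawn ASV-id sets.
#' @param x,object A `NullDraws`.
#' @export
nullDrawSets <- function(x) x@draws

# Run code under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}
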