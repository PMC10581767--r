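#' Classify vertical transmission of every ASV in one pedigree and lineage
#'
#' Applies the strict inheritance rule: an ASV is transmitted to the founding
#' reproductives when it is present in at least one parental colony sample of
#' the lineage AND in every founding-reproductive sample of that lineage and
#' pedigree; it is vertically transmitted when, in addition, it is present in
#' at least one offspring colony sample of the pedigree.
#'
#' Parental-colony presence is evaluated on worker samples by default, since
#' workers house most of the colony microbiome; set `parentalCastes` to
#' include royals. Parental samples of the maternal lineage are matched by
#' pedigree; a parental colony recorded without a pedigree (the shared
#' paternal colony) matches every pedigree.
#'
#' @param x a [PedigreeExperiment-class], or a logical presence matrix
#'   (ASVs x samples) when `metadata` is supplied.
#' @param pedigree pedigree label to classify.
#' @param lineage `"maternal"` or `"paternal"`.
#' @param metadata sample metadata data.frame (only when `x` is a matrix).
#' @param minCount presence threshold in reads (when `x` holds counts).
#' @param parentalCastes castes defining parental-colony presence.
#' @return data.frame with one row per ASV: `asv_id`, `pedigree`, `lineage`,
#'   `present_in_parental_workers`, `in_all_founders`, `in_any_offspring`,
#'   `transmitted_to_founders`, `vertically_transmitted`.
#' @examples
#' sim <- simulatePedigreeDataset(simParams(nPedigrees = 2, seed = 1))
#' calls <- classifyVertical(sim$experiment, pedigree = "red",
#'                           lineage = "maternal")
#' table(calls$vertically_transmitted)
#' @export
classifyVertical <- function(x, pedigree, lineage = c("maternal", "paternal"),
                             metadata = NULL, minCount = 1,
                             parentalCastes = "worker") {
    lineage <- match.arg(lineage)
    if (methods::is(x, "PedigreeExperiment")) {
        metadata <- sampleMetadata(x)
        pres <- presenceMatrix(x, minCount)
    } else {
        if (is.null(metadata))
            stop("metadata is required when x is a matrix")
        metadata <- .normalizeMetadata(metadata)
        pres <- as.matrix(x)
        if (!is.logical(pres)) pres <- pres >= minCount
    }
    metadata <- metadata[colnames(pres), , drop = FALSE]

    ped <- metadata$pedigree
    in_ped <- !is.na(ped) & ped == pedigree
    parental <- metadata$generation == "parental" &
        metadata$parental_role == lineage &
        metadata$caste %in% parentalCastes &
        (is.na(ped) | ped == pedigree)
    founder <- metadata$generation == "founder" &
        metadata$parental_role == lineage & in_ped
    offspring <- metadata$generation == "offspring" & in_ped

    for (tier in c("parental", "founder", "offspring")) {
        if (!any(get(tier)))
            stop("no ", tier, " sample for pedigree '", pedigree,
                 "', lineage '", lineage, "'")
    }

    in_parental <- rowSums(pres[, parental, drop = FALSE]) > 0
    in_all_founders <- rowSums(pres[, founder, drop = FALSE]) == sum(founder)
    in_any_offspring <- rowSums(pres[, offspring, drop = FALSE]) > 0
    ttf <- in_parental & in_all_founders
    data.frame(asv_id = rownames(pres), pedigree = pedigree,
               lineage = lineage,
               present_in_parental_workers = in_parental,
               in_all_founders = in_all_founders,
               in_any_offspring = in_any_offspring,
               transmitted_to_founders = ttf,
               vertically_transmitted = ttf & in_any_offspring,
               row.names = NULL)
}

#' Classify all pedigrees and lineages at once
#'
#' @inheritParams classifyVertical
#' @param lineages lineages to classify (default both).
#' @return Row-bound data.frame of [classifyVertical()] calls.
#' @export
classifyAllPedigrees <- function(x, lineages = c("maternal", "paternal"),
                                 minCount = 1, parentalCastes = "worker") {
    out <- lapply(pedigrees(x), function(p)
        do.call(rbind, lapply(lineages, function(l)
            classifyVertical(x, p, l, minCount = minCount,
                             parentalCastes = parentalCastes))))
    do.call(rbind, out)
}

#' Attribute parentage of vertically transmitted ASVs
#'
#' Merges maternal and paternal calls for one pedigree into a single status:
#' `shared` when vertically transmitted under both lineages, `maternal` or
#' `paternal` when under exactly one, `none` otherwise.
#'
#' @param maternalCalls,paternalCalls outputs of [classifyVertical()] for the
#'   same pedigree and ASV universe.
#' @return data.frame with `asv_id`, `pedigree`, `status`.
#' @export
attributeParentage <- function(maternalCalls, paternalCalls) {
    if (nrow(maternalCalls) != nrow(paternalCalls) ||
        !setequal(maternalCalls$asv_id, paternalCalls$asv_id))
        stop("maternal and paternal calls cover different ASV universes")
    if (!all(maternalCalls$pedigree == paternalCalls$pedigree[1]) ||
        !all(paternalCalls$pedigree == paternalCalls$pedigree[1]))
        stop("calls mix pedigrees")
    paternalCalls <- paternalCalls[match(maternalCalls$asv_id,
                                         paternalCalls$asv_id), ]
    m <- maternalCalls$vertically_transmitted
    p <- paternalCalls$vertically_transmitted
    status <- ifelse(m & p, "shared",
                     ifelse(m, "maternal", ifelse(p, "paternal", "none")))
    data.frame(asv_id = maternalCalls$asv_id,
               pedigree = maternalCalls$pedigree,
               status = status, row.names = NULL)
}

.inheritedSet <- function(calls) {
    if ("status" %in% colnames(calls))
        unique(calls$asv_id[calls$status != "none"])
    else
        unique(calls$asv_id[calls$vertically_transmitted])
}

#' Per-sample inherited-microbiome summary
#'
#' For each sample, the fraction of its relative abundance and the fraction
#' of its present ASVs that are vertically transmitted (per the supplied
#' calls). Samples with no ASV present are flagged undefined (`NA`).
#'
#' @param x a [PedigreeExperiment-class].
#' @param calls output of [classifyVertical()] / [classifyAllPedigrees()] or
#'   [attributeParentage()]; the inherited set is `vertically_transmitted`
#'   ASVs (or `status != "none"`).
#' @param samples sample ids to summarize; defaults to all samples of the
#'   pedigree(s) appearing in `calls`.
#' @param minCount presence threshold in reads.
#' @return data.frame with `sample_id`, `generation`, `pedigree`,
#'   `n_present`, `n_inherited_present`, `inherited_relabund_fraction`,
#'   `inherited_asv_fraction`, `defined`.
#' @export
sampleInheritedSummary <- function(x, calls, samples = NULL, minCount = 1) {
    md <- sampleMetadata(x)
    if (is.null(samples)) {
        peds <- unique(calls$pedigree)
        samples <- sampleIds(x)[!is.na(md$pedigree) & md$pedigree %in% peds]
    }
    inherited <- .inheritedSet(calls)
    pres <- presenceMatrix(x, minCount)[, samples, drop = FALSE]
    rel <- suppressWarnings(relativeAbundance(x))[, samples, drop = FALSE]
    is_inh <- rownames(pres) %in% inherited

    n_present <- colSums(pres)
    n_inh <- colSums(pres & is_inh)
    rel_frac <- colSums(rel * (pres & is_inh))
    asv_frac <- ifelse(n_present > 0, n_inh / n_present, NA_real_)
    rel_frac[n_present == 0] <- NA_real_
    data.frame(sample_id = samples,
               generation = md[samples, "generation"],
               pedigree = md[samples, "pedigree"],
               n_present = as.integer(n_present),
               n_inherited_present = as.integer(n_inh),
               inherited_relabund_fraction = rel_frac,
               inherited_asv_fraction = asv_frac,
               defined = n_present > 0, row.names = NULL)
}

#' Partition of inherited ASVs by pedigree combination
#'
#' Assigns every vertically transmitted ASV to the exact set of pedigrees it
#' was inherited in (a power-set cell, e.g. `"red"` for pedigree-specific
#' ASVs, `"blue+green+red+yellow"` for the ubiquitous cell). Cells are
#' disjoint and sum to the size of the inherited-ASV union.
#'
#' @param calls combined calls across pedigrees ([classifyAllPedigrees()]).
#' @param lineage optional lineage filter (`"maternal"` or `"paternal"`).
#' @return Named integer vector of cell counts.
#' @export
pedigreeSharing <- function(calls, lineage = NULL) {
    if (!is.null(lineage))
        calls <- calls[calls$lineage == lineage, ]
    if (length(unique(calls$pedigree)) < 2)
        stop("pedigree sharing needs calls from at least 2 pedigrees")
    vt <- calls[calls$vertically_transmitted, c("asv_id", "pedigree")]
    vt <- unique(vt)
    if (!nrow(vt)) return(integer())
    cells <- vapply(split(vt$pedigree, vt$asv_id),
                    function(p) paste(sort(unique(p)), collapse = "+"), "")
    tab <- table(cells)
    stats::setNames(as.integer(tab), names(tab))
}

#' Pairwise overlap of inherited genera between pedigrees
#'
#' For pedigrees i and j with inherited genus sets G_i, G_j (genera holding
#' at least one vertically transmitted ASV, after unclassified grouping),
#' the overlap is |G_i intersect G_j| / mean(|G_i|, |G_j|). Symmetric, with
#' unit diagonal; a pedigree with no inherited genus gives `NA` cells.
#'
#' @param calls combined calls across pedigrees.
#' @param taxonomy taxonomy data.frame or [PedigreeExperiment-class].
#' @param lineage optional lineage filter.
#' @return Numeric matrix, pedigrees x pedigrees.
#' @export
genusOverlap <- function(calls, taxonomy, lineage = NULL) {
    if (!is.null(lineage))
        calls <- calls[calls$lineage == lineage, ]
    groups <- genusGroups(taxonomy)
    peds <- sort(unique(calls$pedigree))
    gsets <- lapply(peds, function(p) {
        ids <- unique(calls$asv_id[calls$pedigree == p &
                                   calls$vertically_transmitted])
        unique(groups[ids])
    })
    names(gsets) <- peds
    empty <- peds[lengths(gsets) == 0]
    if (length(empty))
        warning("pedigree(s) with no inherited genus: ",
                paste(empty, collapse = ", "))
    out <- matrix(NA_real_, length(peds), length(peds),
                  dimnames = list(peds, peds))
    for (i in seq_along(peds)) for (j in seq_along(peds)) {
        gi <- gsets[[i]]; gj <- gsets[[j]]
        if (length(gi) > 0 && length(gj) > 0)
            out[i, j] <- length(intersect(gi, gj)) /
                mean(c(length(gi), length(gj)))
    }
    diag(out)[lengths(gsets) > 0] <- 1
    out
}

#' Retention of founder-transmitted ASVs in offspring colonies
#'
#' The fraction of ASVs transmitted to founding reproductives that are also
#' detected in offspring colonies: vertically transmitted /
#' founder-transmitted, per pedigree-lineage and pooled over all calls.
#'
#' @param calls output of [classifyVertical()] or [classifyAllPedigrees()].
#' @return data.frame with `pedigree`, `lineage`, `n_founder_transmitted`,
#'   `n_vertically_transmitted`, `retention` (NA when nothing reached the
#'   founders), ending with a `pooled` row.
#' @export
founderRetention <- function(calls) {
    grp <- interaction(calls$pedigree, calls$lineage, drop = TRUE)
    rows <- lapply(levels(grp), function(g) {
        cc <- calls[grp == g, ]
        data.frame(pedigree = cc$pedigree[1], lineage = cc$lineage[1],
                   n_founder_transmitted = sum(cc$transmitted_to_founders),
                   n_vertically_transmitted = sum(cc$vertically_transmitted))
    })
    out <- do.call(rbind, rows)
    out <- rbind(out, data.frame(
        pedigree = "pooled", lineage = "all",
        n_founder_transmitted = sum(calls$transmitted_to_founders),
        n_vertically_transmitted = sum(calls$vertically_transmitted)))
    out$retention <- ifelse(out$n_founder_transmitted > 0,
                            out$n_vertically_transmitted /
                                out$n_founder_transmitted, NA_real_)
    if (all(calls$transmitted_to_founders == 0))
        warning("no founder-transmitted ASV; retention undefined")
    out
}
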