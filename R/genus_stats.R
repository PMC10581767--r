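#' Center ASV abundances within their genus
#'
#' Normalizes each ASV's (mean) relative abundance in a sample context by
#' subtracting the mean relative abundance of its genus group, so values
#' express how an ASV ranks against congeners. Within every genus the
#' centered values sum to zero.
#'
#' @param relabund named numeric vector: per-ASV mean relative abundance in
#'   one context (e.g. maternal workers, founders or offspring workers; see
#'   [maternalWorkerWeights()]).
#' @param taxonomy taxonomy data.frame or [PedigreeExperiment-class].
#' @param context optional label recorded in the output.
#' @return data.frame with `asv_id`, `genus`, `context`, `relabund`,
#'   `centered`.
#' @export
centerWithinGenus <- function(relabund, taxonomy, context = NA_character_) {
    if (is.null(names(relabund))) stop("relabund must be named by ASV id")
    groups <- genusGroups(taxonomy)
    missing <- setdiff(names(relabund), names(groups))
    if (length(missing))
        stop("taxonomy does not cover ASV(s): ",
             paste(head(missing, 5), collapse = ", "))
    genus <- groups[names(relabund)]
    centered <- relabund - stats::ave(relabund, genus)
    data.frame(asv_id = names(relabund), genus = unname(genus),
               context = context, relabund = unname(relabund),
               centered = unname(centered), row.names = NULL)
}

#' Signed-log transform for centered abundances
#'
#' The visualization transform y(x) = sign(x) * log(1 + |x| / scale) with
#' natural logarithm and scale 1e-5: odd, monotone increasing, near-linear
#' below the scale and logarithmic above it, so that centered abundances of
#' both signs can share an axis.
#'
#' @param x numeric vector (centered abundances, may be negative).
#' @param scale linearization constant (default 1e-5).
#' @return Transformed numeric vector.
#' @examples
#' signedLogTransform(c(-1e-5, 0, 1e-5))  # -log(2), 0, log(2)
#' @export
signedLogTransform <- function(x, scale = 1e-5) {
    sign(x) * log1p(abs(x) / scale)
}

#' Stratified permutation test: does within-genus abundance predict
#' transmission?
#'
#' Tests whether genus-centered abundance differs between transmitted and
#' non-transmitted ASVs while controlling for pedigree and genus: the
#' statistic is the mean centered abundance of transmitted minus
#' non-transmitted ASVs, and the null is built by shuffling the transmission
#' labels within each (pedigree, genus) stratum, which preserves per-stratum
#' label counts. Strata containing a single label class cannot inform the
#' comparison and are dropped with a warning.
#'
#' @param values numeric vector of centered abundances (see
#'   [centerWithinGenus()]; the test may equally be run on
#'   [signedLogTransform()]ed values).
#' @param labels logical vector, `TRUE` for transmitted ASVs.
#' @param strata factor/character vector of stratum ids (pedigree x genus).
#' @param nPerm number of label permutations.
#' @param seed integer seed.
#' @param alternative passed to [permutationPvalue()] (default two-sided).
#' @return list with `statistic` (observed mean difference), `null_values`,
#'   `p_raw`, `p_add_one`, `p`, `n_transmitted`, `n_not`, `n_strata_used`.
#' @export
transmissionAssociation <- function(values, labels, strata, nPerm = 1000,
                                    seed, alternative = "two_sided") {
    stopifnot(length(values) == length(labels),
              length(values) == length(strata))
    labels <- as.logical(labels)
    if (!any(labels) || all(labels))
        stop("both label classes must be non-empty")
    strata <- as.character(strata)
    informative <- stats::ave(labels, strata,
                              FUN = function(l) any(l) && !all(l))
    if (!any(informative))
        stop("all strata contain a single label class")
    if (!all(informative))
        warning(length(unique(strata[!informative])),
                " stratum/strata with a single label class contribute nothing")
    v <- values[informative]
    l <- labels[informative]
    s <- strata[informative]

    stat <- function(lab) mean(v[lab]) - mean(v[!lab])
    observed <- stat(l)
    idx <- split(seq_along(v), s)
    null_values <- .withSeed(seed, vapply(seq_len(nPerm), function(i) {
        perm <- l
        for (ii in idx) perm[ii] <- l[ii][sample.int(length(ii))]
        stat(perm)
    }, 1.0))
    res <- permutationPvalue(observed, null_values, alternative)
    list(statistic = observed, null_values = null_values,
         p_raw = res$p_raw, p_add_one = res$p_add_one, p = res$p,
         alternative = res$alternative,
         n_transmitted = sum(l), n_not = sum(!l),
         n_strata_used = length(idx), seed = as.integer(seed))
}
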