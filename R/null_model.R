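#' Abundance-weighted null draws of ASV sets
#'
#' The abundance-driven null model: each iteration selects `nSelect` distinct
#' ASVs from those with positive weight, by sequential weighted sampling
#' without replacement (probability proportional to weight at each draw,
#' renormalized over the remaining pool). Weights are the mean relative
#' abundances of ASVs in maternal colony workers, so the null represents
#' inheritance driven by abundance alone; 100 iterations by default.
#'
#' @param weights named non-negative numeric vector, one weight per ASV.
#' @param nSelect number of ASVs per draw (the observed inherited-set size).
#' @param iterations number of null iterations.
#' @param seed integer seed; draws are reproducible from it.
#' @param weightSource label recorded in the result.
#' @return A [NullDraws-class].
#' @examples
#' d <- drawNullSets(c(A = .7, B = .2, C = .1), nSelect = 2,
#'                   iterations = 10, seed = 1)
#' nullDrawSets(d)[[1]]
#' @export
drawNullSets <- function(weights, nSelect, iterations = 100, seed,
                         weightSource = "maternal_worker_relabund") {
    if (is.null(names(weights)) || anyDuplicated(names(weights)))
        stop("weights must be uniquely named by ASV id")
    if (any(weights < 0)) stop("negative weight")
    pool <- names(weights)[weights > 0]
    if (!length(pool)) stop("all weights are zero")
    if (nSelect > length(pool))
        stop("nSelect (", nSelect, ") exceeds the positive-weight pool (",
             length(pool), ")")
    stopifnot(nSelect >= 1, iterations >= 1)
    w <- weights[pool]
    draws <- .withSeed(seed, replicate(
        iterations, sample(pool, nSelect, replace = FALSE, prob = w),
        simplify = FALSE))
    draws <- lapply(draws, as.character)
    methods::new("NullDraws", draws = draws, nSelect = as.integer(nSelect),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 weightSource = weightSource)
}

#' Mean relative abundance per ASV within a sample group
#'
#' Convenience weight source for [drawNullSets()]: the per-ASV mean relative
#' abundance over the selected samples (default: maternal parental workers
#' of a pedigree).
#'
#' @param x a [PedigreeExperiment-class].
#' @param pedigree pedigree whose maternal workers to average over; ignored
#'   when `samples` is given.
#' @param samples explicit sample ids to average over.
#' @return Named numeric vector of mean relative abundances.
#' @export
maternalWorkerWeights <- function(x, pedigree = NULL, samples = NULL) {
    if (is.null(samples)) {
        md <- sampleMetadata(x)
        sel <- md$generation == "parental" & md$parental_role == "maternal" &
            md$caste == "worker"
        if (!is.null(pedigree))
            sel <- sel & !is.na(md$pedigree) & md$pedigree == pedigree
        samples <- sampleIds(x)[sel]
    }
    if (!length(samples)) stop("no maternal worker sample selected")
    rel <- suppressWarnings(relativeAbundance(x))[, samples, drop = FALSE]
    rowMeans(rel)
}

#' Genus richness of each null draw
#'
#' Counts the distinct genus groups (see [genusGroups()]) represented in each
#' iteration's drawn ASV set, giving the null distribution against which the
#' observed number of inherited genera is compared.
#'
#' @param draws a [NullDraws-class].
#' @param taxonomy taxonomy data.frame or [PedigreeExperiment-class] covering
#'   all drawn ASVs.
#' @return Integer vector, one genus count per iteration.
#' @export
genusRichnessDistribution <- function(draws, taxonomy) {
    groups <- genusGroups(taxonomy)
    missing <- setdiff(unique(unlist(nullDrawSets(draws))), names(groups))
    if (length(missing))
        stop("taxonomy does not cover drawn ASV(s): ",
             paste(head(missing, 5), collapse = ", "))
    vapply(nullDrawSets(draws),
           function(d) length(unique(groups[d])), 1L)
}

#' Proportion-based permutation p-value
#'
#' The manual permutation convention: the p-value is the proportion of null
#' iterations on the observed side or beyond. With `alternative = "less"`
#' (observed extreme on the low side) it is the fraction of null values at or
#' below the observed; with `"greater"`, at or above; ties count toward the
#' tail. `"two_sided"` doubles the smaller tail, capped at 1. For example,
#' with 96 of 100 null iterations above the observed value the one-sided
#' p-value is 0.04. The raw proportion can be exactly 0; the add-one
#' correction (tail count + 1)/(iterations + 1) never is, and is reported
#' alongside.
#'
#' @param observed observed statistic.
#' @param nullValues numeric vector of null-model statistics.
#' @param alternative `"less"`, `"greater"` or `"two_sided"`.
#' @param correction which convention fills `p`: the raw proportion
#'   (default) or the add-one correction.
#' @return list with `observed`, `null_values`, `iterations`, `alternative`,
#'   `correction`, `p_raw`, `p_add_one` and `p` (the selected one).
#' @examples
#' permutationPvalue(0, c(rep(1, 96), rep(-1, 4)), "less")$p
#' @export
permutationPvalue <- function(observed,
                              nullValues,
                              alternative = c("less", "greater", "two_sided"),
                              correction = c("raw", "add_one")) {
    alternative <- match.arg(alternative)
    correction <- match.arg(correction)
    if (!length(nullValues)) stop("empty null distribution")
    if (is.na(observed) || any(is.na(nullValues)))
        stop("NA in observed or null values")
    n <- length(nullValues)
    n_low <- sum(nullValues <= observed)
    n_high <- sum(nullValues >= observed)
    tail_count <- switch(alternative,
                         less = n_low,
                         greater = n_high,
                         two_sided = min(n_low, n_high))
    mult <- if (alternative == "two_sided") 2 else 1
    p_raw <- min(1, mult * tail_count / n)
    p_add_one <- min(1, mult * (tail_count + 1) / (n + 1))
    list(observed = observed, null_values = nullValues, iterations = n,
         alternative = alternative, correction = correction,
         p_raw = p_raw, p_add_one = p_add_one,
         p = if (correction == "raw") p_raw else p_add_one)
}

#' Observed-vs-null genus richness test for one pedigree
#'
#' Bundles the null model for the question "are fewer genera inherited than
#' abundance alone predicts": draws null ASV sets of the observed inherited
#' size weighted by maternal worker abundance, computes their genus richness,
#' and compares the observed inherited genus count (one-sided, observed-low).
#'
#' @param x a [PedigreeExperiment-class].
#' @param calls output of [classifyVertical()] for the pedigree (maternal
#'   lineage for the canonical comparison).
#' @param pedigree pedigree label.
#' @param stage `"founders"` compares the founder-transmitted set,
#'   `"offspring"` the vertically transmitted set.
#' @param iterations,seed passed to [drawNullSets()].
#' @return list with the [permutationPvalue()] fields plus `n_select`,
#'   `observed_genera` and `seed`.
#' @export
genusRichnessTest <- function(x, calls, pedigree,
                              stage = c("offspring", "founders"),
                              iterations = 100, seed) {
    stage <- match.arg(stage)
    flag <- if (stage == "founders") calls$transmitted_to_founders else
        calls$vertically_transmitted
    sel <- unique(calls$asv_id[flag])
    if (!length(sel)) stop("no inherited ASV to compare for '", pedigree, "'")
    groups <- genusGroups(x)
    weights <- maternalWorkerWeights(x, pedigree)
    # the null draws from ASVs detectable in maternal workers
    draws <- drawNullSets(weights, nSelect = length(sel),
                          iterations = iterations, seed = seed)
    null_rich <- genusRichnessDistribution(draws, x)
    res <- permutationPvalue(length(unique(groups[sel])), null_rich, "less")
    res$n_select <- length(sel)
    res$observed_genera <- res$observed
    res$seed <- as.integer(seed)
    res
}
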