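#' Simulation parameters for the pedigree-data generator
#'
#' Defaults emulate the study design the pipeline targets: four maternal
#' colonies crossed with one shared paternal colony; parental-worker,
#' founding-reproductive (alate) and offspring-worker sample tiers; pooled
#' gut samples; ASVs nested in genera; a heritable subset enriched in
#' founders; and environment-only ASVs appearing in offspring colonies.
#'
#' @param nPedigrees number of maternal pedigrees (default 4).
#' @param nGenera number of bacterial genera in the source pool (default 60).
#' @param asvsPerGenusMean mean of the geometric (1 + Geom) ASVs-per-genus
#'   distribution (default 5).
#' @param fracHeritable fraction of each parental community planted as
#'   heritable (default 0.25).
#' @param founderEnrichment multiplicative abundance boost of heritable ASVs
#'   in founder samples (default 3).
#' @param founderDropout probability a non-heritable parental ASV is absent
#'   from a given founder sample (default 0.8; the founding bottleneck).
#' @param envPoolSize number of environment-only ASVs available to offspring
#'   colonies (default 200).
#' @param envOccupancy probability an environmental ASV enters a given
#'   pedigree's offspring community (default 0.6).
#' @param depth reads per sample (default 50000).
#' @param overdispersion Dirichlet concentration scale; sample compositions
#'   are Dirichlet-multinomial with concentration `overdispersion *
#'   expected proportions` (default 50; smaller = noisier).
#' @param nParentalWorkers,nFounders,nOffspring samples per tier
#'   (defaults 2, 3, 3; founders are per lineage).
#' @param colonyOccupancy probability a pool ASV occurs in a given parental
#'   colony (default 0.7), creating pedigree-specific repertoires.
#' @param lognormSigma log-normal sigma of base ASV abundances (default 1.5),
#'   giving a realistic steep rank-abundance curve.
#' @param fracUnresolvedGenus fraction of ASVs with unresolved genus
#'   (default 0.05), exercising the unclassified grouping rule.
#' @param ensurePresence guarantee the planted structure after multinomial
#'   sampling by depth-preserving read reallocation (default TRUE); see
#'   [simulatePedigreeDataset()].
#' @param seed integer seed (default 1).
#' @return Validated list of class `SimParams`.
#' @export
simParams <- function(nPedigrees = 4, nGenera = 60, asvsPerGenusMean = 5,
                      fracHeritable = 0.25, founderEnrichment = 3.0,
                      founderDropout = 0.8, envPoolSize = 200,
                      envOccupancy = 0.6, depth = 50000, overdispersion = 50,
                      nParentalWorkers = 2, nFounders = 3, nOffspring = 3,
                      colonyOccupancy = 0.7, lognormSigma = 1.5,
                      fracUnresolvedGenus = 0.05, ensurePresence = TRUE,
                      seed = 1) {
    p <- as.list(environment())
    probs <- c("fracHeritable", "founderDropout", "envOccupancy",
               "colonyOccupancy", "fracUnresolvedGenus")
    for (nm in probs)
        if (p[[nm]] < 0 || p[[nm]] > 1)
            stop(nm, " must be in [0, 1]")
    stopifnot(p$nPedigrees >= 1, p$depth >= 1, p$nGenera >= 1,
              p$asvsPerGenusMean >= 1, p$founderEnrichment > 0,
              p$overdispersion > 0, p$nParentalWorkers >= 1,
              p$nFounders >= 1, p$nOffspring >= 1, p$envPoolSize >= 0)
    structure(p, class = "SimParams")
}

.PEDIGREE_NAMES <- c("red", "yellow", "blue", "green")

.pedigreeNames <- function(n) {
    if (n <= length(.PEDIGREE_NAMES)) .PEDIGREE_NAMES[seq_len(n)]
    else c(.PEDIGREE_NAMES, paste0("ped", seq_len(n - length(.PEDIGREE_NAMES))))
}

#' Generate a pedigree-structured ASV dataset with planted ground truth
#'
#' Simulates the full study design: per-colony base communities are drawn
#' from a shared ASV pool (log-normal expected abundances, ASVs nested in
#' genera), a heritable subset of each parental community is planted, and
#' per-sample read counts are Dirichlet-multinomial at the stated depth.
#' Heritable ASVs appear in parental workers, in EVERY founder sample of
#' their lineage (abundance-boosted by `founderEnrichment`), and in at least
#' one offspring sample; non-heritable parental ASVs drop out of founder
#' samples with probability `founderDropout` and never reach the offspring;
#' environmental ASVs appear only in offspring samples. With
#' `ensurePresence = TRUE` (default) the planted presence pattern is
#' guaranteed structurally: after the multinomial draw, a heritable ASV left
#' at zero reads in a required sample receives one read taken from that
#' sample's most abundant ASV, keeping the sample total at `depth`.
#'
#' @param params a [simParams()] list (its `seed` drives all randomness).
#' @return list with `experiment` (a [PedigreeExperiment-class]) and `truth`
#'   (data.frame `asv_id`, `pedigree`, `class` with classes
#'   `heritable_maternal`, `heritable_paternal`, `heritable_shared`,
#'   `parental_only`, `environmental`).
#' @examples
#' sim <- simulatePedigreeDataset(simParams(nPedigrees = 2, nGenera = 10,
#'                                          envPoolSize = 20, depth = 5000))
#' sim$experiment
#' @export
simulatePedigreeDataset <- function(params = simParams()) {
    stopifnot(inherits(params, "SimParams"))
    .withSeed(params$seed, .simulatePedigree(params))
}

.simulatePedigree <- function(p) {
    peds <- .pedigreeNames(p$nPedigrees)

    ## -- ASV pool nested in genera ------------------------------------
    sizes <- 1L + stats::rgeom(p$nGenera, prob = 1 / p$asvsPerGenusMean)
    pool_genus <- rep(paste0("g", seq_len(p$nGenera)), sizes)
    env_genus <- if (p$envPoolSize > 0)
        sample(paste0("g", seq_len(p$nGenera)), p$envPoolSize, replace = TRUE)
    else character()
    genus <- c(pool_genus, env_genus)
    n_asv <- length(genus)
    asv <- sprintf("ASV%04d", seq_len(n_asv))
    is_env <- c(rep(FALSE, length(pool_genus)), rep(TRUE, p$envPoolSize))
    taxonomy <- .simTaxonomy(asv, genus, p)

    ## -- parental colony communities ----------------------------------
    pool_ids <- asv[!is_env]
    community <- function() {
        present <- pool_ids[stats::runif(length(pool_ids)) <
                                p$colonyOccupancy]
        stats::setNames(stats::rlnorm(length(present), 0, p$lognormSigma),
                        present)
    }
    maternal <- lapply(peds, function(i) community())
    names(maternal) <- peds
    paternal <- community()
    pick_heritable <- function(comm) {
        if (p$fracHeritable == 0) return(character())
        sample(names(comm), max(1, round(p$fracHeritable * length(comm))))
    }
    herit_m <- lapply(maternal, pick_heritable)
    herit_p <- pick_heritable(paternal)

    ## -- environmental communities per pedigree -----------------------
    env_ids <- asv[is_env]
    env_comm <- lapply(peds, function(i) {
        present <- env_ids[stats::runif(length(env_ids)) < p$envOccupancy]
        stats::setNames(stats::rlnorm(length(present), 0, p$lognormSigma),
                        present)
    })
    names(env_comm) <- peds

    ## -- ground truth ---------------------------------------------------
    truth <- do.call(rbind, lapply(peds, function(pp) {
        par_union <- union(names(maternal[[pp]]), names(paternal))
        hm <- herit_m[[pp]]
        cls <- rep("parental_only", length(par_union))
        names(cls) <- par_union
        cls[par_union %in% hm] <- "heritable_maternal"
        cls[par_union %in% herit_p] <- "heritable_paternal"
        cls[par_union %in% intersect(hm, herit_p)] <- "heritable_shared"
        rbind(data.frame(asv_id = par_union, pedigree = pp,
                         class = unname(cls)),
              data.frame(asv_id = names(env_comm[[pp]]), pedigree = pp,
                         class = "environmental"))
    }))

    ## -- samples --------------------------------------------------------
    cols <- list(); md <- list()
    add <- function(counts, id, pedigree, generation, role, caste, colony) {
        cols[[length(cols) + 1L]] <<- stats::setNames(counts, NULL)
        md[[length(md) + 1L]] <<- data.frame(
            sample_id = id, pedigree = pedigree, generation = generation,
            parental_role = role, caste = caste, colony_id = colony,
            guts_pooled = sample(5:10, 1))
        names(cols)[length(cols)] <<- id
    }
    full <- function(comm) {
        v <- numeric(n_asv); names(v) <- asv
        v[names(comm)] <- comm
        v
    }
    dm_draw <- function(expected, guarantee = character()) {
        counts <- .rdirmult(full(expected), p$depth, p$overdispersion)
        if (p$ensurePresence && length(guarantee))
            counts <- .ensureReads(counts, guarantee)
        counts
    }
    founder_sample <- function(comm, herit) {
        expected <- comm
        boost <- names(expected) %in% herit
        expected[boost] <- expected[boost] * p$founderEnrichment
        drop <- !boost & stats::runif(length(expected)) < p$founderDropout
        expected[drop] <- 0
        expected
    }

    # paternal parental workers (shared colony, no pedigree)
    for (s in seq_len(p$nParentalWorkers))
        add(dm_draw(paternal, herit_p), sprintf("PW_pat_%d", s),
            NA_character_, "parental", "paternal", "worker", "PAT")

    for (pp in peds) {
        for (s in seq_len(p$nParentalWorkers))
            add(dm_draw(maternal[[pp]], herit_m[[pp]]),
                sprintf("PW_%s_%d", pp, s), pp, "parental", "maternal",
                "worker", paste0("M_", pp))
        for (s in seq_len(p$nFounders)) {
            add(dm_draw(founder_sample(maternal[[pp]], herit_m[[pp]]),
                        herit_m[[pp]]),
                sprintf("F_mat_%s_%d", pp, s), pp, "founder", "maternal",
                "alate", paste0("O_", pp, "_", s))
            add(dm_draw(founder_sample(paternal, herit_p), herit_p),
                sprintf("F_pat_%s_%d", pp, s), pp, "founder", "paternal",
                "alate", paste0("O_", pp, "_", s))
        }
        off_comm <- c(maternal[[pp]][herit_m[[pp]]],
                      paternal[setdiff(herit_p, herit_m[[pp]])],
                      env_comm[[pp]])
        off_ids <- character()
        for (s in seq_len(p$nOffspring)) {
            id <- sprintf("OW_%s_%d", pp, s)
            add(dm_draw(off_comm), id, pp, "offspring", "na", "worker",
                paste0("O_", pp))
            off_ids <- c(off_ids, id)
        }
        if (p$ensurePresence) {
            herit_all <- union(herit_m[[pp]], herit_p)
            block <- do.call(cbind, cols[off_ids])  # rows follow `asv` order
            hidx <- match(herit_all, asv)
            absent <- herit_all[rowSums(block[hidx, , drop = FALSE]) == 0]
            if (length(absent)) {
                first <- stats::setNames(cols[[off_ids[1]]], asv)
                cols[[off_ids[1]]] <- stats::setNames(
                    .ensureReads(first, absent), NULL)
            }
        }
    }

    counts <- do.call(cbind, cols)
    rownames(counts) <- asv
    metadata <- do.call(rbind, md)
    pe <- PedigreeExperiment(counts, taxonomy, metadata)
    list(experiment = pe, truth = truth)
}

# Dirichlet-multinomial draw: concentration = scale * proportions.
.rdirmult <- function(expected, depth, scale) {
    q <- numeric(length(expected))
    names(q) <- names(expected)
    pos <- expected > 0
    if (!any(pos))  # sterile community (e.g. full founder dropout, nothing
        return(stats::setNames(integer(length(q)), names(q)))  # heritable)
    alpha <- scale * expected[pos] / sum(expected[pos])
    g <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(g) == 0) g[] <- alpha  # degenerate gamma underflow guard
    q[pos] <- g / sum(g)
    stats::setNames(as.integer(stats::rmultinom(1, depth, q)), names(q))
}

# Give one read (taken from the most abundant ASV) to each listed ASV that
# sampled to zero; keeps the sample total unchanged.
.ensureReads <- function(counts, ids) {
    for (i in ids[counts[ids] == 0]) {
        donor <- names(which.max(counts))
        if (counts[donor] <= 1) break
        counts[donor] <- counts[donor] - 1L
        counts[i] <- 1L
    }
    counts
}

.simTaxonomy <- function(asv, genus, p) {
    phyla <- c("Bacteroidota", "Bacillota", "Pseudomonadota",
               "Actinomycetota", "Spirochaetota")
    glev <- sort(unique(genus))
    gphy <- stats::setNames(sample(phyla, length(glev), replace = TRUE), glev)
    tax <- data.frame(
        asv_id = asv,
        phylum = gphy[genus],
        class = paste0("c_", gphy[genus]),
        order = paste0("o_", substr(genus, 2, 99)),
        family = paste0("f", ceiling(as.integer(substr(genus, 2, 99)) / 2)),
        genus = genus, row.names = NULL)
    unresolved <- stats::runif(length(asv)) < p$fracUnresolvedGenus
    tax$genus[unresolved] <- NA_character_
    tax
}

#' Generate a planted-partition signed network
#'
#' Positive edges are placed independently with probability
#' `pWithinPositive` inside label blocks and `pBetweenPositive` between
#' blocks; negative edges with probability `pNegative` on the remaining
#' pairs (a pair carries at most one edge). With `pBetweenPositive = 0` the
#' positive subgraph is perfectly assortative by construction.
#'
#' @param blockLabels character/factor vector of node block labels; node ids
#'   are taken from its names (or generated).
#' @param pWithinPositive,pBetweenPositive,pNegative edge probabilities.
#' @param seed integer seed.
#' @return list with `network` (a [SignedNetwork-class] over all nodes) and
#'   `labels` (named vector).
#' @export
simulateSignedNetwork <- function(blockLabels, pWithinPositive = 0.2,
                                  pBetweenPositive = 0.05, pNegative = 0.05,
                                  seed = 1) {
    stopifnot(all(c(pWithinPositive, pBetweenPositive, pNegative) >= 0),
              all(c(pWithinPositive, pBetweenPositive, pNegative) <= 1))
    if (is.null(names(blockLabels)))
        names(blockLabels) <- sprintf("ASV%04d", seq_along(blockLabels))
    nodes <- names(blockLabels)
    pairs <- t(combn(nodes, 2))
    same <- blockLabels[pairs[, 1]] == blockLabels[pairs[, 2]]
    .withSeed(seed, {
        p_pos <- ifelse(same, pWithinPositive, pBetweenPositive)
        u <- stats::runif(nrow(pairs))
        pos <- u < p_pos
        neg <- !pos & stats::runif(nrow(pairs)) < pNegative
        edges <- rbind(
            data.frame(from = pairs[pos, 1], to = pairs[pos, 2],
                       sign = rep("positive", sum(pos))),
            data.frame(from = pairs[neg, 1], to = pairs[neg, 2],
                       sign = rep("negative", sum(neg))))
        list(network = SignedNetwork(edges, nodes = nodes),
             labels = blockLabels)
    })
}
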