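#' Pipeline run configuration
#'
#' Collects input paths, filter thresholds, resampling settings and the seed
#' for a [runPipeline()] run. With no input paths the pipeline starts from
#' the synthetic generator ([simulatePedigreeDataset()]).
#'
#' @param counts,taxonomy,metadata input TSV paths (all three, or none to
#'   simulate).
#' @param network optional signed edge-list TSV for the assortativity stage;
#'   when absent and simulating, a planted network is generated.
#' @param sim list of [simParams()] overrides used when simulating.
#' @param minReads dataset-level read filter (default 25).
#' @param networkMinReads network prefilter (default 200).
#' @param iterations null-model iterations (default 100).
#' @param nPerm label permutations for the association test (default 1000).
#' @param seed integer master seed, recorded in every output.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(counts = NULL, taxonomy = NULL, metadata = NULL,
                      network = NULL, sim = list(), minReads = 25,
                      networkMinReads = 200, iterations = 100, nPerm = 1000,
                      seed = 1) {
    paths <- c(counts, taxonomy, metadata, network)
    missing <- paths[!vapply(paths, file.exists, TRUE)]
    if (length(missing))
        stop("missing input file(s): ", paste(missing, collapse = ", "))
    simulate <- is.null(counts)
    if (!simulate && (is.null(taxonomy) || is.null(metadata)))
        stop("counts, taxonomy and metadata paths must be given together")
    structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata,
                   network = network, sim = sim, simulate = simulate,
                   minReads = minReads, networkMinReads = networkMinReads,
                   iterations = iterations, nPerm = nPerm,
                   seed = as.integer(seed)),
              class = "RunConfig")
}

#' Read a RunConfig from YAML
#'
#' @param path YAML file whose keys match the [runConfig()] arguments.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("missing config file: ", path)
    do.call(runConfig, yaml::read_yaml(path))
}

.configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    saveRDS(config[order(names(config))], tmp)
    unname(tools::md5sum(tmp))
}

.writeTsv <- function(df, path, provenance) {
    con <- file(path, "w")
    writeLines(paste0("# ", provenance), con)
    close(con)
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    path
}

.writeJson <- function(x, path, seed, hash) {
    x$seed <- seed
    x$config_md5 <- hash
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing plain TSV/JSON artifacts
#' (each embedding the seed and a config hash) so any stage can be re-entered
#' independently:
#' \describe{
#'   \item{simulate}{generate the dataset and planted truth (or load the
#'     configured input tables).}
#'   \item{classify}{dataset filter, vertical-transmission calls for every
#'     pedigree and lineage, parentage attribution, per-sample summaries.}
#'   \item{nullmodel}{abundance-weighted genus-richness null test per
#'     pedigree.}
#'   \item{genus-stats}{within-genus centering and the stratified
#'     permutation association test.}
#'   \item{assort}{network prefilter and inheritance-label assortativity of
#'     the positive and negative subnetworks against null labelings.}
#'   \item{report}{aggregate summary (tier means, sharing partition,
#'     retention, genus overlap).}
#' }
#'
#' @param config a [runConfig()] / [readRunConfig()] object.
#' @param outDir output directory, created if needed.
#' @param stages stages to run (subset of the above, order fixed).
#' @return Invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config, outDir,
                        stages = c("simulate", "classify", "nullmodel",
                                   "genus-stats", "assort", "report")) {
    stopifnot(inherits(config, "RunConfig"))
    stages <- match.arg(stages, several.ok = TRUE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hash <- .configHash(config)
    prov <- paste0("seed=", config$seed, " config_md5=", hash)
    out <- list()
    wjson <- function(x, f) .writeJson(x, file.path(outDir, f),
                                       config$seed, hash)
    wtsv <- function(df, f) .writeTsv(df, file.path(outDir, f), prov)

    ## ---- simulate / load -------------------------------------------
    truth <- NULL
    if (config$simulate) {
        params <- do.call(simParams, c(config$sim,
                                       list(seed = config$seed)))
        simdat <- simulatePedigreeDataset(params)
        pe <- simdat$experiment
        truth <- simdat$truth
        if ("simulate" %in% stages) {
            out$dataset <- writePedigreeDataset(pe, outDir)
            out$truth <- wtsv(truth, "ground_truth.tsv")
        }
    } else {
        pe <- readPedigreeDataset(config$counts, config$taxonomy,
                                  config$metadata)
    }
    out$run_info <- wjson(list(stages = stages,
                               simulate = config$simulate,
                               n_asvs = nrow(pe), n_samples = ncol(pe)),
                          "run_info.json")

    filt <- filterMinTotalReads(pe, config$minReads)
    calls <- NULL
    if (any(c("classify", "nullmodel", "genus-stats", "assort",
              "report") %in% stages))
        calls <- classifyAllPedigrees(filt)

    ## ---- classify ----------------------------------------------------
    if ("classify" %in% stages) {
        out$calls <- wtsv(calls, "inheritance_calls.tsv")
        parentage <- do.call(rbind, lapply(pedigrees(filt), function(pp) {
            attributeParentage(
                calls[calls$pedigree == pp & calls$lineage == "maternal", ],
                calls[calls$pedigree == pp & calls$lineage == "paternal", ])
        }))
        out$parentage <- wtsv(parentage, "parentage_status.tsv")
        out$sample_summary <- wtsv(sampleInheritedSummary(filt, calls),
                                   "sample_inherited_summary.tsv")
        if (!is.null(truth)) {
            rec <- recoverPlantedTruth(calls, truth)
            out$recovery <- wjson(rec, "recovery.json")
        }
    }

    ## ---- null model ---------------------------------------------------
    if ("nullmodel" %in% stages) {
        tests <- lapply(pedigrees(filt), function(pp) {
            res <- genusRichnessTest(
                filt, calls[calls$pedigree == pp &
                            calls$lineage == "maternal", ],
                pp, stage = "offspring", iterations = config$iterations,
                seed = config$seed)
            res$pedigree <- pp
            res
        })
        names(tests) <- pedigrees(filt)
        out$nullmodel <- wjson(list(genus_richness_tests = tests),
                               "nullmodel.json")
    }

    ## ---- genus stats ---------------------------------------------------
    if ("genus-stats" %in% stages) {
        tabs <- lapply(pedigrees(filt), function(pp) {
            w <- maternalWorkerWeights(filt, pp)
            cen <- centerWithinGenus(w, filt, context = "maternal_workers")
            cen$pedigree <- pp
            cen$transformed <- signedLogTransform(cen$centered)
            vt <- calls$asv_id[calls$pedigree == pp &
                               calls$lineage == "maternal" &
                               calls$vertically_transmitted]
            cen$transmitted <- cen$asv_id %in% vt
            cen
        })
        cen_all <- do.call(rbind, tabs)
        out$centered <- wtsv(cen_all, "centered_abundance.tsv")
        assoc <- transmissionAssociation(
            cen_all$centered, cen_all$transmitted,
            paste(cen_all$pedigree, cen_all$genus, sep = ":"),
            nPerm = config$nPerm, seed = config$seed)
        assoc$null_values <- NULL
        out$genus_stats <- wjson(list(association = assoc),
                                 "genus_stats.json")
    }

    ## ---- assortativity ---------------------------------------------------
    if ("assort" %in% stages) {
        netfilt <- prefilterForNetwork(filt, config$networkMinReads)
        inherited <- unique(calls$asv_id[calls$vertically_transmitted])
        node_lab <- ifelse(asvIds(netfilt) %in% inherited, "inherited",
                           "non-inherited")
        names(node_lab) <- asvIds(netfilt)
        if (!is.null(config$network)) {
            net <- readSignedNetwork(config$network, nodes = asvIds(netfilt))
        } else {
            net <- simulateSignedNetwork(node_lab, seed = config$seed)$network
        }
        ped1 <- pedigrees(filt)[1]
        w <- maternalWorkerWeights(filt, ped1)
        w <- w[names(w) %in% networkNodes(net)]
        n_inh <- sum(node_lab == "inherited")
        res <- lapply(c(positive = "positive", negative = "negative"),
                      function(sgn) {
            sub <- suppressWarnings(subsetBySign(net, sgn))
            if (!nrow(networkEdges(sub))) return(list(skipped = "no edges"))
            draws <- drawNullSets(w, nSelect = min(n_inh, sum(w > 0)),
                                  iterations = config$iterations,
                                  seed = config$seed)
            r <- nullAssortativity(sub, draws, names(node_lab)[
                node_lab == "inherited"])
            r$null_r <- NULL
            r
        })
        res$n_nodes <- length(networkNodes(net))
        out$assort <- wjson(res, "assortativity.json")
    }

    ## ---- report ----------------------------------------------------------
    if ("report" %in% stages) {
        summ <- sampleInheritedSummary(filt, calls)
        tier <- split(summ, summ$generation)
        tier_means <- lapply(tier, function(d) list(
            mean_inherited_relabund = mean(d$inherited_relabund_fraction,
                                           na.rm = TRUE),
            mean_inherited_asv_fraction = mean(d$inherited_asv_fraction,
                                               na.rm = TRUE),
            n_samples = nrow(d)))
        sharing <- as.list(pedigreeSharing(calls, lineage = "maternal"))
        ret <- founderRetention(calls[calls$lineage == "maternal", ])
        ov <- genusOverlap(calls, filt, lineage = "maternal")
        off <- ov[upper.tri(ov)]
        out$report <- wjson(list(
            tier_means = tier_means,
            maternal_sharing_partition = sharing,
            maternal_retention = ret[ret$pedigree == "pooled", "retention"],
            mean_pairwise_genus_overlap = mean(off, na.rm = TRUE)),
            "report.json")
    }
    invisible(out)
}

#' Compare classification with planted ground truth
#'
#' Precision and recall of the classified vertically transmitted set (union
#' over lineages) against the planted heritable classes of the synthetic
#' generator, per (ASV, pedigree) pair.
#'
#' @param calls output of [classifyAllPedigrees()].
#' @param truth `truth` element of [simulatePedigreeDataset()].
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
recoverPlantedTruth <- function(calls, truth) {
    key <- function(a, p) paste(a, p, sep = "\r")
    vt <- calls[calls$vertically_transmitted, c("asv_id", "pedigree")]
    called <- unique(key(vt$asv_id, vt$pedigree))
    planted <- key(truth$asv_id, truth$pedigree)[
        startsWith(truth$class, "heritable")]
    tp <- length(intersect(called, planted))
    fp <- length(setdiff(called, planted))
    fn <- length(setdiff(planted, called))
    list(tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
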