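#' Network-specific abundance prefilter
#'
#' Before network analysis, ASVs with fewer than 200 reads across all samples
#' are removed (strictly below the threshold); identical to
#' [filterMinTotalReads()] with the network default.
#'
#' @inheritParams filterMinTotalReads
#' @export
prefilterForNetwork <- function(x, threshold = 200) {
    filterMinTotalReads(x, threshold)
}

#' Read a signed edge list
#'
#' Edge-list TSV with columns `node_a`, `node_b`, `sign` and optional
#' `weight` (any inference tool's output can be exported to this form).
#'
#' @param path TSV path.
#' @param nodes optional node universe (adds isolated nodes).
#' @return A [SignedNetwork-class].
#' @export
readSignedNetwork <- function(path, nodes = NULL) {
    if (!file.exists(path)) stop("missing file: ", path)
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("node_a", "node_b", "sign")
    if (!all(need %in% colnames(df)))
        stop("edge list needs columns: ", paste(need, collapse = ", "))
    edges <- data.frame(from = df$node_a, to = df$node_b, sign = df$sign)
    if ("weight" %in% colnames(df)) edges$weight <- df$weight
    SignedNetwork(edges, nodes = nodes)
}

#' Subset a signed network by edge sign
#'
#' Keeps only edges of the requested sign; all nodes are retained, so nodes
#' left without edges become isolated (important for assortativity on the
#' fixed node set).
#'
#' @param net a [SignedNetwork-class].
#' @param sign `"positive"` or `"negative"`.
#' @return A [SignedNetwork-class] on the same nodes.
#' @export
subsetBySign <- function(net, sign = c("positive", "negative")) {
    sign <- match.arg(sign)
    edges <- networkEdges(net)
    keep <- edges$sign == sign
    if (!any(keep))
        warning("no ", sign, " edges in the network")
    SignedNetwork(edges[keep, , drop = FALSE], nodes = networkNodes(net))
}

#' Categorical (label) assortativity coefficient
#'
#' Newman's categorical assortativity on the edge mixing matrix: with e[i,j]
#' the fraction of edge ends joining classes i and j (each undirected edge
#' contributing symmetrically) and a_i = b_i the marginal fractions,
#' r = (sum_i e[i,i] - sum_i a_i b_i) / (1 - sum_i a_i b_i). r = 1 when all
#' edges join same-class nodes; negative r marks disassortative mixing. When
#' every edge lies within a single class the denominator is 0 and r is
#' undefined (`NA` with `defined = FALSE`).
#'
#' @param net a [SignedNetwork-class].
#' @param labels named vector (names covering every network node) of node
#'   categories, e.g. inherited / non-inherited.
#' @param weighted if `TRUE`, edges contribute their weight instead of 1.
#' @return list with `r`, `defined`, `n_edges`, `mixing` (the e matrix).
#' @examples
#' net <- SignedNetwork(data.frame(from = c("A", "C", "B"),
#'                                 to = c("B", "D", "C"), sign = "positive"))
#' lab <- c(A = "inherited", B = "inherited",
#'          C = "non-inherited", D = "non-inherited")
#' labelAssortativity(net, lab)$r  # 1/3
#' @export
labelAssortativity <- function(net, labels, weighted = FALSE) {
    edges <- networkEdges(net)
    if (!nrow(edges)) stop("assortativity needs at least one edge")
    unl <- setdiff(networkNodes(net), names(labels))
    if (length(unl))
        stop("unlabeled node(s): ", paste(head(unl, 5), collapse = ", "))
    lab <- as.character(labels)
    names(lab) <- names(labels)
    classes <- sort(unique(lab[networkNodes(net)]))
    li <- factor(lab[edges$from], classes)
    lj <- factor(lab[edges$to], classes)
    w <- if (weighted) abs(edges$weight) else rep(1, nrow(edges))
    m <- sum(w)
    k <- length(classes)
    e <- matrix(0, k, k, dimnames = list(classes, classes))
    half <- w / (2 * m)
    for (idx in seq_len(nrow(edges))) {
        e[li[idx], lj[idx]] <- e[li[idx], lj[idx]] + half[idx]
        e[lj[idx], li[idx]] <- e[lj[idx], li[idx]] + half[idx]
    }
    a <- rowSums(e)
    b <- colSums(e)
    denom <- 1 - sum(a * b)
    if (abs(denom) < 1e-14)
        return(list(r = NA_real_, defined = FALSE, n_edges = nrow(edges),
                    mixing = e))
    r <- (sum(diag(e)) - sum(a * b)) / denom
    list(r = r, defined = TRUE, n_edges = nrow(edges), mixing = e)
}

#' Assortativity against null-model label assignments
#'
#' Recomputes the assortativity of the FIXED network topology under each
#' null labeling (a drawn ASV set marks its members inherited, all other
#' nodes non-inherited) and compares the observed coefficient by permutation
#' p-value (one-sided, observed-high by default, i.e. assortativity excess
#' over the abundance-driven null).
#'
#' @param net a [SignedNetwork-class].
#' @param nullLabelSets a [NullDraws-class] or list of character vectors;
#'   each set must only reference network nodes.
#' @param observedLabels named vector of observed categories (or a character
#'   vector of inherited node ids).
#' @param alternative tail convention for [permutationPvalue()].
#' @param weighted passed to [labelAssortativity()].
#' @return list with `r`, `defined`, `n_edges`, `null_r`, `p_raw`,
#'   `p_add_one`, `p`, `alternative`, `n_null_defined`.
#' @export
nullAssortativity <- function(net, nullLabelSets, observedLabels,
                              alternative = "greater", weighted = FALSE) {
    if (methods::is(nullLabelSets, "NullDraws"))
        nullLabelSets <- nullDrawSets(nullLabelSets)
    nodes <- networkNodes(net)
    if (is.null(names(observedLabels)))
        observedLabels <- .labelsFromSet(observedLabels, nodes)
    obs <- labelAssortativity(net, observedLabels, weighted)
    bad <- setdiff(unique(unlist(nullLabelSets)), nodes)
    if (length(bad))
        stop("null draw references node(s) absent from network: ",
             paste(head(bad, 5), collapse = ", "))
    null_r <- vapply(nullLabelSets, function(set) {
        labelAssortativity(net, .labelsFromSet(set, nodes), weighted)$r
    }, 1.0)
    usable <- !is.na(null_r)
    if (!any(usable)) stop("all null labelings give undefined assortativity")
    if (!obs$defined)
        return(list(r = NA_real_, defined = FALSE, n_edges = obs$n_edges,
                    null_r = null_r, p_raw = NA_real_, p_add_one = NA_real_,
                    p = NA_real_, alternative = alternative,
                    n_null_defined = sum(usable)))
    res <- permutationPvalue(obs$r, null_r[usable], alternative)
    list(r = obs$r, defined = TRUE, n_edges = obs$n_edges, null_r = null_r,
         p_raw = res$p_raw, p_add_one = res$p_add_one, p = res$p,
         alternative = res$alternative, n_null_defined = sum(usable))
}

.labelsFromSet <- function(set, nodes) {
    stats::setNames(ifelse(nodes %in% set, "inherited", "non-inherited"),
                    nodes)
}

#' Signed degrees per node
#'
#' Counts of incident positive and negative edges for every node (isolated
#' nodes get zeros); the handshake lemma holds per sign.
#'
#' @param net a [SignedNetwork-class].
#' @return data.frame with `node`, `positive_degree`, `negative_degree`.
#' @export
degreeFeatures <- function(net) {
    nodes <- networkNodes(net)
    edges <- networkEdges(net)
    count <- function(sgn) {
        ends <- c(edges$from[edges$sign == sgn], edges$to[edges$sign == sgn])
        tab <- table(factor(ends, nodes))
        as.integer(tab)
    }
    data.frame(node = nodes, positive_degree = count("positive"),
               negative_degree = count("negative"), row.names = NULL)
}

#' Display filter: nodes with at least `minDegree` connections
#'
#' Visualization-only helper mirroring the practice of plotting just the
#' well-connected part of a co-occurrence network; never applied before
#' computing assortativity.
#'
#' @param net a [SignedNetwork-class].
#' @param minDegree minimum total degree to keep a node (default 6).
#' @return A [SignedNetwork-class] induced on the kept nodes.
#' @export
displayFilter <- function(net, minDegree = 6) {
    deg <- degreeFeatures(net)
    keep <- deg$node[deg$positive_degree + deg$negative_degree >= minDegree]
    edges <- networkEdges(net)
    edges <- edges[edges$from %in% keep & edges$to %in% keep, , drop = FALSE]
    SignedNetwork(edges, nodes = keep)
}
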