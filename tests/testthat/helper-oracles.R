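# Independent oracles, deliberately naive.

# Exact inclusion probabilities of sequential weighted sampling without
# replacement, by recursive enumeration over all ordered draw sequences.
inclusionProbsExact <- function(weights, k) {
    stopifnot(!is.null(names(weights)), k <= sum(weights > 0))
    probs <- setNames(numeric(length(weights)), names(weights))
    recurse <- function(remaining, depth, pathProb) {
        if (depth == 0) return(invisible())
        total <- sum(remaining)
        for (nm in names(remaining)[remaining > 0]) {
            p <- pathProb * remaining[[nm]] / total
            probs[[nm]] <<- probs[[nm]] + p
            recurse(remaining[names(remaining) != nm], depth - 1, p)
        }
    }
    recurse(weights[weights > 0], k, 1)
    probs
}

# Naive edge-loop categorical assortativity: mixing matrix accumulated one
# edge end at a time, NA when all edge mass sits in one class.
naiveAssortativity <- function(from, to, labels) {
    classes <- sort(unique(labels))
    e <- matrix(0, length(classes), length(classes),
                dimnames = list(classes, classes))
    m <- length(from)
    for (i in seq_len(m)) {
        a <- labels[[from[i]]]
        b <- labels[[to[i]]]
        e[a, b] <- e[a, b] + 1 / (2 * m)
        e[b, a] <- e[b, a] + 1 / (2 * m)
    }
    ab <- sum(rowSums(e) * colSums(e))
    if (abs(1 - ab) < 1e-14) return(NA_real_)
    (sum(diag(e)) - ab) / (1 - ab)
}

# Hand-coded strict inheritance rule for one parental-worker sample, a set
# of founder samples and a set of offspring samples (logical vectors).
truthRule <- function(pw, founders, offspring) {
    ttf <- pw && all(founders)
    list(transmitted_to_founders = ttf,
         vertically_transmitted = ttf && any(offspring))
}
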