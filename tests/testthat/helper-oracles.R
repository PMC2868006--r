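# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths: triads are counted with an explicit loop and densities
# with a naive double loop, so agreement is a real cross-check.

# All distinct arrangements of a small multiset (each equally likely under
# a uniform permutation of the underlying elements).
allArrangements <- function(x) {
    if (length(x) <= 1L) return(list(x))
    out <- list()
    for (v in unique(x)) {
        rest <- x[-match(v, x)]
        for (p in allArrangements(rest)) {
            out[[length(out) + 1L]] <- c(v, p)
        }
    }
    out
}

# Naive triad counting by explicit window loop.
naiveTriadCounts <- function(g) {
    o <- integer(343)
    if (length(g) >= 3L) {
        for (p in seq_len(length(g) - 2L)) {
            i <- (g[p] - 1L) * 49L + (g[p + 1L] - 1L) * 7L + g[p + 2L]
            o[i] <- o[i] + 1L
        }
    }
    o
}

# Exact significance by enumeration: s_i = Pr(X_i < o_i) over all distinct
# arrangements of the group multiset.
exactSignificance <- function(g) {
    o <- naiveTriadCounts(g)
    arr <- allArrangements(g)
    counts <- vapply(arr, naiveTriadCounts, integer(343))
    rowMeans(counts < o)
}

# Naive untruncated variable-bandwidth Gaussian KDE.
naiveKDE <- function(samples, sigmas, v) {
    m <- ncol(samples)
    vals <- vapply(seq_len(nrow(samples)), function(i) {
        d2 <- sum((v - samples[i, ])^2)
        (2 * pi)^(-m / 2) * sigmas[i]^(-m) * exp(-d2 / (2 * sigmas[i]^2))
    }, 0)
    mean(vals)
}

# Random amino-acid sequence over the full 20-letter alphabet.
randomProtein <- function(L) {
    paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                   "P","Q","R","S","T","V","W","Y"), L, replace = TRUE),
          collapse = "")
}
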