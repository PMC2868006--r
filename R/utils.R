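# Internal numerical and RNG helpers shared across modules.

# log(sum(exp(x))) with the max factored out; returns -Inf for all -Inf input.
.logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

# Squared Euclidean cross-distances between rows of A and rows of B.
# Clamped at zero: the expansion ||a||^2 + ||b||^2 - 2<a,b> can go slightly
# negative in floating point for near-coincident points.
.sqDist <- function(A, B) {
    d2 <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
    d2[d2 < 0] <- 0
    d2
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user RNG.
.withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

# Deterministic 31-bit hash of a string (polynomial rolling hash mod the
# Mersenne prime 2^31 - 1).  Used to derive independent-looking substream
# seeds from (top-level seed, stream key) without any non-base dependency.
.hashString <- function(s) {
    h <- 17
    for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
    as.integer(h)
}

.subSeed <- function(seed, key) {
    .hashString(paste0(format(seed, scientific = FALSE), "::", key))
}

# Locale-independent string sort/order (byte order), so canonical pair
# ordering and manifests are identical across systems.
.sortC <- function(x) sort(x, method = "radix")
.orderC <- function(...) order(..., method = "radix")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
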