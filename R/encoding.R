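# Conjoint-triad feature encoding.
#
# A protein sequence is reduced to 7 physicochemical amino-acid groups
# (dipole strength / side-chain volume clustering), scanned with an
# overlapping 3-residue window, and summarised either as raw triad counts,
# as relative triad frequencies, or as the permutation significance of each
# triad count: the probability that a composition-preserving shuffle of the
# sequence shows strictly fewer occurrences of the triad than observed.

.GROUP_MEMBERS <- list(
    `1` = c("A", "G", "V"),
    `2` = c("I", "L", "F", "P"),
    `3` = c("Y", "M", "T", "S"),
    `4` = c("H", "N", "Q", "W"),
    `5` = c("R", "K"),
    `6` = c("D", "E"),
    `7` = c("C")
)

.AA_TO_GROUP <- local({
    m <- integer(0)
    for (g in seq_along(.GROUP_MEMBERS)) {
        m[.GROUP_MEMBERS[[g]]] <- g
    }
    m
})

.N_GROUPS <- 7L
.N_TRIADS <- 343L

#' Amino-acid group mapping
#'
#' The 20 standard amino acids clustered into 7 groups by dipole strength and
#' side-chain volume: 1 = \{A,G,V\}, 2 = \{I,L,F,P\}, 3 = \{Y,M,T,S\},
#' 4 = \{H,N,Q,W\}, 5 = \{R,K\}, 6 = \{D,E\}, 7 = \{C\}.  Grouping reduces a
#' protein-pair triad encoding from 2 x 20^3 = 16000 to 2 x 7^3 = 686
#' dimensions.
#'
#' @return Named integer vector mapping each one-letter code to its group
#'   index in 1..7.
#' @examples
#' aminoAcidGroups()[c("A", "C", "K")]
#' @export
aminoAcidGroups <- function() .AA_TO_GROUP

#' Triad labels
#'
#' @return Character vector of the 343 grouped-triad labels `"g1g2g3"`, in
#'   the index order used by all 343-dimensional feature vectors.
#' @export
triadLabels <- function() {
    g <- expand.grid(g3 = 1:7, g2 = 1:7, g1 = 1:7)
    paste0(g$g1, g$g2, g$g3)
}

#' Map an amino-acid sequence to its group sequence
#'
#' Non-standard residues (including selenocysteine `U` and ambiguity codes
#' `B`, `Z`, `X`) are rejected: the encoding is only defined over the 20
#' standard amino acids, and sequences carrying such residues are removed
#' upstream during dataset filtering.
#'
#' @param sequence Single non-empty character string of uppercase one-letter
#'   amino-acid codes.
#' @return Integer vector of group indices in 1..7, one per residue.
#' @examples
#' mapToGroups("AGV")
#' @export
mapToGroups <- function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (is.na(sequence) || nchar(sequence) == 0L) {
        .stopf("sequence must be a non-empty string")
    }
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    g <- unname(.AA_TO_GROUP[chars])
    if (anyNA(g)) {
        bad <- which(is.na(g))[1L]
        .stopf("non-standard residue '%s' at position %d", chars[bad], bad)
    }
    g
}

# 1-based index of triad (a, b, c) in the canonical 343 ordering.
.triadIndex <- function(a, b, c) (a - 1L) * 49L + (b - 1L) * 7L + c

#' Count grouped triads along a group sequence
#'
#' Scans all overlapping 3-symbol windows.  A sequence shorter than 3 symbols
#' has no window and yields the all-zero vector; otherwise the counts sum to
#' `length(groups) - 2`.
#'
#' @param groups Integer vector of group indices (from [mapToGroups()]).
#' @return Named integer vector of 343 triad counts (names from
#'   [triadLabels()]).
#' @examples
#' countTriads(mapToGroups("AAAA"))[["111"]]
#' @export
countTriads <- function(groups) {
    stopifnot(is.numeric(groups))
    groups <- as.integer(groups)
    if (length(groups) && (min(groups) < 1L || max(groups) > 7L)) {
        .stopf("group indices must lie in 1..7")
    }
    L <- length(groups)
    if (L < 3L) {
        o <- integer(.N_TRIADS)
    } else {
        idx <- .triadIndex(groups[1:(L - 2L)], groups[2:(L - 1L)], groups[3:L])
        o <- tabulate(idx, nbins = .N_TRIADS)
    }
    names(o) <- triadLabels()
    o
}

# Cache of permutation null distributions.  Two sequences with identical
# group composition define the same null, so the cache (and the RNG
# substream) is keyed by (composition, n, seed); encoding order cannot
# change any result.
.sigCache <- new.env(parent = emptyenv())

#' Clear the permutation-null cache
#'
#' @return Invisibly, the number of cached null distributions dropped.
#' @export
clearSignificanceCache <- function() {
    n <- length(ls(.sigCache))
    rm(list = ls(.sigCache), envir = .sigCache)
    invisible(n)
}

# Cumulative null table for a group composition: M[i, k] = number of
# permutations in which triad i occurs strictly fewer than k times
# (k = 1 .. maxCount + 1).  Built from nPermutations uniform shuffles.
.nullTable <- function(groups, nPermutations, streamSeed) {
    L <- length(groups)
    .withSeed(streamSeed, {
        P <- vapply(seq_len(nPermutations),
                    function(j) sample(groups),
                    integer(L))
    })
    idx <- .triadIndex(P[1:(L - 2L), , drop = FALSE],
                       P[2:(L - 1L), , drop = FALSE],
                       P[3:L, , drop = FALSE])
    offset <- rep((seq_len(nPermutations) - 1L) * .N_TRIADS, each = L - 2L)
    counts <- matrix(tabulate(as.vector(idx) + offset,
                              nbins = .N_TRIADS * nPermutations),
                     nrow = .N_TRIADS)
    K <- max(counts) + 1L
    rowIdx <- rep_len(seq_len(.N_TRIADS), length(counts))
    joint <- (rowIdx - 1L) * K + as.vector(counts) + 1L
    freq <- matrix(tabulate(joint, nbins = .N_TRIADS * K), nrow = K)
    t(apply(freq, 2L, cumsum))
}

#' Triad significance vector of a protein sequence
#'
#' For each of the 343 grouped triads, estimates
#' `s_i = Pr(X_i < o_i)`: the probability that a uniformly random
#' composition-preserving permutation of the sequence contains strictly
#' fewer occurrences of triad `i` than the `o_i` actually observed (one
#' minus the permutation p-value).  The inequality is strict, so any triad
#' with `o_i = 0` has `s_i = 0`, and a sequence whose permutations all share
#' the same counts (e.g. a single-group sequence) is all-zero.
#'
#' The null is estimated from `nPermutations` uniform shuffles
#' (Fisher-Yates) of the group sequence; shuffling residues directly would
#' give the same distribution because counts depend only on groups.  Nulls
#' are cached and shared between sequences of identical group composition,
#' with the RNG substream derived from `(seed, composition)` so results do
#' not depend on encoding order.
#'
#' @param sequence Amino-acid string (validated by [mapToGroups()]).
#' @param nPermutations Number of permutations for the null estimate
#'   (default 10000, giving each `s_i` a Monte-Carlo standard error below
#'   0.005).
#' @param seed Integer top-level seed.
#' @return Named numeric vector of 343 significances in \[0, 1\], with
#'   attributes `nPermutations` and `seed`.
#' @examples
#' s <- significanceVector("AAALLLAAA", nPermutations = 500, seed = 1)
#' s[s > 0]
#' @export
significanceVector <- function(sequence, nPermutations = 10000L, seed = 1L) {
    stopifnot(nPermutations >= 1L)
    groups <- mapToGroups(sequence)
    o <- countTriads(groups)
    s <- numeric(.N_TRIADS)
    names(s) <- triadLabels()
    L <- length(groups)
    if (L >= 3L) {
        comp <- paste(tabulate(groups, nbins = .N_GROUPS), collapse = ",")
        key <- sprintf("%s|%d|%d", comp, as.integer(nPermutations),
                       as.integer(seed))
        if (is.null(.sigCache[[key]])) {
            .sigCache[[key]] <- .nullTable(groups, as.integer(nPermutations),
                                           .subSeed(seed, key))
        }
        cum <- .sigCache[[key]]
        nz <- which(o > 0L)
        col <- pmin(o[nz], ncol(cum))
        s[nz] <- cum[cbind(nz, col)] / nPermutations
    }
    structure(s, nPermutations = as.integer(nPermutations),
              seed = as.integer(seed))
}

#' Triad frequency vector (comparison encoding)
#'
#' The baseline conjoint-triad encoding used for comparison: occurrence
#' counts normalised by the number of windows, `o_i / (L - 2)`.  Sequences
#' shorter than 3 residues yield the all-zero vector.
#'
#' @inheritParams significanceVector
#' @return Named numeric vector of 343 relative frequencies summing to 1
#'   (or 0 for windowless sequences).
#' @export
frequencyVector <- function(sequence) {
    o <- countTriads(mapToGroups(sequence))
    n <- sum(o)
    if (n > 0L) o / n else o + 0
}

#' Concatenate two per-protein feature vectors into a pair feature
#'
#' Interacting pairs are unordered but concatenation is ordered, so the two
#' proteins are placed in lexicographic order of their identifiers:
#' `encodePair(a, b)` and `encodePair(b, a)` are identical.
#'
#' @param featureA,featureB Numeric vectors of length 343.
#' @param idA,idB Protein identifiers used for canonical ordering.
#' @return Numeric vector of length 686 with attributes `proteinA` and
#'   `proteinB` (the canonical order used).
#' @export
encodePair <- function(featureA, featureB, idA, idB) {
    if (length(featureA) != .N_TRIADS || length(featureB) != .N_TRIADS) {
        .stopf("per-protein features must have length %d (got %d and %d)",
               .N_TRIADS, length(featureA), length(featureB))
    }
    if (idB < idA) {
        tmp <- featureA; featureA <- featureB; featureB <- tmp
        tmpi <- idA; idA <- idB; idB <- tmpi
    }
    structure(c(as.numeric(featureA), as.numeric(featureB)),
              proteinA = idA, proteinB = idB)
}

#' Encode a set of proteins into a feature matrix
#'
#' @param sequences Named character vector or
#'   [Biostrings::AAStringSet] of protein sequences.
#' @param feature `"significance"` (default) or `"frequency"`.
#' @param nPermutations,seed Passed to [significanceVector()].
#' @param onInvalid What to do with sequences containing non-standard
#'   residues: `"error"` (default) or `"drop"` (dropped ids are reported in
#'   a message and in the `dropped` attribute).
#' @return Numeric matrix, one row per protein (rownames = identifiers),
#'   343 columns labelled by [triadLabels()].
#' @export
encodeProteins <- function(sequences,
                           feature = c("significance", "frequency"),
                           nPermutations = 10000L, seed = 1L,
                           onInvalid = c("error", "drop")) {
    feature <- match.arg(feature)
    onInvalid <- match.arg(onInvalid)
    if (methods::is(sequences, "XStringSet")) {
        sequences <- stats::setNames(as.character(sequences), names(sequences))
    }
    if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
        .stopf("sequences must be uniquely named by protein identifier")
    }
    enc <- function(x) {
        if (feature == "significance") {
            significanceVector(x, nPermutations = nPermutations, seed = seed)
        } else {
            frequencyVector(x)
        }
    }
    rows <- vector("list", length(sequences))
    ok <- logical(length(sequences))
    for (i in seq_along(sequences)) {
        res <- if (onInvalid == "drop") {
            tryCatch(enc(sequences[[i]]), error = function(e) NULL)
        } else {
            enc(sequences[[i]])
        }
        if (!is.null(res)) {
            rows[[i]] <- as.numeric(res)
            ok[i] <- TRUE
        }
    }
    if (!any(ok)) .stopf("no valid sequences to encode")
    dropped <- names(sequences)[!ok]
    if (length(dropped)) {
        message(length(dropped), " sequence(s) with non-standard residues dropped")
    }
    m <- do.call(rbind, rows[ok])
    dimnames(m) <- list(names(sequences)[ok], triadLabels())
    structure(m, dropped = dropped)
}

#' Build the pair-feature matrix for a set of protein pairs
#'
#' @param pairs Data frame with columns `idA`, `idB`.
#' @param features Per-protein feature matrix from [encodeProteins()].
#' @return Numeric matrix with one 686-dimensional row per pair, rows named
#'   `"idA|idB"` in canonical (lexicographic) order.
#' @export
encodePairs <- function(pairs, features) {
    stopifnot(is.data.frame(pairs), all(c("idA", "idB") %in% names(pairs)))
    missing <- setdiff(unique(c(pairs$idA, pairs$idB)), rownames(features))
    if (length(missing)) {
        .stopf("no features for protein(s): %s",
               paste(utils::head(missing, 5L), collapse = ", "))
    }
    swap <- pairs$idB < pairs$idA
    a <- ifelse(swap, pairs$idB, pairs$idA)
    b <- ifelse(swap, pairs$idA, pairs$idB)
    m <- cbind(features[a, , drop = FALSE], features[b, , drop = FALSE])
    rownames(m) <- paste(a, b, sep = "|")
    colnames(m) <- c(paste0("A.", triadLabels()), paste0("B.", triadLabels()))
    m
}
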