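# Construction of positive and negative PPI instance sets and of
# ratio-controlled, repetition-aware train/test datasets.
#
# Conventions: a pair is always stored canonically with idA <= idB
# (byte order); self-pairs are legal members of the negative space, which
# for n proteins and m known interactions has exactly n(n+1)/2 - m
# elements.

.pairKeys <- function(d) paste(d$idA, d$idB, sep = "|")

#' Canonicalise protein pairs
#'
#' Orders each pair so that `idA <= idB` (byte order) and optionally drops
#' duplicates.  Self-pairs are kept: the negative pair space includes them.
#'
#' @param idA,idB Character vectors of protein identifiers.
#' @param dedupe Drop duplicate pairs after canonicalisation (default
#'   `TRUE`).
#' @return Data frame with columns `idA`, `idB`.
#' @export
canonicalPairs <- function(idA, idB, dedupe = TRUE) {
    stopifnot(length(idA) == length(idB))
    idA <- as.character(idA); idB <- as.character(idB)
    if (any(!nzchar(idA)) || any(!nzchar(idB))) {
        .stopf("protein identifiers must be non-empty")
    }
    swap <- idB < idA
    d <- data.frame(idA = ifelse(swap, idB, idA),
                    idB = ifelse(swap, idA, idB),
                    stringsAsFactors = FALSE)
    if (dedupe) d <- d[!duplicated(.pairKeys(d)), , drop = FALSE]
    rownames(d) <- NULL
    d
}

#' Filter raw interaction records into the positive set
#'
#' Applies the dataset-construction rules: records with more than two
#' participating proteins are removed (physical pairwise contact cannot be
#' attributed within a complex); records involving a sequence with a
#' non-standard residue (selenocysteine U in particular) are removed; only
#' in-vivo detections enter the positive set, since in-vitro interactions
#' may be laboratory artefacts.  Surviving pairs are canonicalised and
#' deduplicated.
#'
#' @param interactions Data frame with columns `idA`, `idB`, and optionally
#'   `detection` (values `in_vivo`, `in_vitro`, `other`; absent column
#'   means all records are treated as in vivo) and `arity` (number of
#'   participating proteins, default 2).
#' @param sequences Named character vector or `AAStringSet` of protein
#'   sequences used for the residue filter and id resolution.
#' @param unknownIds `"error"` (default) or `"drop"` for records that
#'   reference a protein absent from `sequences`.
#' @return List with `positives` (canonical pair data frame), `proteins`
#'   (sorted ids involved in the positives) and `stats` (named counts of
#'   records removed per rule).
#' @export
filterInteractions <- function(interactions, sequences,
                               unknownIds = c("error", "drop")) {
    unknownIds <- match.arg(unknownIds)
    stopifnot(is.data.frame(interactions),
              all(c("idA", "idB") %in% names(interactions)))
    if (methods::is(sequences, "XStringSet")) {
        sequences <- stats::setNames(as.character(sequences), names(sequences))
    }
    n0 <- nrow(interactions)
    stats <- c(input = n0, arity = 0L, unknown_id = 0L,
               nonstandard_residue = 0L, not_in_vivo = 0L, duplicate = 0L)

    if ("arity" %in% names(interactions)) {
        keep <- is.na(interactions$arity) | interactions$arity <= 2L
        stats["arity"] <- sum(!keep)
        interactions <- interactions[keep, , drop = FALSE]
    }
    known <- names(sequences)
    unknown <- !(interactions$idA %in% known) | !(interactions$idB %in% known)
    if (any(unknown)) {
        if (unknownIds == "error") {
            bad <- unique(c(interactions$idA, interactions$idB))
            bad <- setdiff(bad, known)
            .stopf("unknown protein id(s): %s",
                   paste(utils::head(bad, 5L), collapse = ", "))
        }
        stats["unknown_id"] <- sum(unknown)
        interactions <- interactions[!unknown, , drop = FALSE]
    }
    # sequences carrying any residue outside the 20 standard codes
    valid <- !vapply(sequences, function(s) {
        grepl("[^ACDEFGHIKLMNPQRSTVWY]", s)
    }, TRUE)
    bad <- !(interactions$idA %in% known[valid]) |
           !(interactions$idB %in% known[valid])
    stats["nonstandard_residue"] <- sum(bad)
    interactions <- interactions[!bad, , drop = FALSE]

    if ("detection" %in% names(interactions)) {
        keep <- interactions$detection == "in_vivo"
        stats["not_in_vivo"] <- sum(!keep)
        interactions <- interactions[keep, , drop = FALSE]
    }
    pairs <- canonicalPairs(interactions$idA, interactions$idB, dedupe = FALSE)
    dup <- duplicated(.pairKeys(pairs))
    stats["duplicate"] <- sum(dup)
    pairs <- pairs[!dup, , drop = FALSE]
    rownames(pairs) <- NULL
    if (nrow(pairs) == 0L) {
        .stopf("no interactions survive filtering")
    }
    message(sprintf(
        "filterInteractions: %d records -> %d positives (%d arity, %d unknown id, %d non-standard residue, %d not in vivo, %d duplicate)",
        n0, nrow(pairs), stats["arity"], stats["unknown_id"],
        stats["nonstandard_residue"], stats["not_in_vivo"],
        stats["duplicate"]))
    list(positives = pairs,
         proteins = .sortC(unique(c(pairs$idA, pairs$idB))),
         stats = stats)
}

#' Size of the negative pair space
#'
#' For `n` proteins there are `n(n+1)/2` unordered pairs including
#' self-pairs; removing the `m` known interactions leaves
#' `n(n+1)/2 - m` candidate negatives.
#'
#' @param nProteins Number of proteins `n`.
#' @param nExcluded Number of excluded (known-interaction) pairs `m`.
#' @return The count as a numeric scalar (may exceed integer range).
#' @examples
#' negativeSpaceSize(6429, 38167)
#' @export
negativeSpaceSize <- function(nProteins, nExcluded) {
    stopifnot(nProteins >= 1, nExcluded >= 0)
    total <- nProteins * (nProteins + 1) / 2
    if (nExcluded > total) {
        .stopf("cannot exclude %s pairs from a space of %s",
               format(nExcluded, scientific = FALSE),
               format(total, scientific = FALSE))
    }
    total - nExcluded
}

# Decode 1-based triangular index k into the pair (i, j), j <= i.
.decodePairIndex <- function(k, ids) {
    i <- floor((sqrt(8 * k + 1) - 1) / 2)
    # guard against floating-point boundary error
    i <- i + (k > i * (i + 1) / 2) - (k <= i * (i - 1) / 2)
    j <- k - i * (i - 1) / 2
    data.frame(idA = ids[pmin(i, j)], idB = ids[pmax(i, j)],
               stringsAsFactors = FALSE)
}

#' Sample non-interacting pairs uniformly without replacement
#'
#' Draws `count` unordered pairs (self-pairs included) over `proteins`,
#' excluding every known interaction and every pair in `alreadyUsed`, so
#' successive calls that thread their accumulated draws through
#' `alreadyUsed` yield pairwise-disjoint negative sets.  When the candidate
#' space is small (under `enumerationLimit` pairs) the complement is
#' enumerated and sampled directly; otherwise pairs are drawn by rejection
#' from the triangular index space against a used-pair registry.
#'
#' @param proteins Character vector of protein ids.
#' @param excluded Data frame of canonical pairs that may never be
#'   negatives (all known interactions, in-vitro and multi-protein derived
#'   ones included).
#' @param count Number of negatives to draw.
#' @param seed Integer seed; the draw is deterministic given
#'   (inputs, seed).
#' @param alreadyUsed Optional data frame of pairs consumed by earlier
#'   draws.
#' @param enumerationLimit Pair-space size below which the complement is
#'   materialised (default 1e6).
#' @return Canonical pair data frame with `count` rows.
#' @export
sampleNegatives <- function(proteins, excluded, count, seed = 1L,
                            alreadyUsed = NULL, enumerationLimit = 1e6) {
    ids <- .sortC(unique(as.character(proteins)))
    n <- length(ids)
    total <- n * (n + 1) / 2
    forbidden <- .pairKeys(canonicalPairs(excluded$idA, excluded$idB))
    if (!is.null(alreadyUsed) && nrow(alreadyUsed)) {
        forbidden <- unique(c(forbidden,
                              .pairKeys(canonicalPairs(alreadyUsed$idA,
                                                       alreadyUsed$idB))))
    }
    # only forbidden pairs inside the pair space reduce availability
    inSpace <- function(keys) {
        parts <- strsplit(keys, "|", fixed = TRUE)
        vapply(parts, function(p) all(p %in% ids), TRUE)
    }
    nForbidden <- sum(inSpace(forbidden))
    available <- total - nForbidden
    if (count > available) {
        .stopf("requested %s negatives but only %s are available",
               format(count, scientific = FALSE),
               format(available, scientific = FALSE))
    }
    if (count == 0L) {
        return(data.frame(idA = character(0), idB = character(0)))
    }
    if (total <= enumerationLimit) {
        all <- .decodePairIndex(seq_len(total), ids)
        pool <- all[!(.pairKeys(all) %in% forbidden), , drop = FALSE]
        pick <- .withSeed(seed, sample.int(nrow(pool), count))
        out <- pool[pick, , drop = FALSE]
    } else {
        taken <- new.env(parent = emptyenv())
        for (k in forbidden) assign(k, TRUE, envir = taken)
        out <- vector("list", 0L)
        got <- 0L
        .withSeed(seed, {
            while (got < count) {
                batch <- ceiling((count - got) * 1.2) + 16L
                k <- ceiling(stats::runif(batch) * total)
                cand <- .decodePairIndex(k, ids)
                keys <- .pairKeys(cand)
                keep <- !duplicated(keys)
                for (q in which(keep)) {
                    if (!is.null(taken[[keys[q]]])) keep[q] <- FALSE
                }
                cand <- cand[keep, , drop = FALSE]
                keys <- keys[keep]
                if (nrow(cand)) {
                    take <- seq_len(min(nrow(cand), count - got))
                    cand <- cand[take, , drop = FALSE]
                    for (q in take) assign(keys[q], TRUE, envir = taken)
                    out[[length(out) + 1L]] <- cand
                    got <- got + nrow(cand)
                }
            }
        })
        out <- do.call(rbind, out)
    }
    rownames(out) <- NULL
    out
}

#' Build ratio-controlled train/test datasets with disjoint negatives
#'
#' Splits the positive pairs into train/test once per repetition (the same
#' positive split is reused across all ratios of that repetition) and
#' samples, for every ratio r, exactly `r x` as many negatives as
#' positives for each of the train and test sets.  All negative sets drawn
#' within one call — across ratios, repetitions, and the train/test
#' boundary — are pairwise disjoint, and no negative ever coincides with a
#' known interaction.
#'
#' When `trainPos + testPos` is smaller than the number of available
#' positives, a seeded subsample of that size is used per repetition (the
#' split sizes then define the positive pool).
#'
#' @param positives Canonical pair data frame of positive interactions.
#' @param proteins Protein ids spanning the negative space.
#' @param excluded Pairs excluded from the negative space (defaults to
#'   `positives`; pass the full known-interaction set when it is larger).
#' @param ratios Numeric vector of r values (1:r datasets).
#' @param trainPos,testPos Positive counts of the train and test sets.
#' @param repetitions Number of repeated random draws.
#' @param seed Integer seed; everything downstream is deterministic.
#' @return List of [RatioDataset-class] objects, ordered by repetition then
#'   ratio, with a `manifest` attribute summarising counts and seeds.
#' @export
buildRatioDatasets <- function(positives, proteins, excluded = positives,
                               ratios, trainPos, testPos,
                               repetitions = 1L, seed = 1L) {
    stopifnot(nrow(positives) >= 1L, all(ratios >= 1))
    positives <- canonicalPairs(positives$idA, positives$idB)
    # the positives are themselves known interactions: never negatives
    excluded <- canonicalPairs(c(excluded$idA, positives$idA),
                               c(excluded$idB, positives$idB))
    nPos <- trainPos + testPos
    if (nPos > nrow(positives)) {
        .stopf("split sizes (%d + %d) exceed the %d available positives",
               trainPos, testPos, nrow(positives))
    }
    space <- negativeSpaceSize(length(unique(proteins)), 0)
    needed <- repetitions * sum(ratios) * nPos
    # upper bound check; sampleNegatives re-checks exactly as it draws
    if (needed > space) {
        .stopf(paste("the %d repetitions need %s disjoint negatives but the",
                     "pair space holds only %s"),
               repetitions, format(needed, scientific = FALSE),
               format(space, scientific = FALSE))
    }
    usedNeg <- data.frame(idA = character(0), idB = character(0))
    out <- vector("list", repetitions * length(ratios))
    k <- 0L
    for (rep in seq_len(repetitions)) {
        repSeed <- .subSeed(seed, paste0("rep", rep))
        ord <- .withSeed(repSeed, sample.int(nrow(positives)))
        pool <- positives[ord[seq_len(nPos)], , drop = FALSE]
        trPos <- pool[seq_len(trainPos), , drop = FALSE]
        tePos <- pool[trainPos + seq_len(testPos), , drop = FALSE]
        for (r in ratios) {
            trSeed <- .subSeed(seed, sprintf("rep%d|ratio%g|train", rep, r))
            trNeg <- sampleNegatives(proteins, excluded, r * trainPos,
                                     seed = trSeed, alreadyUsed = usedNeg)
            usedNeg <- rbind(usedNeg, trNeg)
            teSeed <- .subSeed(seed, sprintf("rep%d|ratio%g|test", rep, r))
            teNeg <- sampleNegatives(proteins, excluded, r * testPos,
                                     seed = teSeed, alreadyUsed = usedNeg)
            usedNeg <- rbind(usedNeg, teNeg)
            k <- k + 1L
            out[[k]] <- methods::new("RatioDataset",
                trainPos = trPos, trainNeg = trNeg,
                testPos = tePos, testNeg = teNeg,
                ratio = as.numeric(r), repetition = rep,
                seed = as.integer(seed))
        }
    }
    attr(out, "manifest") <- list(
        seed = as.integer(seed), repetitions = as.integer(repetitions),
        ratios = as.numeric(ratios),
        trainPos = as.integer(trainPos), testPos = as.integer(testPos),
        nProteins = length(unique(proteins)),
        nPositivesAvailable = nrow(positives),
        negativesDrawn = nrow(usedNeg))
    out
}
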