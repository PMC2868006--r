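# S4 classes for the density models, the pair classifier, ratio-controlled
# datasets and the synthetic-data configuration.

#' RVKDE: relaxed variable kernel density estimator
#'
#' A Gaussian kernel density estimate with one bandwidth per training
#' sample, derived from the sample's ks-nearest-neighbour radius.  For
#' sample \eqn{s_i} with radius \eqn{R(s_i)} (the distance to its ks-th
#' nearest other training sample) the bandwidth is
#' \deqn{\sigma_i = \beta \, (V_m(R(s_i)) / ks)^{1/m},}
#' where \eqn{V_m(R) = \pi^{m/2} R^m / \Gamma(m/2 + 1)} is the volume of
#' the m-ball of radius R: beta times the per-neighbour volume share of the
#' neighbourhood, on the scale of a length.  All volume terms are kept in
#' log space, so the formula is stable at any dimension.
#'
#' @slot samples Numeric matrix, one training sample per row.
#' @slot logBandwidths Numeric, `log(sigma_i)` per sample.
#' @slot alpha,beta Numeric hyperparameters (`alpha` is carried for the
#'   classifier's prior exponent; it does not enter the density itself).
#' @slot ks Integer neighbour count used for the radii.
#'
#' @seealso [fitKDE()], [densityAt()]
#' @export
setClass("RVKDE",
    representation(samples = "matrix",
                   logBandwidths = "numeric",
                   alpha = "numeric",
                   beta = "numeric",
                   ks = "integer"),
    validity = function(object) {
        n <- nrow(object@samples)
        msg <- character(0)
        if (length(object@logBandwidths) != n)
            msg <- c(msg, "one bandwidth per training sample required")
        if (any(!is.finite(object@logBandwidths)))
            msg <- c(msg, "all bandwidths must be finite and positive")
        if (object@ks < 1L || object@ks >= n)
            msg <- c(msg, "ks must satisfy 1 <= ks < number of samples")
        if (object@beta <= 0)
            msg <- c(msg, "beta must be positive")
        if (length(msg)) msg else TRUE
    })

#' PPIClassifier: two-class RVKDE likelihood classifier
#'
#' One density estimate per class plus the class sizes.  A query v is
#' scored by the log-likelihood ratio
#' \deqn{score(v) = \log(|S_+|^\alpha \hat f_+(v)) -
#'                  \log(|S_-|^\alpha \hat f_-(v))}
#' with each density evaluated over the query's `kt` nearest training
#' samples of that class; positive score predicts "interacting", ties go to
#' the negative (majority) class.
#'
#' @slot kdePos,kdeNeg [RVKDE-class] models for interacting and
#'   non-interacting pairs.
#' @slot nPos,nNeg Integer class sizes.
#' @slot kt Integer, number of nearest training samples used per query.
#' @slot alpha Numeric exponent on the class-size prior (1 = plain
#'   frequency weighting; values below 1 temper class imbalance).
#'
#' @seealso [fitPPIClassifier()], [decisionScore()]
#' @export
setClass("PPIClassifier",
    representation(kdePos = "RVKDE", kdeNeg = "RVKDE",
                   nPos = "integer", nNeg = "integer",
                   kt = "integer", alpha = "numeric"),
    validity = function(object) {
        msg <- character(0)
        if (object@nPos < 1L || object@nNeg < 1L)
            msg <- c(msg, "both classes must be non-empty")
        if (object@kt < 1L)
            msg <- c(msg, "kt must be >= 1")
        if (ncol(object@kdePos@samples) != ncol(object@kdeNeg@samples))
            msg <- c(msg, "class models must share the feature dimension")
        if (length(msg)) msg else TRUE
    })

#' RatioDataset: a train/test split at a fixed positive-to-negative ratio
#'
#' @slot trainPos,trainNeg,testPos,testNeg Data frames of canonical pairs
#'   (columns `idA`, `idB` with `idA <= idB`).
#' @slot ratio Numeric r of the 1:r positive-to-negative ratio.
#' @slot repetition Integer repetition index.
#' @slot seed Integer seed the negative draws derived from.
#' @export
setClass("RatioDataset",
    representation(trainPos = "data.frame", trainNeg = "data.frame",
                   testPos = "data.frame", testNeg = "data.frame",
                   ratio = "numeric", repetition = "integer",
                   seed = "integer"),
    validity = function(object) {
        msg <- character(0)
        key <- function(d) paste(d$idA, d$idB, sep = "|")
        sets <- list(object@trainPos, object@trainNeg,
                     object@testPos, object@testNeg)
        for (d in sets) {
            if (!all(c("idA", "idB") %in% names(d)))
                return("pair tables need columns idA, idB")
            if (any(d$idB < d$idA))
                msg <- c(msg, "pairs must be canonical (idA <= idB)")
        }
        if (nrow(object@trainNeg) != object@ratio * nrow(object@trainPos) ||
            nrow(object@testNeg) != object@ratio * nrow(object@testPos))
            msg <- c(msg, "negative counts must equal ratio x positive counts")
        keys <- lapply(sets, key)
        if (any(vapply(keys, anyDuplicated, 0L) > 0L))
            msg <- c(msg, "duplicate pairs within a set")
        all4 <- unlist(keys)
        if (anyDuplicated(all4))
            msg <- c(msg, "train/test and positive/negative sets must be disjoint")
        if (length(msg)) msg else TRUE
    })

#' SyntheticPPIConfig: parameters of the synthetic proteome/interactome
#'
#' @slot nProteins Integer number of proteins.
#' @slot lengthRange Integer length-2 vector, inclusive sequence-length
#'   bounds.
#' @slot groupProfile Numeric 7-vector of amino-acid group probabilities
#'   (summing to 1); residues are uniform within a group.
#' @slot nInteractions Integer number of interacting pairs to draw.
#' @slot signalStrength Numeric theta in \[0, 1\]: 0 gives a uniform random
#'   network, 1 a fully motif-determined one.
#' @slot motifSet Character vector of triad labels (`"g1g2g3"`) whose
#'   permutation significance defines the per-protein motif enrichment.
#' @slot selectionGain Numeric sharpness of the motif-driven pair weights.
#' @slot enrichmentPermutations Integer permutations used for the
#'   generator's internal enrichment scores.
#' @slot seed Integer seed.
#' @export
setClass("SyntheticPPIConfig",
    representation(nProteins = "integer", lengthRange = "integer",
                   groupProfile = "numeric", nInteractions = "integer",
                   signalStrength = "numeric", motifSet = "character",
                   selectionGain = "numeric",
                   enrichmentPermutations = "integer", seed = "integer"),
    validity = function(object) {
        msg <- character(0)
        if (object@nProteins < 2L)
            msg <- c(msg, "need at least 2 proteins")
        if (length(object@lengthRange) != 2L ||
            object@lengthRange[1L] < 3L ||
            object@lengthRange[2L] < object@lengthRange[1L])
            msg <- c(msg, "lengthRange must be increasing and >= 3")
        if (length(object@groupProfile) != 7L ||
            any(object@groupProfile < 0) ||
            abs(sum(object@groupProfile) - 1) > 1e-8)
            msg <- c(msg, "groupProfile must be 7 probabilities summing to 1")
        maxPairs <- object@nProteins * (object@nProteins + 1) / 2
        if (object@nInteractions < 1L || object@nInteractions > maxPairs)
            msg <- c(msg, "nInteractions must lie in 1 .. n(n+1)/2")
        if (object@signalStrength < 0 || object@signalStrength > 1)
            msg <- c(msg, "signalStrength must lie in [0, 1]")
        if (!all(object@motifSet %in% triadLabels()))
            msg <- c(msg, "motifSet entries must be triad labels over groups 1..7")
        if (length(msg)) msg else TRUE
    })

setMethod("show", "RVKDE", function(object) {
    cat(sprintf("RVKDE model: %d samples in %d dimensions\n",
                nrow(object@samples), ncol(object@samples)))
    cat(sprintf("  ks = %d, beta = %g; bandwidth range [%.4g, %.4g]\n",
                object@ks, object@beta,
                exp(min(object@logBandwidths)),
                exp(max(object@logBandwidths))))
})

setMethod("show", "PPIClassifier", function(object) {
    cat(sprintf("PPIClassifier: %d positive / %d negative training pairs (1:%.3g)\n",
                object@nPos, object@nNeg, object@nNeg / object@nPos))
    cat(sprintf("  dimension %d, kt = %d, alpha = %g, ks = %d, beta = %g\n",
                ncol(object@kdePos@samples), object@kt, object@alpha,
                object@kdePos@ks, object@kdePos@beta))
})

setMethod("show", "RatioDataset", function(object) {
    cat(sprintf("RatioDataset 1:%g (repetition %d)\n",
                object@ratio, object@repetition))
    cat(sprintf("  train: %d pos / %d neg; test: %d pos / %d neg\n",
                nrow(object@trainPos), nrow(object@trainNeg),
                nrow(object@testPos), nrow(object@testNeg)))
})

setMethod("show", "SyntheticPPIConfig", function(object) {
    cat(sprintf(
        "SyntheticPPIConfig: %d proteins (length %d-%d), %d interactions\n",
        object@nProteins, object@lengthRange[1L], object@lengthRange[2L],
        object@nInteractions))
    cat(sprintf("  signalStrength = %g, %d motif triads, seed = %d\n",
                object@signalStrength, length(object@motifSet), object@seed))
})

#' @describeIn RVKDE-class per-sample bandwidths `sigma_i`.
#' @param object An `RVKDE` or `PPIClassifier` object.
#' @export
bandwidths <- function(object) {
    stopifnot(methods::is(object, "RVKDE"))
    exp(object@logBandwidths)
}

#' @describeIn RatioDataset-class pair tables as a named list of data
#'   frames.
#' @param x A `RatioDataset`.
#' @export
pairSets <- function(x) {
    stopifnot(methods::is(x, "RatioDataset"))
    list(trainPos = x@trainPos, trainNeg = x@trainNeg,
         testPos = x@testPos, testNeg = x@testNeg)
}
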