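# Relaxed variable kernel density estimation and the two-class likelihood
# classifier built on it.
#
# The estimator at query v is
#   f(v) = (1/n) * sum_{i in kt-NN(v)} (2*pi)^(-m/2) sigma_i^(-m)
#                                      exp(-||v - s_i||^2 / (2 sigma_i^2))
# with per-sample bandwidths sigma_i = beta * (V_m(R_i)/ks)^(1/m), where R_i
# is the distance from s_i to its ks-th nearest other training sample.  With
# kt = n the estimator is untruncated and integrates to 1.  Everything that
# involves the m-ball volume or the kernel normalisation is computed in log
# space: at m = 686 the raw factors overflow double precision.

# log V_m(R): volume of the m-ball of radius R.
.logBallVolume <- function(R, m) {
    (m / 2) * log(pi) + m * log(R) - lgamma(m / 2 + 1)
}

#' Fit a relaxed variable kernel density estimator
#'
#' Computes each sample's ks-nearest-neighbour radius `R_i` (Euclidean,
#' self excluded) and converts it to a Gaussian bandwidth
#' `sigma_i = beta * (V_m(R_i)/ks)^(1/m)`.  Duplicated points give
#' `R_i = 0`; their bandwidth is floored at `1e-8` times the mean bandwidth
#' of the non-degenerate samples so replicated training pairs never produce
#' a singular kernel.
#'
#' @param samples Numeric matrix (or vector for 1-D), one sample per row.
#' @param beta Positive bandwidth scale.
#' @param ks Number of nearest neighbours defining the radius; must satisfy
#'   `ks < nrow(samples)`.
#' @param alpha Prior exponent carried through to the classifier (does not
#'   affect the density); default 1.
#' @return An [RVKDE-class] object.
#' @examples
#' m <- fitKDE(c(0, 1, 3), beta = 1, ks = 1)
#' bandwidths(m)
#' @export
fitKDE <- function(samples, beta, ks, alpha = 1) {
    if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
    samples <- as.matrix(samples)
    storage.mode(samples) <- "double"
    n <- nrow(samples)
    ks <- as.integer(ks)
    if (n < ks + 1L) {
        .stopf("need at least ks + 1 = %d samples, got %d", ks + 1L, n)
    }
    m <- ncol(samples)
    d2 <- .sqDist(samples, samples)
    # ks-th smallest distance to another sample (diagonal excluded)
    R <- sqrt(vapply(seq_len(n), function(i) {
        sort.int(d2[i, -i], partial = ks)[ks]
    }, 0))
    logSig <- rep(NA_real_, n)
    pos <- R > 0
    logSig[pos] <- log(beta) + (.logBallVolume(R[pos], m) - log(ks)) / m
    if (!all(pos)) {
        if (!any(pos)) .stopf("all samples are duplicated points; no usable radius")
        logSig[!pos] <- log(1e-8 * mean(exp(logSig[pos])))
    }
    methods::new("RVKDE", samples = samples, logBandwidths = logSig,
                 alpha = as.numeric(alpha), beta = as.numeric(beta), ks = ks)
}

# Log-density of one RVKDE model at the rows of V, using the kt nearest
# training samples per query.  Returns a numeric vector of log f(v).
.logDensity <- function(model, V, kt) {
    S <- model@samples
    n <- nrow(S)
    m <- ncol(S)
    kt <- min(as.integer(kt), n)
    d2 <- .sqDist(V, S)
    logSig <- model@logBandwidths
    const <- -(m / 2) * log(2 * pi)
    vapply(seq_len(nrow(V)), function(q) {
        idx <- if (kt < n) {
            order(d2[q, ])[seq_len(kt)]
        } else {
            seq_len(n)
        }
        lk <- const - m * logSig[idx] -
            d2[q, idx] / (2 * exp(2 * logSig[idx]))
        .logSumExp(lk) - log(n)
    }, 0)
}

#' Evaluate an RVKDE density
#'
#' @param model An [RVKDE-class] object.
#' @param v Query point(s): numeric vector of the model dimension or a
#'   matrix with one query per row (plain numeric input is interpreted as a
#'   single m-dimensional query when its length matches the model, else as
#'   multiple 1-D queries for a 1-D model).
#' @param kt Number of nearest training samples included per query;
#'   `NULL` (default) uses all of them, the untruncated estimator.
#' @param log Return log-density instead of density.
#' @return Numeric vector of (log-)density values, one per query.
#' @export
densityAt <- function(model, v, kt = NULL, log = FALSE) {
    stopifnot(methods::is(model, "RVKDE"))
    m <- ncol(model@samples)
    if (is.null(dim(v))) {
        v <- if (m == 1L) matrix(v, ncol = 1L) else matrix(v, nrow = 1L)
    }
    v <- as.matrix(v)
    if (ncol(v) != m) {
        .stopf("query dimension %d does not match model dimension %d",
               ncol(v), m)
    }
    if (is.null(kt)) kt <- nrow(model@samples)
    if (kt < 1L) .stopf("kt must be >= 1")
    lf <- .logDensity(model, v, kt)
    if (log) lf else exp(lf)
}

#' Fit the two-class RVKDE interaction classifier
#'
#' One density model per class (interacting / non-interacting pairs), with
#' the class sizes retained as likelihood priors.
#'
#' @param pos,neg Feature matrices of the positive and negative training
#'   pairs (e.g. from [encodePairs()]), one pair per row.
#' @param beta,ks Bandwidth hyperparameters shared by both class models,
#'   see [fitKDE()].
#' @param kt Nearest-training-sample count used at query time.
#' @param alpha Exponent on the class-size prior: the class-j likelihood is
#'   `|S_j|^alpha * f_j(v)`.
#' @return A [PPIClassifier-class] object.
#' @export
fitPPIClassifier <- function(pos, neg, beta, ks, kt, alpha = 1) {
    if (is.null(dim(pos))) pos <- matrix(pos, ncol = 1L)
    if (is.null(dim(neg))) neg <- matrix(neg, ncol = 1L)
    if (nrow(pos) < 1L || nrow(neg) < 1L) {
        .stopf("both classes must be non-empty")
    }
    if (ncol(pos) != ncol(neg)) {
        .stopf("class feature dimensions differ (%d vs %d)", ncol(pos), ncol(neg))
    }
    methods::new("PPIClassifier",
                 kdePos = fitKDE(pos, beta = beta, ks = ks, alpha = alpha),
                 kdeNeg = fitKDE(neg, beta = beta, ks = ks, alpha = alpha),
                 nPos = nrow(pos), nNeg = nrow(neg),
                 kt = as.integer(kt), alpha = as.numeric(alpha))
}

#' Log-likelihood-ratio score of query pairs
#'
#' `score(v) = alpha*(log nPos - log nNeg) + log f_pos(v) - log f_neg(v)`,
#' each density truncated to the query's `kt` nearest training samples of
#' that class.  Positive score means "interacting"; a tie (score exactly 0)
#' is resolved to the negative class.  Queries where both class densities
#' underflow to zero even in log space are given score 0 (hence predicted
#' negative) and reported via a warning.
#'
#' @param object A [PPIClassifier-class].
#' @param v Query feature vector or matrix (one query per row).
#' @param kt Override of the model's `kt` (optional).
#' @return Numeric score vector, one per query.
#' @export
decisionScore <- function(object, v, kt = NULL) {
    stopifnot(methods::is(object, "PPIClassifier"))
    m <- ncol(object@kdePos@samples)
    if (is.null(dim(v))) {
        v <- if (m == 1L) matrix(v, ncol = 1L) else matrix(v, nrow = 1L)
    }
    v <- as.matrix(v)
    if (ncol(v) != m) {
        .stopf("query dimension %d does not match model dimension %d",
               ncol(v), m)
    }
    if (is.null(kt)) kt <- object@kt
    lp <- .logDensity(object@kdePos, v, kt)
    ln <- .logDensity(object@kdeNeg, v, kt)
    score <- object@alpha * (log(object@nPos) - log(object@nNeg)) + lp - ln
    degenerate <- is.infinite(lp) & lp < 0 & is.infinite(ln) & ln < 0
    if (any(degenerate)) {
        warning(sum(degenerate),
                " query(ies) with zero likelihood under both classes; scored 0",
                call. = FALSE)
        score[degenerate] <- 0
    }
    score
}

#' Predict interaction labels or scores
#'
#' @param object A [PPIClassifier-class].
#' @param newdata Query feature matrix (one pair per row).
#' @param type `"class"` for logical predictions (`TRUE` = interacting) or
#'   `"score"` for the continuous log-likelihood ratio.
#' @param ... Ignored.
#' @return Logical or numeric vector, one element per query row.
#' @export
setMethod("predict", "PPIClassifier",
    function(object, newdata, type = c("class", "score"), ...) {
        type <- match.arg(type)
        sc <- suppressWarnings(decisionScore(object, newdata))
        if (type == "score") sc else sc > 0
    })

#' Grid search of RVKDE hyperparameters by cross-validated F-measure
#'
#' Evaluates every combination of the candidate values by stratified
#' k-fold cross-validation on the training pairs and returns the
#' combination with the highest mean F-measure (ties broken by grid
#' order).  Duplicated candidate values are collapsed.
#'
#' @param x Feature matrix of all training pairs.
#' @param y Logical labels (`TRUE` = interacting).
#' @param grid Named list with candidate vectors `alpha`, `beta`, `ks`,
#'   `kt`.
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `best` (named list of the selected values), `bestF`
#'   (its mean CV F-measure) and `table` (data frame of all combinations
#'   with their mean and per-fold F-measures).
#' @export
gridSearchRVKDE <- function(x, y, grid, folds = 5L, seed = 1L) {
    stopifnot(is.matrix(x), length(y) == nrow(x), is.logical(y))
    needed <- c("alpha", "beta", "ks", "kt")
    if (!all(needed %in% names(grid)) ||
        any(!vapply(grid[needed], length, 0L))) {
        .stopf("grid must supply non-empty candidates for alpha, beta, ks, kt")
    }
    if (folds < 2L) .stopf("folds must be >= 2")
    grid <- lapply(grid[needed], function(v) unique(v))
    combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    # stratified fold assignment, seeded
    fold <- integer(length(y))
    for (cls in c(TRUE, FALSE)) {
        idx <- which(y == cls)
        if (length(idx) < folds) {
            .stopf(paste("class with %d instance(s) cannot be stratified into",
                         "%d folds; regenerate the dataset or reduce folds"),
                   length(idx), folds)
        }
        fold[idx] <- .withSeed(.subSeed(seed, paste0("fold", cls)),
                               sample(rep_len(seq_len(folds), length(idx))))
    }
    foldF <- matrix(NA_real_, nrow(combos), folds)
    for (f in seq_len(folds)) {
        tr <- fold != f
        for (ci in seq_len(nrow(combos))) {
            p <- combos[ci, ]
            model <- fitPPIClassifier(x[tr & y, , drop = FALSE],
                                      x[tr & !y, , drop = FALSE],
                                      beta = p$beta, ks = p$ks, kt = p$kt,
                                      alpha = p$alpha)
            pred <- predict(model, x[!tr, , drop = FALSE])
            cc <- confusionCounts(y[!tr], pred)
            foldF[ci, f] <- computeMetrics(cc)$f_measure
        }
    }
    meanF <- rowMeans(foldF)
    bi <- which.max(meanF)
    tab <- cbind(combos, meanF = meanF,
                 stats::setNames(as.data.frame(foldF),
                                 paste0("fold", seq_len(folds))))
    list(best = as.list(combos[bi, ]), bestF = meanF[bi], table = tab)
}

#' Save / load a fitted classifier
#'
#' The archive is a versioned list (`format = "triadKDE-classifier-1"`)
#' holding, per class, the training samples and their bandwidths, plus the
#' class sizes and hyperparameters, so a model survives package upgrades
#' that change the S4 layout.
#'
#' @param object A [PPIClassifier-class].
#' @param path File to write (RDS container).
#' @return `writeClassifier` invisibly returns `path`; `readClassifier`
#'   returns the rebuilt [PPIClassifier-class].
#' @export
writeClassifier <- function(object, path) {
    stopifnot(methods::is(object, "PPIClassifier"))
    pack <- function(k) list(samples = k@samples,
                             logBandwidths = k@logBandwidths,
                             alpha = k@alpha, beta = k@beta, ks = k@ks)
    saveRDS(list(format = "triadKDE-classifier-1",
                 pos = pack(object@kdePos), neg = pack(object@kdeNeg),
                 nPos = object@nPos, nNeg = object@nNeg,
                 kt = object@kt, alpha = object@alpha),
            path)
    invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
    x <- readRDS(path)
    if (!identical(x$format, "triadKDE-classifier-1")) {
        .stopf("unrecognised classifier archive format: %s",
               paste(x$format, collapse = ","))
    }
    unpack <- function(k) methods::new("RVKDE", samples = k$samples,
                                       logBandwidths = k$logBandwidths,
                                       alpha = k$alpha, beta = k$beta,
                                       ks = k$ks)
    methods::new("PPIClassifier", kdePos = unpack(x$pos),
                 kdeNeg = unpack(x$neg), nPos = x$nPos, nNeg = x$nNeg,
                 kt = x$kt, alpha = x$alpha)
}
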