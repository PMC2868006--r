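# End-to-end ratio sweep: synthetic data -> significance encoding ->
# ratio datasets -> RVKDE classification -> repetition-aggregated metrics,
# with the trivial baselines evaluated on the same test sets.

#' Run the full imbalance benchmark on synthetic data
#'
#' Generates a proteome and interaction network, encodes every protein by
#' triad significance, builds train/test datasets at each
#' positive-to-negative ratio (disjoint negatives across ratios and
#' repetitions), trains the RVKDE pair classifier and evaluates it next to
#' the random and opportunistic baselines.  The whole run is deterministic
#' given the configuration and `seed`.
#'
#' @param cfg A [SyntheticPPIConfig-class] describing the data.
#' @param ratios Positive-to-negative ratios r of the 1:r datasets.
#' @param trainPos,testPos Positive pair counts of the train/test split;
#'   their sum may be below `cfg@nInteractions`, in which case a seeded
#'   subsample of the positives is used per repetition.
#' @param repetitions Number of repeated dataset draws.
#' @param nPermutations Permutations for the significance encoding
#'   (default 1000, the desk-scale profile; 10000 is the full-fidelity
#'   default of [significanceVector()]).
#' @param classifier Named list of RVKDE hyperparameters `alpha`, `beta`,
#'   `ks`, `kt`.
#' @param seed Integer seed driving encoding, dataset draws and the random
#'   baseline.
#' @param outDir If non-`NULL`, `report.json` and `manifest.json` are
#'   written there (created if needed).
#' @return List with `summary` (data frame: predictor, ratio, metric,
#'   mean, sd across repetitions), `perRepetition` (data frame of raw
#'   per-dataset metrics) and `params` (the run parameters); written to
#'   `outDir` as a JSON report when requested.
#' @export
ratioBenchmark <- function(cfg,
                           ratios = c(1, 3, 7, 15),
                           trainPos = 250L, testPos = 50L,
                           repetitions = 5L,
                           nPermutations = 1000L,
                           classifier = list(alpha = 1, beta = 0.25,
                                             ks = 4L, kt = 30L),
                           seed = cfg@seed,
                           outDir = NULL) {
    stopifnot(methods::is(cfg, "SyntheticPPIConfig"))
    proteome <- generateProteome(cfg)
    network <- generateNetwork(cfg, proteome)
    features <- encodeProteins(proteome, feature = "significance",
                               nPermutations = nPermutations,
                               seed = .subSeed(seed, "encode"))
    datasets <- buildRatioDatasets(network, proteins = names(proteome),
                                   ratios = ratios,
                                   trainPos = trainPos, testPos = testPos,
                                   repetitions = repetitions,
                                   seed = .subSeed(seed, "datasets"))
    rows <- list()
    for (ds in datasets) {
        xTrPos <- encodePairs(ds@trainPos, features)
        xTrNeg <- encodePairs(ds@trainNeg, features)
        xTe <- rbind(encodePairs(ds@testPos, features),
                     encodePairs(ds@testNeg, features))
        yTe <- rep(c(TRUE, FALSE), c(nrow(ds@testPos), nrow(ds@testNeg)))
        model <- fitPPIClassifier(xTrPos, xTrNeg,
                                  beta = classifier$beta, ks = classifier$ks,
                                  kt = classifier$kt, alpha = classifier$alpha)
        scores <- suppressWarnings(decisionScore(model, xTe))
        preds <- list(
            rvkde = scores > 0,
            random = baselinePredict("random", length(yTe),
                                     seed = .subSeed(seed,
                                         sprintf("baseline|%d|%g",
                                                 ds@repetition, ds@ratio))),
            opportunistic_neg = baselinePredict("opportunistic_neg",
                                                length(yTe)),
            opportunistic_pos = baselinePredict("opportunistic_pos",
                                                length(yTe)))
        for (nm in names(preds)) {
            panel <- computeMetrics(confusionCounts(yTe, preds[[nm]]))
            rows[[length(rows) + 1L]] <- data.frame(
                predictor = nm, repetition = ds@repetition,
                ratio = ds@ratio,
                precision = panel$precision, sensitivity = panel$sensitivity,
                specificity = panel$specificity, accuracy = panel$accuracy,
                f_measure = panel$f_measure)
        }
    }
    perRep <- do.call(rbind, rows)
    metricCols <- c("precision", "sensitivity", "specificity",
                    "accuracy", "f_measure")
    summ <- list()
    for (p in unique(perRep$predictor)) {
        for (r in ratios) {
            sub <- perRep[perRep$predictor == p & perRep$ratio == r, ]
            for (mc in metricCols) {
                summ[[length(summ) + 1L]] <- data.frame(
                    predictor = p, ratio = r, metric = mc,
                    mean = mean(sub[[mc]]),
                    sd = if (nrow(sub) > 1L) stats::sd(sub[[mc]]) else NA_real_)
            }
        }
    }
    params <- list(ratios = as.numeric(ratios),
                   trainPos = as.integer(trainPos),
                   testPos = as.integer(testPos),
                   repetitions = as.integer(repetitions),
                   nPermutations = as.integer(nPermutations),
                   classifier = classifier,
                   seed = as.integer(seed),
                   config = list(nProteins = cfg@nProteins,
                                 lengthRange = cfg@lengthRange,
                                 groupProfile = cfg@groupProfile,
                                 nInteractions = cfg@nInteractions,
                                 signalStrength = cfg@signalStrength,
                                 motifSet = cfg@motifSet,
                                 selectionGain = cfg@selectionGain,
                                 enrichmentPermutations =
                                     cfg@enrichmentPermutations,
                                 seed = cfg@seed))
    report <- list(summary = do.call(rbind, summ),
                   perRepetition = perRep,
                   params = params)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        reportPath <- file.path(outDir, "report.json")
        writeManifest(report, reportPath)
        manifest <- runManifest("benchmark",
                                seeds = list(seed = as.integer(seed)),
                                config = params,
                                outputs = reportPath)
        writeManifest(manifest, file.path(outDir, "manifest.json"))
    }
    report
}

#' Extract one metric of one predictor across ratios
#'
#' Convenience accessor over the [ratioBenchmark()] summary.
#'
#' @param report A [ratioBenchmark()] result (or its `summary` data
#'   frame).
#' @param metric Metric name (default `"f_measure"`).
#' @param predictor Predictor name (default `"rvkde"`).
#' @return Named numeric vector of per-ratio means (names = ratios).
#' @export
metricByRatio <- function(report, metric = "f_measure",
                          predictor = "rvkde") {
    s <- if (is.data.frame(report)) report else report$summary
    sub <- s[s$predictor == predictor & s$metric == metric, ]
    sub <- sub[order(sub$ratio), ]
    stats::setNames(sub$mean, sub$ratio)
}
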