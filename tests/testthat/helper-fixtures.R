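# Shared fixtures, computed lazily and memoised so expensive runs happen
# once per test session.

.fixtureCache <- new.env(parent = emptyenv())

# Full desk-scale benchmark: 300 proteins, 400 interactions, theta = 1,
# 1000 encoding permutations, 5 repetitions over ratios 1/3/7/15.
benchmarkFixture <- function() {
    if (is.null(.fixtureCache$benchmark)) {
        cfg <- syntheticConfig(seed = 2026L)
        .fixtureCache$benchmark <- ratioBenchmark(
            cfg, ratios = c(1, 3, 7, 15),
            trainPos = 250L, testPos = 50L,
            repetitions = 5L, nPermutations = 1000L,
            seed = 2026L)
    }
    .fixtureCache$benchmark
}

# Small configuration for fast end-to-end and determinism tests.
smallConfig <- function(seed = 7L, signalStrength = 1) {
    syntheticConfig(nProteins = 60L, lengthRange = c(30L, 80L),
                    nInteractions = 60L, signalStrength = signalStrength,
                    enrichmentPermutations = 100L, seed = seed)
}
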