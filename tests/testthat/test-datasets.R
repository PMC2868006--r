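# Positive-set filtering, negative-space arithmetic, disjoint negative
# sampling and ratio dataset construction.

toySequences <- c(A = "AALKKDYC", B = "MSTYAA", C = "AAGUVA", D = "GGVVLL",
                  E = "KKDDEE", F = "AYMTSL")

test_that("pairs canonicalise and deduplicate", {
    p <- canonicalPairs(c("B", "A", "C", "A"), c("A", "B", "D", "C"))
    expect_identical(p$idA, c("A", "C", "A"))
    expect_identical(p$idB, c("B", "D", "C"))
    # self-pairs are legal
    s <- canonicalPairs("A", "A")
    expect_identical(s$idA, s$idB)
    expect_error(canonicalPairs("", "B"), "non-empty")
})

test_that("interaction filtering applies the arity, residue and in-vivo rules", {
    rec <- data.frame(
        idA = c("A", "B", "A", "C", "A", "B", "E"),
        idB = c("B", "A", "D", "D", "E", "D", "F"),
        detection = c("in_vivo", "in_vivo", "in_vivo", "in_vivo",
                      "in_vitro", "in_vivo", "in_vivo"),
        arity = c(2L, 2L, 2L, 2L, 2L, 3L, 2L))
    res <- suppressMessages(filterInteractions(rec, toySequences))
    # (A,B) twice -> once; (C,D) removed: C contains U; (A,E) in vitro
    # removed; (B,D) arity 3 removed; (A,D) and (E,F) kept
    keys <- paste(res$positives$idA, res$positives$idB)
    expect_setequal(keys, c("A B", "A D", "E F"))
    expect_identical(res$proteins, c("A", "B", "D", "E", "F"))
    expect_equal(unname(res$stats[c("arity", "nonstandard_residue",
                                    "not_in_vivo", "duplicate")]),
                 c(1L, 1L, 1L, 1L))
    # unknown ids: error by default, droppable by policy
    rec2 <- data.frame(idA = c("A", "Q"), idB = c("B", "A"))
    expect_error(suppressMessages(filterInteractions(rec2, toySequences)), "Q")
    res2 <- suppressMessages(
        filterInteractions(rec2, toySequences, unknownIds = "drop"))
    expect_equal(nrow(res2$positives), 1L)
    # nothing surviving is an error
    rec3 <- data.frame(idA = "C", idB = "C")
    expect_error(suppressMessages(filterInteractions(rec3, toySequences)),
                 "survive")
})

test_that("negative space size is n(n+1)/2 - m", {
    expect_equal(negativeSpaceSize(3, 2), 4)
    expect_equal(negativeSpaceSize(1, 0), 1)
    expect_equal(negativeSpaceSize(6429, 38167), 20631068)
    expect_error(negativeSpaceSize(2, 10), "exclude")
})

test_that("negative sampling is uniform over the complement and disjoint", {
    prot <- LETTERS[1:6]
    excl <- canonicalPairs(c("A", "B"), c("B", "C"))
    # full complement: 21 - 2 = 19 pairs, exactly the complement set
    all19 <- sampleNegatives(prot, excl, 19L, seed = 1L)
    expect_equal(nrow(all19), 19L)
    keys <- paste(all19$idA, all19$idB)
    expect_false(any(c("A B", "B C") %in% keys))
    expect_equal(anyDuplicated(keys), 0L)
    # one more than available is an error that reports the exact count
    expect_error(sampleNegatives(prot, excl, 20L, seed = 1L), "19")
    # successive draws with the registry never share a pair, over seeds
    for (seed in 1:5) {
        n1 <- sampleNegatives(prot, excl, 7L, seed = seed)
        n2 <- sampleNegatives(prot, excl, 7L, seed = seed + 100L,
                              alreadyUsed = n1)
        k1 <- paste(n1$idA, n1$idB); k2 <- paste(n2$idA, n2$idB)
        expect_length(intersect(k1, k2), 0L)
        expect_false(any(c("A B", "B C") %in% c(k1, k2)))
    }
})

test_that("rejection sampling agrees with enumeration on its guarantees", {
    prot <- sprintf("P%02d", 1:40)
    excl <- canonicalPairs(prot[1:10], prot[11:20])
    byRejection <- sampleNegatives(prot, excl, 100L, seed = 3L,
                                   enumerationLimit = 10)
    expect_equal(nrow(byRejection), 100L)
    keys <- paste(byRejection$idA, byRejection$idB)
    expect_equal(anyDuplicated(keys), 0L)
    expect_length(intersect(keys, paste(excl$idA, excl$idB)), 0L)
    expect_true(all(byRejection$idA <= byRejection$idB))
    # deterministic given the seed
    again <- sampleNegatives(prot, excl, 100L, seed = 3L,
                             enumerationLimit = 10)
    expect_identical(byRejection, again)
})

test_that("ratio datasets have exact counts and full disjointness", {
    prot <- sprintf("P%02d", 1:12)
    pos <- canonicalPairs(prot[c(1, 2, 3, 4, 5, 6, 7, 8)],
                          prot[c(2, 3, 4, 5, 6, 7, 8, 9)])
    dss <- buildRatioDatasets(pos, proteins = prot, ratios = c(1, 3),
                              trainPos = 6L, testPos = 2L,
                              repetitions = 2L, seed = 5L)
    expect_length(dss, 4L)
    posKeys <- paste(pos$idA, pos$idB)
    allNeg <- character(0)
    for (ds in dss) {
        expect_s4_class(ds, "RatioDataset")
        expect_equal(nrow(ds@trainNeg), ds@ratio * 6)
        expect_equal(nrow(ds@testNeg), ds@ratio * 2)
        negKeys <- c(paste(ds@trainNeg$idA, ds@trainNeg$idB),
                     paste(ds@testNeg$idA, ds@testNeg$idB))
        # negatives never coincide with a known interaction
        expect_length(intersect(negKeys, posKeys), 0L)
        # and are disjoint across every dataset of the build
        expect_length(intersect(negKeys, allNeg), 0L)
        allNeg <- c(allNeg, negKeys)
        # train and test positives are disjoint
        expect_length(intersect(paste(ds@trainPos$idA, ds@trainPos$idB),
                                paste(ds@testPos$idA, ds@testPos$idB)), 0L)
    }
    # within a repetition the positive split is shared across ratios
    expect_identical(dss[[1]]@trainPos, dss[[2]]@trainPos)
    # across repetitions the splits differ (seeded independently)
    expect_false(identical(dss[[1]]@trainNeg, dss[[3]]@trainNeg))
    # determinism: identical call, identical objects
    again <- buildRatioDatasets(pos, proteins = prot, ratios = c(1, 3),
                                trainPos = 6L, testPos = 2L,
                                repetitions = 2L, seed = 5L)
    expect_identical(lapply(dss, pairSets), lapply(again, pairSets))
    # infeasible demand fails upfront
    expect_error(buildRatioDatasets(pos, proteins = prot, ratios = 15,
                                    trainPos = 6L, testPos = 2L,
                                    repetitions = 2L, seed = 1L),
                 "negative")
})

test_that("a positive subsample is used when the split is smaller", {
    prot <- sprintf("P%02d", 1:12)
    pos <- canonicalPairs(prot[1:8], prot[c(2:8, 1)])
    dss <- buildRatioDatasets(pos, proteins = prot, ratios = 1,
                              trainPos = 4L, testPos = 2L,
                              repetitions = 1L, seed = 9L)
    expect_equal(nrow(dss[[1]]@trainPos), 4L)
    expect_equal(nrow(dss[[1]]@testPos), 2L)
    expect_error(buildRatioDatasets(pos, proteins = prot, ratios = 1,
                                    trainPos = 8L, testPos = 2L,
                                    repetitions = 1L, seed = 9L),
                 "exceed")
})
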