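# Triad feature encoding: group mapping, occurrence counting, permutation
# significance, frequency baseline and pair concatenation.

test_that("amino acids map to their physicochemical groups", {
    expect_identical(mapToGroups("AGV"), c(1L, 1L, 1L))
    expect_identical(mapToGroups("C"), 7L)
    expect_identical(mapToGroups("ILFP"), rep(2L, 4L))
    expect_identical(mapToGroups("YMTS"), rep(3L, 4L))
    expect_identical(mapToGroups("HNQW"), rep(4L, 4L))
    expect_identical(mapToGroups("RK"), c(5L, 5L))
    expect_identical(mapToGroups("DE"), c(6L, 6L))
    g <- aminoAcidGroups()
    expect_length(g, 20L)
    expect_setequal(unique(g), 1:7)
})

test_that("non-standard residues are rejected with position information", {
    expect_error(mapToGroups("AUG"), "'U' at position 2")
    expect_error(mapToGroups("XAA"), "'X' at position 1")
    expect_error(mapToGroups("AAB"), "'B'")
    expect_error(mapToGroups("AAZ"), "'Z'")
    expect_error(mapToGroups(""), "non-empty")
})

test_that("triad counting enumerates overlapping windows", {
    o <- countTriads(c(1L, 1L, 1L, 1L))
    expect_equal(o[["111"]], 2L)
    expect_equal(sum(o), 2L)
    expect_equal(sum(countTriads(c(1L, 2L))), 0L)
    o2 <- countTriads(c(1L, 2L, 1L, 2L, 1L, 2L))
    expect_equal(o2[["121"]], 2L)
    expect_equal(o2[["212"]], 2L)
    expect_equal(sum(o2), 4L)
})

test_that("counts sum to L - 2 and match a naive window loop", {
    set.seed(101)
    for (L in c(3L, 10L, 57L, 200L)) {
        g <- sample(1:7, L, replace = TRUE)
        o <- countTriads(g)
        expect_equal(sum(o), L - 2L)
        expect_equal(unname(o), naiveTriadCounts(g))
    }
})

test_that("significance is zero for unobserved triads and constant sequences", {
    s <- significanceVector("AAAA", nPermutations = 200L, seed = 1L)
    expect_true(all(s == 0))
    s2 <- significanceVector("ALKDYC", nPermutations = 200L, seed = 1L)
    o2 <- countTriads(mapToGroups("ALKDYC"))
    expect_true(all(s2[o2 == 0L] == 0))
    expect_true(all(s2 >= 0 & s2 <= 1))
})

test_that("Monte-Carlo significance matches exact enumeration", {
    # AAL has group pattern (1,1,2): arrangements 112/121/211 equally
    # likely, observed triad 112 has o = 1, X < 1 in 2 of 3 arrangements.
    s <- significanceVector("AAL", nPermutations = 10000L, seed = 42L)
    expect_equal(s[["112"]], 2 / 3, tolerance = 0.03)
    # a longer mixed sequence against the enumeration oracle
    seqGroups <- mapToGroups("AALKKD")
    exact <- exactSignificance(seqGroups)
    mc <- significanceVector("AALKKD", nPermutations = 10000L, seed = 42L)
    tol <- 3 * sqrt(exact * (1 - exact) / 10000) + 1 / 10000
    expect_true(all(abs(as.numeric(mc) - exact) <= tol))
})

test_that("significance is reproducible and order-independent", {
    a <- significanceVector("AALKKDYC", nPermutations = 500L, seed = 9L)
    b <- significanceVector("AALKKDYC", nPermutations = 500L, seed = 9L)
    expect_identical(a, b)
    # same group composition in a different arrangement shares the null,
    # so a cold cache must give identical values for the same sequence
    clearSignificanceCache()
    c1 <- significanceVector("AALKKDYC", nPermutations = 500L, seed = 9L)
    expect_identical(as.numeric(a), as.numeric(c1))
    expect_error(significanceVector("AUL", 10L), "'U'")
})

test_that("frequency encoding normalises counts by window count", {
    f <- frequencyVector("AAAA")
    expect_equal(f[["111"]], 1)
    expect_equal(sum(f), 1)
    expect_equal(sum(frequencyVector("AG")), 0)
    g <- frequencyVector("AGVLKD")
    o <- countTriads(mapToGroups("AGVLKD"))
    expect_equal(as.numeric(g), as.numeric(o / 4))
})

test_that("pair encoding is symmetric, canonical and 686-dimensional", {
    fa <- seq_len(343) / 343
    fb <- rev(fa)
    p1 <- encodePair(fa, fb, "P2", "P1")
    p2 <- encodePair(fb, fa, "P1", "P2")
    expect_length(p1, 2L * 343L)
    expect_length(p1, 686L)
    expect_identical(as.numeric(p1), as.numeric(p2))
    expect_identical(attr(p1, "proteinA"), "P1")
    # without the 7-group reduction the pair vector would need 2 * 20^3
    expect_identical(as.integer(2 * length(aminoAcidGroups())^3), 16000L)
    # self-pair: halves identical
    ps <- encodePair(fa, fa, "P1", "P1")
    expect_identical(ps[1:343], ps[344:686])
    expect_error(encodePair(fa[-1], fb, "a", "b"), "343")
})

test_that("protein sets encode to a feature matrix with drop policy", {
    seqs <- c(A = "AALKKDYC", B = "AAAA", C = "AAUA")
    expect_error(encodeProteins(seqs, nPermutations = 50L), "'U'")
    m <- suppressMessages(
        encodeProteins(seqs, nPermutations = 50L, onInvalid = "drop"))
    expect_identical(rownames(m), c("A", "B"))
    expect_identical(attr(m, "dropped"), "C")
    expect_identical(dim(m), c(2L, 343L))
    pm <- encodePairs(data.frame(idA = "B", idB = "A"), m)
    expect_identical(dim(pm), c(1L, 686L))
    expect_identical(rownames(pm), "A|B")
    expect_error(encodePairs(data.frame(idA = "A", idB = "Z"), m), "Z")
})
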