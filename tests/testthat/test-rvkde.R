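# RVKDE density estimation and the two-class likelihood classifier.

test_that("neighbour radii drive the bandwidths", {
    m <- fitKDE(c(0, 1, 3), beta = 1, ks = 1L)
    # in 1-D, V_1(R) = 2R, so sigma = beta * 2R / ks; R = (1, 1, 2)
    expect_equal(bandwidths(m), c(2, 2, 4))
    # ks = n - 1: radius is the distance to the farthest other sample
    m2 <- fitKDE(c(0, 1, 3), beta = 0.5, ks = 2L)
    expect_equal(bandwidths(m2), 0.5 * 2 * c(3, 2, 3) / 2)
    # 2-D unit grid with ks = 1: all radii equal the spacing
    grid <- as.matrix(expand.grid(0:3, 0:3))
    m3 <- fitKDE(grid, beta = 1, ks = 1L)
    expect_equal(length(unique(round(bandwidths(m3), 12))), 1L)
    expect_error(fitKDE(c(0, 1), beta = 1, ks = 2L), "ks \\+ 1")
})

test_that("single-component density equals the closed-form normal pdf", {
    m <- fitKDE(matrix(c(0, 10), ncol = 1), beta = 1, ks = 1L)
    sig <- bandwidths(m)
    v <- c(-1, 0.3, 2, 9.4)
    expect_equal(densityAt(m, v),
                 (stats::dnorm(v, 0, sig[1]) + stats::dnorm(v, 10, sig[2])) / 2,
                 tolerance = 1e-12)
})

test_that("untruncated density matches the naive double-loop oracle", {
    set.seed(5)
    X <- matrix(rnorm(200 * 3), ncol = 3)
    m <- fitKDE(X, beta = 1.3, ks = 4L)
    sig <- bandwidths(m)
    V <- matrix(rnorm(10 * 3), ncol = 3)
    got <- densityAt(m, V, kt = nrow(X))
    want <- vapply(seq_len(nrow(V)), function(q) naiveKDE(X, sig, V[q, ]), 0)
    expect_equal(got, want, tolerance = 1e-10)
})

test_that("the untruncated estimator integrates to one", {
    set.seed(11)
    m1 <- fitKDE(rnorm(40), beta = 1, ks = 3L)
    total <- stats::integrate(function(z) densityAt(m1, z), -30, 30,
                              subdivisions = 500L)$value
    expect_equal(total, 1, tolerance = 1e-3)
    # 2-D by midpoint quadrature
    X <- matrix(rnorm(60), ncol = 2)
    m2 <- fitKDE(X, beta = 1, ks = 2L)
    h <- 0.05
    gr <- seq(-8, 8, by = h)
    cells <- as.matrix(expand.grid(gr + h / 2, gr + h / 2))
    expect_equal(sum(densityAt(m2, cells)) * h^2, 1, tolerance = 1e-3)
})

test_that("beta rescales all bandwidths linearly", {
    set.seed(3)
    X <- matrix(rnorm(50 * 2), ncol = 2)
    b1 <- bandwidths(fitKDE(X, beta = 1, ks = 3L))
    b2 <- bandwidths(fitKDE(X, beta = 2.5, ks = 3L))
    expect_equal(b2, 2.5 * b1, tolerance = 1e-12)
})

test_that("truncation error shrinks monotonically as kt grows", {
    set.seed(8)
    X <- matrix(rnorm(80 * 2), ncol = 2)
    m <- fitKDE(X, beta = 1, ks = 3L)
    v <- c(0.2, -0.4)
    full <- densityAt(m, v, kt = nrow(X))
    errs <- vapply(seq_len(nrow(X)), function(kt) {
        abs(densityAt(m, v, kt = kt) - full)
    }, 0)
    expect_true(all(diff(errs) <= 1e-14))
    expect_equal(errs[length(errs)], 0)
})

test_that("duplicate training points get a floored positive bandwidth", {
    X <- matrix(c(0, 0, 1, 3), ncol = 1)
    m <- fitKDE(X, beta = 1, ks = 1L)
    expect_true(all(is.finite(m@logBandwidths)))
    expect_true(all(bandwidths(m) > 0))
    expect_true(is.finite(densityAt(m, 0, log = TRUE)))
})

test_that("the classifier respects symmetry, priors and the tie rule", {
    # symmetric 1-D setup: boundary at 0, tie scored 0, predicted negative
    P <- matrix(c(-1, -1.5), ncol = 1)
    N <- matrix(c(1, 1.5), ncol = 1)
    m <- fitPPIClassifier(P, N, beta = 1, ks = 1L, kt = 2L)
    expect_equal(decisionScore(m, 0), 0)
    expect_false(predict(m, matrix(0)))
    expect_true(predict(m, matrix(-1.2)))
    expect_false(predict(m, matrix(1.2)))
    # identical point sets, equal sizes: score 0 everywhere
    Z <- matrix(c(0, 1, 2.5), ncol = 1)
    ms <- fitPPIClassifier(Z, Z, beta = 1, ks = 1L, kt = 3L)
    expect_equal(decisionScore(ms, c(-1, 0.4, 3)), rep(0, 3))
    # identical densities but a larger negative class: negative wins
    kde <- fitKDE(Z, beta = 1, ks = 1L)
    mp <- methods::new("PPIClassifier", kdePos = kde, kdeNeg = kde,
                       nPos = 5L, nNeg = 10L, kt = 3L, alpha = 1)
    expect_true(all(decisionScore(mp, c(-1, 0.4, 3)) < 0))
    # and with alpha = 0 the prior is neutralised again
    mp0 <- methods::new("PPIClassifier", kdePos = kde, kdeNeg = kde,
                        nPos = 5L, nNeg = 10L, kt = 3L, alpha = 0)
    expect_equal(decisionScore(mp0, c(-1, 0.4, 3)), rep(0, 3),
                 tolerance = 1e-12)
})

test_that("kt = n scores equal the brute-force log-likelihood ratio", {
    set.seed(21)
    P <- matrix(rnorm(60, 1), ncol = 2)
    N <- matrix(rnorm(80, -1), ncol = 2)
    m <- fitPPIClassifier(P, N, beta = 1, ks = 2L, kt = max(nrow(P), nrow(N)))
    sp <- bandwidths(m@kdePos); sn <- bandwidths(m@kdeNeg)
    v <- c(0.3, -0.2)
    want <- log(nrow(P) * naiveKDE(P, sp, v)) -
        log(nrow(N) * naiveKDE(N, sn, v))
    expect_equal(decisionScore(m, v), want, tolerance = 1e-10)
})

test_that("well-separated Gaussian clouds are classified accurately", {
    set.seed(99)
    tr1 <- matrix(rnorm(400, 2), ncol = 2)
    tr0 <- matrix(rnorm(400, -2), ncol = 2)
    te <- rbind(matrix(rnorm(200, 2), ncol = 2),
                matrix(rnorm(200, -2), ncol = 2))
    y <- rep(c(TRUE, FALSE), each = 100)
    m <- fitPPIClassifier(tr1, tr0, beta = 1, ks = 5L, kt = 50L)
    expect_gte(mean(predict(m, te) == y), 0.95)
})

test_that("grid search maximises cross-validated F-measure", {
    set.seed(31)
    x <- rbind(matrix(rnorm(120, 1.5), ncol = 2),
               matrix(rnorm(120, -1.5), ncol = 2))
    y <- rep(c(TRUE, FALSE), each = 60)
    one <- gridSearchRVKDE(x, y, list(alpha = 1, beta = 1, ks = 3L, kt = 20L),
                           folds = 5L, seed = 1L)
    expect_equal(one$best, list(alpha = 1, beta = 1, ks = 3L, kt = 20L))
    # duplicated candidates collapse to the deduplicated grid
    dup <- gridSearchRVKDE(x, y,
                           list(alpha = c(1, 1), beta = c(1, 2, 2),
                                ks = 3L, kt = c(20L, 20L)),
                           folds = 5L, seed = 1L)
    ded <- gridSearchRVKDE(x, y,
                           list(alpha = 1, beta = c(1, 2), ks = 3L, kt = 20L),
                           folds = 5L, seed = 1L)
    expect_equal(dup$best, ded$best)
    expect_equal(nrow(dup$table), 2L)
    # the selected combination beats every other grid point's mean CV F
    g <- list(alpha = c(0.5, 1), beta = c(0.5, 1.5), ks = c(2L, 4L),
              kt = c(10L, 40L))
    res <- gridSearchRVKDE(x, y, g, folds = 5L, seed = 2L)
    expect_equal(nrow(res$table), 16L)
    expect_true(all(res$bestF >= res$table$meanF))
    # a class too small for the folds is a stratification error
    expect_error(gridSearchRVKDE(x[c(1, 61:120), ], y[c(1, 61:120)],
                                 list(alpha = 1, beta = 1, ks = 1L, kt = 5L),
                                 folds = 5L, seed = 1L),
                 "stratifi")
})
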