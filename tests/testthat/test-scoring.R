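test_that("plain Pearson follows the zero-variance convention", {
    expect_equal(pearsonPlain(c(1, 2, 3), c(2, 4, 6)), 1)
    expect_equal(pearsonPlain(c(1, 2, 3), c(3, 2, 1)), -1)
    expect_equal(pearsonPlain(c(5, 5, 5), c(1, 2, 3)), 0)
    expect_error(pearsonPlain(1:3, 1:4), "lengths differ")
})

test_that("noised Pearson reduces to plain Pearson when noise is off", {
    for (seed in 1:50) {
        set.seed(seed)
        n <- sample(5:20, 1)
        x <- stats::rpois(n, 3); y <- stats::rpois(n, 3)
        expect_identical(
            pearsonPoissonNoise(x, y, ScoreParams(noiseReps = 0L)),
            pearsonPlain(x, y))
    }
    expect_error(pearsonPoissonNoise(c(0.5, 1, 2), c(1, 1, 1)),
                 "integer")
})

test_that("noised Pearson is deterministic, symmetric and calibrated", {
    x <- c(0L, 3L, 9L, 2L, 0L, 1L)
    y <- c(1L, 2L, 8L, 3L, 0L, 0L)
    p <- ScoreParams(noiseReps = 50L, rngSeed = 7L)
    expect_identical(pearsonPoissonNoise(x, y, p),
                     pearsonPoissonNoise(x, y, p))  # bit-reproducible
    expect_identical(pearsonPoissonNoise(x, y, p),
                     pearsonPoissonNoise(y, x, p))  # exactly symmetric

    # independent noise-only profiles: expectation 0
    z <- rep(0L, 5)
    s0 <- pearsonPoissonNoise(z, z, ScoreParams(noiseReps = 1000L,
                                                pseudocount = 1,
                                                rngSeed = 11L))
    expect_lt(abs(s0), 0.1)

    # small noise barely perturbs a perfectly correlated pair
    v <- c(0L, 20L, 80L, 20L, 0L)
    s1 <- pearsonPoissonNoise(v, v, ScoreParams(noiseReps = 2000L,
                                                pseudocount = 0.1,
                                                rngSeed = 11L))
    expect_lt(s1, 1)
    expect_gt(s1, 0.95)
})

test_that("weighted cross-correlation matches the direct-summation oracle", {
    set.seed(12)
    for (i in 1:40) {
        n <- sample(10:60, 1)
        K <- sample(0:2, 1)
        x <- stats::rpois(n, 2); y <- stats::rpois(n, 2)
        expect_equal(
            weightedCrossCorrelation(x, y, ScoreParams(maxLag = K)),
            wccOracle(x, y, K), tolerance = 1e-12)
    }
})

test_that("weighted cross-correlation reduces to Pearson at K = 0 and rewards matching lags", {
    set.seed(2)
    for (i in 1:50) {
        x <- stats::rpois(10, 2); y <- stats::rpois(10, 2)
        expect_identical(
            weightedCrossCorrelation(x, y, ScoreParams(maxLag = 0L)),
            pearsonPlain(x, y))
    }
    # one-fraction offset peaks: the matching lag contributes rho = 1
    x <- c(0, 0, 10, 0, 0, 0)
    y <- c(0, 0, 0, 10, 0, 0)
    rho0 <- stats::cor(x, y)
    rho1 <- stats::cor(x[2:6], y[1:5])
    hand <- (0.5 * 1 + 1 * rho0 + 0.5 * rho1) / 2
    expect_equal(weightedCrossCorrelation(x, y, ScoreParams(maxLag = 1L)),
                 hand, tolerance = 1e-12)
    expect_error(weightedCrossCorrelation(1:5, 1:5,
                                          ScoreParams(maxLag = 3L)),
                 "maxLag")
})

test_that("co-apex score follows the earliest-max rule", {
    expect_equal(coApex(c(0, 9, 1), c(2, 7, 0)), 1)
    expect_equal(coApex(c(9, 0, 0, 0), c(0, 0, 0, 9)), 0.25)  # distance 3
    expect_equal(coApex(c(5, 5, 1), c(9, 0, 0)), 1)  # tie -> earliest
    expect_true(is.na(coApex(c(0, 0, 0), c(1, 2, 3))))
    # translation never changes it when the apex is unique
    set.seed(4)
    for (i in 1:20) {
        x <- sample(10); y <- sample(10)
        expect_identical(coApex(x, y), coApex(x + 3, y + 7))
    }
})

test_that("Euclidean similarity is normalized, bounded and scale-invariant", {
    expect_equal(euclideanSimilarity(c(2, 3, 1), c(2, 3, 1)), 1)
    expect_equal(euclideanSimilarity(c(1, 0), c(0, 1)), 0)
    expect_equal(euclideanSimilarity(c(1, 1, 0, 0), c(0, 0, 1, 1)),
                 1 - 1 / sqrt(2))
    expect_true(is.na(euclideanSimilarity(c(0, 0), c(1, 1))))
    set.seed(9)
    for (i in 1:20) {
        x <- stats::rlnorm(6); y <- stats::rlnorm(6)
        c1 <- stats::runif(1, 0.01, 100)
        expect_equal(euclideanSimilarity(x * c1, y),
                     euclideanSimilarity(x, y), tolerance = 1e-12)
    }
})

test_that("experiment scoring enumerates exactly the qualifying pairs", {
    # three mutually overlapping proteins -> C(3,2) records
    vAll <- matrix(c(1, 2, 3, 0,
                     0, 1, 4, 1,
                     1, 1, 1, 2), 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), NULL))
    mAll <- ProfileMatrix(cbind(vAll, 0, 0, 0), "MS2_COUNTS", "e", "s")
    expect_equal(nrow(scoreExperiment(mAll,
                                      params = ScoreParams(noiseReps = 10L))),
                 3L)
    # C elutes in fractions disjoint from A and B -> only the A/B pair
    v <- matrix(c(0, 2, 3, 0,
                  0, 1, 4, 0,
                  1, 0, 0, 2), 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), NULL))
    m <- ProfileMatrix(cbind(v, 0, 0, 0), "MS2_COUNTS", "e", "s")
    sAB <- scoreExperiment(m, params = ScoreParams(noiseReps = 0L,
                                                   minOverlap = 1L))
    expect_equal(nrow(sAB), 1L)
    expect_equal(sAB$protein_a, "A")
    expect_equal(sAB$protein_b, "B")
})

test_that("scored pair count matches brute-force overlap enumeration", {
    v <- randomCountMatrix(20, 12, seed = 31, lambda = 0.7)
    m <- ProfileMatrix(v, "MS2_COUNTS", "e", "s")
    for (minOv in c(1L, 2L, 3L)) {
        s <- scoreExperiment(m, params = ScoreParams(noiseReps = 0L,
                                                     minOverlap = minOv))
        want <- 0L
        for (i in 1:19) for (j in (i + 1):20)
            if (sum(v[i, ] > 0 & v[j, ] > 0) >= minOv) want <- want + 1L
        expect_equal(nrow(s), want)
    }
})

test_that("experiment scoring is invariant to row order and includes MS1 only when present", {
    v <- randomCountMatrix(8, 10, seed = 13, lambda = 1.5)
    m <- ProfileMatrix(v, "MS2_COUNTS", "e", "s")
    perm <- ProfileMatrix(v[sample(8), ], "MS2_COUNTS", "e", "s")
    p <- ScoreParams(noiseReps = 20L, rngSeed = 3L)
    expect_identical(scoreExperiment(m, params = p),
                     scoreExperiment(perm, params = p))
    # without MS1 every euclid_sim is missing
    expect_true(all(is.na(scoreExperiment(m, params = p)$euclid_sim)))
    ms1 <- ProfileMatrix(v[1:4, ] + 0.5, "MS1_INTENSITY", "e", "s")
    s <- scoreExperiment(m, ms1, p)
    inMs1 <- s$protein_a %in% rownames(v)[1:4] &
        s$protein_b %in% rownames(v)[1:4]
    expect_true(all(!is.na(s$euclid_sim[inMs1])))
    expect_true(all(is.na(s$euclid_sim[!inMs1])))
})

test_that("co-complex pairs score higher than random pairs on synthetic data", {
    w <- defaultWorld()
    tab <- defaultFeatureTable()
    pcc <- rowMeans(tab[, grep("__pcc_noise$", colnames(tab))],
                    na.rm = TRUE)
    pos <- which(tab$label == "positive")
    neg <- which(tab$label == "negative")
    expect_gte(length(pos) + length(neg), 500L)
    expect_gt(mean(pcc[pos]), mean(pcc[neg]))
    wt <- stats::wilcox.test(pcc[pos], pcc[neg],
                             alternative = "greater")
    expect_lt(wt$p.value, 0.01)
})
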