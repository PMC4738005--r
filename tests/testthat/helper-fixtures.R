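## Shared fixtures, computed once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

## The reference study conditions: default SimParams, fixed seed.
defaultWorld <- function() {
    if (is.null(.fixtures$world))
        .fixtures$world <- generateWorld(SimParams(seed = 101L))
    .fixtures$world
}

## Small, fast world for structural tests.
tinyWorld <- function() {
    if (is.null(.fixtures$tiny))
        .fixtures$tiny <- generateWorld(SimParams(
            nSpecies = 1L, nComplexes = 6L, nMonomers = 10L,
            nExperimentsPerSpecies = 1L, nFractions = 30L, seed = 5L))
    .fixtures$tiny
}

## Reference-namespace scores for every experiment of the default world.
defaultMappedScores <- function() {
    if (is.null(.fixtures$mapped)) {
        w <- defaultWorld()
        params <- ScoreParams(rngSeed = 101L)
        .fixtures$mapped <- lapply(names(w@experiments), function(eid) {
            ex <- w@experiments[[eid]]
            s <- scoreExperiment(ex$ms2, filterMS1ByMS2(ex$ms1, ex$ms2),
                                 params)
            mapScoresToReference(s, w@orthologMaps[[ex$species]])
        })
    }
    .fixtures$mapped
}

## Labeled feature table over the default world.
defaultFeatureTable <- function() {
    if (is.null(.fixtures$table)) {
        w <- defaultWorld()
        tab <- buildFeatureTable(defaultMappedScores())
        tab$label <- derivePairLabels(w@goldStandard, tab)
        .fixtures$table <- tab
    }
    .fixtures$table
}

## Write a wide profile TSV by hand (independent of writeProfileMatrix).
writeProfileTsv <- function(lines, path = tempfile(fileext = ".tsv")) {
    writeLines(lines, path)
    path
}

## Independent weighted-cross-correlation oracle: per lag, align the two
## profiles by explicit index enumeration and use stats::cor.
wccOracle <- function(x, y, K) {
    n <- length(x)
    num <- 0
    den <- 0
    for (k in seq.int(-K, K)) {
        ii <- (1:n)[(1:n) - k >= 1 & (1:n) - k <= n]
        a <- vapply(ii, function(i) x[i], numeric(1))
        b <- vapply(ii, function(i) y[i - k], numeric(1))
        rho <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else
            stats::cor(a, b)
        w <- 1 / (1 + abs(k))
        num <- num + w * rho
        den <- den + w
    }
    num / den
}

## Random non-negative count matrix for profile fixtures.
randomCountMatrix <- function(nProt, nFrac, seed, lambda = 2) {
    set.seed(seed)
    matrix(stats::rpois(nProt * nFrac, lambda), nProt, nFrac,
           dimnames = list(sprintf("P%03d", seq_len(nProt)), NULL))
}
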