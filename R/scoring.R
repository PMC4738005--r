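## Deterministic per-pair noise substreams: a seed is derived from the
## (global seed, canonical pair id) so that scoring is reproducible and
## exactly symmetric in the two proteins.
.hashString <- function(s) {
    h <- 17
    for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 2147483629
    h
}

.pairSeed <- function(seed, a, b) {
    h <- .hashString(paste(a, b, sep = "\r"))
    as.integer((h * 31 + (as.numeric(seed) %% 2147483629)) %% 2147483629) + 1L
}

## TRUE when a precedes b lexicographically (element-wise numeric order).
.lexLess <- function(a, b) {
    d <- which(a != b)
    length(d) > 0L && a[d[1L]] < b[d[1L]]
}

#' Pearson correlation with a zero-variance convention
#'
#' Standard Pearson correlation of two equal-length fraction vectors,
#' defined as 0 when either vector is constant. Flat profiles carry no
#' co-elution information, and downstream learners need total (non-NaN)
#' feature values.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @export
pearsonPlain <- function(x, y) {
    if (length(x) != length(y))
        stop("profile lengths differ: ", length(x), " vs ", length(y))
    if (length(x) < 3L) stop("need at least 3 fractions")
    .pearsonRaw(x, y)
}

## no length checks; shared by WCC overlap windows
.pearsonRaw <- function(x, y) {
    xc <- x - mean(x)
    yc <- y - mean(y)
    den <- sqrt(sum(xc^2) * sum(yc^2))
    if (den == 0) return(0)
    min(1, max(-1, sum(xc * yc) / den))
}

## mean Pearson over R Poisson-noised replicate pairs; x consumes the
## first block of the RNG stream. Vectorized across replicates.
.noisedPearsonMean <- function(x, y, R, p) {
    n <- length(x)
    X <- matrix(stats::rpois(R * n, rep(x + p, each = R)), R, n)
    Y <- matrix(stats::rpois(R * n, rep(y + p, each = R)), R, n)
    Xc <- X - rowMeans(X)
    Yc <- Y - rowMeans(Y)
    den <- sqrt(rowSums(Xc^2) * rowSums(Yc^2))
    num <- rowSums(Xc * Yc)
    r <- ifelse(den == 0, 0, num / den)
    mean(pmin(1, pmax(-1, r)))
}

#' Pearson correlation with added Poisson noise
#'
#' The noised MS2 co-elution score: each of R replicates redraws every
#' count as Poisson(count + p) and the replicate Pearson correlations are
#' averaged. The pseudocount p keeps sparse profiles from correlating
#' perfectly by shared zeros; R = 0 disables noise and returns
#' \code{\link{pearsonPlain}}. The noise stream is deterministic given
#' \code{rngSeed} and symmetric in the two profiles (the lexicographically
#' smaller profile always consumes the first block of draws), so
#' \code{score(x, y) == score(y, x)} exactly.
#'
#' @param x,y non-negative integer MS2 count vectors of equal length >= 3.
#' @param params a \linkS4class{ScoreParams} (uses \code{noiseReps},
#'   \code{pseudocount}, \code{rngSeed}).
#' @return score in [-1, 1].
#' @export
pearsonPoissonNoise <- function(x, y, params = ScoreParams()) {
    if (length(x) != length(y))
        stop("profile lengths differ: ", length(x), " vs ", length(y))
    if (length(x) < 3L) stop("need at least 3 fractions")
    if (any(x < 0) || any(y < 0) ||
        any(abs(x - round(x)) > 1e-9) || any(abs(y - round(y)) > 1e-9))
        stop("MS2 counts must be non-negative integers")
    R <- params@noiseReps
    if (R == 0L) return(pearsonPlain(x, y))
    if (.lexLess(y, x)) { tmp <- x; x <- y; y <- tmp }
    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    set.seed(params@rngSeed)
    .noisedPearsonMean(x, y, R, params@pseudocount)
}

#' Weighted cross-correlation of two elution profiles
#'
#' Averages the Pearson correlation of the two profiles over relative
#' shifts (lags) k = -K..K, weighting lag k by 1/(1 + |k|) so that the
#' unshifted correlation dominates while small elution offsets - as caused
#' by slightly different peak positions across a complex - still
#' contribute:
#' \deqn{WCC = \sum_k w_k \rho_k / \sum_k w_k, \quad w_k = 1/(1+|k|)}
#' where \eqn{\rho_k} is the Pearson correlation of the length (n - |k|)
#' aligned overlap. K = 0 reduces to \code{\link{pearsonPlain}}.
#'
#' @param x,y numeric vectors of equal length n with n - K >= 3.
#' @param params a \linkS4class{ScoreParams} (uses \code{maxLag}).
#' @return score in [-1, 1].
#' @export
weightedCrossCorrelation <- function(x, y, params = ScoreParams()) {
    if (length(x) != length(y))
        stop("profile lengths differ: ", length(x), " vs ", length(y))
    K <- params@maxLag
    n <- length(x)
    if (n - K < 3L)
        stop(sprintf("maxLag %d too large for %d fractions", K, n))
    num <- 0
    den <- 0
    for (k in seq.int(-K, K)) {
        a <- if (k >= 0) x[seq_len(n - k) + k] else x[seq_len(n + k)]
        b <- if (k >= 0) y[seq_len(n - k)] else y[seq_len(n + k) - k]
        w <- 1 / (1 + abs(k))
        num <- num + w * .pearsonRaw(a, b)
        den <- den + w
    }
    num / den
}

#' Co-apex score
#'
#' The apex of a profile is the first fraction index attaining its
#' maximum; the score is \eqn{1/(1 + |apex(x) - apex(y)|)} in (0, 1],
#' so proteins peaking in the same fraction score 1. All-zero profiles
#' have no apex: the score is missing (NA), not an error.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return score in (0, 1], or \code{NA_real_} when either profile is
#'   all-zero.
#' @export
coApex <- function(x, y) {
    if (length(x) != length(y))
        stop("profile lengths differ: ", length(x), " vs ", length(y))
    if (all(x == 0) || all(y == 0)) return(NA_real_)
    1 / (1 + abs(which.max(x) - which.max(y)))
}

#' Euclidean similarity of normalized MS1 profiles
#'
#' Profiles are scaled to unit sum (so the score is invariant to overall
#' protein abundance), then the Euclidean distance d is mapped to a
#' similarity \eqn{1 - d/\sqrt{2}} in [0, 1]: for non-negative unit-sum
#' vectors d is at most \eqn{\sqrt{2}}, attained by disjoint profiles.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return similarity in [0, 1], or \code{NA_real_} when either profile
#'   has zero total signal.
#' @export
euclideanSimilarity <- function(x, y) {
    if (length(x) != length(y))
        stop("profile lengths differ: ", length(x), " vs ", length(y))
    if (sum(x) == 0 || sum(y) == 0) return(NA_real_)
    xh <- normalizeRow(x, "UNIT_SUM")
    yh <- normalizeRow(y, "UNIT_SUM")
    1 - sqrt(sum((xh - yh)^2)) / sqrt(2)
}

.saveRNG <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restoreRNG <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Score all protein pairs of one experiment
#'
#' Computes the four co-elution scores for every unordered protein pair of
#' the MS2 matrix whose profiles are both nonzero in at least
#' \code{minOverlap} common fractions: the Poisson-noised Pearson
#' correlation, the weighted cross-correlation and the co-apex score from
#' MS2 counts, and the Euclidean profile similarity from MS1 intensities
#' (missing when MS1 is absent or lacks either protein). Pairs failing the
#' overlap requirement are omitted. Pair order is canonical
#' (\code{protein_a < protein_b}) and per-pair noise substreams make the
#' result independent of row order and reproducible across runs.
#'
#' @param ms2 MS2 \linkS4class{ProfileMatrix}.
#' @param ms1 optional MS1 \linkS4class{ProfileMatrix}, already restricted
#'   via \code{\link{filterMS1ByMS2}}.
#' @param params a \linkS4class{ScoreParams}.
#' @return data.frame with columns \code{protein_a}, \code{protein_b},
#'   \code{experiment_id}, \code{pcc_noise}, \code{wcc}, \code{coapex},
#'   \code{euclid_sim} (missing values are NA), sorted by pair.
#' @export
scoreExperiment <- function(ms2, ms1 = NULL, params = ScoreParams()) {
    v2 <- profileValues(ms2)
    n <- ncol(v2)
    if (params@maxLag >= n - 2L)
        stop("maxLag must be smaller than nFractions - 2")
    empty <- data.frame(protein_a = character(0), protein_b = character(0),
                        experiment_id = character(0),
                        pcc_noise = numeric(0), wcc = numeric(0),
                        coapex = numeric(0), euclid_sim = numeric(0),
                        stringsAsFactors = FALSE)
    if (nrow(v2) < 2L) return(empty)
    if (!is.null(ms1) &&
        !identical(experimentId(ms1), experimentId(ms2)))
        stop("MS1/MS2 experiment mismatch")
    v1 <- if (is.null(ms1)) NULL else profileValues(ms1)
    nz <- v2 > 0
    ov <- tcrossprod(nz * 1)
    idx <- which(upper.tri(ov) & ov >= params@minOverlap, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(empty)
    ids <- rownames(v2)
    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    m <- nrow(idx)
    pa <- pb <- character(m)
    pcc <- wcc <- cap <- euc <- numeric(m)
    for (r in seq_len(m)) {
        i <- idx[r, 1L]; j <- idx[r, 2L]
        a <- ids[i]; b <- ids[j]
        if (a > b) { tmp <- a; a <- b; b <- tmp; tmp <- i; i <- j; j <- tmp }
        x <- v2[i, ]; y <- v2[j, ]
        pa[r] <- a; pb[r] <- b
        if (params@noiseReps == 0L) {
            pcc[r] <- .pearsonRaw(x, y)
        } else {
            set.seed(.pairSeed(params@rngSeed, a, b))
            pcc[r] <- .noisedPearsonMean(x, y, params@noiseReps,
                                         params@pseudocount)
        }
        wcc[r] <- weightedCrossCorrelation(x, y, params)
        cap[r] <- coApex(x, y)
        euc[r] <- if (!is.null(v1) && a %in% rownames(v1) &&
                      b %in% rownames(v1))
            euclideanSimilarity(v1[a, ], v1[b, ]) else NA_real_
    }
    out <- data.frame(protein_a = pa, protein_b = pb,
                      experiment_id = experimentId(ms2),
                      pcc_noise = pcc, wcc = wcc, coapex = cap,
                      euclid_sim = euc, stringsAsFactors = FALSE)
    out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read and write pair-score tables
#'
#' Long-format TSV with columns \code{protein_a}, \code{protein_b},
#' \code{experiment_id}, \code{pcc_noise}, \code{wcc}, \code{coapex},
#' \code{euclid_sim}; missing scores are the literal \code{NA}.
#'
#' @param scores data.frame as returned by \code{\link{scoreExperiment}}.
#' @param path file path.
#' @return \code{readPairScores} returns the data.frame;
#'   \code{writePairScores} invisibly returns \code{path}.
#' @export
writePairScores <- function(scores, path) {
    num <- c("pcc_noise", "wcc", "coapex", "euclid_sim")
    out <- scores
    for (cn in num) out[[cn]] <- ifelse(is.na(out[[cn]]), "NA",
                                        sprintf("%.17g", out[[cn]]))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writePairScores
#' @export
readPairScores <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("character", "character", "character",
                                     rep("numeric", 4)),
                      na.strings = "NA", stringsAsFactors = FALSE)
}
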