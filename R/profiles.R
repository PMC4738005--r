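#' Read a wide elution-profile TSV
#'
#' Parses one experiment's proteins x fractions quantitation table. The
#' expected format is UTF-8 tab-separated text with a header row; the
#' first column holds gene-level protein identifiers and the remaining
#' columns the fractions in elution order. Missing cells are an error, not
#' implicit zeros: an undetected protein/fraction is an explicit 0, so a
#' short row indicates a truncated file.
#'
#' @param path path to the TSV file.
#' @param quantKind \code{"MS2_COUNTS"} (values must be whole numbers) or
#'   \code{"MS1_INTENSITY"}.
#' @param experimentId,species labels stored in the result's metadata.
#' @return a validated \linkS4class{ProfileMatrix}.
#' @seealso \code{\link{writeProfileMatrix}} for the inverse.
#' @export
readProfileMatrix <- function(path,
                              quantKind = c("MS2_COUNTS", "MS1_INTENSITY"),
                              experimentId, species) {
    quantKind <- match.arg(quantKind)
    if (!file.exists(path)) stop("profile file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    if (length(lines) == 0L) stop("empty profile file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1L]]
    nf <- length(header) - 1L
    if (nf < 1L) stop("profile header must name at least one fraction: ", path)
    body <- fields[-1L]
    lens <- lengths(body)
    if (any(lens != nf + 1L)) {
        bad <- which(lens != nf + 1L)[1L]
        stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                     bad + 1L, path, lens[bad], nf + 1L))
    }
    ids <- vapply(body, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicate protein id: ", ids[duplicated(ids)][1L])
    vals <- matrix(NA_real_, length(body), nf,
                   dimnames = list(ids, header[-1L]))
    for (i in seq_along(body)) {
        v <- suppressWarnings(as.numeric(body[[i]][-1L]))
        if (anyNA(v))
            stop(sprintf("non-numeric or missing value at line %d of %s",
                         i + 1L, path))
        vals[i, ] <- v
    }
    if (any(vals < 0))
        stop("negative quantitation value in ", path)
    if (quantKind == "MS2_COUNTS" && any(abs(vals - round(vals)) > 1e-9))
        stop("MS2 spectral counts must be whole numbers in ", path)
    ProfileMatrix(vals, quantKind, experimentId, species)
}

#' Write a ProfileMatrix as wide TSV
#'
#' Inverse of \code{\link{readProfileMatrix}}: header
#' \code{protein<TAB>f1<TAB>f2...}, one row per protein. Doubles are
#' written with 17 significant digits so that read-back reproduces the
#' values bit-exactly.
#'
#' @param m a \linkS4class{ProfileMatrix}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeProfileMatrix <- function(m, path) {
    v <- profileValues(m)
    header <- paste(c("protein", colnames(v)), collapse = "\t")
    fmt <- function(x) {
        out <- sprintf("%.17g", x)
        whole <- x == round(x) & abs(x) < 1e15
        out[whole] <- sprintf("%.0f", x[whole])
        out
    }
    rows <- if (nrow(v)) {
        vapply(seq_len(nrow(v)), function(i)
            paste(c(rownames(v)[i], fmt(v[i, ])), collapse = "\t"),
            character(1))
    } else character(0)
    writeLines(c(header, rows), path, useBytes = TRUE)
    invisible(path)
}

#' Assemble an MS2 profile matrix from long-format PSM counts
#'
#' Bridges upstream search output (one row per protein/fraction count) to
#' profile form. Counts for identical (protein, fraction) pairs are
#' summed; absent cells are zero. Fraction indices are 0-based.
#'
#' @param records data.frame with columns \code{protein},
#'   \code{fraction_index} (0-based integer) and \code{count}
#'   (non-negative integer).
#' @param nFractions total number of fractions of the experiment.
#' @param experimentId,species metadata labels.
#' @return an MS2 \linkS4class{ProfileMatrix}; proteins appear in first-seen
#'   order.
#' @export
assembleFromPsmTable <- function(records, nFractions, experimentId, species) {
    nFractions <- as.integer(nFractions)
    if (nrow(records) == 0L) {
        return(ProfileMatrix(matrix(0, 0L, nFractions,
                                    dimnames = list(character(0), NULL)),
                             "MS2_COUNTS", experimentId, species))
    }
    fi <- as.integer(records$fraction_index)
    if (any(fi < 0L | fi >= nFractions))
        stop(sprintf("fraction_index %d out of range [0, %d)",
                     fi[fi < 0L | fi >= nFractions][1L], nFractions))
    if (any(records$count < 0) ||
        any(abs(records$count - round(records$count)) > 1e-9))
        stop("PSM counts must be non-negative integers")
    ids <- unique(as.character(records$protein))
    vals <- matrix(0, length(ids), nFractions, dimnames = list(ids, NULL))
    for (i in seq_len(nrow(records)))
        vals[as.character(records$protein[i]), fi[i] + 1L] <-
            vals[as.character(records$protein[i]), fi[i] + 1L] +
            records$count[i]
    ProfileMatrix(vals, "MS2_COUNTS", experimentId, species)
}

#' Restrict MS1 intensities to MS2-identified proteins
#'
#' CF-MS MS1 quantitation is noisy for proteins never confirmed by
#' spectral counting, so the MS1 matrix is filtered to retain only
#' proteins identified in the same sample by MS2. "Identified" means at
#' least one nonzero MS2 count; an all-zero MS2 row carries no
#' identification evidence. Row order of \code{ms1} is preserved.
#'
#' @param ms1 MS1 \linkS4class{ProfileMatrix}.
#' @param ms2 MS2 \linkS4class{ProfileMatrix} of the same experiment.
#' @return the filtered MS1 \linkS4class{ProfileMatrix}.
#' @export
filterMS1ByMS2 <- function(ms1, ms2) {
    if (!identical(experimentId(ms1), experimentId(ms2)))
        stop(sprintf("experiment mismatch: MS1 '%s' vs MS2 '%s'",
                     experimentId(ms1), experimentId(ms2)))
    identified <- proteinIds(ms2)[rowSums(profileValues(ms2) > 0) > 0L]
    keep <- proteinIds(ms1) %in% identified
    ProfileMatrix(profileValues(ms1)[keep, , drop = FALSE],
                  quantKind(ms1), experimentId(ms1), speciesName(ms1))
}

#' Drop sparsely detected proteins before scoring
#'
#' Keeps proteins detected (nonzero) in at least
#' \code{minNonzeroFractions} fractions. The default 0 is the identity:
#' all-zero rows are retained unless filtering is requested explicitly.
#'
#' @param m a \linkS4class{ProfileMatrix}.
#' @param minNonzeroFractions non-negative integer threshold.
#' @return the filtered \linkS4class{ProfileMatrix}.
#' @export
minEvidenceFilter <- function(m, minNonzeroFractions = 0L) {
    stopifnot(minNonzeroFractions >= 0L)
    keep <- rowSums(profileValues(m) > 0) >= minNonzeroFractions
    ProfileMatrix(profileValues(m)[keep, , drop = FALSE],
                  quantKind(m), experimentId(m), speciesName(m))
}

#' Normalize a fraction vector
#'
#' \code{UNIT_SUM} scales entries to sum to one (a relative elution
#' density); \code{UNIT_L2} scales to unit Euclidean norm. An all-zero
#' vector cannot be normalized and is returned unchanged with attribute
#' \code{degenerate = TRUE}.
#'
#' @param x non-negative numeric vector with at least one entry.
#' @param mode \code{"UNIT_SUM"} or \code{"UNIT_L2"}.
#' @return the normalized vector, carrying a logical \code{degenerate}
#'   attribute.
#' @export
normalizeRow <- function(x, mode = c("UNIT_SUM", "UNIT_L2")) {
    mode <- match.arg(mode)
    stopifnot(length(x) >= 1L)
    if (any(x < 0)) stop("negative entries cannot be normalized")
    denom <- if (mode == "UNIT_SUM") sum(x) else sqrt(sum(x^2))
    if (denom == 0) {
        attr(x, "degenerate") <- TRUE
        return(x)
    }
    out <- x / denom
    attr(out, "degenerate") <- FALSE
    out
}
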