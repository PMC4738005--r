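#' Generate a synthetic multi-species fractionation world
#'
#' Builds a complete CF-MS study with known ground truth, emulating the
#' multi-species, multi-experiment design of real co-fractionation
#' studies. The reference proteome consists of the members of
#' \code{nComplexes} ground-truth complexes plus free monomers. Each
#' species retains each reference gene with probability
#' \code{orthologConservationProb} (optionally as two co-orthologs). Per
#' experiment, every complex draws an elution apex (uniform over the
#' fraction range) and a Gaussian peak width shared by all its members -
#' perfect co-elution before noise - while monomers draw independent
#' apexes; apexes resample per experiment, emulating different
#' fractionation techniques. A protein's expected signal is its
#' log-normal abundance times the Gaussian elution density. Observed MS2
#' spectral counts are Poisson(\code{ms2Depth} x expected); MS1
#' intensities are expected times multiplicative log-normal noise; whole
#' profiles drop out with probability \code{dropoutProb}. Fully
#' deterministic given \code{params@seed}.
#'
#' @param params a \linkS4class{SimParams}.
#' @return a \linkS4class{SyntheticWorld}; its \code{experiments} list
#'   holds, per experiment, the MS2 and MS1
#'   \linkS4class{ProfileMatrix} and the noise-free \code{expected}
#'   signal matrix.
#' @export
generateWorld <- function(params) {
    validObject(params)
    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    set.seed(params@seed)
    nC <- params@nComplexes
    sizes <- sample(seq(params@complexSizeRange[1L],
                        params@complexSizeRange[2L]), nC, replace = TRUE)
    nGenes <- sum(sizes) + params@nMonomers
    genes <- sprintf("G%04d", seq_len(nGenes))
    cxEnd <- cumsum(sizes)
    complexes <- lapply(seq_len(nC), function(i)
        genes[seq(cxEnd[i] - sizes[i] + 1L, cxEnd[i])])
    names(complexes) <- sprintf("CPX%03d", seq_len(nC))
    monomers <- genes[seq(sum(sizes) + 1L, nGenes)]
    geneComplex <- stats::setNames(rep(NA_integer_, nGenes), genes)
    for (i in seq_len(nC)) geneComplex[complexes[[i]]] <- i
    pos <- do.call(rbind, lapply(complexes, function(m) {
        cmb <- utils::combn(sort(m), 2L)
        data.frame(protein_a = cmb[1L, ], protein_b = cmb[2L, ],
                   stringsAsFactors = FALSE)
    }))
    rownames(pos) <- NULL
    abundance <- stats::setNames(
        stats::rlnorm(nGenes, params@abundanceMeanlog,
                      params@abundanceSdlog), genes)
    nf <- params@nFractions
    fracs <- seq_len(nf)
    maps <- list()
    experiments <- list()
    for (s in seq_len(params@nSpecies)) {
        sp <- sprintf("sp%d", s)
        keep <- stats::runif(nGenes) < params@orthologConservationProb
        dup <- stats::runif(nGenes) < params@duplicationProb
        srcGene <- rep(genes[keep], times = 1L + dup[keep])
        srcId <- unlist(lapply(which(keep), function(g) {
            base <- paste0(sp, "_", genes[g])
            if (dup[g]) c(base, paste0(base, "_b")) else base
        }))
        maps[[sp]] <- OrthologMap(sp, source = srcId, reference = srcGene)
        for (e in seq_len(params@nExperimentsPerSpecies)) {
            eid <- sprintf("%s_e%d", sp, e)
            apexC <- stats::runif(nC, 1, nf)
            widthC <- stats::runif(nC, params@peakWidthRange[1L],
                                   params@peakWidthRange[2L])
            apexM <- stats::setNames(stats::runif(length(monomers), 1, nf),
                                     monomers)
            widthM <- stats::setNames(
                stats::runif(length(monomers), params@peakWidthRange[1L],
                             params@peakWidthRange[2L]), monomers)
            expected <- matrix(0, length(srcId), nf,
                               dimnames = list(srcId, NULL))
            for (r in seq_along(srcId)) {
                g <- srcGene[r]
                ci <- geneComplex[g]
                apex <- if (is.na(ci)) apexM[g] else apexC[ci]
                width <- if (is.na(ci)) widthM[g] else widthC[ci]
                prof <- abundance[g] * stats::dnorm(fracs, apex, width)
                prof[prof < 1e-8] <- 0
                expected[r, ] <- prof
            }
            drop <- stats::runif(length(srcId)) < params@dropoutProb
            expected[drop, ] <- 0
            ms2 <- matrix(stats::rpois(length(expected),
                                       params@ms2Depth * expected),
                          nrow(expected), nf,
                          dimnames = dimnames(expected))
            noise <- matrix(stats::rlnorm(length(expected), 0,
                                          params@ms1NoiseCv),
                            nrow(expected), nf)
            ms1 <- expected * noise
            experiments[[eid]] <- list(
                species = sp,
                ms2 = ProfileMatrix(ms2, "MS2_COUNTS", eid, sp),
                ms1 = ProfileMatrix(ms1, "MS1_INTENSITY", eid, sp),
                expected = expected)
        }
    }
    new("SyntheticWorld", params = params, referenceGenes = genes,
        orthologMaps = maps, goldStandard = GoldStandard(complexes),
        experiments = experiments, positivePairs = pos)
}

#' Write a synthetic world to a directory
#'
#' Emits one MS2 and one MS1 wide profile TSV per experiment
#' (\code{<experiment>_ms2.tsv}, \code{<experiment>_ms1.tsv}), one
#' ortholog TSV per species (\code{ortholog_<species>.tsv}), the
#' ground-truth gold standard (\code{gold_standard.tsv}) and a manifest
#' of all simulation parameters including the seed
#' (\code{manifest.tsv}), sufficient to regenerate the world bit-exactly
#' via \code{\link{readSimManifest}} + \code{\link{generateWorld}}.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeWorld <- function(world, dir) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create directory: ", dir)
    paths <- character(0)
    for (eid in names(world@experiments)) {
        ex <- world@experiments[[eid]]
        p2 <- file.path(dir, paste0(eid, "_ms2.tsv"))
        p1 <- file.path(dir, paste0(eid, "_ms1.tsv"))
        writeProfileMatrix(ex$ms2, p2)
        writeProfileMatrix(ex$ms1, p1)
        paths <- c(paths, p2, p1)
    }
    for (sp in names(world@orthologMaps)) {
        p <- file.path(dir, paste0("ortholog_", sp, ".tsv"))
        writeOrthologMap(world@orthologMaps[[sp]], p)
        paths <- c(paths, p)
    }
    pg <- file.path(dir, "gold_standard.tsv")
    writeGoldStandard(world@goldStandard, pg)
    pm <- file.path(dir, "manifest.tsv")
    writeSimManifest(world@params, pm)
    invisible(c(paths, pg, pm))
}

.simParamFields <- c(
    nSpecies = "nSpecies", nComplexes = "nComplexes",
    complexSizeRange = "complexSizeRange", nMonomers = "nMonomers",
    nExperimentsPerSpecies = "nExperimentsPerSpecies",
    nFractions = "nFractions", peakWidthRange = "peakWidthRange",
    abundanceMeanlog = "abundanceMeanlog",
    abundanceSdlog = "abundanceSdlog", ms2Depth = "ms2Depth",
    ms1NoiseCv = "ms1NoiseCv", dropoutProb = "dropoutProb",
    orthologConservationProb = "orthologConservationProb",
    duplicationProb = "duplicationProb", seed = "seed")

#' Read and write simulation manifests
#'
#' Key-value TSV (\code{key<TAB>value}, ranges comma-separated) holding
#' every \linkS4class{SimParams} field including the seed.
#'
#' @param params a \linkS4class{SimParams}.
#' @param path file path.
#' @return \code{readSimManifest} returns the \linkS4class{SimParams};
#'   \code{writeSimManifest} invisibly returns \code{path}.
#' @export
writeSimManifest <- function(params, path) {
    lines <- vapply(.simParamFields, function(f)
        sprintf("%s\t%s", f,
                paste(sprintf("%.17g", as.numeric(slot(params, f))),
                      collapse = ",")), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeSimManifest
#' @export
readSimManifest <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "\t", fixed = TRUE)
    vals <- stats::setNames(
        lapply(kv, function(f)
            as.numeric(strsplit(f[[2L]], ",", fixed = TRUE)[[1L]])),
        vapply(kv, `[[`, character(1), 1L))
    miss <- setdiff(.simParamFields, names(vals))
    if (length(miss))
        stop("manifest lacks fields: ", paste(miss, collapse = ", "))
    SimParams(nSpecies = vals$nSpecies, nComplexes = vals$nComplexes,
              complexSizeRange = vals$complexSizeRange,
              nMonomers = vals$nMonomers,
              nExperimentsPerSpecies = vals$nExperimentsPerSpecies,
              nFractions = vals$nFractions,
              peakWidthRange = vals$peakWidthRange,
              abundanceMeanlog = vals$abundanceMeanlog,
              abundanceSdlog = vals$abundanceSdlog,
              ms2Depth = vals$ms2Depth, ms1NoiseCv = vals$ms1NoiseCv,
              dropoutProb = vals$dropoutProb,
              orthologConservationProb = vals$orthologConservationProb,
              duplicationProb = vals$duplicationProb, seed = vals$seed)
}
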