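#' @import methods
#' @importFrom S4Vectors metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
NULL

#' ProfileMatrix: one experiment's elution profiles
#'
#' A \code{ProfileMatrix} holds the quantitation table of a single
#' fractionation experiment: proteins (rows, gene-level identifiers) by
#' ordered chromatographic fractions (columns). It extends
#' \linkS4class{SummarizedExperiment} with a single assay named
#' \code{"quant"}; the experiment identifier, species and quantitation kind
#' (\code{"MS2_COUNTS"} or \code{"MS1_INTENSITY"}) live in
#' \code{metadata()}. Fraction order is elution order: column index equals
#' elution position.
#'
#' Invariants enforced by the validity method: unique non-empty protein
#' identifiers, all values non-negative and finite, and whole-number values
#' when the quantitation kind is \code{"MS2_COUNTS"}.
#'
#' @seealso \code{\link{readProfileMatrix}}, \code{\link{scoreExperiment}}
#' @aliases ProfileMatrix-class
#' @exportClass ProfileMatrix
setClass("ProfileMatrix", contains = "SummarizedExperiment")

setValidity("ProfileMatrix", function(object) {
    md <- metadata(object)
    needed <- c("experimentId", "species", "quantKind")
    if (!all(needed %in% names(md)))
        return(paste("metadata must contain", paste(needed, collapse = ", ")))
    if (!md$quantKind %in% c("MS2_COUNTS", "MS1_INTENSITY"))
        return("quantKind must be MS2_COUNTS or MS1_INTENSITY")
    if (!"quant" %in% SummarizedExperiment::assayNames(object))
        return("assay 'quant' is required")
    v <- assay(object, "quant")
    ids <- rownames(v)
    if (nrow(v) > 0L) {
        if (is.null(ids) || any(!nzchar(ids)))
            return("all proteins must carry non-empty identifiers")
        if (anyDuplicated(ids))
            return(paste0("duplicate protein id: ",
                          ids[duplicated(ids)][1L]))
    }
    if (length(v) && (any(!is.finite(v)) || any(v < 0)))
        return("profile values must be finite and non-negative")
    if (md$quantKind == "MS2_COUNTS" && length(v) &&
        any(abs(v - round(v)) > 1e-9))
        return("MS2 spectral counts must be whole numbers")
    TRUE
})

#' Construct a ProfileMatrix
#'
#' @param values numeric matrix, proteins x fractions, non-negative
#'   (whole numbers for MS2 counts). Row names are taken as protein ids
#'   unless \code{proteinIds} is given.
#' @param quantKind \code{"MS2_COUNTS"} or \code{"MS1_INTENSITY"}.
#' @param experimentId opaque experiment identifier.
#' @param species opaque species label.
#' @param proteinIds optional character vector of protein identifiers.
#' @return a validated \linkS4class{ProfileMatrix}.
#' @examples
#' m <- ProfileMatrix(matrix(c(1, 0, 2, 0, 5, 0), 2, byrow = TRUE,
#'                           dimnames = list(c("P1", "P2"), NULL)),
#'                    "MS2_COUNTS", "exp1", "human")
#' nFractions(m)
#' @export
ProfileMatrix <- function(values, quantKind = c("MS2_COUNTS", "MS1_INTENSITY"),
                          experimentId, species, proteinIds = NULL) {
    quantKind <- match.arg(quantKind)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (!is.null(proteinIds)) rownames(values) <- proteinIds
    if (is.null(colnames(values)) && ncol(values) > 0L)
        colnames(values) <- paste0("f", seq_len(ncol(values)))
    se <- SummarizedExperiment(
        assays = S4Vectors::SimpleList(quant = values),
        metadata = list(experimentId = experimentId, species = species,
                        quantKind = quantKind))
    new("ProfileMatrix", se)
}

#' Co-elution scoring parameters
#'
#' Free parameters of the four pairwise co-elution scores.
#'
#' @slot noiseReps integer, number of Poisson-noise replicates R of the
#'   noised Pearson score (0 disables noise; default 100).
#' @slot pseudocount non-negative real p added to every count before
#'   Poisson sampling; breaks spurious perfect correlations among sparse
#'   profiles (default 1).
#' @slot maxLag integer K; the weighted cross-correlation averages Pearson
#'   correlations over lags -K..K with weights 1/(1+|k|) (default 2).
#' @slot rngSeed integer seed of the deterministic noise stream.
#' @slot minOverlap minimum number of fractions in which both profiles are
#'   nonzero for a pair to be scored (default 1).
#' @aliases ScoreParams-class
#' @exportClass ScoreParams
setClass("ScoreParams", representation(
    noiseReps = "integer", pseudocount = "numeric", maxLag = "integer",
    rngSeed = "integer", minOverlap = "integer"))

setValidity("ScoreParams", function(object) {
    if (object@noiseReps < 0L) return("noiseReps must be >= 0")
    if (object@pseudocount < 0) return("pseudocount must be >= 0")
    if (object@maxLag < 0L) return("maxLag must be >= 0")
    if (object@minOverlap < 0L) return("minOverlap must be >= 0")
    TRUE
})

#' @param noiseReps,pseudocount,maxLag,rngSeed,minOverlap see slots.
#' @return \code{ScoreParams()} returns a parameter object.
#' @rdname ScoreParams-class
#' @export
ScoreParams <- function(noiseReps = 100L, pseudocount = 1, maxLag = 2L,
                        rngSeed = 1L, minOverlap = 1L) {
    new("ScoreParams", noiseReps = as.integer(noiseReps),
        pseudocount = as.numeric(pseudocount), maxLag = as.integer(maxLag),
        rngSeed = as.integer(rngSeed), minOverlap = as.integer(minOverlap))
}

#' Ortholog map between a species and the reference namespace
#'
#' A possibly many-to-many relation from source-species genes to
#' reference (e.g. human) genes, with set semantics (no duplicate pairs).
#'
#' @slot species opaque source-species label.
#' @slot table data.frame with character columns \code{source} and
#'   \code{reference}.
#' @aliases OrthologMap-class
#' @exportClass OrthologMap
setClass("OrthologMap", representation(species = "character",
                                       table = "data.frame"))

setValidity("OrthologMap", function(object) {
    tb <- object@table
    if (!identical(colnames(tb), c("source", "reference")))
        return("table must have columns source, reference")
    if (nrow(tb) && (any(!nzchar(tb$source)) || any(!nzchar(tb$reference))))
        return("gene identifiers must be non-empty")
    if (anyDuplicated(tb)) return("duplicate entries violate set semantics")
    TRUE
})

#' @param species source species label.
#' @param source,reference character vectors of equal length; duplicates
#'   are collapsed.
#' @return \code{OrthologMap()} returns the map object.
#' @rdname OrthologMap-class
#' @export
OrthologMap <- function(species, source = character(),
                        reference = character()) {
    tb <- unique(data.frame(source = as.character(source),
                            reference = as.character(reference),
                            stringsAsFactors = FALSE))
    rownames(tb) <- NULL
    new("OrthologMap", species = species, table = tb)
}

#' Reference complexes used for supervision and evaluation
#'
#' @slot complexes named list of character vectors (member sets); every
#'   complex has at least two members and names are unique.
#' @aliases GoldStandard-class
#' @exportClass GoldStandard
setClass("GoldStandard", representation(complexes = "list"))

setValidity("GoldStandard", function(object) {
    cx <- object@complexes
    if (length(cx)) {
        if (is.null(names(cx)) || any(!nzchar(names(cx))) ||
            anyDuplicated(names(cx)))
            return("complex names must be unique and non-empty")
        if (any(vapply(cx, function(m) length(unique(m)) < 2L, logical(1))))
            return("every complex needs >= 2 distinct members")
    }
    TRUE
})

#' @param complexes named list of character member vectors.
#' @return \code{GoldStandard()} returns the object.
#' @rdname GoldStandard-class
#' @export
GoldStandard <- function(complexes) {
    new("GoldStandard", complexes = lapply(complexes, unique))
}

#' A classifier-scored interaction network
#'
#' @slot edges data.frame with columns \code{protein_a}, \code{protein_b}
#'   (canonical order, a < b) and \code{score} in [0, 1].
#' @slot threshold numeric(1); the applied score cutoff, or NA when the
#'   network is unthresholded.
#' @slot provenance list describing the scoring model and parameters.
#' @aliases ScoredNetwork-class
#' @exportClass ScoredNetwork
setClass("ScoredNetwork", representation(
    edges = "data.frame", threshold = "numeric", provenance = "list"))

setValidity("ScoredNetwork", function(object) {
    e <- object@edges
    if (!all(c("protein_a", "protein_b", "score") %in% colnames(e)))
        return("edges need columns protein_a, protein_b, score")
    if (nrow(e)) {
        if (any(e$protein_a >= e$protein_b))
            return("edges must be canonical (protein_a < protein_b), no self-edges")
        if (any(e$score < 0 | e$score > 1))
            return("scores must lie in [0, 1]")
        if (anyDuplicated(paste(e$protein_a, e$protein_b, sep = "\r")))
            return("duplicate edges")
    }
    TRUE
})

#' @param edges data.frame of edges (see slots); pairs are canonicalized.
#' @param threshold applied cutoff or NA.
#' @param provenance free-form provenance list.
#' @return \code{ScoredNetwork()} returns the network object.
#' @rdname ScoredNetwork-class
#' @export
ScoredNetwork <- function(edges, threshold = NA_real_, provenance = list()) {
    if (nrow(edges)) {
        a <- pmin(edges$protein_a, edges$protein_b)
        b <- pmax(edges$protein_a, edges$protein_b)
        edges$protein_a <- a
        edges$protein_b <- b
        edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
        rownames(edges) <- NULL
    }
    new("ScoredNetwork", edges = edges, threshold = as.numeric(threshold),
        provenance = provenance)
}

#' A set of putative complexes from network clustering
#'
#' Possibly overlapping node sets with their cohesiveness scores.
#'
#' @slot members named list of character vectors.
#' @slot cohesiveness numeric vector parallel to \code{members}, in [0, 1].
#' @slot params list of clustering parameters used.
#' @aliases ComplexSet-class
#' @exportClass ComplexSet
setClass("ComplexSet", representation(
    members = "list", cohesiveness = "numeric", params = "list"))

setValidity("ComplexSet", function(object) {
    if (length(object@members) != length(object@cohesiveness))
        return("members and cohesiveness lengths differ")
    if (length(object@cohesiveness) &&
        any(object@cohesiveness < 0 | object@cohesiveness > 1))
        return("cohesiveness must lie in [0, 1]")
    if (any(vapply(object@members, length, integer(1)) < 2L))
        return("every complex needs >= 2 members")
    TRUE
})

#' @param members named list of member vectors.
#' @param cohesiveness parallel numeric vector.
#' @param params clustering parameter list.
#' @return \code{ComplexSet()} returns the object.
#' @rdname ComplexSet-class
#' @export
ComplexSet <- function(members, cohesiveness, params = list()) {
    if (is.null(names(members)) && length(members))
        names(members) <- sprintf("cluster%03d", seq_along(members))
    new("ComplexSet", members = members,
        cohesiveness = as.numeric(cohesiveness), params = params)
}

#' Synthetic fractionation world parameters
#'
#' Parameters of the multi-species CF-MS simulator. Defaults define the
#' package's reference study conditions: 2 species, 20 ground-truth
#' complexes of 3-6 members plus 40 monomers, 2 experiments per species,
#' 60 fractions, Gaussian elution peaks of width 1-3 fractions, log-normal
#' protein abundances (meanlog 3, sdlog 1), Poisson-sampled MS2 counts,
#' 20\% multiplicative MS1 noise, 10\% per-protein-per-experiment dropout
#' and 90\% ortholog conservation.
#'
#' @slot nSpecies,nComplexes,nMonomers,nExperimentsPerSpecies,nFractions
#'   integer design sizes.
#' @slot complexSizeRange integer(2) inclusive member-count range.
#' @slot peakWidthRange numeric(2) range of Gaussian peak sigma (fractions).
#' @slot abundanceMeanlog,abundanceSdlog log-normal abundance parameters.
#' @slot ms2Depth multiplicative sampling-depth scale on expected MS2
#'   counts.
#' @slot ms1NoiseCv sdlog of multiplicative log-normal MS1 noise.
#' @slot dropoutProb probability a protein is entirely missed in one
#'   experiment.
#' @slot orthologConservationProb probability each reference gene is
#'   retained in a species.
#' @slot duplicationProb probability a retained gene appears as two
#'   co-orthologs.
#' @slot seed integer RNG seed.
#' @aliases SimParams-class
#' @exportClass SimParams
setClass("SimParams", representation(
    nSpecies = "integer", nComplexes = "integer",
    complexSizeRange = "integer", nMonomers = "integer",
    nExperimentsPerSpecies = "integer", nFractions = "integer",
    peakWidthRange = "numeric", abundanceMeanlog = "numeric",
    abundanceSdlog = "numeric", ms2Depth = "numeric",
    ms1NoiseCv = "numeric", dropoutProb = "numeric",
    orthologConservationProb = "numeric", duplicationProb = "numeric",
    seed = "integer"))

setValidity("SimParams", function(object) {
    pr <- c(object@dropoutProb, object@orthologConservationProb,
            object@duplicationProb)
    if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0, 1]")
    if (object@nFractions < 10L) return("nFractions must be >= 10")
    if (any(c(object@nSpecies, object@nComplexes,
              object@nExperimentsPerSpecies) < 1L))
        return("design sizes must be positive")
    if (object@complexSizeRange[1] < 2L)
        return("complexes need >= 2 members")
    if (diff(object@complexSizeRange) < 0 || diff(object@peakWidthRange) < 0)
        return("ranges must be non-decreasing")
    if (object@ms2Depth <= 0) return("ms2Depth must be positive")
    TRUE
})

#' @param nSpecies,nComplexes,complexSizeRange,nMonomers
#'   design sizes (see slots).
#' @param nExperimentsPerSpecies,nFractions design sizes (see slots).
#' @param peakWidthRange,abundanceMeanlog,abundanceSdlog,ms2Depth
#'   signal model parameters (see slots).
#' @param ms1NoiseCv,dropoutProb,orthologConservationProb,duplicationProb
#'   noise and conservation parameters (see slots).
#' @param seed integer RNG seed.
#' @return \code{SimParams()} returns the parameter object.
#' @rdname SimParams-class
#' @export
SimParams <- function(nSpecies = 2L, nComplexes = 20L,
                      complexSizeRange = c(3L, 6L), nMonomers = 40L,
                      nExperimentsPerSpecies = 2L, nFractions = 60L,
                      peakWidthRange = c(1, 3), abundanceMeanlog = 3,
                      abundanceSdlog = 1, ms2Depth = 1, ms1NoiseCv = 0.2,
                      dropoutProb = 0.1, orthologConservationProb = 0.9,
                      duplicationProb = 0, seed = 1L) {
    new("SimParams", nSpecies = as.integer(nSpecies),
        nComplexes = as.integer(nComplexes),
        complexSizeRange = as.integer(complexSizeRange),
        nMonomers = as.integer(nMonomers),
        nExperimentsPerSpecies = as.integer(nExperimentsPerSpecies),
        nFractions = as.integer(nFractions),
        peakWidthRange = as.numeric(peakWidthRange),
        abundanceMeanlog = as.numeric(abundanceMeanlog),
        abundanceSdlog = as.numeric(abundanceSdlog),
        ms2Depth = as.numeric(ms2Depth),
        ms1NoiseCv = as.numeric(ms1NoiseCv),
        dropoutProb = as.numeric(dropoutProb),
        orthologConservationProb = as.numeric(orthologConservationProb),
        duplicationProb = as.numeric(duplicationProb),
        seed = as.integer(seed))
}

#' A generated synthetic fractionation world
#'
#' @slot params the \linkS4class{SimParams} used.
#' @slot referenceGenes character vector of reference-namespace genes.
#' @slot orthologMaps list of \linkS4class{OrthologMap}, one per species.
#' @slot goldStandard ground-truth \linkS4class{GoldStandard}.
#' @slot experiments named list; each element has \code{ms2}, \code{ms1}
#'   (\linkS4class{ProfileMatrix}) and \code{expected} (the noise-free
#'   expected-signal matrix), plus \code{species}.
#' @slot positivePairs data.frame of ground-truth co-complex pairs
#'   (reference namespace, canonical order).
#' @aliases SyntheticWorld-class
#' @exportClass SyntheticWorld
setClass("SyntheticWorld", representation(
    params = "SimParams", referenceGenes = "character",
    orthologMaps = "list", goldStandard = "GoldStandard",
    experiments = "list", positivePairs = "data.frame"))

#' Trained co-complex classifier
#'
#' Wraps a probability random forest together with the feature schema and
#' the missing-value encoding (observed-mask channels), so that scoring is
#' reproducible after serialization.
#'
#' @slot forest fitted ranger probability forest.
#' @slot featureNames character, feature-column schema at training time.
#' @slot hyperparams list of forest hyperparameters.
#' @slot seed integer training seed.
#' @aliases CoComplexModel-class
#' @exportClass CoComplexModel
setClass("CoComplexModel", representation(
    forest = "ANY", featureNames = "character", hyperparams = "list",
    seed = "integer"))
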