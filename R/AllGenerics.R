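#' Accessors for CoFracNet classes
#'
#' Small accessor generics: \code{profileValues} returns the quantitation
#' matrix of a \linkS4class{ProfileMatrix}; \code{proteinIds} its row
#' identifiers; \code{nFractions} its fraction count; \code{quantKind},
#' \code{experimentId} and \code{speciesName} its metadata;
#' \code{networkEdges} and \code{networkThreshold} the edge table and
#' cutoff of a \linkS4class{ScoredNetwork}; \code{complexMembers} and
#' \code{cohesiveness} the member sets and scores of a
#' \linkS4class{ComplexSet}; \code{orthologTable} the pair table of an
#' \linkS4class{OrthologMap}; \code{complexList} the member list of a
#' \linkS4class{GoldStandard}.
#'
#' @param x the object.
#' @return the accessed component (see description).
#' @name accessors
#' @examples
#' m <- ProfileMatrix(matrix(1:6, 2, dimnames = list(c("A", "B"), NULL)),
#'                    "MS2_COUNTS", "e1", "human")
#' proteinIds(m)
#' quantKind(m)
NULL

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("nFractions", function(x) standardGeneric("nFractions"))
#' @rdname accessors
#' @export
setGeneric("quantKind", function(x) standardGeneric("quantKind"))
#' @rdname accessors
#' @export
setGeneric("experimentId", function(x) standardGeneric("experimentId"))
#' @rdname accessors
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))
#' @rdname accessors
#' @export
setGeneric("complexMembers", function(x) standardGeneric("complexMembers"))
#' @rdname accessors
#' @export
setGeneric("cohesiveness", function(x) standardGeneric("cohesiveness"))
#' @rdname accessors
#' @export
setGeneric("orthologTable", function(x) standardGeneric("orthologTable"))
#' @rdname accessors
#' @export
setGeneric("complexList", function(x) standardGeneric("complexList"))

#' @rdname accessors
setMethod("profileValues", "ProfileMatrix",
          function(x) assay(x, "quant"))
#' @rdname accessors
setMethod("proteinIds", "ProfileMatrix", function(x) {
    ids <- rownames(x)
    if (is.null(ids)) character(0) else ids
})
#' @rdname accessors
setMethod("nFractions", "ProfileMatrix", function(x) ncol(x))
#' @rdname accessors
setMethod("quantKind", "ProfileMatrix",
          function(x) metadata(x)$quantKind)
#' @rdname accessors
setMethod("experimentId", "ProfileMatrix",
          function(x) metadata(x)$experimentId)
#' @rdname accessors
setMethod("speciesName", "ProfileMatrix",
          function(x) metadata(x)$species)
#' @rdname accessors
setMethod("speciesName", "OrthologMap", function(x) x@species)
#' @rdname accessors
setMethod("networkEdges", "ScoredNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("networkThreshold", "ScoredNetwork", function(x) x@threshold)
#' @rdname accessors
setMethod("complexMembers", "ComplexSet", function(x) x@members)
#' @rdname accessors
setMethod("cohesiveness", "ComplexSet", function(x) x@cohesiveness)
#' @rdname accessors
setMethod("orthologTable", "OrthologMap", function(x) x@table)
#' @rdname accessors
setMethod("complexList", "GoldStandard", function(x) x@complexes)

setMethod("show", "ProfileMatrix", function(object) {
    cat(sprintf("ProfileMatrix (%s) experiment '%s', species '%s'\n",
                quantKind(object), experimentId(object),
                speciesName(object)))
    cat(sprintf("  %d proteins x %d fractions\n", nrow(object),
                ncol(object)))
})

setMethod("show", "ScoredNetwork", function(object) {
    cat(sprintf("ScoredNetwork: %d edges", nrow(object@edges)))
    if (!is.na(object@threshold))
        cat(sprintf(", thresholded at %.4f", object@threshold))
    cat("\n")
})

setMethod("show", "ComplexSet", function(object) {
    sz <- vapply(object@members, length, integer(1))
    cat(sprintf("ComplexSet: %d complexes", length(sz)))
    if (length(sz))
        cat(sprintf(" (sizes %d-%d, median cohesiveness %.3f)",
                    min(sz), max(sz), stats::median(object@cohesiveness)))
    cat("\n")
})

setMethod("show", "OrthologMap", function(object) {
    cat(sprintf("OrthologMap '%s': %d gene pairs\n", object@species,
                nrow(object@table)))
})

setMethod("show", "GoldStandard", function(object) {
    cat(sprintf("GoldStandard: %d complexes, %d distinct proteins\n",
                length(object@complexes),
                length(unique(unlist(object@complexes)))))
})

setMethod("show", "SyntheticWorld", function(object) {
    cat(sprintf(
        "SyntheticWorld: %d species, %d experiments, %d reference genes, %d complexes\n",
        object@params@nSpecies, length(object@experiments),
        length(object@referenceGenes),
        length(object@goldStandard@complexes)))
})

setMethod("show", "CoComplexModel", function(object) {
    cat(sprintf("CoComplexModel: %d features, %d trees, seed %d\n",
                length(object@featureNames),
                object@hyperparams$num.trees, object@seed))
})
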