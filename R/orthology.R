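#' Load an ortholog map from two-column TSV
#'
#' Each line maps one source-species gene to one reference (human) gene;
#' the relation may be many-to-many and exact duplicates are collapsed.
#'
#' @param path TSV file with columns \code{source_gene},
#'   \code{reference_gene} (no header required; a header line named
#'   exactly like that is skipped).
#' @param species source species label.
#' @return an \linkS4class{OrthologMap}.
#' @export
loadOrthologMap <- function(path, species) {
    if (!file.exists(path)) stop("ortholog file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    if (length(lines) && identical(strsplit(lines[1L], "\t")[[1L]],
                                   c("source_gene", "reference_gene")))
        lines <- lines[-1L]
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(OrthologMap(species))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 2L |
                 vapply(fields, function(f) any(!nzchar(f)), logical(1)))
    if (length(bad))
        stop(sprintf("malformed ortholog entry at line %d of %s",
                     bad[1L], path))
    OrthologMap(species,
                source = vapply(fields, `[[`, character(1), 1L),
                reference = vapply(fields, `[[`, character(1), 2L))
}

#' Write an ortholog map as TSV
#'
#' @param map an \linkS4class{OrthologMap}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeOrthologMap <- function(map, path) {
    tb <- orthologTable(map)
    writeLines(c("source_gene\treference_gene",
                 paste(tb$source, tb$reference, sep = "\t")), path)
    invisible(path)
}

#' Map pair scores into the reference namespace
#'
#' Rewrites a source-species pair-score table onto reference (human)
#' genes. Each scored pair (a, b) expands to every combination of
#' reference orthologs of a and b; pairs with an unmapped side are
#' dropped (the harmonized table must be purely orthologous), as are
#' expansions that collapse onto a single reference gene. When several
#' source pairs land on the same reference pair within an experiment,
#' each score column keeps the maximum over non-missing values - the
#' strongest co-elution evidence among co-orthologs.
#'
#' @param records pair-score data.frame (source namespace), as from
#'   \code{\link{scoreExperiment}}.
#' @param map an \linkS4class{OrthologMap} for the records' species.
#' @return pair-score data.frame in reference namespace, canonical order.
#' @export
mapScoresToReference <- function(records, map) {
    tb <- orthologTable(map)
    empty <- records[0, , drop = FALSE]
    if (nrow(records) == 0L || nrow(tb) == 0L) return(empty)
    refs <- split(tb$reference, tb$source)
    num <- c("pcc_noise", "wcc", "coapex", "euclid_sim")
    pieces <- vector("list", nrow(records))
    for (i in seq_len(nrow(records))) {
        ra <- refs[[records$protein_a[i]]]
        rb <- refs[[records$protein_b[i]]]
        if (is.null(ra) || is.null(rb)) next
        grid <- expand.grid(a = ra, b = rb, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
        grid <- grid[grid$a != grid$b, , drop = FALSE]
        if (nrow(grid) == 0L) next
        piece <- records[rep(i, nrow(grid)), , drop = FALSE]
        piece$protein_a <- pmin(grid$a, grid$b)
        piece$protein_b <- pmax(grid$a, grid$b)
        pieces[[i]] <- piece
    }
    out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    if (is.null(out) || nrow(out) == 0L) return(empty)
    key <- paste(out$protein_a, out$protein_b, out$experiment_id,
                 sep = "\r")
    maxNA <- function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    first <- !duplicated(key)
    merged <- out[first, , drop = FALSE]
    grp <- match(key, key[first])   # first-occurrence group ids 1..G
    for (cn in num) {
        agg <- tapply(out[[cn]], grp, maxNA)
        merged[[cn]] <- as.numeric(agg[as.character(seq_len(sum(first)))])
    }
    merged <- merged[order(merged$protein_a, merged$protein_b,
                           merged$experiment_id), , drop = FALSE]
    rownames(merged) <- NULL
    merged
}

#' Project a reference network onto another species
#'
#' The inverse direction of \code{\link{mapScoresToReference}}: each edge
#' (u, v, score) of a reference-namespace network yields every pair of
#' source-species orthologs of u and v. Edges with an unmapped endpoint
#' are absent from the projection; projected self-pairs are dropped, and
#' when two reference edges project onto the same species pair the higher
#' score is kept.
#'
#' @param network a \linkS4class{ScoredNetwork} in reference namespace.
#' @param map the target species' \linkS4class{OrthologMap}
#'   (source gene -> reference gene).
#' @return a \linkS4class{ScoredNetwork} in the target species namespace.
#' @export
projectNetwork <- function(network, map) {
    tb <- orthologTable(map)
    edges <- networkEdges(network)
    inv <- split(tb$source, tb$reference)
    pieces <- vector("list", nrow(edges))
    for (i in seq_len(nrow(edges))) {
        su <- inv[[edges$protein_a[i]]]
        sv <- inv[[edges$protein_b[i]]]
        if (is.null(su) || is.null(sv)) next
        grid <- expand.grid(a = su, b = sv, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
        grid <- grid[grid$a != grid$b, , drop = FALSE]
        if (nrow(grid) == 0L) next
        pieces[[i]] <- data.frame(
            protein_a = pmin(grid$a, grid$b),
            protein_b = pmax(grid$a, grid$b),
            score = edges$score[i], stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    if (is.null(out) || nrow(out) == 0L)
        return(ScoredNetwork(data.frame(protein_a = character(0),
                                        protein_b = character(0),
                                        score = numeric(0)),
                             provenance = c(network@provenance,
                                            list(projectedTo = map@species))))
    key <- paste(out$protein_a, out$protein_b, sep = "\r")
    agg <- tapply(out$score, key, max)
    first <- out[!duplicated(key), c("protein_a", "protein_b")]
    first$score <- as.numeric(agg[key[!duplicated(key)]])
    ScoredNetwork(first, threshold = networkThreshold(network),
                  provenance = c(network@provenance,
                                 list(projectedTo = map@species)))
}
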