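## Cohesiveness of node set S in a weighted graph:
##   C(S) = W_in / (W_in + W_bound + penalty * |S|)
## where W_in is the total weight inside S and W_bound the total weight
## crossing its boundary. The size penalty discourages weakly attached
## accretion onto large sets.
.cohesion <- function(S, adj, wdeg, penalty) {
    win <- 0
    for (u in S) {
        nb <- adj[[u]]
        win <- win + sum(nb[names(nb) %in% S])
    }
    win <- win / 2
    wb <- sum(wdeg[S]) - 2 * win
    win / (win + wb + penalty * length(S))
}

#' Cluster a thresholded network into putative complexes
#'
#' Greedy seeded cohesiveness growth in the spirit of ClusterONE: seeds
#' are taken from edges in order of decreasing weight (ties by pair id);
#' each seed set is grown and shrunk by single-node moves that strictly
#' increase the cohesiveness
#' \eqn{C(S) = W_{in}/(W_{in} + W_{bound} + penalty \cdot |S|)}
#' until a local optimum, accepted when \eqn{C \ge} \code{cohesivenessMin}
#' and the set has at least \code{minSize} members, and finally accepted
#' sets with Jaccard overlap \eqn{\ge} \code{overlapMergeJaccard} are
#' merged. All tie-breaks are explicit (higher cohesiveness gain, then
#' additions before removals, then lexicographic node id), so the result
#' is deterministic.
#'
#' @param network a thresholded \linkS4class{ScoredNetwork}; edge scores
#'   act as weights.
#' @param minSize minimum complex size (default 3).
#' @param cohesivenessMin acceptance floor for C(S) (default 0.3).
#' @param overlapMergeJaccard Jaccard at or above which accepted sets are
#'   merged (default 0.8).
#' @param penalty per-node boundary penalty in C(S) (default 2).
#' @return a \linkS4class{ComplexSet}; empty for an empty network.
#' @export
clusterNetwork <- function(network, minSize = 3L, cohesivenessMin = 0.3,
                           overlapMergeJaccard = 0.8, penalty = 2) {
    edges <- networkEdges(network)
    params <- list(minSize = minSize, cohesivenessMin = cohesivenessMin,
                   overlapMergeJaccard = overlapMergeJaccard,
                   penalty = penalty)
    if (nrow(edges) == 0L)
        return(ComplexSet(list(), numeric(0), params))
    nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
    adj <- stats::setNames(vector("list", length(nodes)), nodes)
    for (i in seq_len(nrow(edges))) {
        a <- edges$protein_a[i]; b <- edges$protein_b[i]
        w <- edges$score[i]
        adj[[a]] <- c(adj[[a]], stats::setNames(w, b))
        adj[[b]] <- c(adj[[b]], stats::setNames(w, a))
    }
    wdeg <- vapply(adj, sum, numeric(1))
    ord <- order(-edges$score, edges$protein_a, edges$protein_b)
    accepted <- list()
    acceptedC <- numeric(0)
    for (i in ord) {
        a <- edges$protein_a[i]; b <- edges$protein_b[i]
        if (any(vapply(accepted, function(S) all(c(a, b) %in% S),
                       logical(1))))
            next
        S <- c(a, b)
        curC <- .cohesion(S, adj, wdeg, penalty)
        repeat {
            nb <- sort(setdiff(unique(unlist(lapply(S, function(u)
                names(adj[[u]])))), S))
            bestC <- curC + 1e-12
            move <- NULL
            for (u in nb) {
                cc <- .cohesion(c(S, u), adj, wdeg, penalty)
                if (cc > bestC) { bestC <- cc; move <- c("add", u) }
            }
            if (is.null(move) && length(S) > 2L) {
                for (u in sort(S)) {
                    cc <- .cohesion(setdiff(S, u), adj, wdeg, penalty)
                    if (cc > bestC) { bestC <- cc; move <- c("rm", u) }
                }
            }
            if (is.null(move)) break
            S <- if (move[1L] == "add") c(S, move[2L]) else
                setdiff(S, move[2L])
            curC <- .cohesion(S, adj, wdeg, penalty)
        }
        S <- sort(S)
        if (length(S) >= minSize && curC >= cohesivenessMin &&
            !any(vapply(accepted, identical, logical(1), y = S))) {
            accepted[[length(accepted) + 1L]] <- S
            acceptedC <- c(acceptedC, curC)
        }
    }
    ## merge heavily overlapping accepted sets (fixpoint, deterministic order)
    repeat {
        merged <- FALSE
        for (i in seq_along(accepted)) {
            if (merged) break
            for (j in seq_along(accepted)) {
                if (j <= i) next
                jac <- length(intersect(accepted[[i]], accepted[[j]])) /
                    length(union(accepted[[i]], accepted[[j]]))
                if (jac >= overlapMergeJaccard) {
                    accepted[[i]] <- sort(union(accepted[[i]],
                                                accepted[[j]]))
                    acceptedC[i] <- .cohesion(accepted[[i]], adj, wdeg,
                                              penalty)
                    accepted[[j]] <- NULL
                    acceptedC <- acceptedC[-j]
                    merged <- TRUE
                    break
                }
            }
        }
        if (!merged) break
    }
    if (length(accepted))
        names(accepted) <- sprintf("cluster%03d", seq_along(accepted))
    ComplexSet(accepted, acceptedC, params)
}

#' Compare predicted complexes against a reference
#'
#' A predicted/reference pair "matches" when the Jaccard index of their
#' member sets is at least \code{jaccardMatch}. Complex-level precision
#' is the fraction of predicted complexes matching some reference
#' complex, recall the fraction of reference complexes matched by some
#' prediction, and F1 their harmonic mean.
#'
#' @param predicted a \linkS4class{ComplexSet}.
#' @param reference a \linkS4class{GoldStandard} in the same namespace.
#' @param jaccardMatch matching threshold (default 0.25).
#' @return list with \code{precision}, \code{recall}, \code{f1} and
#'   \code{matches} (data.frame \code{predicted}, \code{reference},
#'   \code{jaccard} of all matching pairs).
#' @export
compareComplexes <- function(predicted, reference, jaccardMatch = 0.25) {
    pred <- complexMembers(predicted)
    ref <- complexList(reference)
    matches <- NULL
    for (p in names(pred)) for (r in names(ref)) {
        jac <- length(intersect(pred[[p]], ref[[r]])) /
            length(union(pred[[p]], ref[[r]]))
        if (jac >= jaccardMatch)
            matches <- rbind(matches, data.frame(
                predicted = p, reference = r, jaccard = jac,
                stringsAsFactors = FALSE))
    }
    precision <- if (length(pred) == 0L) 0 else
        length(unique(matches$predicted)) / length(pred)
    recall <- if (length(ref) == 0L) 0 else
        length(unique(matches$reference)) / length(ref)
    f1 <- if (precision + recall == 0) 0 else
        2 * precision * recall / (precision + recall)
    list(precision = precision, recall = recall, f1 = f1,
         matches = if (is.null(matches))
             data.frame(predicted = character(0),
                        reference = character(0), jaccard = numeric(0))
         else matches)
}

#' Read and write complex-set files
#'
#' Same format as the gold-standard file plus a cohesiveness column:
#' \code{name<TAB>member1,member2,...<TAB>cohesiveness}.
#'
#' @param cs a \linkS4class{ComplexSet}.
#' @param path file path.
#' @return \code{readComplexSet} returns a \linkS4class{ComplexSet};
#'   \code{writeComplexSet} invisibly returns \code{path}.
#' @export
writeComplexSet <- function(cs, path) {
    m <- complexMembers(cs)
    writeLines(vapply(seq_along(m), function(i)
        sprintf("%s\t%s\t%.17g", names(m)[i],
                paste(m[[i]], collapse = ","), cohesiveness(cs)[i]),
        character(1)), path)
    invisible(path)
}

#' @rdname writeComplexSet
#' @export
readComplexSet <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) return(ComplexSet(list(), numeric(0)))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 3L))
        stop("malformed complex-set file: ", path)
    members <- lapply(fields, function(f)
        strsplit(f[[2L]], ",", fixed = TRUE)[[1L]])
    names(members) <- vapply(fields, `[[`, character(1), 1L)
    ComplexSet(members,
               as.numeric(vapply(fields, `[[`, character(1), 3L)))
}
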