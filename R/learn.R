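#' Read and write gold-standard complex files
#'
#' One complex per line: \code{name<TAB>member1,member2,...}.
#'
#' @param path file path.
#' @param gold a \linkS4class{GoldStandard}.
#' @return \code{readGoldStandard} returns a \linkS4class{GoldStandard};
#'   \code{writeGoldStandard} invisibly returns \code{path}.
#' @export
readGoldStandard <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2L)
    if (length(bad))
        stop(sprintf("malformed complex entry at line %d of %s",
                     bad[1L], path))
    cx <- lapply(fields, function(f) strsplit(f[[2L]], ",", fixed = TRUE)[[1L]])
    names(cx) <- vapply(fields, `[[`, character(1), 1L)
    GoldStandard(cx)
}

#' @rdname readGoldStandard
#' @export
writeGoldStandard <- function(gold, path) {
    cx <- complexList(gold)
    writeLines(vapply(names(cx), function(nm)
        paste0(nm, "\t", paste(cx[[nm]], collapse = ",")), character(1)),
        path)
    invisible(path)
}

#' Derive co-complex pair labels from a gold standard
#'
#' A pair is \code{"positive"} when both proteins co-occur in at least
#' one reference complex, \code{"negative"} when both appear somewhere in
#' the gold standard but never together, and unlabeled (NA) when either
#' protein is absent from the reference.
#'
#' @param gold a \linkS4class{GoldStandard}.
#' @param pairs data.frame with columns \code{protein_a},
#'   \code{protein_b}.
#' @return character vector (\code{"positive"}, \code{"negative"}, NA)
#'   parallel to \code{pairs}.
#' @export
derivePairLabels <- function(gold, pairs) {
    cx <- complexList(gold)
    byProt <- .proteinComplexIndex(cx)
    vapply(seq_len(nrow(pairs)), function(i) {
        ca <- byProt[[pairs$protein_a[i]]]
        cb <- byProt[[pairs$protein_b[i]]]
        if (is.null(ca) || is.null(cb)) return(NA_character_)
        if (length(intersect(ca, cb))) "positive" else "negative"
    }, character(1))
}

.proteinComplexIndex <- function(cx) {
    prot <- unlist(cx, use.names = FALSE)
    idx <- split(rep(names(cx), lengths(cx)), prot)
    idx
}

#' Partition complexes into cross-validation folds
#'
#' Complexes are shuffled with the given seed and dealt round-robin into
#' k folds. Splitting at the complex level (rather than the pair level)
#' is what prevents label leakage: all pairs of one complex stand or fall
#' together.
#'
#' @param gold a \linkS4class{GoldStandard} with at least k complexes.
#' @param k number of folds (>= 2).
#' @param seed integer shuffle seed.
#' @return named integer vector, complex name -> fold in 1..k.
#' @export
splitByComplex <- function(gold, k, seed = 1L) {
    nm <- names(complexList(gold))
    if (k < 2L) stop("need at least 2 folds")
    if (k > length(nm))
        stop(sprintf("k = %d exceeds the %d available complexes",
                     k, length(nm)))
    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    set.seed(as.integer(seed))
    shuffled <- sample(nm)
    folds <- rep(seq_len(k), length.out = length(nm))
    stats::setNames(folds[match(nm, shuffled)], nm)
}

#' Assign labeled pairs to complex-held-out folds
#'
#' A labeled pair belongs to a fold only when every gold-standard complex
#' containing either of its proteins lies in that fold; pairs whose
#' complexes straddle folds are held out of cross-validation entirely
#' (NA). Unlabeled pairs get NA.
#'
#' @param gold a \linkS4class{GoldStandard}.
#' @param folds complex -> fold assignment from
#'   \code{\link{splitByComplex}}.
#' @param pairs data.frame with \code{protein_a}, \code{protein_b}.
#' @return integer fold per pair, NA when excluded.
#' @export
assignPairFolds <- function(gold, folds, pairs) {
    byProt <- .proteinComplexIndex(complexList(gold))
    vapply(seq_len(nrow(pairs)), function(i) {
        ca <- byProt[[pairs$protein_a[i]]]
        cb <- byProt[[pairs$protein_b[i]]]
        if (is.null(ca) || is.null(cb)) return(NA_integer_)
        f <- unique(folds[union(ca, cb)])
        if (length(f) == 1L) f else NA_integer_
    }, integer(1))
}

#' Build a wide per-pair feature table from pair scores
#'
#' Aggregates per-experiment pair-score tables (already harmonized into
#' one namespace) into one row per protein pair with a column per
#' (experiment, score) combination, named
#' \code{<experiment_id>__<score>}. A pair unscored in an experiment has
#' NA there; every row has at least one observed feature by construction.
#' Extra numeric columns in the input (external evidence) are carried
#' through under the same naming scheme.
#'
#' @param scores one pair-score data.frame or a list of them.
#' @return data.frame keyed by \code{protein_a}, \code{protein_b}
#'   followed by feature columns, sorted by pair.
#' @export
buildFeatureTable <- function(scores) {
    if (is.data.frame(scores)) scores <- list(scores)
    all <- do.call(rbind, scores)
    featCols <- setdiff(colnames(all),
                        c("protein_a", "protein_b", "experiment_id"))
    key <- paste(all$protein_a, all$protein_b, sep = "\r")
    ukey <- unique(key)
    tab <- all[match(ukey, key), c("protein_a", "protein_b"), drop = FALSE]
    rownames(tab) <- NULL
    row <- match(key, ukey)
    for (ex in sort(unique(all$experiment_id))) {
        sel <- all$experiment_id == ex
        for (fc in featCols) {
            col <- rep(NA_real_, length(ukey))
            col[row[sel]] <- all[[fc]][sel]
            tab[[paste0(ex, "__", fc)]] <- col
        }
    }
    tab <- tab[order(tab$protein_a, tab$protein_b), , drop = FALSE]
    rownames(tab) <- NULL
    tab
}

## Missing-feature encoding shared by training and scoring: every feature
## column f yields (f with NA -> 0, obs__f in {0,1}). "Not co-detected"
## is informative and distinct from "uncorrelated", so the mask channel
## is kept alongside the zero-filled value.
.designMatrix <- function(tab, featureNames) {
    miss <- setdiff(featureNames, colnames(tab))
    if (length(miss))
        stop("feature table lacks model columns: ",
             paste(miss, collapse = ", "))
    X <- matrix(0, nrow(tab), 2L * length(featureNames))
    colnames(X) <- c(featureNames, paste0("obs__", featureNames))
    for (i in seq_along(featureNames)) {
        v <- tab[[featureNames[i]]]
        obs <- !is.na(v)
        X[, i] <- ifelse(obs, v, 0)
        X[, length(featureNames) + i] <- as.numeric(obs)
    }
    X
}

#' Train the probabilistic co-complex classifier
#'
#' Fits a probability random forest (via \pkg{ranger}) on the labeled
#' rows of a feature table. Missing co-elution scores are encoded as a
#' zero-filled value plus a 0/1 observed-mask channel per feature column,
#' so "not co-detected" stays distinct from "uncorrelated". Training is
#' deterministic given \code{seed} (single-threaded forest growth), and
#' the returned model serializes with \code{saveRDS} and reproduces its
#' scores bit-exactly after reload.
#'
#' @param table feature table from \code{\link{buildFeatureTable}} with a
#'   \code{label} column (\code{"positive"}/\code{"negative"}/NA); at
#'   least 10 rows of each class must be labeled.
#' @param hyperparams list; recognised: \code{num.trees} (default 500),
#'   \code{mtry}, \code{min.node.size}.
#' @param seed integer training seed.
#' @return a \linkS4class{CoComplexModel}.
#' @export
trainClassifier <- function(table, hyperparams = list(), seed = 1L) {
    if (!"label" %in% colnames(table))
        stop("feature table needs a 'label' column")
    lab <- table$label
    sel <- !is.na(lab)
    npos <- sum(lab[sel] == "positive")
    nneg <- sum(lab[sel] == "negative")
    if (npos == 0L || nneg == 0L)
        stop("degenerate single-class training set")
    if (npos < 10L || nneg < 10L)
        stop(sprintf("need >= 10 labels per class (have %d+/%d-)",
                     npos, nneg))
    featureNames <- setdiff(colnames(table),
                            c("protein_a", "protein_b", "label"))
    hp <- utils::modifyList(list(num.trees = 500L, mtry = NULL,
                                 min.node.size = NULL), hyperparams)
    X <- .designMatrix(table[sel, , drop = FALSE], featureNames)
    y <- factor(lab[sel], levels = c("negative", "positive"))
    forest <- ranger::ranger(
        x = as.data.frame(X), y = y, probability = TRUE,
        num.trees = hp$num.trees, mtry = hp$mtry,
        min.node.size = hp$min.node.size,
        seed = as.integer(seed), num.threads = 1L)
    new("CoComplexModel", forest = forest, featureNames = featureNames,
        hyperparams = hp, seed = as.integer(seed))
}

#' Score all pairs of a feature table
#'
#' Applies a trained \linkS4class{CoComplexModel} to every row of a
#' feature table (labeled or not), yielding an unthresholded
#' \linkS4class{ScoredNetwork} whose edge scores are the forest's
#' positive-class probabilities.
#'
#' @param model a \linkS4class{CoComplexModel}.
#' @param table feature table whose columns cover the model's schema.
#' @return a \linkS4class{ScoredNetwork}.
#' @export
scorePairs <- function(model, table) {
    prov <- list(model = "ranger probability forest",
                 num.trees = model@hyperparams$num.trees,
                 seed = model@seed)
    if (nrow(table) == 0L)
        return(ScoredNetwork(data.frame(protein_a = character(0),
                                        protein_b = character(0),
                                        score = numeric(0)),
                             provenance = prov))
    X <- .designMatrix(table, model@featureNames)
    pred <- stats::predict(model@forest, data = as.data.frame(X),
                           num.threads = 1L)
    ScoredNetwork(data.frame(protein_a = table$protein_a,
                             protein_b = table$protein_b,
                             score = pred$predictions[, "positive"],
                             stringsAsFactors = FALSE),
                  provenance = prov)
}

#' Precision-recall curve over labeled edges
#'
#' Edges are sorted by descending score with ties grouped: each distinct
#' score is one operating point, with cumulative precision and recall
#' after admitting all edges at or above it.
#'
#' @param scores numeric scores.
#' @param labels logical (TRUE = positive) or
#'   \code{"positive"}/\code{"negative"} character, parallel to
#'   \code{scores}.
#' @return data.frame with columns \code{score}, \code{tp}, \code{fp},
#'   \code{precision}, \code{recall}, one row per distinct score,
#'   descending.
#' @export
precisionRecallCurve <- function(scores, labels) {
    if (is.character(labels) || is.factor(labels))
        labels <- as.character(labels) == "positive"
    keep <- !is.na(labels) & !is.na(scores)
    scores <- scores[keep]; labels <- labels[keep]
    P <- sum(labels)
    if (P == 0L || sum(!labels) == 0L)
        stop("need at least one positive and one negative labeled edge")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; l <- labels[ord]
    grpEnd <- cumsum(rle(s)$lengths)
    tp <- cumsum(l)[grpEnd]
    fp <- cumsum(!l)[grpEnd]
    data.frame(score = s[grpEnd], tp = tp, fp = fp,
               precision = tp / (tp + fp), recall = tp / P)
}

#' Area under the precision-recall curve (average precision)
#'
#' Standard average precision with tied scores grouped: each operating
#' point contributes its precision weighted by the recall it adds.
#'
#' @inheritParams precisionRecallCurve
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
    curve <- precisionRecallCurve(scores, labels)
    dr <- diff(c(0, curve$recall))
    sum(dr * curve$precision)
}

#' Find the score cutoff attaining a target precision
#'
#' Returns the lowest score (hence highest recall) operating point of a
#' precision-recall curve whose cumulative precision reaches the target.
#' When no cutoff attains it the result says so explicitly
#' (\code{attainable = FALSE}) instead of silently clamping.
#'
#' @param curve result of \code{\link{precisionRecallCurve}}.
#' @param targetPrecision precision in (0, 1].
#' @return list with \code{threshold}, \code{attainable},
#'   \code{precision}, \code{recall}.
#' @export
thresholdAtPrecision <- function(curve, targetPrecision) {
    ok <- which(curve$precision >= targetPrecision)
    if (length(ok) == 0L)
        return(list(threshold = NA_real_, attainable = FALSE,
                    precision = NA_real_, recall = NA_real_))
    pick <- ok[which.max(curve$recall[ok])]
    list(threshold = curve$score[pick], attainable = TRUE,
         precision = curve$precision[pick], recall = curve$recall[pick])
}

#' Keep only edges at or above a score threshold
#'
#' @param network a \linkS4class{ScoredNetwork}.
#' @param threshold score cutoff.
#' @return the thresholded \linkS4class{ScoredNetwork} (threshold slot
#'   set).
#' @export
applyThreshold <- function(network, threshold) {
    e <- networkEdges(network)
    ScoredNetwork(e[e$score >= threshold, , drop = FALSE],
                  threshold = threshold, provenance = network@provenance)
}

#' Complex-held-out cross-validated scoring
#'
#' Runs k-fold cross-validation at the complex level: complexes are
#' partitioned by \code{\link{splitByComplex}}, labeled pairs are
#' assigned folds by \code{\link{assignPairFolds}} (pairs straddling
#' folds are excluded), and each fold's pairs are scored by a classifier
#' trained on the remaining folds.
#'
#' @param table labeled feature table (see \code{\link{trainClassifier}}).
#' @param gold the \linkS4class{GoldStandard} behind the labels.
#' @param k number of folds.
#' @param seed integer seed for the fold split and forest training.
#' @param hyperparams forest hyperparameters.
#' @return list with \code{predictions} (data.frame \code{protein_a},
#'   \code{protein_b}, \code{label}, \code{fold}, \code{score}) and
#'   \code{auprc} (pooled held-out average precision).
#' @export
crossValidate <- function(table, gold, k = 5L, seed = 1L,
                          hyperparams = list()) {
    folds <- splitByComplex(gold, k, seed)
    pf <- assignPairFolds(gold, folds, table)
    pf[is.na(table$label)] <- NA_integer_
    preds <- NULL
    for (f in sort(unique(pf[!is.na(pf)]))) {
        trainSel <- !is.na(pf) & pf != f
        testSel <- !is.na(pf) & pf == f
        model <- trainClassifier(table[trainSel, , drop = FALSE],
                                 hyperparams, seed = seed)
        net <- scorePairs(model, table[testSel, , drop = FALSE])
        sc <- networkEdges(net)
        key <- paste(sc$protein_a, sc$protein_b, sep = "\r")
        tk <- paste(table$protein_a[testSel], table$protein_b[testSel],
                    sep = "\r")
        preds <- rbind(preds, data.frame(
            protein_a = table$protein_a[testSel],
            protein_b = table$protein_b[testSel],
            label = table$label[testSel], fold = f,
            score = sc$score[match(tk, key)],
            stringsAsFactors = FALSE))
    }
    list(predictions = preds,
         auprc = auprc(preds$score, preds$label))
}
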