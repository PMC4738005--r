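test_that("gold-standard files round-trip and induce co-complex labels", {
    gold <- GoldStandard(list(C1 = c("A", "B", "C"), C2 = c("D", "E")))
    p <- tempfile()
    writeGoldStandard(gold, p)
    expect_identical(complexList(readGoldStandard(p)), complexList(gold))

    pairs <- data.frame(protein_a = c("A", "A", "A"),
                        protein_b = c("B", "D", "X"),
                        stringsAsFactors = FALSE)
    expect_identical(derivePairLabels(gold, pairs),
                     c("positive", "negative", NA_character_))
})

test_that("complex-level fold splitting is balanced, deterministic and guarded", {
    gold <- GoldStandard(list(C1 = c("A", "B"), C2 = c("C", "D"),
                              C3 = c("E", "F"), C4 = c("G", "H")))
    f <- splitByComplex(gold, 2L, seed = 3L)
    expect_equal(as.vector(sort(table(f))), c(2L, 2L))
    expect_identical(f, splitByComplex(gold, 2L, seed = 3L))
    expect_error(splitByComplex(gold, 5L), "exceeds")
    expect_error(splitByComplex(gold, 1L), "2 folds")
})

test_that("pairs whose complexes straddle folds are excluded, per brute force", {
    gold <- GoldStandard(list(C1 = c("A", "B", "C"),
                              C2 = c("C", "D"),      # overlaps C1 via C
                              C3 = c("E", "F"), C4 = c("G", "H")))
    folds <- splitByComplex(gold, 2L, seed = 1L)
    prots <- LETTERS[1:8]
    cmb <- utils::combn(prots, 2)
    pairs <- data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
                        stringsAsFactors = FALSE)
    got <- assignPairFolds(gold, folds, pairs)
    cx <- complexList(gold)
    for (i in seq_len(nrow(pairs))) {
        inCx <- names(cx)[vapply(cx, function(m)
            pairs$protein_a[i] %in% m || pairs$protein_b[i] %in% m,
            logical(1))]
        want <- if (length(inCx) == 0L) NA_integer_ else {
            ff <- unique(folds[inCx])
            if (length(ff) == 1L) ff else NA_integer_
        }
        expect_identical(got[i], unname(want))
    }
    # by construction no assigned pair draws on complexes in two folds
    assigned <- !is.na(got)
    for (i in which(assigned)) {
        inCx <- names(cx)[vapply(cx, function(m)
            pairs$protein_a[i] %in% m || pairs$protein_b[i] %in% m,
            logical(1))]
        expect_length(unique(folds[inCx]), 1L)
    }
})

## Separable fixture: positives score 0.9 on every feature, negatives 0.1.
.separableTable <- function(nComplex = 8L, perComplex = 3L) {
    members <- split(sprintf("P%03d", seq_len(nComplex * perComplex)),
                     rep(seq_len(nComplex), each = perComplex))
    names(members) <- sprintf("C%d", seq_len(nComplex))
    gold <- GoldStandard(members)
    prots <- unlist(members)
    cmb <- utils::combn(prots, 2)
    tab <- data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
                      stringsAsFactors = FALSE)
    tab$label <- derivePairLabels(gold, tab)
    val <- ifelse(tab$label == "positive", 0.9, 0.1)
    tab$e1__pcc_noise <- val
    tab$e1__wcc <- val
    list(gold = gold, table = tab)
}

test_that("a separable table yields perfect held-out rankings", {
    fx <- .separableTable()
    cv <- crossValidate(fx$table, fx$gold, k = 2L, seed = 1L,
                        hyperparams = list(num.trees = 100L))
    expect_equal(cv$auprc, 1.0)
})

test_that("training rejects degenerate and undersized label sets", {
    fx <- .separableTable()
    onlyPos <- fx$table[fx$table$label %in% "positive", ]
    expect_error(trainClassifier(onlyPos), "single-class")
    tiny <- fx$table[c(which(fx$table$label == "positive")[1:3],
                       which(fx$table$label == "negative")[1:30]), ]
    expect_error(trainClassifier(tiny), ">= 10")
})

test_that("label permutation drives held-out AUPRC to prevalence", {
    tab <- defaultFeatureTable()
    w <- defaultWorld()
    set.seed(77)
    perm <- tab
    lab <- perm$label
    perm$label[!is.na(lab)] <- sample(lab[!is.na(lab)])
    cv <- crossValidate(perm, w@goldStandard, k = 5L, seed = 77L,
                        hyperparams = list(num.trees = 200L))
    prevalence <- mean(cv$predictions$label == "positive")
    expect_lt(abs(cv$auprc - prevalence), 0.1)
})

test_that("models serialize and rescore bit-identically", {
    fx <- .separableTable()
    model <- trainClassifier(fx$table,
                             hyperparams = list(num.trees = 100L),
                             seed = 9L)
    net1 <- scorePairs(model, fx$table)
    p <- tempfile(fileext = ".rds")
    saveRDS(model, p)
    net2 <- scorePairs(readRDS(p), fx$table)
    expect_identical(networkEdges(net1)$score, networkEdges(net2)$score)
    # empty table -> empty network
    expect_equal(nrow(networkEdges(scorePairs(model, fx$table[0, ]))), 0L)
    # schema mismatch is a contract error
    expect_error(scorePairs(model, fx$table[, 1:4]), "lacks")
})

test_that("precision-recall machinery matches hand enumeration", {
    curve <- precisionRecallCurve(c(0.9, 0.8, 0.7),
                                  c("positive", "positive", "negative"))
    thr <- thresholdAtPrecision(curve, 1.0)
    expect_true(thr$attainable)
    expect_equal(thr$threshold, 0.8)
    expect_equal(thr$recall, 1.0)
    # all negatives above all positives: 0.9 precision unattainable
    badCurve <- precisionRecallCurve(c(0.9, 0.8, 0.3, 0.2),
                                     c(FALSE, FALSE, TRUE, TRUE))
    bad <- thresholdAtPrecision(badCurve, 0.9)
    expect_false(bad$attainable)
    expect_true(is.na(bad$threshold))
})

test_that("the PR curve equals brute-force cumulative computation", {
    set.seed(8)
    scores <- round(stats::runif(200), 2)   # ties guaranteed
    labels <- stats::runif(200) < 0.3
    curve <- precisionRecallCurve(scores, labels)
    for (r in seq_len(nrow(curve))) {
        cut <- curve$score[r]
        tp <- sum(labels & scores >= cut)
        fp <- sum(!labels & scores >= cut)
        expect_equal(curve$tp[r], tp)
        expect_equal(curve$precision[r], tp / (tp + fp))
        expect_equal(curve$recall[r], tp / sum(labels))
    }
    # average precision against direct summation over operating points
    ap <- sum(diff(c(0, curve$recall)) * curve$precision)
    expect_equal(auprc(scores, labels), ap)
})

test_that("threshold selection is monotone in the precision target", {
    set.seed(15)
    scores <- stats::runif(300)
    labels <- stats::runif(300) < 0.4 * scores + 0.2
    curve <- precisionRecallCurve(scores, labels)
    targets <- seq(0.2, 0.95, by = 0.05)
    thr <- vapply(targets, function(t)
        thresholdAtPrecision(curve, t)$threshold, numeric(1))
    ok <- !is.na(thr)
    expect_true(all(diff(thr[ok]) >= 0))
})
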