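test_that("ortholog maps load with set semantics and reject malformed lines", {
    p <- tempfile()
    writeLines(c("g1\tH1", "g2\tH2", "g1\tH1"), p)
    expect_equal(nrow(orthologTable(loadOrthologMap(p, "fly"))), 2L)

    bad <- tempfile()
    writeLines(c("g1\tH1", "g2"), bad)
    expect_error(loadOrthologMap(bad, "fly"), "line 2")

    empty <- tempfile()
    writeLines(character(0), empty)
    expect_equal(nrow(orthologTable(loadOrthologMap(empty, "fly"))), 0L)

    # write/read round-trip
    map <- OrthologMap("fly", c("a", "b"), c("H1", "H2"))
    rt <- tempfile()
    writeOrthologMap(map, rt)
    expect_identical(orthologTable(loadOrthologMap(rt, "fly")),
                     orthologTable(map))
})

.scoreRecord <- function(a, b, pcc = 0.5, wcc = 0.5, cap = 1,
                         euc = NA_real_, exp = "e1") {
    data.frame(protein_a = pmin(a, b), protein_b = pmax(a, b),
               experiment_id = exp, pcc_noise = pcc, wcc = wcc,
               coapex = cap, euclid_sim = euc, stringsAsFactors = FALSE)
}

test_that("bijective maps rename scores without loss", {
    rec <- rbind(.scoreRecord("a", "b", 0.4), .scoreRecord("b", "c", 0.7))
    map <- OrthologMap("fly", c("a", "b", "c"), c("H1", "H2", "H3"))
    out <- mapScoresToReference(rec, map)
    expect_equal(nrow(out), 2L)
    expect_equal(out$protein_a, c("H1", "H2"))
    expect_equal(out$pcc_noise, c(0.4, 0.7))
})

test_that("co-ortholog collisions merge by per-feature maximum", {
    rec <- rbind(.scoreRecord("a1", "b", pcc = 0.4, wcc = 0.9,
                              euc = 0.3),
                 .scoreRecord("a2", "b", pcc = 0.7, wcc = 0.2,
                              euc = NA_real_))
    map <- OrthologMap("fly", c("a1", "a2", "b"), c("HA", "HA", "HB"))
    out <- mapScoresToReference(rec, map)
    expect_equal(nrow(out), 1L)
    expect_equal(out$pcc_noise, 0.7)  # max over colliding records
    expect_equal(out$wcc, 0.9)        # per-feature, not per-record
    expect_equal(out$euclid_sim, 0.3) # NA ignored in the max
    # unmapped proteins are dropped
    rec2 <- .scoreRecord("zz", "b")
    expect_equal(nrow(mapScoresToReference(rec2, map)), 0L)
    # expansions collapsing to one reference gene are dropped
    rec3 <- .scoreRecord("a1", "a2")
    expect_equal(nrow(mapScoresToReference(rec3, map)), 0L)
})

test_that("many-to-many mapping matches the brute-force expansion oracle", {
    rec <- rbind(.scoreRecord("a", "b", 0.1), .scoreRecord("a", "c", 0.2),
                 .scoreRecord("b", "c", 0.3), .scoreRecord("c", "d", 0.4),
                 .scoreRecord("d", "x", 0.5))
    map <- OrthologMap("fly",
                       c("a", "a", "b", "c", "d"),
                       c("H1", "H2", "H2", "H3", "H1"))
    out <- mapScoresToReference(rec, map)

    ## oracle: expand every record against every ortholog combination
    lut <- split(orthologTable(map)$reference, orthologTable(map)$source)
    expanded <- list()
    for (i in seq_len(nrow(rec))) {
        ra <- lut[[rec$protein_a[i]]]; rb <- lut[[rec$protein_b[i]]]
        if (is.null(ra) || is.null(rb)) next
        for (u in ra) for (v in rb) {
            if (u == v) next
            expanded[[length(expanded) + 1L]] <-
                data.frame(a = min(u, v), b = max(u, v),
                           pcc = rec$pcc_noise[i])
        }
    }
    expanded <- do.call(rbind, expanded)
    key <- paste(expanded$a, expanded$b)
    wantPairs <- sort(unique(key))
    expect_equal(sort(paste(out$protein_a, out$protein_b)), wantPairs)
    wantMax <- tapply(expanded$pcc, key, max)
    expect_equal(out$pcc_noise[match(names(wantMax),
                                     paste(out$protein_a, out$protein_b))],
                 as.numeric(wantMax))
    # merged values are attained by some source record
    expect_true(all(out$pcc_noise %in% rec$pcc_noise))
})

test_that("network projection expands, drops unmapped ends and keeps max scores", {
    edges <- data.frame(protein_a = c("H1", "H2"),
                        protein_b = c("H2", "H3"),
                        score = c(0.9, 0.8), stringsAsFactors = FALSE)
    net <- ScoredNetwork(edges)
    bij <- OrthologMap("fly", c("f1", "f2", "f3"), c("H1", "H2", "H3"))
    proj <- projectNetwork(net, bij)
    expect_equal(nrow(networkEdges(proj)), 2L)
    expect_equal(sort(networkEdges(proj)$score), c(0.8, 0.9))
    # unmapped endpoint H3 -> its edge is absent
    partial <- OrthologMap("fly", c("f1", "f2"), c("H1", "H2"))
    expect_equal(nrow(networkEdges(projectNetwork(net, partial))), 1L)
})

test_that("projection count matches brute force under one-to-two maps", {
    set.seed(21)
    nodes <- sprintf("H%d", 1:8)
    cmb <- utils::combn(nodes, 2)
    sel <- sample(ncol(cmb), 10)
    edges <- data.frame(protein_a = cmb[1, sel], protein_b = cmb[2, sel],
                        score = round(stats::runif(10), 3),
                        stringsAsFactors = FALSE)
    net <- ScoredNetwork(edges)
    src <- c(paste0("f", 1:8), paste0("f", 1:3, "bis"))
    ref <- c(nodes, nodes[1:3])      # H1..H3 have two co-orthologs
    map <- OrthologMap("fly", src, ref)
    proj <- networkEdges(projectNetwork(net, map))

    inv <- split(src, ref)
    want <- new.env()
    for (i in seq_len(nrow(edges)))
        for (u in inv[[edges$protein_a[i]]])
            for (v in inv[[edges$protein_b[i]]]) {
                if (u == v) next
                k <- paste(min(u, v), max(u, v))
                prev <- mget(k, envir = want, ifnotfound = -1)[[1]]
                assign(k, max(prev, edges$score[i]), envir = want)
            }
    expect_equal(nrow(proj), length(ls(want)))
    got <- stats::setNames(proj$score,
                           paste(proj$protein_a, proj$protein_b))
    for (k in ls(want)) expect_equal(unname(got[k]), get(k, envir = want))
})

test_that("projection through a bijective map and back is the identity", {
    set.seed(33)
    nodes <- sprintf("H%02d", 1:15)
    cmb <- utils::combn(nodes, 2)
    sel <- sample(ncol(cmb), 50)
    edges <- data.frame(protein_a = cmb[1, sel], protein_b = cmb[2, sel],
                        score = stats::runif(50), stringsAsFactors = FALSE)
    net <- ScoredNetwork(edges)
    fwd <- OrthologMap("fly", sprintf("f%02d", 1:15), nodes)
    inv <- OrthologMap("ref", nodes, sprintf("f%02d", 1:15))
    back <- projectNetwork(projectNetwork(net, fwd), inv)
    expect_equal(networkEdges(back)[, c("protein_a", "protein_b")],
                 networkEdges(net)[, c("protein_a", "protein_b")])
    expect_equal(networkEdges(back)$score, networkEdges(net)$score)
})
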