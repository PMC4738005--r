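#' Pipeline configuration
#'
#' The pipeline is driven by one declarative YAML file with sections
#' \code{paths} (\code{world}: directory of profile/ortholog/gold files;
#' \code{output}: artifact directory), \code{score}, \code{learn},
#' \code{cluster}, \code{simulate} and a top-level \code{seed}. Unknown
#' keys are rejected by name; numeric parameters are range-checked before
#' any computation. \code{defaultPipelineConfig} returns the full default
#' configuration as a named list (the same structure
#' \code{readPipelineConfig} produces).
#'
#' @param worldDir directory holding (or receiving) the profile files.
#' @param outputDir directory for pipeline artifacts.
#' @param seed integer seed used by every stochastic stage.
#' @return a validated configuration list.
#' @export
defaultPipelineConfig <- function(worldDir = "world", outputDir = "out",
                                  seed = 1L) {
    config <- list(
        paths = list(world = worldDir, output = outputDir),
        score = list(noise_reps = 100L, pseudocount = 1.0, max_lag = 2L,
                     min_overlap = 1L),
        learn = list(folds = 5L, precision_target = 0.9,
                     num_trees = 500L),
        cluster = list(min_size = 3L, cohesiveness_min = 0.3,
                       overlap_merge_jaccard = 0.8, penalty = 2.0),
        simulate = list(n_species = 2L, n_complexes = 20L,
                        complex_size_min = 3L, complex_size_max = 6L,
                        n_monomers = 40L, n_experiments_per_species = 2L,
                        n_fractions = 60L, peak_width_min = 1,
                        peak_width_max = 3, abundance_meanlog = 3,
                        abundance_sdlog = 1, ms2_depth = 1,
                        ms1_noise_cv = 0.2, dropout_prob = 0.1,
                        ortholog_conservation_prob = 0.9,
                        duplication_prob = 0),
        seed = as.integer(seed))
    validatePipelineConfig(config)
}

#' @param path YAML file path.
#' @rdname defaultPipelineConfig
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    config <- defaultPipelineConfig()
    for (section in names(user)) {
        if (!section %in% names(config))
            stop("unknown config section: ", section)
        if (is.list(config[[section]])) {
            for (key in names(user[[section]])) {
                if (!key %in% names(config[[section]]))
                    stop(sprintf("unknown config key: %s.%s", section, key))
                config[[section]][[key]] <- user[[section]][[key]]
            }
        } else config[[section]] <- user[[section]]
    }
    validatePipelineConfig(config)
}

#' @param config configuration list to check.
#' @rdname defaultPipelineConfig
#' @export
validatePipelineConfig <- function(config) {
    sc <- config$score
    if (sc$noise_reps < 0) stop("score.noise_reps must be >= 0")
    if (sc$pseudocount < 0) stop("score.pseudocount must be >= 0")
    if (sc$max_lag < 0) stop("score.max_lag must be >= 0")
    if (sc$min_overlap < 0) stop("score.min_overlap must be >= 0")
    ln <- config$learn
    if (ln$folds < 2) stop("learn.folds must be >= 2")
    if (ln$precision_target <= 0 || ln$precision_target > 1)
        stop("learn.precision_target must lie in (0, 1]")
    cl <- config$cluster
    if (cl$min_size < 2) stop("cluster.min_size must be >= 2")
    if (cl$cohesiveness_min < 0 || cl$cohesiveness_min > 1)
        stop("cluster.cohesiveness_min must lie in [0, 1]")
    if (cl$penalty < 0) stop("cluster.penalty must be >= 0")
    config
}

.configSimParams <- function(config) {
    sm <- config$simulate
    SimParams(nSpecies = sm$n_species, nComplexes = sm$n_complexes,
              complexSizeRange = c(sm$complex_size_min,
                                   sm$complex_size_max),
              nMonomers = sm$n_monomers,
              nExperimentsPerSpecies = sm$n_experiments_per_species,
              nFractions = sm$n_fractions,
              peakWidthRange = c(sm$peak_width_min, sm$peak_width_max),
              abundanceMeanlog = sm$abundance_meanlog,
              abundanceSdlog = sm$abundance_sdlog,
              ms2Depth = sm$ms2_depth, ms1NoiseCv = sm$ms1_noise_cv,
              dropoutProb = sm$dropout_prob,
              orthologConservationProb = sm$ortholog_conservation_prob,
              duplicationProb = sm$duplication_prob,
              seed = config$seed)
}

.configScoreParams <- function(config) {
    sc <- config$score
    ScoreParams(noiseReps = sc$noise_reps, pseudocount = sc$pseudocount,
                maxLag = sc$max_lag, rngSeed = config$seed,
                minOverlap = sc$min_overlap)
}

## Deterministic provenance: stage, versions, seed, flattened params and
## md5 of every input file. No timestamps, so reruns are byte-identical.
.writeRunLog <- function(outDir, stage, config, inputs = character(0)) {
    lines <- c(sprintf("stage\t%s", stage),
               sprintf("package\tCoFracNet %s",
                       as.character(utils::packageVersion("CoFracNet"))),
               sprintf("r_version\t%s", R.version.string),
               sprintf("seed\t%d", config$seed),
               sprintf("config\t%s",
                       gsub("\n", " | ", yaml::as.yaml(config))))
    if (length(inputs)) {
        h <- tools::md5sum(inputs)
        lines <- c(lines, sprintf("input\t%s\t%s", names(h), h))
    }
    writeLines(lines, file.path(outDir, paste0(stage, "_runlog.tsv")))
}

#' Read and write network TSV files
#'
#' Columns \code{protein_a}, \code{protein_b}, \code{score}; the
#' threshold and model provenance travel in a key-value sidecar file
#' \code{<path>.meta}.
#'
#' @param network a \linkS4class{ScoredNetwork}.
#' @param path TSV path.
#' @return \code{readNetwork} returns a \linkS4class{ScoredNetwork};
#'   \code{writeNetwork} invisibly returns \code{path}.
#' @export
writeNetwork <- function(network, path) {
    e <- networkEdges(network)
    writeLines(c("protein_a\tprotein_b\tscore",
                 sprintf("%s\t%s\t%.17g", e$protein_a, e$protein_b,
                         e$score)), path)
    prov <- network@provenance
    meta <- c(sprintf("threshold\t%s",
                      ifelse(is.na(networkThreshold(network)), "NA",
                             sprintf("%.17g", networkThreshold(network)))),
              vapply(names(prov), function(k)
                  sprintf("%s\t%s", k, paste(format(prov[[k]]),
                                             collapse = ",")),
                  character(1)))
    writeLines(meta, paste0(path, ".meta"))
    invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = c("character", "character",
                                            "numeric"))
    threshold <- NA_real_
    prov <- list()
    metaPath <- paste0(path, ".meta")
    if (file.exists(metaPath)) {
        kv <- strsplit(readLines(metaPath), "\t", fixed = TRUE)
        for (f in kv) {
            if (f[[1L]] == "threshold")
                threshold <- suppressWarnings(as.numeric(f[[2L]]))
            else prov[[f[[1L]]]] <- f[[2L]]
        }
    }
    ScoredNetwork(tab, threshold = threshold, provenance = prov)
}

.worldExperiments <- function(worldDir) {
    ms2 <- sort(list.files(worldDir, pattern = "_ms2\\.tsv$"))
    if (length(ms2) == 0L)
        stop("no *_ms2.tsv profile files found in ", worldDir)
    eids <- sub("_ms2\\.tsv$", "", ms2)
    data.frame(experiment = eids,
               species = sub("_e[0-9]+$", "", eids),
               ms2 = file.path(worldDir, ms2),
               ms1 = file.path(worldDir, paste0(eids, "_ms1.tsv")),
               stringsAsFactors = FALSE)
}

#' Run pipeline stages
#'
#' Each stage reads its inputs from the configured directories, writes
#' its artifacts plus a deterministic run-log (parameters, seed, input
#' hashes, versions) under \code{paths$output}, and returns its main
#' result invisibly. Stages are re-entrant: rerunning with unchanged
#' inputs and seed rewrites identical content.
#'
#' \describe{
#'   \item{\code{runSimulate}}{generates the synthetic world into
#'     \code{paths$world}.}
#'   \item{\code{runScore}}{scores every experiment's protein pairs
#'     (MS1 filtered to MS2-identified proteins first) into
#'     \code{scores/}.}
#'   \item{\code{runMap}}{harmonizes score tables into the reference
#'     namespace via each species' ortholog map, into \code{mapped/}.}
#'   \item{\code{runTrainPredict}}{builds the labeled feature table,
#'     runs complex-held-out cross-validation, trains the final
#'     classifier, scores all pairs and thresholds at the target
#'     precision; writes \code{network.tsv},
#'     \code{network_highconf.tsv}, \code{pr_curve.tsv},
#'     \code{cv_predictions.tsv}.}
#'   \item{\code{runCluster}}{clusters the high-confidence network into
#'     \code{complexes.tsv}.}
#'   \item{\code{runProject}}{projects the high-confidence network onto
#'     every species with an ortholog map, into \code{projected/}.}
#'   \item{\code{runEvaluate}}{writes \code{evaluation.tsv} with
#'     held-out AUPRC, threshold and complex-recovery
#'     precision/recall/F1.}
#'   \item{\code{runPipeline}}{all of the above in order; returns the
#'     evaluation list.}
#' }
#'
#' @param config configuration list from
#'   \code{\link{defaultPipelineConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @return see individual stage descriptions; always invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(config) {
    config <- validatePipelineConfig(config)
    world <- generateWorld(.configSimParams(config))
    writeWorld(world, config$paths$world)
    dir.create(config$paths$output, recursive = TRUE, showWarnings = FALSE)
    .writeRunLog(config$paths$output, "simulate", config)
    invisible(world)
}

#' @rdname pipeline
#' @export
runScore <- function(config) {
    config <- validatePipelineConfig(config)
    exps <- .worldExperiments(config$paths$world)
    outDir <- file.path(config$paths$output, "scores")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    params <- .configScoreParams(config)
    written <- character(0)
    for (i in seq_len(nrow(exps))) {
        ms2 <- readProfileMatrix(exps$ms2[i], "MS2_COUNTS",
                                 exps$experiment[i], exps$species[i])
        ms1 <- NULL
        if (file.exists(exps$ms1[i])) {
            ms1 <- readProfileMatrix(exps$ms1[i], "MS1_INTENSITY",
                                     exps$experiment[i], exps$species[i])
            ms1 <- filterMS1ByMS2(ms1, ms2)
        }
        scores <- scoreExperiment(ms2, ms1, params)
        p <- file.path(outDir, paste0(exps$experiment[i], "_scores.tsv"))
        writePairScores(scores, p)
        written <- c(written, p)
    }
    .writeRunLog(config$paths$output, "score", config,
                 c(exps$ms2, exps$ms1[file.exists(exps$ms1)]))
    invisible(written)
}

#' @rdname pipeline
#' @export
runMap <- function(config) {
    config <- validatePipelineConfig(config)
    exps <- .worldExperiments(config$paths$world)
    inDir <- file.path(config$paths$output, "scores")
    outDir <- file.path(config$paths$output, "mapped")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    inputs <- character(0)
    for (i in seq_len(nrow(exps))) {
        sp <- exps$species[i]
        mapPath <- file.path(config$paths$world,
                             paste0("ortholog_", sp, ".tsv"))
        if (!file.exists(mapPath))
            stop("missing ortholog map: ", mapPath)
        scorePath <- file.path(inDir,
                               paste0(exps$experiment[i], "_scores.tsv"))
        if (!file.exists(scorePath))
            stop("missing score table (run the score stage first): ",
                 scorePath)
        map <- loadOrthologMap(mapPath, sp)
        mapped <- mapScoresToReference(readPairScores(scorePath), map)
        p <- file.path(outDir, paste0(exps$experiment[i], "_scores.tsv"))
        writePairScores(mapped, p)
        written <- c(written, p)
        inputs <- c(inputs, mapPath, scorePath)
    }
    .writeRunLog(config$paths$output, "map", config, inputs)
    invisible(written)
}

#' @rdname pipeline
#' @export
runTrainPredict <- function(config) {
    config <- validatePipelineConfig(config)
    inDir <- file.path(config$paths$output, "mapped")
    files <- sort(list.files(inDir, pattern = "_scores\\.tsv$",
                             full.names = TRUE))
    if (length(files) == 0L)
        stop("no mapped score tables in ", inDir,
             " (run the map stage first)")
    goldPath <- file.path(config$paths$world, "gold_standard.tsv")
    if (!file.exists(goldPath))
        stop("missing gold standard: ", goldPath)
    gold <- readGoldStandard(goldPath)
    table <- buildFeatureTable(lapply(files, readPairScores))
    table$label <- derivePairLabels(gold, table)
    hp <- list(num.trees = config$learn$num_trees)
    cv <- crossValidate(table, gold, k = config$learn$folds,
                        seed = config$seed, hyperparams = hp)
    curve <- precisionRecallCurve(cv$predictions$score,
                                  cv$predictions$label)
    thr <- thresholdAtPrecision(curve, config$learn$precision_target)
    model <- trainClassifier(table, hp, seed = config$seed)
    network <- scorePairs(model, table)
    outDir <- config$paths$output
    writeNetwork(network, file.path(outDir, "network.tsv"))
    if (thr$attainable) {
        high <- applyThreshold(network, thr$threshold)
        writeNetwork(high, file.path(outDir, "network_highconf.tsv"))
    }
    utils::write.table(curve, file.path(outDir, "pr_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cv$predictions,
                       file.path(outDir, "cv_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("heldout_auprc\t%.17g", cv$auprc),
                 sprintf("precision_target\t%.17g",
                         config$learn$precision_target),
                 sprintf("threshold\t%s",
                         ifelse(thr$attainable,
                                sprintf("%.17g", thr$threshold), "NA")),
                 sprintf("threshold_attainable\t%s", thr$attainable)),
               file.path(outDir, "pr_report.tsv"))
    .writeRunLog(outDir, "train_predict", config, c(files, goldPath))
    invisible(list(model = model, network = network, cv = cv,
                   threshold = thr))
}

#' @rdname pipeline
#' @export
runCluster <- function(config) {
    config <- validatePipelineConfig(config)
    netPath <- file.path(config$paths$output, "network_highconf.tsv")
    if (!file.exists(netPath))
        stop("missing high-confidence network (run train-predict first): ",
             netPath)
    cl <- config$cluster
    cs <- clusterNetwork(readNetwork(netPath), minSize = cl$min_size,
                         cohesivenessMin = cl$cohesiveness_min,
                         overlapMergeJaccard = cl$overlap_merge_jaccard,
                         penalty = cl$penalty)
    writeComplexSet(cs, file.path(config$paths$output, "complexes.tsv"))
    .writeRunLog(config$paths$output, "cluster", config, netPath)
    invisible(cs)
}

#' @rdname pipeline
#' @export
runProject <- function(config) {
    config <- validatePipelineConfig(config)
    netPath <- file.path(config$paths$output, "network_highconf.tsv")
    if (!file.exists(netPath))
        stop("missing high-confidence network (run train-predict first): ",
             netPath)
    network <- readNetwork(netPath)
    mapFiles <- sort(list.files(config$paths$world,
                                pattern = "^ortholog_.*\\.tsv$",
                                full.names = TRUE))
    outDir <- file.path(config$paths$output, "projected")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    for (mf in mapFiles) {
        sp <- sub("^ortholog_(.*)\\.tsv$", "\\1", basename(mf))
        proj <- projectNetwork(network, loadOrthologMap(mf, sp))
        p <- file.path(outDir, paste0(sp, "_network.tsv"))
        writeNetwork(proj, p)
        written <- c(written, p)
    }
    .writeRunLog(config$paths$output, "project", config,
                 c(netPath, mapFiles))
    invisible(written)
}

#' @rdname pipeline
#' @export
runEvaluate <- function(config) {
    config <- validatePipelineConfig(config)
    outDir <- config$paths$output
    cvPath <- file.path(outDir, "cv_predictions.tsv")
    if (!file.exists(cvPath))
        stop("missing cv_predictions.tsv (run train-predict first)")
    preds <- utils::read.table(cvPath, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    heldoutAuprc <- auprc(preds$score, preds$label)
    gold <- readGoldStandard(file.path(config$paths$world,
                                       "gold_standard.tsv"))
    cxPath <- file.path(outDir, "complexes.tsv")
    if (!file.exists(cxPath))
        stop("missing complexes.tsv (run cluster first)")
    cmp <- compareComplexes(readComplexSet(cxPath), gold)
    res <- list(heldout_auprc = heldoutAuprc,
                complex_precision = cmp$precision,
                complex_recall = cmp$recall, complex_f1 = cmp$f1)
    writeLines(sprintf("%s\t%.17g", names(res), unlist(res)),
               file.path(outDir, "evaluation.tsv"))
    .writeRunLog(outDir, "evaluate", config,
                 c(cvPath, cxPath))
    invisible(res)
}

#' @rdname pipeline
#' @export
runPipeline <- function(config) {
    config <- validatePipelineConfig(config)
    runSimulate(config)
    runScore(config)
    runMap(config)
    runTrainPredict(config)
    runCluster(config)
    runProject(config)
    invisible(runEvaluate(config))
}
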