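## End-to-end orchestration: filter -> tokenise -> train the three encoders
## -> embed -> DE-weighted fusion -> Shapley ranking -> top-k grid CV with
## the CNN -> final model (+ optional independent test). Encoders, fusion
## weights and the feature ranking are fitted on training data only; the
## test set is embedded with the training-fitted encoders and never touches
## weight learning or ranking.

#' Pipeline configuration
#'
#' Collects every stage's parameters. A single `seed` deterministically
#' derives all stage seeds.
#'
#' @param k,stride Tokeniser parameters.
#' @param embedDim Per-encoder embedding dimension.
#' @param window Context window for CBOW/fastText and co-occurrence.
#' @param embedEpochs Encoder training epochs.
#' @param embedLr Encoder learning rate.
#' @param de A [deConfig()] for fusion-weight learning.
#' @param ridgeLambda Ridge penalty of the DE fitness classifier.
#' @param kGrid Top-k subset sizes to evaluate (NULL = [selectionGrid()]
#'   over the fused width).
#' @param cnn A [cnnConfig()] for the final classifier.
#' @param folds CV folds.
#' @param minLen,dropUnknown Sequence filters, see [filterSequences()].
#' @param strictCV Recompute the feature ranking inside each CV training
#'   fold (leakage-free selection) instead of once up front.
#' @param seed Global seed.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(k = 3L, stride = 1L, embedDim = 200L,
                           window = 5L, embedEpochs = 5L, embedLr = 0.05,
                           de = deConfig(Gmax = 50L), ridgeLambda = 1e-2,
                           kGrid = NULL, cnn = cnnConfig(), folds = 5L,
                           minLen = 50L, dropUnknown = TRUE,
                           strictCV = FALSE, seed = 1L) {
    structure(list(k = k, stride = stride, embedDim = embedDim,
                   window = window, embedEpochs = embedEpochs,
                   embedLr = embedLr, de = de, ridgeLambda = ridgeLambda,
                   kGrid = kGrid, cnn = cnn, folds = folds, minLen = minLen,
                   dropUnknown = dropUnknown, strictCV = strictCV,
                   seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Scaled-down pipeline configuration
#'
#' A [pipelineConfig()] sized for corpora of a few hundred sequences, as
#' used by the bundled synthetic benchmark: fewer DE generations, a coarse
#' top-k grid, more encoder epochs (small corpora need more passes for the
#' embeddings to stabilise), and a CNN trained at learning rate 1e-3 (the
#' reference rate 1e-5 needs hundreds of epochs to converge, which is
#' disproportionate at this corpus size). All values stay inside the ranges
#' accepted by the full-size configuration.
#'
#' @param seed Global pipeline seed.
#' @return A `PipelineConfig`.
#' @export
demoPipelineConfig <- function(seed = 1L) {
    pipelineConfig(de = deConfig(N = 20L, Gmax = 40L),
                   kGrid = c(200L, 300L, 400L), embedEpochs = 8L,
                   cnn = cnnConfig(learningRate = 1e-3, epochs = 30L,
                                   batchSize = 32L, valFraction = 0),
                   seed = seed)
}

trainEncoders <- function(corpus, cfg) {
    X <- buildCooccurrence(corpus, cfg$window)
    list(
        glove = trainGlove(X, dim = cfg$embedDim, epochs = cfg$embedEpochs,
                           seed = deriveSeed(cfg$seed, "glove")),
        fasttext = trainFastText(corpus, dim = cfg$embedDim,
                                 window = cfg$window,
                                 epochs = cfg$embedEpochs, lr = cfg$embedLr,
                                 seed = deriveSeed(cfg$seed, "fasttext")),
        cbow = trainCBOW(corpus, dim = cfg$embedDim, window = cfg$window,
                         epochs = cfg$embedEpochs, lr = cfg$embedLr,
                         seed = deriveSeed(cfg$seed, "cbow")))
}

embedBlocks <- function(ds, corpus, encoders) {
    lapply(encoders, function(m) embedDataset(ds, corpus, m))
}

logStage <- function(verbose, stage, t0, ...) {
    if (!verbose) return(invisible())
    message(sprintf("[%s] %s (%.1fs)", format(Sys.time(), "%H:%M:%S"),
                    paste0(stage, " ", paste(..., sep = " ")),
                    as.numeric(Sys.time()) - t0))
}

#' Run the full prediction pipeline
#'
#' @param train A [LabeledProteinSet-class] of training sequences.
#' @param test Optional held-out [LabeledProteinSet-class]; ids must be
#'   disjoint from the training ids.
#' @param config A [pipelineConfig()].
#' @param classifier Classifier factory for the final model and the top-k
#'   grid (default [cnnClassifier()] on `config$cnn`); anything honouring
#'   the factory contract can be plugged in.
#' @param outputDir Optional directory: each stage writes its artifact
#'   (filtered FASTA, embeddings, fused matrix, weights, ranking, report).
#' @param verbose Log one line per stage.
#' @return List of class `PipelineResult`: `report` (CV
#'   [MetricReport-class] at the selected k), `testReport` (independent
#'   test, or NULL), `bestK`, `weights`, `ranking`, `blocks`, `fused`,
#'   `encoders`, `gridTable`, `finalModel`, `dropped`.
#' @export
runPipeline <- function(train, test = NULL, config = pipelineConfig(),
                        classifier = NULL, outputDir = NULL,
                        verbose = FALSE) {
    stopifnot(is(train, "LabeledProteinSet"))
    cfg <- config
    if (is.null(classifier)) classifier <- cnnClassifier(cfg$cnn)
    t0 <- as.numeric(Sys.time())
    out <- function(...) if (!is.null(outputDir)) file.path(outputDir, ...)
    if (!is.null(outputDir))
        for (d in c("01_prepared", "02_embeddings", "03_fused", "04_ranking",
                    "05_model", "06_report"))
            dir.create(file.path(outputDir, d), recursive = TRUE,
                       showWarnings = FALSE)

    ## 1. filter + tokenise (training data)
    train <- filterSequences(train, cfg$minLen, cfg$dropUnknown)
    dropped <- attr(train, "dropped")
    if (length(train) == 0) stopf("prepare stage: no sequences survive the filters")
    corpus <- buildCorpus(train, cfg$k, cfg$stride)
    logStage(verbose, "prepare:", t0, length(train), "sequences, |V| =",
             length(corpus@vocabulary))
    if (!is.null(outputDir))
        writeFasta(train, c(out("01_prepared", "train_pos.fasta"),
                            out("01_prepared", "train_neg.fasta")))

    ## 2. encoders + feature blocks
    encoders <- trainEncoders(corpus, cfg)
    blocks <- embedBlocks(train, corpus, encoders)
    logStage(verbose, "embed:", t0, "3 blocks of dim", cfg$embedDim)
    if (!is.null(outputDir))
        for (nm in names(encoders))
            writeEmbedding(encoders[[nm]],
                           out("02_embeddings", paste0(nm, ".vec")))

    ## 3. DE fusion-weight learning
    y <- as.integer(labels(train))
    deCfg <- cfg$de
    deCfg$seed <- deriveSeed(cfg$seed, "de")
    fw <- learnFusionWeights(blocks, y, config = deCfg,
                             cvSeed = deriveSeed(cfg$seed, "decv"),
                             lambda = cfg$ridgeLambda)
    fused <- fw$fused
    logStage(verbose, "fuse:", t0, "weights =",
             paste(sprintf("%.3f", fused@weights), collapse = ", "))
    if (!is.null(outputDir)) {
        writeDEResult(fw$de, out("03_fused", "weights.json"))
        writeFeatureTSV(featureMatrix(fused), out("03_fused", "fused.tsv"))
    }

    ## 4. Shapley ranking + top-k grid with the classifier under CV
    rankSeed <- deriveSeed(cfg$seed, "shap")
    cvSeed <- deriveSeed(cfg$seed, "cv")
    kGrid <- cfg$kGrid %||% selectionGrid(ncol(featureMatrix(fused)))
    kGrid <- kGrid[kGrid <= ncol(featureMatrix(fused))]
    if (!length(kGrid)) kGrid <- ncol(featureMatrix(fused))
    if (cfg$strictCV) {
        reports <- lapply(kGrid, function(kk)
            crossValidate(featureMatrix(fused), y,
                          strictTopKFactory(classifier, kk, rankSeed),
                          k = cfg$folds, seed = cvSeed))
        ranking <- rankFeatures(fused, y, seed = rankSeed)
    } else {
        ranking <- rankFeatures(fused, y, seed = rankSeed)
        reports <- lapply(kGrid, function(kk) {
            idx <- selectTopK(ranking, kk)
            crossValidate(featureMatrix(fused)[, idx, drop = FALSE], y,
                          classifier, k = cfg$folds, seed = cvSeed)
        })
    }
    aucs <- vapply(reports, function(r) metrics(r)["AUC"], numeric(1))
    bestI <- which.max(aucs)
    bestK <- kGrid[bestI]
    gridTable <- data.frame(k = kGrid,
                            t(vapply(reports, metrics, numeric(7))))
    logStage(verbose, "select:", t0, "best k =", bestK, "CV AUC =",
             sprintf("%.3f", aucs[bestI]))
    if (!is.null(outputDir))
        writeRanking(ranking, out("04_ranking", "ranking.tsv"))

    ## 5. final model on all training data at the selected k
    idx <- selectTopK(ranking, bestK)
    Xsel <- featureMatrix(fused)[, idx, drop = FALSE]
    finalModel <- withSeed(deriveSeed(cfg$seed, "final"),
                           classifier(Xsel, y))

    ## 6. optional independent test, embedded with training-fitted encoders
    testReport <- NULL
    if (!is.null(test)) {
        test <- filterSequences(test, cfg$minLen, cfg$dropUnknown)
        shared <- intersect(names(sequences(test)), names(sequences(train)))
        if (length(shared))
            stopf("train/test id overlap: %s", paste(shared, collapse = ", "))
        testCorpus <- buildCorpus(test, cfg$k, cfg$stride)
        testBlocks <- embedBlocks(test, testCorpus, encoders)
        testFused <- fuseFeatures(testBlocks, fused@weights)
        Xte <- featureMatrix(testFused)[, idx, drop = FALSE]
        p <- finalModel(Xte)
        yte <- as.integer(labels(test))
        cc <- confusionCounts(yte, as.integer(p >= 0.5))
        testReport <- new("MetricReport",
                          metrics = c(suppressWarnings(classMetrics(cc)),
                                      AUC = rocAUC(yte, p)),
                          perFold = data.frame(), sds = numeric(0),
                          scores = p, folds = integer(0))
        logStage(verbose, "test:", t0, "AUC =",
                 sprintf("%.3f", metrics(testReport)["AUC"]))
    }
    report <- reports[[bestI]]
    if (!is.null(outputDir)) {
        writeMetricReport(report, out("06_report", "cv_report.json"))
        if (!is.null(testReport))
            writeMetricReport(testReport, out("06_report", "test_report.json"))
    }
    structure(list(report = report, testReport = testReport, bestK = bestK,
                   weights = fused@weights, ranking = ranking,
                   blocks = blocks, fused = fused, encoders = encoders,
                   gridTable = gridTable, gridReports = reports,
                   finalModel = finalModel, dropped = dropped,
                   config = cfg),
              class = "PipelineResult")
}

## Leakage-free variant: rank features on the training fold only, then train
## the classifier on that fold's top-k columns.
strictTopKFactory <- function(classifier, kk, rankSeed) {
    function(X, y) {
        ranking <- rankFeatures(X, y, seed = rankSeed)
        idx <- selectTopK(ranking, min(kk, ncol(X)))
        inner <- classifier(X[, idx, drop = FALSE], y)
        function(Xnew) inner(Xnew[, idx, drop = FALSE])
    }
}

#' Write / read a numeric matrix as TSV with a feature-name header
#'
#' @param m Matrix with colnames (feature names) and rownames (ids).
#' @param path TSV path.
#' @return `path` (write); matrix (read).
#' @export
writeFeatureTSV <- function(m, path) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTSV
#' @export
readFeatureTSV <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}
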