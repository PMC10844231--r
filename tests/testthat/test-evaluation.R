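test_that("confusionCounts counts the four cells", {
    cc <- confusionCounts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
    expect_identical(cc, c(TP = 2L, FP = 1L, TN = 1L, FN = 1L))
    expect_error(confusionCounts(c(1, 0), c(1)), "length mismatch")
    expect_error(confusionCounts(c(1, 2), c(1, 0)), "binary")
})

test_that("classMetrics matches the defining formulas", {
    m <- classMetrics(c(TP = 3, FP = 1, TN = 4, FN = 2))
    expect_equal(m[["ACC"]], 7 / 10)
    expect_equal(m[["Sen"]], 3 / 5)
    expect_equal(m[["Spe"]], 4 / 5)
    expect_equal(m[["Pre"]], 3 / 4)
    expect_equal(m[["F1"]], 2 * (3 / 4) * (3 / 5) / ((3 / 4) + (3 / 5)))
    expect_equal(m[["MCC"]],
                 (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6))
})

test_that("zero denominators yield NaN with a warning, not silent zeros", {
    ## one warning per undefined metric
    w <- capture_warnings(m <- classMetrics(c(TP = 0, FP = 0, TN = 5,
                                              FN = 0)))
    expect_match(w, "Pre undefined", all = FALSE)
    expect_true(is.nan(m[["Pre"]]))
    w2 <- capture_warnings(m2 <- classMetrics(c(TP = 0, FP = 0, TN = 0,
                                                FN = 0)))
    expect_match(w2, "zero denominator", all = FALSE)
    expect_true(is.nan(m2[["ACC"]]))
})

test_that("rocPoints spans (0,0) to (1,1) monotonically", {
    y <- c(1, 1, 0, 0, 1, 0)
    s <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
    pts <- rocPoints(y, s)
    expect_equal(pts$FPR[1], 0); expect_equal(pts$TPR[1], 0)
    expect_equal(tail(pts$FPR, 1), 1); expect_equal(tail(pts$TPR, 1), 1)
    expect_true(all(diff(pts$FPR) >= 0))
    expect_true(all(diff(pts$TPR) >= 0))
})

test_that("rocAUC handles perfect, inverted and tied scores", {
    y <- c(1, 1, 0, 0)
    expect_equal(rocAUC(y, c(0.9, 0.8, 0.2, 0.1)), 1)
    expect_equal(rocAUC(y, c(0.1, 0.2, 0.8, 0.9)), 0)
    expect_equal(rocAUC(y, rep(0.5, 4)), 0.5)
    expect_error(rocAUC(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("stratifiedFolds balances classes and is seeded", {
    y <- rep(c(1L, 0L), c(23, 17))
    f1 <- stratifiedFolds(y, 5, seed = 3)
    f2 <- stratifiedFolds(y, 5, seed = 3)
    expect_identical(f1, f2)
    for (cls in 0:1) {
        sizes <- table(f1[y == cls])
        expect_lte(max(sizes) - min(sizes), 1)
    }
})

test_that("crossValidate reports per-fold and pooled metrics", {
    d <- separableData(n = 40, p = 8, shift = 2.5, seed = 41)
    rep5 <- crossValidate(d$X, d$y, ridgeClassifier(), k = 5, seed = 2)
    expect_s4_class(rep5, "MetricReport")
    expect_identical(nrow(rep5@perFold), 5L)
    expect_length(rep5@scores, 40)
    expect_identical(sort(unique(rep5@folds)), 1:5)
    expect_gt(metrics(rep5)[["AUC"]], 0.9)
    ## the headline AUC is the pooled out-of-fold AUC
    expect_equal(metrics(rep5)[["AUC"]], rocAUC(d$y, rep5@scores))
    expect_error(crossValidate(d$X, d$y, ridgeClassifier(), k = 25),
                 "at least 25")
})

test_that("independentTest evaluates once and rejects id overlap", {
    d <- separableData(n = 60, p = 8, shift = 2.5, seed = 42)
    tr <- c(1:20, 31:50); te <- c(21:30, 51:60)
    rep1 <- independentTest(d$X[tr, ], d$y[tr], d$X[te, ], d$y[te],
                            ridgeClassifier(), seed = 1)
    expect_identical(nrow(rep1@perFold), 0L)
    expect_gt(metrics(rep1)[["AUC"]], 0.9)
    expect_error(independentTest(d$X[tr, ], d$y[tr], d$X[c(1:5, 31:35), ],
                                 d$y[c(1:5, 31:35)], ridgeClassifier()),
                 "overlap")
})

test_that("writeMetricReport serialises metrics to JSON", {
    d <- separableData(n = 20, p = 6, shift = 2, seed = 43)
    rep2 <- crossValidate(d$X, d$y, ridgeClassifier(), k = 2, seed = 2)
    f <- tempfile(fileext = ".json")
    writeMetricReport(rep2, f)
    parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
    expect_equal(parsed$metrics$AUC, metrics(rep2)[["AUC"]],
                 tolerance = 1e-12)
    expect_identical(nrow(parsed$perFold), 2L)
})
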