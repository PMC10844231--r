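## Confusion-matrix metrics, ROC/AUC, stratified cross-validation and the
## independent-test protocol.

#' Confusion counts
#'
#' @param yTrue,yPred Equal-length binary (0/1) vectors.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusionCounts <- function(yTrue, yPred) {
    if (length(yTrue) != length(yPred))
        stopf("length mismatch: %d vs %d", length(yTrue), length(yPred))
    if (!all(yTrue %in% c(0, 1)) || !all(yPred %in% c(0, 1)))
        stopf("labels and predictions must be binary 0/1")
    c(TP = sum(yTrue == 1 & yPred == 1),
      FP = sum(yTrue == 0 & yPred == 1),
      TN = sum(yTrue == 0 & yPred == 0),
      FN = sum(yTrue == 1 & yPred == 0))
}

#' Confusion-matrix metrics
#'
#' ACC = (TP+TN)/total; Sen = TP/(TP+FN); Spe = TN/(FP+TN);
#' Pre = TP/(TP+FP); F1 = 2*Pre*Sen/(Pre+Sen);
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Metrics with a zero denominator are reported as `NaN` with a warning
#' rather than silently coerced to 0.
#'
#' @param counts Output of [confusionCounts()] (or any named TP/FP/TN/FN
#'   vector).
#' @return Named numeric: ACC, Sen, Spe, MCC, Pre, F1.
#' @examples
#' classMetrics(c(TP = 50, FP = 10, TN = 40, FN = 0))
#' @export
classMetrics <- function(counts) {
    TP <- as.numeric(counts["TP"]); FP <- as.numeric(counts["FP"])
    TN <- as.numeric(counts["TN"]); FN <- as.numeric(counts["FN"])
    safeDiv <- function(num, den, what) {
        if (den == 0) { warning(what, " undefined: zero denominator",
                                call. = FALSE); return(NaN) }
        num / den
    }
    ACC <- safeDiv(TP + TN, TP + TN + FP + FN, "ACC")
    Sen <- safeDiv(TP, TP + FN, "Sen")
    Spe <- safeDiv(TN, FP + TN, "Spe")
    Pre <- safeDiv(TP, TP + FP, "Pre")
    F1  <- if (is.nan(Pre) || is.nan(Sen) || (Pre + Sen) == 0) {
        warning("F1 undefined", call. = FALSE); NaN
    } else 2 * Pre * Sen / (Pre + Sen)
    mccDen <- sqrt((TP + FP) * (TP + FN)) * sqrt((TN + FP) * (TN + FN))
    MCC <- if (mccDen == 0) { warning("MCC undefined: zero denominator",
                                      call. = FALSE); NaN }
           else (TP * TN - FP * FN) / mccDen
    c(ACC = ACC, Sen = Sen, Spe = Spe, MCC = MCC, Pre = Pre, F1 = F1)
}

#' ROC curve points
#'
#' @param yTrue Binary labels.
#' @param scores Real-valued scores (higher = more positive).
#' @return data.frame of (threshold, FPR, TPR), one row per distinct score
#'   plus the all-negative end point.
#' @export
rocPoints <- function(yTrue, scores) {
    ord <- order(scores, decreasing = TRUE)
    y <- yTrue[ord]; s <- scores[ord]
    nPos <- sum(yTrue == 1); nNeg <- sum(yTrue == 0)
    grp <- !duplicated(s)
    tp <- cumsum(y == 1); fp <- cumsum(y == 0)
    last <- c(which(grp)[-1] - 1L, length(s))
    data.frame(threshold = c(Inf, s[grp]),
               FPR = c(0, fp[last] / nNeg),
               TPR = c(0, tp[last] / nPos))
}

#' Area under the ROC curve
#'
#' Trapezoidal area over all score thresholds; tied positive-negative pairs
#' contribute 1/2, so the value equals the rank-sum (Mann-Whitney)
#' statistic scaled by `1/(n_pos * n_neg)`.
#'
#' @inheritParams rocPoints
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(yTrue, scores) {
    nPos <- sum(yTrue == 1); nNeg <- sum(yTrue == 0)
    if (nPos == 0 || nNeg == 0)
        stopf("AUC needs both classes present")
    pts <- rocPoints(yTrue, scores)
    sum(diff(pts$FPR) * (head(pts$TPR, -1) + pts$TPR[-1]) / 2)
}

buildReport <- function(metricMat, aucPooled, scores, folds) {
    means <- colMeans(metricMat)
    means["AUC"] <- aucPooled        # headline AUC: pooled out-of-fold scores
    new("MetricReport", metrics = means,
        perFold = as.data.frame(metricMat),
        sds = apply(metricMat, 2, sd),
        scores = scores, folds = as.integer(folds))
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified (per-class shuffle under `seed`, dealt round-robin),
#' so per-class fold sizes differ by at most one. The classifier factory is
#' called on each training split and its predictor evaluated on the held-out
#' fold. The headline AUC is computed on the pooled out-of-fold scores;
#' per-fold AUCs are kept in the fold table.
#'
#' @param X Feature matrix (or [FusedFeatures-class]).
#' @param y Binary labels.
#' @param factory `function(X, y)` returning a predictor
#'   `function(Xnew) -> probabilities`.
#' @param k Number of folds (default 5); every class must have >= k members.
#' @param seed Fold-assignment seed; also seeds each fold's training
#'   (derived deterministically).
#' @param threshold Probability cut-off for the hard label (default 0.5).
#' @return A [MetricReport-class].
#' @export
crossValidate <- function(X, y, factory, k = 5L, seed = 1L,
                          threshold = 0.5) {
    if (is(X, "FusedFeatures")) X <- featureMatrix(X)
    y <- as.integer(y)
    if (min(table(y)) < k)
        stopf("each class needs at least %d members for %d-fold CV", k, k)
    folds <- stratifiedFolds(y, k, seed)
    scores <- numeric(length(y))
    metricMat <- matrix(NA_real_, k, 7,
                        dimnames = list(NULL, c("ACC", "Sen", "Spe", "MCC",
                                                "Pre", "F1", "AUC")))
    for (fold in seq_len(k)) {
        tr <- folds != fold
        predictor <- withSeed(deriveSeed(seed, paste0("fold", fold)),
                              factory(X[tr, , drop = FALSE], y[tr]))
        p <- predictor(X[!tr, , drop = FALSE])
        scores[!tr] <- p
        cc <- confusionCounts(y[!tr], as.integer(p >= threshold))
        metricMat[fold, ] <- c(suppressWarnings(classMetrics(cc)),
                               AUC = rocAUC(y[!tr], p))
    }
    buildReport(metricMat, rocAUC(y, scores), scores, folds)
}

#' Independent-test evaluation
#'
#' Fits once on the full training set and evaluates once on the test set.
#' Train and test id sets must be disjoint.
#'
#' @param Xtrain,ytrain Training features and labels.
#' @param Xtest,ytest Test features and labels.
#' @param factory Classifier factory as in [crossValidate()].
#' @param seed Training seed.
#' @param threshold Probability cut-off.
#' @return A [MetricReport-class] (no fold breakdown).
#' @export
independentTest <- function(Xtrain, ytrain, Xtest, ytest, factory,
                            seed = 1L, threshold = 0.5) {
    if (is(Xtrain, "FusedFeatures")) Xtrain <- featureMatrix(Xtrain)
    if (is(Xtest, "FusedFeatures")) Xtest <- featureMatrix(Xtest)
    shared <- intersect(rownames(Xtrain), rownames(Xtest))
    if (length(shared))
        stopf("train/test id overlap: %s", paste(shared, collapse = ", "))
    predictor <- withSeed(deriveSeed(seed, "indtest"),
                          factory(Xtrain, as.integer(ytrain)))
    p <- predictor(Xtest)
    cc <- confusionCounts(as.integer(ytest), as.integer(p >= threshold))
    metrics <- c(suppressWarnings(classMetrics(cc)),
                 AUC = rocAUC(as.integer(ytest), p))
    new("MetricReport", metrics = metrics, perFold = data.frame(),
        sds = numeric(0), scores = p, folds = integer(0))
}

#' Ridge classifier factory
#'
#' Regularised least-squares classifier (closed form); probabilities are the
#' logistic transform of the decision score. A fast, deterministic baseline
#' for the pluggable-classifier contract.
#'
#' @param lambda Ridge penalty relative to the mean feature-Gram diagonal.
#' @return A classifier factory for [crossValidate()].
#' @export
ridgeClassifier <- function(lambda = 1e-2) {
    function(X, y) {
        Xtr <- X
        Ktr <- tcrossprod(Xtr)
        yc <- as.numeric(y) - mean(y)
        reg <- lambda * mean(diag(Ktr))
        if (reg <= 0) reg <- lambda
        alpha <- solve(Ktr + diag(reg, nrow(Ktr)), yc)
        b <- mean(y)
        function(Xnew) {
            s <- as.numeric(Xnew %*% crossprod(Xtr, alpha)) + b
            1 / (1 + exp(-4 * (s - 0.5)))
        }
    }
}

#' Serialise a MetricReport to JSON
#'
#' @param report A [MetricReport-class].
#' @param path Output path.
#' @export
writeMetricReport <- function(report, path) {
    jsonlite::write_json(list(metrics = as.list(metrics(report)),
                              sds = as.list(report@sds),
                              perFold = report@perFold),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}
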