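## Shapley-value feature attribution: exact subset enumeration for small M,
## a permutation-sampling estimator, global importance aggregation, and a
## gradient-boosted-tree surrogate for wide feature matrices.

## f_x(S): mean model output over the background with the features in S
## replaced by x's values. `model` must accept a matrix and return a vector.
coalitionValue <- function(model, background, x, S) {
    Z <- background
    if (length(S)) Z[, S] <- matrix(x[S], nrow(Z), length(S), byrow = TRUE)
    mean(model(Z))
}

#' Exact Shapley values by subset enumeration
#'
#' For each feature i,
#' `phi_i = sum_{S subset of M\\{i}} |S|!(M-|S|-1)!/M! (f_x(S u {i}) - f_x(S))`
#' with `f_x(S)` the interventional expectation over the background set.
#' Enumerates all 2^M coalitions, so M is capped at 15.
#'
#' @param model Prediction function: matrix in, numeric vector out.
#' @param background Background instance matrix (reference distribution).
#' @param x Instance to explain (numeric vector of length M).
#' @return Numeric attribution vector of length M with attribute `phi0`
#'   (mean background output); `phi0 + sum(phi)` equals `f(x)`.
#' @export
exactShapley <- function(model, background, x) {
    M <- length(x)
    if (M > 15)
        stopf("M = %d features: exact enumeration capped at 15; use sampledShapley()", M)
    background <- as.matrix(background)
    nS <- bitwShiftL(1L, M)
    v <- numeric(nS)
    for (mask in 0:(nS - 1L)) {
        S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(M - 1L))) != 0L)
        v[mask + 1L] <- coalitionValue(model, background, x, S)
    }
    lf <- lfactorial(0:M)
    phi <- numeric(M)
    for (i in seq_len(M)) {
        bit <- bitwShiftL(1L, i - 1L)
        for (mask in 0:(nS - 1L)) {
            if (bitwAnd(mask, bit) != 0L) next
            s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(M - 1L))) != 0L)
            wgt <- exp(lf[s + 1L] + lf[M - s] - lf[M + 1L])
            phi[i] <- phi[i] +
                wgt * (v[bitwOr(mask, bit) + 1L] - v[mask + 1L])
        }
    }
    names(phi) <- colnames(background)
    attr(phi, "phi0") <- v[1L]
    phi
}

#' Monte-Carlo Shapley values by permutation sampling
#'
#' Averages marginal contributions along uniformly sampled feature
#' orderings; each permutation's contributions telescope, so efficiency
#' (`phi0 + sum(phi) = f(x)`) holds by construction. Unbiased for the exact
#' values; deterministic given `seed`.
#'
#' @inheritParams exactShapley
#' @param nPermutations Number of sampled orderings (>= 1).
#' @param seed RNG seed.
#' @return Numeric attribution vector with attribute `phi0`.
#' @export
sampledShapley <- function(model, background, x, nPermutations = 2000L,
                           seed = 1L) {
    stopifnot(nPermutations >= 1)
    M <- length(x)
    background <- as.matrix(background)
    phi <- numeric(M)
    withSeed(seed, {
        for (p in seq_len(nPermutations)) {
            ord <- sample.int(M)
            prev <- coalitionValue(model, background, x, integer(0))
            S <- integer(0)
            for (i in ord) {
                S <- c(S, i)
                cur <- coalitionValue(model, background, x, S)
                phi[i] <- phi[i] + (cur - prev)
                prev <- cur
            }
        }
    })
    phi <- phi / nPermutations
    names(phi) <- colnames(background)
    attr(phi, "phi0") <- coalitionValue(model, background, x, integer(0))
    phi
}

#' Explain a set of instances
#'
#' @inheritParams exactShapley
#' @param X Matrix of instances to explain (one per row).
#' @param method `"exact"` or `"sampled"`.
#' @param ... Passed to [sampledShapley()].
#' @return A [ShapExplanation-class].
#' @export
shapExplain <- function(model, background, X, method = c("exact", "sampled"),
                        ...) {
    method <- match.arg(method)
    X <- as.matrix(X)
    fn <- if (method == "exact") function(x) exactShapley(model, background, x)
          else function(x) sampledShapley(model, background, x, ...)
    phi <- t(apply(X, 1, fn))
    new("ShapExplanation",
        phi0 = mean(model(as.matrix(background))),
        phi = phi, fx = as.numeric(model(X)))
}

#' Global feature importance from attributions
#'
#' `I_j = sum_i |phi_j^(i)|` over instances, ranked in decreasing importance
#' with ties broken by ascending feature index.
#'
#' @param phi n_instances x M attribution matrix (or a
#'   [ShapExplanation-class]).
#' @return A [FeatureRanking-class].
#' @export
globalImportance <- function(phi) {
    if (is(phi, "ShapExplanation")) phi <- phi@phi
    if (is.null(dim(phi))) phi <- matrix(phi, 1)
    if (nrow(phi) == 0 || ncol(phi) == 0) stopf("empty attribution matrix")
    if (any(!is.finite(phi))) stopf("non-finite attributions")
    I <- colSums(abs(phi))
    if (is.null(names(I))) names(I) <- paste0("f", seq_along(I))
    ord <- order(-I, seq_along(I))
    new("FeatureRanking", importance = I, rankOrder = as.integer(ord))
}

#' Rank fused features by Shapley importance of a tree surrogate
#'
#' Trains a gradient-boosted tree classifier (xgboost) on the fused matrix
#' and attributes every training instance with TreeSHAP path attributions
#' (`predcontrib`), then aggregates with [globalImportance()]. With
#' `method = "sampled"`, permutation-sampling attributions of the surrogate
#' are used instead.
#'
#' @param fused A [FusedFeatures-class] or numeric matrix.
#' @param labels Binary labels (both classes present).
#' @param seed Seed for the surrogate fit (and sampling, if used).
#' @param nrounds,maxDepth,eta Surrogate booster parameters.
#' @param method `"tree"` (TreeSHAP, default) or `"sampled"`.
#' @param backgroundSize Background sample size for `"sampled"`.
#' @param nPermutations Permutations per instance for `"sampled"`.
#' @return A [FeatureRanking-class] over the fused columns.
#' @export
rankFeatures <- function(fused, labels, seed = 1L, nrounds = 100L,
                         maxDepth = 4L, eta = 0.3,
                         method = c("tree", "sampled"),
                         backgroundSize = 100L, nPermutations = 200L) {
    method <- match.arg(method)
    X <- if (is(fused, "FusedFeatures")) featureMatrix(fused) else as.matrix(fused)
    y <- as.integer(labels)
    if (length(unique(y)) < 2) stopf("labels are single-class")
    bst <- withSeed(seed, {
        dtrain <- xgboost::xgb.DMatrix(X, label = y)
        xgboost::xgb.train(
            params = list(objective = "binary:logistic", max_depth = maxDepth,
                          eta = eta, nthread = 1, seed = seed),
            data = dtrain, nrounds = nrounds, verbose = 0)
    })
    if (method == "tree") {
        contrib <- predict(bst, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
        phi <- contrib[, seq_len(ncol(X)), drop = FALSE]
        colnames(phi) <- colnames(X)
    } else {
        bg <- X[withSeed(deriveSeed(seed, "background"),
                         sample.int(nrow(X), min(backgroundSize, nrow(X)))),
                , drop = FALSE]
        mfun <- function(Z) {
            colnames(Z) <- colnames(X)
            predict(bst, xgboost::xgb.DMatrix(Z))
        }
        phi <- t(vapply(seq_len(nrow(X)), function(i)
            as.numeric(sampledShapley(mfun, bg, X[i, ], nPermutations,
                                      seed = deriveSeed(seed, paste0("inst", i)))),
            numeric(ncol(X))))
        colnames(phi) <- colnames(X)
    }
    globalImportance(phi)
}

#' Select the top-k ranked features
#'
#' @param ranking A [FeatureRanking-class].
#' @param k Subset size (k <= number of features).
#' @return Integer column indices, in rank order.
#' @export
selectTopK <- function(ranking, k) {
    M <- length(ranking@importance)
    if (k > M) stopf("k = %d exceeds feature count %d", k, M)
    ranking@rankOrder[seq_len(k)]
}

#' The top-k evaluation grid
#'
#' Subset sizes from 200 to 450 in steps of 50, truncated to the available
#' feature count (sizes larger than M are dropped; if all are, M itself is
#' used).
#'
#' @param M Number of available features.
#' @param from,to,by Grid specification (defaults 200, 450, 50).
#' @return Integer vector of subset sizes.
#' @export
selectionGrid <- function(M, from = 200L, to = 450L, by = 50L) {
    g <- seq.int(from, to, by)
    g <- g[g <= M]
    if (!length(g)) g <- M
    as.integer(g)
}

#' Write a feature ranking as TSV
#'
#' Columns: feature, importance, rank.
#'
#' @param ranking A [FeatureRanking-class].
#' @param path Output path.
#' @export
writeRanking <- function(ranking, path) {
    ord <- ranking@rankOrder
    df <- data.frame(feature = names(ranking@importance)[ord],
                     importance = ranking@importance[ord],
                     rank = seq_along(ord))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
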