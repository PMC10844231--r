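## Differential evolution (DE/rand/1/bin) over per-encoder fusion weights,
## and the weighted sequential fusion of the three feature blocks.

BLOCK_ORDER <- c("glove", "fasttext", "cbow")

#' DE configuration
#'
#' @param N Population size (>= 4; mutation needs three distinct partners).
#' @param Gmax Maximum number of generations (default 1000).
#' @param CR Crossover rate in (0, 1) (default 0.5).
#' @param F Mutation scale factor (default 0.5).
#' @param lower,upper Component-wise bounds (default [0, 1]).
#' @param seed RNG seed; the whole trajectory is deterministic given it.
#' @return A list of class `DEConfig`.
#' @export
deConfig <- function(N = 20L, Gmax = 1000L, CR = 0.5, F = 0.5,
                     lower = 0, upper = 1, seed = 1L) {
    if (N < 4) stopf("population size must be >= 4")
    if (Gmax < 1) stopf("Gmax must be >= 1")
    if (CR <= 0 || CR >= 1) stopf("CR must lie in (0, 1)")
    structure(list(N = as.integer(N), Gmax = as.integer(Gmax), CR = CR,
                   F = F, lower = lower, upper = upper,
                   seed = as.integer(seed)),
              class = "DEConfig")
}

#' DE mutation: rand/1 difference vector
#'
#' `MV = FW_r1 + F * (FW_r2 - FW_r3)` with r1, r2, r3 drawn uniformly,
#' mutually distinct and distinct from the target index, then clipped to the
#' bounds.
#'
#' @param pop N x D population matrix (one member per row).
#' @param i Target member index (excluded from the partner draw).
#' @param F Scale factor.
#' @param lower,upper Bounds for clipping.
#' @return Mutant vector of length D.
#' @export
deMutate <- function(pop, i, F, lower = 0, upper = 1) {
    if (nrow(pop) < 4) stopf("mutation needs a population of at least 4")
    r <- sample(setdiff(seq_len(nrow(pop)), i), 3L)
    mv <- pop[r[1], ] + F * (pop[r[2], ] - pop[r[3], ])
    pmin(pmax(mv, lower), upper)
}

#' DE binomial crossover
#'
#' Component j of the trial takes the mutant value when `R_j <= CR` or when
#' j equals a uniformly chosen forced index `j_r`, else the target value; so
#' at least one mutant component is always present.
#'
#' @param target,mutant Equal-length weight vectors.
#' @param CR Crossover rate.
#' @return Trial vector.
#' @export
deCrossover <- function(target, mutant, CR) {
    stopifnot(length(target) == length(mutant))
    D <- length(target)
    jr <- sample.int(D, 1L)
    useMutant <- runif(D) <= CR
    useMutant[jr] <- TRUE
    ifelse(useMutant, mutant, target)
}

#' DE greedy selection
#'
#' Returns the trial iff `f(trial) <= f(target)` (ties go to the trial),
#' else the target.
#'
#' @param target,trial Weight vectors.
#' @param fTarget,fTrial Their fitness values (lower is better).
#' @return List with `vector` and `fitness` of the survivor.
#' @export
deSelect <- function(target, trial, fTarget, fTrial) {
    if (!is.finite(fTarget) || !is.finite(fTrial))
        stopf("non-finite fitness (target: %g, trial: %g)", fTarget, fTrial)
    if (fTrial <= fTarget) list(vector = trial, fitness = fTrial)
    else list(vector = target, fitness = fTarget)
}

#' Minimise a fitness function by differential evolution
#'
#' Initialises N members uniformly within the bounds, then runs `Gmax`
#' generations of mutate -> crossover -> select per member. The best-so-far
#' fitness trace is non-increasing by construction of the greedy selection.
#'
#' @param fitness Function mapping a weight vector to a finite scalar
#'   (lower is better); must be deterministic in its argument.
#' @param D Dimension of the weight vector.
#' @param config A [deConfig()] list.
#' @return List: `best` (weight vector), `bestFitness`, `trace`
#'   (best fitness after initialisation and after each generation),
#'   `population`, `fitnessValues`.
#' @examples
#' res <- deOptimize(function(w) sum((w - 0.3)^2), D = 3,
#'                   config = deConfig(Gmax = 100, seed = 7))
#' round(res$best, 2)
#' @export
deOptimize <- function(fitness, D, config = deConfig()) {
    stopifnot(inherits(config, "DEConfig"))
    withSeed(config$seed, {
        pop <- matrix(runif(config$N * D, config$lower, config$upper),
                      config$N, D)
        fit <- apply(pop, 1, fitness)
        if (any(!is.finite(fit))) stopf("non-finite fitness at initialisation")
        trace <- numeric(config$Gmax + 1L)
        trace[1] <- min(fit)
        for (g in seq_len(config$Gmax)) {
            for (i in seq_len(config$N)) {
                mv <- deMutate(pop, i, config$F, config$lower, config$upper)
                tv <- deCrossover(pop[i, ], mv, config$CR)
                ftv <- fitness(tv)
                sel <- deSelect(pop[i, ], tv, fit[i], ftv)
                pop[i, ] <- sel$vector
                fit[i] <- sel$fitness
            }
            trace[g + 1L] <- min(fit)
        }
    })
    best <- which.min(fit)
    list(best = pop[best, ], bestFitness = fit[best], trace = trace,
         population = pop, fitnessValues = fit)
}

#' Weighted sequential fusion of feature blocks
#'
#' Concatenates the blocks column-wise in the fixed order
#' (GloVe, fastText, CBOW), scaling every column of block b by `w[b]`.
#'
#' @param blocks List of [FeatureBlock-class] objects with equal row counts.
#'   Blocks are reordered to the canonical order when their encoder tags
#'   allow it; otherwise the given order is kept.
#' @param w Numeric weight vector, one weight per block.
#' @return A [FusedFeatures-class].
#' @export
fuseFeatures <- function(blocks, w) {
    stopifnot(length(blocks) == length(w))
    tags <- vapply(blocks, function(b) b@encoder, character(1))
    if (setequal(tags, BLOCK_ORDER)) {
        ord <- match(BLOCK_ORDER, tags)
        blocks <- blocks[ord]
        tags <- tags[ord]
        w <- w[ord]
    }
    ns <- vapply(blocks, function(b) nrow(b@matrix), integer(1))
    if (length(unique(ns)) != 1)
        stopf("blocks have mismatching row counts: %s",
              paste(ns, collapse = ", "))
    scaled <- mapply(function(b, wi) b@matrix * wi, blocks, w,
                     SIMPLIFY = FALSE)
    mat <- do.call(cbind, scaled)
    widths <- vapply(blocks, function(b) ncol(b@matrix), integer(1))
    names(widths) <- tags
    names(w) <- tags
    new("FusedFeatures", matrix = mat, blockWidths = widths,
        weights = as.numeric(w))
}

## Closed-form ridge classifier in dual form. Training scores for new data
## need only the Gram matrices K = X X', which for block-weighted features
## decompose as sum_b w_b^2 G_b with G_b precomputable per block -- this is
## what makes thousands of DE fitness evaluations affordable.
ridgeDualScores <- function(Ktr, Kte, ytr, lambda) {
    n <- nrow(Ktr)
    yc <- ytr - mean(ytr)
    reg <- lambda * mean(diag(Ktr))
    if (reg <= 0) reg <- lambda
    alpha <- solve(Ktr + diag(reg, n), yc)
    as.numeric(Kte %*% alpha)
}

#' Cross-validated fusion-weight fitness
#'
#' Returns the objective minimised by [deOptimize()]: `w |->`
#' `1 - mean stratified k-fold CV AUC` of a ridge (regularised least-squares)
#' classifier trained on the blocks fused with weights `w`. Folds are fixed
#' by `cvSeed`, so the function is deterministic in `w`. Per-fold, per-block
#' Gram matrices are precomputed once.
#'
#' @param blocks List of [FeatureBlock-class] objects, rows aligned with
#'   `labels`.
#' @param labels Binary labels (both classes present).
#' @param cvSeed Seed fixing the folds.
#' @param k Number of folds (default 5).
#' @param lambda Ridge penalty, relative to the mean Gram diagonal.
#' @return A function from a weight vector to a scalar in [0, 1].
#' @export
makeFusionFitness <- function(blocks, labels, cvSeed = 1L, k = 5L,
                              lambda = 1e-2) {
    y <- as.integer(labels)
    if (length(unique(y)) < 2) stopf("labels are single-class")
    folds <- stratifiedFolds(y, k, cvSeed)
    pre <- lapply(seq_len(k), function(fold) {
        tr <- folds != fold; te <- !tr
        list(
            Gtr = lapply(blocks, function(b)
                tcrossprod(b@matrix[tr, , drop = FALSE])),
            Gte = lapply(blocks, function(b)
                b@matrix[te, , drop = FALSE] %*%
                    t(b@matrix[tr, , drop = FALSE])),
            ytr = y[tr], yte = y[te])
    })
    function(w) {
        aucs <- vapply(pre, function(p) {
            Ktr <- Reduce(`+`, mapply(function(G, wi) wi^2 * G,
                                      p$Gtr, w, SIMPLIFY = FALSE))
            Kte <- Reduce(`+`, mapply(function(G, wi) wi^2 * G,
                                      p$Gte, w, SIMPLIFY = FALSE))
            sc <- ridgeDualScores(Ktr, Kte, p$ytr, lambda)
            rocAUC(p$yte, sc)
        }, numeric(1))
        1 - mean(aucs)
    }
}

#' Learn fusion weights with DE and fuse the blocks
#'
#' Convenience wrapper: builds the [makeFusionFitness()] objective, runs
#' [deOptimize()], and returns the fused features together with the DE
#' result.
#'
#' @inheritParams makeFusionFitness
#' @param config A [deConfig()].
#' @return List: `fused` ([FusedFeatures-class]), `weights`, `de` (full
#'   optimizer result).
#' @export
learnFusionWeights <- function(blocks, labels, config = deConfig(),
                               cvSeed = 1L, lambda = 1e-2) {
    fitness <- makeFusionFitness(blocks, labels, cvSeed = cvSeed,
                                 lambda = lambda)
    de <- deOptimize(fitness, D = length(blocks), config = config)
    list(fused = fuseFeatures(blocks, de$best), weights = de$best, de = de)
}

#' Serialise a DE result to JSON
#'
#' @param de Result of [deOptimize()] or the `de` element of
#'   [learnFusionWeights()].
#' @param path Output JSON path.
#' @param config Optional [deConfig()] to record.
#' @export
writeDEResult <- function(de, path, config = NULL) {
    jsonlite::write_json(list(weights = de$best, trace = de$trace,
                              config = if (!is.null(config)) unclass(config)),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
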