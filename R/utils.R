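## Helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' surrounding code is unaffected. `seed = NULL` evaluates `expr` with the
#' ambient RNG state.
#'
#' @param seed Integer seed or NULL.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps `(seed, stage)` to an integer below 2^31, so a
#' single global seed threads a distinct, reproducible seed through every
#' stochastic pipeline stage. [runPipeline()] derives the CV fold seed as
#' `deriveSeed(seed, "cv")`.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.double(seed) * 48271 + h * 1009 + 12345) %% 2147483647)
}

#' Stratified fold assignment
#'
#' Shuffles each class under the seed, then deals round-robin into k folds;
#' per-class fold sizes differ by at most 1.
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Assignment seed.
#' @return Integer fold id per instance.
#' @export
stratifiedFolds <- function(y, k, seed) {
    y <- as.integer(y)
    folds <- integer(length(y))
    withSeed(seed, {
        for (cls in sort(unique(y))) {
            idx <- which(y == cls)
            idx <- idx[sample.int(length(idx))]
            folds[idx] <- rep_len(seq_len(k), length(idx))
        }
    })
    folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
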