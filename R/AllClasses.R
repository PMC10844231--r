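## Central S4 containers. Validity methods enforce the structural invariants
## the downstream stages rely on (aligned labels, unique ids, finite matrices).

AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

#' Labeled set of protein sequences
#'
#' Binds an [Biostrings::AAStringSet] of protein chains to a binary label
#' vector (1 = DNA-binding, 0 = non-binding). Row order is meaningful and is
#' preserved by every downstream stage.
#'
#' @slot sequences An `AAStringSet`; names are the record ids.
#' @slot labels Integer vector of 0/1, one per sequence.
#'
#' @exportClass LabeledProteinSet
setClass("LabeledProteinSet",
    representation(sequences = "AAStringSet", labels = "integer"))

setValidity("LabeledProteinSet", function(object) {
    msg <- character()
    n <- length(object@sequences)
    if (length(object@labels) != n)
        msg <- c(msg, "labels must have one entry per sequence")
    if (!all(object@labels %in% c(0L, 1L)))
        msg <- c(msg, "labels must be 0 or 1")
    ids <- names(object@sequences)
    if (is.null(ids) || any(!nzchar(ids)))
        msg <- c(msg, "all sequences must be named")
    else if (anyDuplicated(ids))
        msg <- c(msg, "sequence ids must be unique")
    if (n > 0 && any(Biostrings::width(object@sequences) == 0))
        msg <- c(msg, "sequences must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Construct a LabeledProteinSet
#'
#' @param sequences An `AAStringSet` or named character vector of amino-acid
#'   sequences (uppercased on input).
#' @param labels Binary vector (0/1 or logical), one per sequence.
#' @return A [LabeledProteinSet-class] object.
#' @examples
#' lps <- LabeledProteinSet(c(p1 = "ACDEFGHIK", n1 = "MNPQRSTVW"), c(1, 0))
#' labels(lps)
#' @export
LabeledProteinSet <- function(sequences, labels) {
    if (is.character(sequences))
        sequences <- Biostrings::AAStringSet(toupper(sequences))
    new("LabeledProteinSet", sequences = sequences,
        labels = as.integer(labels))
}

#' @describeIn LabeledProteinSet-class number of records
#' @param x,object A `LabeledProteinSet`.
#' @export
setMethod("length", "LabeledProteinSet", function(x) length(x@sequences))

#' @describeIn LabeledProteinSet-class the 0/1 label vector (named by id)
#' @param ... ignored.
#' @export
setMethod("labels", "LabeledProteinSet", function(object, ...)
    structure(object@labels, names = names(object@sequences)))

#' Sequence accessor
#' @param x An object with sequences.
#' @return An `AAStringSet`.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @describeIn LabeledProteinSet-class the underlying `AAStringSet`
#' @export
setMethod("sequences", "LabeledProteinSet", function(x) x@sequences)

#' @describeIn LabeledProteinSet-class subset records, keeping labels aligned
#' @param i index vector.
#' @param j,drop ignored.
#' @export
setMethod("[", "LabeledProteinSet", function(x, i, j, ..., drop = TRUE)
    new("LabeledProteinSet", sequences = x@sequences[i],
        labels = x@labels[i]))

setMethod("show", "LabeledProteinSet", function(object) {
    cat("LabeledProteinSet with", length(object), "sequences (",
        sum(object@labels == 1L), "positive /",
        sum(object@labels == 0L), "negative )\n")
    if (length(object) > 0) {
        w <- Biostrings::width(object@sequences)
        cat("  length range:", min(w), "-", max(w), "residues\n")
    }
})

#' Tokenised k-mer corpus
#'
#' One "sentence" (ordered token list) per sequence, produced by sliding a
#' window of `k` residues with step `stride`.
#'
#' @slot sentences List of character vectors, one per record, in record order.
#' @slot vocabulary Character vector of the distinct tokens.
#' @slot k,stride Tokeniser parameters (residues).
#' @slot ids Record ids, aligned with `sentences`.
#'
#' @exportClass TokenCorpus
setClass("TokenCorpus",
    representation(sentences = "list", vocabulary = "character",
                   k = "integer", stride = "integer", ids = "character"))

setValidity("TokenCorpus", function(object) {
    msg <- character()
    if (length(object@ids) != length(object@sentences))
        msg <- c(msg, "one id per sentence required")
    toks <- unlist(object@sentences, use.names = FALSE)
    if (length(toks) && !setequal(unique(toks), object@vocabulary))
        msg <- c(msg, "vocabulary must equal the union of sentence tokens")
    if (length(toks) && any(nchar(toks) != object@k))
        msg <- c(msg, "every token must have length k")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TokenCorpus", function(object) {
    cat("TokenCorpus:", length(object@sentences), "sentences, |V| =",
        length(object@vocabulary), paste0("(k = ", object@k,
        ", stride = ", object@stride, ")\n"))
})

#' Trained word-embedding model
#'
#' @slot method One of `"cbow"`, `"glove"`, `"fasttext"`.
#' @slot vectors |V| x dim matrix; rownames are tokens.
#' @slot subwords Character n-gram vector matrix (fastText only), rownames are
#'   n-grams with `<`/`>` boundary markers; otherwise a 0-row matrix.
#' @slot ngramRange Integer length-2 n-gram size range (fastText only).
#' @slot lossTrace Per-epoch training loss.
#' @slot config The training configuration actually used.
#'
#' @exportClass EmbeddingModel
setClass("EmbeddingModel",
    representation(method = "character", vectors = "matrix",
                   subwords = "matrix", ngramRange = "integer",
                   lossTrace = "numeric", config = "list"))

setValidity("EmbeddingModel", function(object) {
    msg <- character()
    if (!object@method %in% c("cbow", "glove", "fasttext"))
        msg <- c(msg, "method must be cbow, glove or fasttext")
    if (is.null(rownames(object@vectors)))
        msg <- c(msg, "vectors must have token rownames")
    if (anyNA(object@vectors) || any(!is.finite(object@vectors)))
        msg <- c(msg, "vectors must be finite")
    if (length(msg)) msg else TRUE
})

setMethod("show", "EmbeddingModel", function(object) {
    cat(sprintf("EmbeddingModel [%s]: |V| = %d, dim = %d, %d epochs\n",
        object@method, nrow(object@vectors), ncol(object@vectors),
        length(object@lossTrace)))
    if (length(object@lossTrace))
        cat(sprintf("  final loss: %.6g\n",
            object@lossTrace[length(object@lossTrace)]))
})

#' Embedding dimension
#' @param x An `EmbeddingModel`.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' @describeIn EmbeddingModel-class vector dimension
#' @export
setMethod("embeddingDim", "EmbeddingModel", function(x) ncol(x@vectors))

#' Per-sequence feature block from one encoder
#'
#' @slot matrix n_sequences x dim numeric matrix; rownames are record ids.
#' @slot encoder Encoder tag (`"glove"`, `"fasttext"`, `"cbow"`).
#'
#' @exportClass FeatureBlock
setClass("FeatureBlock",
    representation(matrix = "matrix", encoder = "character"))

setValidity("FeatureBlock", function(object) {
    if (anyNA(object@matrix) || any(!is.finite(object@matrix)))
        "feature matrix must be finite" else TRUE
})

#' @describeIn FeatureBlock-class the numeric matrix
#' @param x A `FeatureBlock`.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname FeatureBlock-class
#' @export
setMethod("featureMatrix", "FeatureBlock", function(x) x@matrix)

setMethod("show", "FeatureBlock", function(object) {
    cat(sprintf("FeatureBlock [%s]: %d x %d\n", object@encoder,
        nrow(object@matrix), ncol(object@matrix)))
})

#' Weighted, sequentially fused super feature
#'
#' Column-wise concatenation of per-encoder blocks, block b scaled by its
#' learned weight w_b. Block order is fixed (GloVe, fastText, CBOW).
#'
#' @slot matrix n x sum(block widths) matrix with feature-name colnames.
#' @slot blockWidths Named integer vector of per-block column counts.
#' @slot weights Applied fusion weights, same order/names as `blockWidths`.
#'
#' @exportClass FusedFeatures
setClass("FusedFeatures",
    representation(matrix = "matrix", blockWidths = "integer",
                   weights = "numeric"))

setValidity("FusedFeatures", function(object) {
    msg <- character()
    if (sum(object@blockWidths) != ncol(object@matrix))
        msg <- c(msg, "column count must equal the sum of block widths")
    if (length(object@weights) != length(object@blockWidths))
        msg <- c(msg, "one weight per block required")
    if (length(msg)) msg else TRUE
})

#' @rdname FeatureBlock-class
#' @export
setMethod("featureMatrix", "FusedFeatures", function(x) x@matrix)

setMethod("show", "FusedFeatures", function(object) {
    cat("FusedFeatures:", nrow(object@matrix), "x", ncol(object@matrix),
        "\n  blocks:", paste(sprintf("%s(%d, w=%.3f)",
        names(object@blockWidths), object@blockWidths, object@weights),
        collapse = " + "), "\n")
})

#' Global Shapley-importance feature ranking
#'
#' @slot importance Non-negative importance per feature, in original column
#'   order (named by feature).
#' @slot rankOrder Permutation of feature indices, decreasing importance,
#'   ties broken by ascending index.
#'
#' @exportClass FeatureRanking
setClass("FeatureRanking",
    representation(importance = "numeric", rankOrder = "integer"))

setValidity("FeatureRanking", function(object) {
    msg <- character()
    if (any(object@importance < 0)) msg <- c(msg, "importances must be >= 0")
    if (!identical(sort(object@rankOrder),
                   seq_along(object@importance)))
        msg <- c(msg, "rankOrder must be a permutation of feature indices")
    if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureRanking", function(object) {
    cat("FeatureRanking over", length(object@importance), "features\n")
    top <- head(object@rankOrder, 5)
    cat("  top:", paste(sprintf("%s (%.4g)",
        names(object@importance)[top], object@importance[top]),
        collapse = ", "), "\n")
})

#' Per-instance Shapley explanation
#'
#' Additive attributions: for exact values, `phi0 + rowSums(phi)` equals the
#' model output on each explained instance.
#'
#' @slot phi0 Base value (mean model output over the background set).
#' @slot phi n_instances x M attribution matrix.
#' @slot fx Model output per explained instance.
#'
#' @exportClass ShapExplanation
setClass("ShapExplanation",
    representation(phi0 = "numeric", phi = "matrix", fx = "numeric"))

setMethod("show", "ShapExplanation", function(object) {
    cat(sprintf("ShapExplanation: %d instances x %d features, phi0 = %.4g\n",
        nrow(object@phi), ncol(object@phi), object@phi0))
})

#' Classification metric report
#'
#' Six confusion-matrix metrics plus AUC; when produced by cross-validation
#' also carries the per-fold breakdown and pooled out-of-fold scores.
#'
#' @slot metrics Named numeric: ACC, Sen, Spe, MCC, Pre, F1, AUC.
#' @slot perFold Per-fold metric data.frame (0 rows for a single evaluation).
#' @slot sds Fold-to-fold standard deviations (empty when not from CV).
#' @slot scores Out-of-fold (or test-set) predicted probabilities.
#' @slot folds Integer fold assignment per instance (empty when not from CV).
#'
#' @exportClass MetricReport
setClass("MetricReport",
    representation(metrics = "numeric", perFold = "data.frame",
                   sds = "numeric", scores = "numeric", folds = "integer"))

setMethod("show", "MetricReport", function(object) {
    m <- object@metrics
    cat("MetricReport\n")
    for (nm in names(m)) {
        if (nm %in% names(object@sds))
            cat(sprintf("  %-4s %.4f +/- %.4f\n", nm, m[nm], object@sds[nm]))
        else
            cat(sprintf("  %-4s %.4f\n", nm, m[nm]))
    }
    if (nrow(object@perFold))
        cat("  (", nrow(object@perFold), "folds )\n")
})

#' @describeIn MetricReport-class the named metric vector
#' @param x A `MetricReport`.
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname MetricReport-class
#' @export
setMethod("metrics", "MetricReport", function(x) x@metrics)
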