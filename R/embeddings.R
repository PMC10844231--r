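## The three word-embedding encoders and per-sequence aggregation.
## Training loops are compiled (src/embeddings.cpp); wrappers own vocabulary
## indexing, initialisation and seeding so a fixed (corpus, config, seed)
## reproduces vectors exactly.

#' Token-token co-occurrence matrix
#'
#' `X[i, j]` counts, over all sentences, how often token j occurs within
#' `window` positions of an occurrence of token i (symmetric counting, unit
#' weights). The matrix is exactly symmetric.
#'
#' @param corpus A [TokenCorpus-class].
#' @param window Context half-width in tokens.
#' @return A sparse symmetric `dgCMatrix` with token dimnames.
#' @export
buildCooccurrence <- function(corpus, window = 5L) {
    stopifnot(is(corpus, "TokenCorpus"))
    if (window < 1) stopf("window must be >= 1")
    vocab <- corpus@vocabulary
    V <- length(vocab)
    ii <- list(); jj <- list(); n <- 0L
    for (s in corpus@sentences) {
        si <- match(s, vocab)
        ns <- length(si)
        for (d in seq_len(min(window, ns - 1L))) {
            n <- n + 1L
            ii[[n]] <- si[seq_len(ns - d)]
            jj[[n]] <- si[seq.int(1L + d, ns)]
        }
    }
    ii <- unlist(ii); jj <- unlist(jj)
    if (is.null(ii))
        return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                    x = numeric(), dims = c(V, V),
                                    dimnames = list(vocab, vocab)))
    ## each ordered pair and its mirror: X is symmetric by construction
    Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                         dims = c(V, V), dimnames = list(vocab, vocab))
}

## Shared init: small uniform values scaled by 1/dim, standard for both
## word2vec- and GloVe-family trainers. Vector matrices are handed to the
## compiled trainers transposed (dim x entity: one contiguous column per
## entity) and transposed back afterwards.
initMatrix <- function(nr, nc, denom = nc) {
    matrix((runif(nr * nc) - 0.5) / denom, nr, nc)
}

unigramCumulative <- function(counts, power = 0.75) {
    p <- counts^power
    cumsum(p / sum(p))
}

#' Train a continuous bag-of-words (CBOW) embedding
#'
#' Maximises the average log-probability of each target token given the mean
#' of its context-token input vectors, with the target distribution a softmax
#' over the vocabulary. The exact softmax is used while the vocabulary is at
#' most `maxSoftmaxVocab` tokens; larger vocabularies are trained with
#' negative sampling (`negative` noise words per target, unigram^0.75 noise
#' distribution).
#'
#' @param corpus A [TokenCorpus-class] (vocabulary size >= 2).
#' @param dim Embedding dimension (default 200).
#' @param window Context half-width in tokens.
#' @param epochs Training passes over the corpus.
#' @param lr Learning rate.
#' @param negative Noise words per target in negative-sampling mode.
#' @param maxSoftmaxVocab Largest vocabulary trained with the exact softmax.
#' @param seed RNG seed; fixed (corpus, config, seed) reproduces vectors
#'   bit-identically on one platform.
#' @return An [EmbeddingModel-class] with method `"cbow"`.
#' @export
trainCBOW <- function(corpus, dim = 200L, window = 5L, epochs = 5L,
                      lr = 0.05, negative = 5L, maxSoftmaxVocab = 2000L,
                      seed = 1L) {
    stopifnot(is(corpus, "TokenCorpus"), dim >= 1, window >= 1, epochs >= 1)
    vocab <- corpus@vocabulary
    V <- length(vocab)
    if (V < 2) stopf("vocabulary of size %d: softmax degenerate", V)
    sentences <- lapply(corpus@sentences,
                        function(s) match(s, vocab) - 1L)
    counts <- tabulate(unlist(sentences) + 1L, nbins = V)
    fullSoftmax <- V <= maxSoftmaxVocab
    wordRows <- lapply(seq_len(V) - 1L, identity)
    withSeed(seed, {
        win <- initMatrix(dim, V, denom = dim)
        wout <- matrix(0, dim, V)
        trace <- cpp_cbow_train(sentences, win, wout, wordRows,
                                as.integer(window), as.integer(epochs), lr,
                                as.integer(negative),
                                unigramCumulative(counts), fullSoftmax)
    })
    win <- t(win)
    rownames(win) <- vocab
    new("EmbeddingModel", method = "cbow", vectors = win,
        subwords = matrix(0, 0, dim), ngramRange = integer(0),
        lossTrace = as.numeric(trace),
        config = list(dim = dim, window = window, epochs = epochs, lr = lr,
                      negative = negative, fullSoftmax = fullSoftmax,
                      seed = seed))
}

## Character n-grams of a word with boundary markers, as a multiset in
## left-to-right order.
charNgrams <- function(word, nmin, nmax) {
    s <- paste0("<", word, ">")
    L <- nchar(s)
    out <- character(0)
    for (n in seq.int(nmin, nmax)) {
        if (n > L) next
        starts <- seq_len(L - n + 1L)
        out <- c(out, substring(s, starts, starts + n - 1L))
    }
    out
}

#' Train a subword (fastText-style) CBOW embedding
#'
#' Same training contract as [trainCBOW()], but each word's input vector is
#' the sum of its character n-gram vectors (with `<`/`>` word-boundary
#' markers). This makes out-of-vocabulary k-mers embeddable by composing
#' their known n-grams.
#'
#' @inheritParams trainCBOW
#' @param ngramRange Length-2 integer range of character n-gram sizes. The
#'   default 1:2 suits short k-mer words.
#' @return An [EmbeddingModel-class] with method `"fasttext"`; `@vectors`
#'   holds the composed word vectors and `@subwords` the n-gram vectors.
#' @export
trainFastText <- function(corpus, dim = 200L, window = 5L, epochs = 5L,
                          lr = 0.05, negative = 5L, maxSoftmaxVocab = 2000L,
                          ngramRange = c(1L, 2L), seed = 1L) {
    stopifnot(is(corpus, "TokenCorpus"), length(ngramRange) == 2)
    vocab <- corpus@vocabulary
    V <- length(vocab)
    if (V < 2) stopf("vocabulary of size %d: softmax degenerate", V)
    if (ngramRange[2] > corpus@k + 2)
        stopf("n-gram range (%d) exceeds word length + 2 (%d)",
              ngramRange[2], corpus@k + 2)
    wordGrams <- lapply(vocab, charNgrams, nmin = ngramRange[1],
                        nmax = ngramRange[2])
    gramVocab <- unique(unlist(wordGrams))
    G <- length(gramVocab)
    wordRows <- lapply(wordGrams, function(g) match(g, gramVocab) - 1L)
    sentences <- lapply(corpus@sentences,
                        function(s) match(s, vocab) - 1L)
    counts <- tabulate(unlist(sentences) + 1L, nbins = V)
    fullSoftmax <- V <= maxSoftmaxVocab
    withSeed(seed, {
        win <- initMatrix(dim, G, denom = dim)
        wout <- matrix(0, dim, V)
        trace <- cpp_cbow_train(sentences, win, wout, wordRows,
                                as.integer(window), as.integer(epochs), lr,
                                as.integer(negative),
                                unigramCumulative(counts), fullSoftmax)
    })
    composed <- t(vapply(wordRows, function(r)
        rowSums(win[, r + 1L, drop = FALSE]), numeric(dim)))
    rownames(composed) <- vocab
    win <- t(win)
    rownames(win) <- gramVocab
    new("EmbeddingModel", method = "fasttext", vectors = composed,
        subwords = win, ngramRange = as.integer(ngramRange),
        lossTrace = as.numeric(trace),
        config = list(dim = dim, window = window, epochs = epochs, lr = lr,
                      negative = negative, fullSoftmax = fullSoftmax,
                      ngramRange = ngramRange, seed = seed))
}

#' Train a GloVe embedding on a co-occurrence matrix
#'
#' Minimises the weighted least-squares objective
#' `sum f(X_ij) (v_i' v~_j + b_i + b~_j - log X_ij)^2` over nonzero entries,
#' with `f(x) = min((x/xmax)^alpha, 1)`. The reported token vector is the
#' mean of the main and context vectors.
#'
#' @param X Sparse co-occurrence matrix from [buildCooccurrence()], with
#'   token dimnames and at least one nonzero entry.
#' @param dim,epochs,seed As in [trainCBOW()].
#' @param lr Learning rate (AdaGrad step, or fixed step for `"gd"`).
#' @param xmax,alpha Weighting-function parameters.
#' @param optimizer `"adagrad"` (shuffled stochastic updates, default) or
#'   `"gd"` (deterministic full-batch descent; loss is non-increasing for
#'   small enough `lr`).
#' @return An [EmbeddingModel-class] with method `"glove"` and the post-epoch
#'   objective values in `@lossTrace`.
#' @export
trainGlove <- function(X, dim = 200L, epochs = 15L, lr = 0.05, xmax = 100,
                       alpha = 0.75, optimizer = c("adagrad", "gd"),
                       seed = 1L) {
    optimizer <- match.arg(optimizer)
    trip <- Matrix::summary(methods::as(X, "TsparseMatrix"))
    trip <- trip[trip$x > 0, , drop = FALSE]
    if (nrow(trip) == 0) stopf("empty co-occurrence matrix")
    vocab <- rownames(X)
    V <- nrow(X)
    lrGD <- if (optimizer == "gd" && missing(lr)) 0.002 else lr
    withSeed(seed, {
        w <- initMatrix(dim, V, denom = dim)
        wc <- initMatrix(dim, V, denom = dim)
        b <- (runif(V) - 0.5) / dim; bc <- (runif(V) - 0.5) / dim
        trace <- cpp_glove_train(as.integer(trip$i - 1L),
                                 as.integer(trip$j - 1L), trip$x,
                                 w, wc, b, bc, as.integer(epochs), lrGD,
                                 xmax, alpha, optimizer == "adagrad")
    })
    vectors <- t(w + wc) / 2
    rownames(vectors) <- vocab
    new("EmbeddingModel", method = "glove", vectors = vectors,
        subwords = matrix(0, 0, dim), ngramRange = integer(0),
        lossTrace = as.numeric(trace),
        config = list(dim = dim, epochs = epochs, lr = lrGD, xmax = xmax,
                      alpha = alpha, optimizer = optimizer, seed = seed))
}

## Resolve one token to a vector, or NULL if unresolvable.
resolveToken <- function(token, model) {
    i <- match(token, rownames(model@vectors))
    if (!is.na(i)) return(model@vectors[i, ])
    if (model@method == "fasttext") {
        grams <- charNgrams(token, model@ngramRange[1], model@ngramRange[2])
        gi <- match(grams, rownames(model@subwords))
        gi <- gi[!is.na(gi)]
        if (length(gi))
            return(colSums(model@subwords[gi, , drop = FALSE]))
    }
    NULL
}

#' Aggregate a token sentence into one fixed-length vector
#'
#' Arithmetic mean of the resolved token vectors. Tokens absent from the
#' vocabulary are skipped for CBOW/GloVe (their count is returned in the
#' `skipped` attribute) and composed from character n-grams for the subword
#' encoder.
#'
#' @param sentence Character vector of tokens (non-empty).
#' @param model An [EmbeddingModel-class].
#' @return Numeric vector of length `embeddingDim(model)`.
#' @export
embedSequence <- function(sentence, model) {
    stopifnot(is(model, "EmbeddingModel"))
    if (length(sentence) == 0) stopf("empty sentence")
    known <- match(sentence, rownames(model@vectors))
    if (model@method != "fasttext") {
        if (all(is.na(known)))
            stopf("no token resolvable in vocabulary: %s",
                  paste(unique(sentence), collapse = ", "))
        v <- colMeans(model@vectors[known[!is.na(known)], , drop = FALSE])
        attr(v, "skipped") <- sum(is.na(known))
        return(v)
    }
    vecs <- matrix(0, length(sentence), ncol(model@vectors))
    keep <- logical(length(sentence))
    for (i in seq_along(sentence)) {
        r <- resolveToken(sentence[i], model)
        if (!is.null(r)) { vecs[i, ] <- r; keep[i] <- TRUE }
    }
    if (!any(keep)) stopf("no token resolvable, even via subwords")
    v <- colMeans(vecs[keep, , drop = FALSE])
    attr(v, "skipped") <- sum(!keep)
    v
}

#' Embed every sequence of a dataset into a feature block
#'
#' @param ds A [LabeledProteinSet-class].
#' @param corpus The matching [TokenCorpus-class] (same records, same order).
#' @param model A trained [EmbeddingModel-class].
#' @return A [FeatureBlock-class]: one row per record, record order kept.
#' @export
embedDataset <- function(ds, corpus, model) {
    stopifnot(is(ds, "LabeledProteinSet"), is(corpus, "TokenCorpus"))
    if (!identical(corpus@ids, names(sequences(ds))))
        stopf("corpus records do not align with the dataset")
    dim <- embeddingDim(model)
    rows <- t(vapply(seq_along(corpus@sentences), function(i) {
        tryCatch(as.numeric(embedSequence(corpus@sentences[[i]], model)),
                 error = function(e) stopf("record '%s': %s", corpus@ids[i],
                                           conditionMessage(e)))
    }, numeric(dim)))
    rownames(rows) <- corpus@ids
    colnames(rows) <- paste0(model@method, "_", seq_len(dim))
    new("FeatureBlock", matrix = rows, encoder = model@method)
}

#' Write / read an embedding model in word2vec text format
#'
#' Header line `<method> <|V|> <dim>`, then one `token v1 ... v_dim` row per
#' token. Subword vectors of a fastText model are appended after a
#' `#subwords <G>` marker line.
#'
#' @param model An [EmbeddingModel-class].
#' @param path Output file.
#' @return `path` (write) or an `EmbeddingModel` (read).
#' @export
writeEmbedding <- function(model, path) {
    con <- file(path, "w"); on.exit(close(con))
    fmtRows <- function(m) paste(rownames(m),
        apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")))
    writeLines(paste(model@method, nrow(model@vectors),
                     ncol(model@vectors)), con)
    writeLines(fmtRows(model@vectors), con)
    if (nrow(model@subwords)) {
        writeLines(paste("#subwords", nrow(model@subwords),
                         paste(model@ngramRange, collapse = " ")), con)
        writeLines(fmtRows(model@subwords), con)
    }
    invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
    lines <- readLines(path)
    hdr <- strsplit(lines[1], " ")[[1]]
    V <- as.integer(hdr[2]); dim <- as.integer(hdr[3])
    parse <- function(ls) {
        parts <- strsplit(ls, " ")
        m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dim)))
        rownames(m) <- vapply(parts, `[`, character(1), 1)
        m
    }
    vectors <- parse(lines[2:(V + 1)])
    subwords <- matrix(0, 0, dim); ngramRange <- integer(0)
    if (length(lines) > V + 1 && startsWith(lines[V + 2], "#subwords")) {
        sw <- strsplit(lines[V + 2], " ")[[1]]
        G <- as.integer(sw[2])
        ngramRange <- as.integer(sw[3:4])
        subwords <- parse(lines[(V + 3):(V + 2 + G)])
    }
    new("EmbeddingModel", method = hdr[1], vectors = vectors,
        subwords = subwords, ngramRange = ngramRange,
        lossTrace = numeric(0), config = list())
}
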