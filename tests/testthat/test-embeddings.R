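test_that("buildCooccurrence is symmetric with token dimnames", {
    corpus <- charCorpus(c("ABCAB", "BCA"))
    X <- buildCooccurrence(corpus, window = 2)
    expect_true(Matrix::isSymmetric(X))
    expect_identical(rownames(X), corpus@vocabulary)
    ## window = 1 only counts adjacent pairs: A-B twice in "ABCAB", never
    ## in "BCA"
    X1 <- buildCooccurrence(corpus, window = 1)
    expect_identical(X1["A", "B"], 2)
    expect_identical(X1["A", "B"], X1["B", "A"])
    expect_error(buildCooccurrence(corpus, window = 0), "window")
})

test_that("trainCBOW is reproducible and shaped by the vocabulary", {
    corpus <- charCorpus(rep(c("ABCDE", "EDCBA"), 5))
    m1 <- trainCBOW(corpus, dim = 8, window = 2, epochs = 5, seed = 3)
    m2 <- trainCBOW(corpus, dim = 8, window = 2, epochs = 5, seed = 3)
    m3 <- trainCBOW(corpus, dim = 8, window = 2, epochs = 5, seed = 4)
    expect_identical(m1@vectors, m2@vectors)
    expect_false(identical(m1@vectors, m3@vectors))
    expect_identical(rownames(m1@vectors), corpus@vocabulary)
    expect_identical(embeddingDim(m1), 8L)
    expect_length(m1@lossTrace, 5)
    ## softmax loss improves on a predictable corpus
    expect_lt(tail(m1@lossTrace, 1), m1@lossTrace[1])
})

test_that("trainCBOW falls back to negative sampling above the softmax cap", {
    corpus <- charCorpus(rep(c("ABCDEFG", "GFEDCBA"), 4))
    m <- trainCBOW(corpus, dim = 6, epochs = 3, maxSoftmaxVocab = 3, seed = 1)
    expect_false(m@config$fullSoftmax)
    expect_true(all(is.finite(m@vectors)))
    expect_lt(tail(m@lossTrace, 1), m@lossTrace[1])
})

test_that("degenerate vocabularies are rejected", {
    corpus <- charCorpus(c("AAAA", "AA"))
    expect_error(trainCBOW(corpus), "vocabulary of size 1")
    expect_error(trainFastText(corpus), "vocabulary of size 1")
})

test_that("fastText word vectors are sums of their character n-grams", {
    ds <- tinyDataset()
    corpus <- buildCorpus(ds, k = 3)
    m <- trainFastText(corpus, dim = 6, epochs = 1, seed = 2)
    tok <- corpus@vocabulary[1]
    grams <- rownames(m@subwords)
    expected <- colSums(m@subwords[match(dbpWET:::charNgrams(tok, 1, 2),
                                         grams), , drop = FALSE])
    expect_equal(unname(m@vectors[tok, ]), unname(expected))
    expect_error(trainFastText(corpus, ngramRange = c(1L, 9L)),
                 "n-gram range")
})

test_that("fastText composes out-of-vocabulary tokens from subwords", {
    ds <- tinyDataset()
    corpus <- buildCorpus(ds, k = 3)
    m <- trainFastText(corpus, dim = 6, epochs = 1, seed = 2)
    aa <- dbpWET:::AA_ALPHABET20
    oov <- setdiff(apply(expand.grid(aa, aa, aa), 1, paste, collapse = ""),
                   corpus@vocabulary)[1]
    v <- embedSequence(c(corpus@vocabulary[1], oov), m)
    expect_identical(attr(v, "skipped"), 0L)
    expect_true(all(is.finite(v)))
})

test_that("trainGlove fits co-occurrence structure reproducibly", {
    corpus <- charCorpus(rep(c("ABCDE", "ABCDE", "EDCBA"), 4))
    X <- buildCooccurrence(corpus, window = 2)
    g1 <- trainGlove(X, dim = 6, epochs = 10, seed = 5)
    g2 <- trainGlove(X, dim = 6, epochs = 10, seed = 5)
    expect_identical(g1@vectors, g2@vectors)
    expect_identical(rownames(g1@vectors), rownames(X))
    expect_lt(tail(g1@lossTrace, 1), g1@lossTrace[1])
    empty <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                  x = numeric(), dims = c(2, 2),
                                  dimnames = list(c("A", "B"), c("A", "B")))
    expect_error(trainGlove(empty), "empty co-occurrence")
})

test_that("embedSequence averages token vectors and reports skips", {
    corpus <- charCorpus(rep("ABCD", 4))
    m <- trainCBOW(corpus, dim = 5, epochs = 1, seed = 1)
    v <- embedSequence(c("A", "B"), m)
    expect_equal(as.numeric(v), unname((m@vectors["A", ] + m@vectors["B", ]) / 2))
    v2 <- embedSequence(c("A", "Z"), m)
    expect_identical(attr(v2, "skipped"), 1L)
    expect_equal(as.numeric(v2), unname(m@vectors["A", ]))
    expect_error(embedSequence(c("Z"), m), "no token resolvable")
    expect_error(embedSequence(character(0), m), "empty sentence")
})

test_that("embedDataset produces an aligned, named feature block", {
    ds <- tinyDataset()
    corpus <- buildCorpus(ds, k = 3)
    m <- trainCBOW(corpus, dim = 5, epochs = 1, seed = 1)
    block <- embedDataset(ds, corpus, m)
    expect_s4_class(block, "FeatureBlock")
    expect_identical(rownames(featureMatrix(block)), names(sequences(ds)))
    expect_identical(colnames(featureMatrix(block)),
                     paste0("cbow_", 1:5))
    expect_error(embedDataset(ds[1:3], corpus, m), "do not align")
})

test_that("embedding serialisation round-trips, including subwords", {
    corpus <- charCorpus(rep(c("ABCDE", "BCDEA"), 3))
    for (m in list(trainCBOW(corpus, dim = 4, epochs = 1, seed = 1),
                   trainFastText(corpus, dim = 4, epochs = 1, seed = 1))) {
        f <- tempfile(fileext = ".vec")
        writeEmbedding(m, f)
        r <- readEmbedding(f)
        expect_identical(r@method, m@method)
        expect_equal(r@vectors, m@vectors, tolerance = 1e-12)
        expect_equal(r@subwords, m@subwords, tolerance = 1e-12)
        expect_identical(r@ngramRange, m@ngramRange)
    }
})
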