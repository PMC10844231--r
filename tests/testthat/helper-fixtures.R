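## Shared small fixtures. Everything is generated, seeded and cheap; no
## fixture exceeds a few kilobytes in memory.

## A tiny labeled dataset whose chains are long enough for the default
## filters and the k = 3 tokeniser.
tinyDataset <- function(nPos = 6, nNeg = 6, seed = 101) {
    simulateProteins(nPos, nNeg, lengthRange = c(50L, 60L), seed = seed)
}

## A corpus of single-residue tokens (k = 1) built directly from residue
## strings; handy for small, fully controlled vocabularies.
charCorpus <- function(strings) {
    sentences <- strsplit(strings, "")
    new("TokenCorpus", sentences = sentences,
        vocabulary = unique(unlist(sentences)), k = 1L, stride = 1L,
        ids = sprintf("s%03d", seq_along(strings)))
}

## Write a FASTA file from a named character vector; returns the path.
writeTempFasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
    writeLines(unlist(lapply(names(seqs), function(id)
        c(paste0(">", id), seqs[[id]]))), path)
    path
}

## A deterministic, linearly separable feature matrix for classifier tests.
separableData <- function(n = 40, p = 12, shift = 2, seed = 7) {
    withSeed(seed, {
        y <- rep(c(1L, 0L), each = n / 2)
        X <- matrix(rnorm(n * p), n, p)
        X[y == 1L, 1:3] <- X[y == 1L, 1:3] + shift
        rownames(X) <- sprintf("r%03d", seq_len(n))
        colnames(X) <- sprintf("f%02d", seq_len(p))
        list(X = X, y = y)
    })
}
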