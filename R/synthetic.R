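## Synthetic labeled protein datasets with planted k-mer motif signal, plus
## the block fixture used to validate fusion-weight recovery. These are the
## package's test bench: every pipeline stage is exercisable without any
## external download.

#' Generate a labeled synthetic protein dataset with planted motifs
#'
#' Background sequences are i.i.d. draws from `background` over the 20
#' canonical residues, with lengths uniform on `lengthRange`. Each positive
#' sequence receives `rpois(1, rate * effectSize)` motif copies (motif drawn
#' uniformly from `motifs`), overwritten at non-overlapping random
#' positions so lengths are unchanged; negatives are pure background.
#' `effectSize = 0` makes the classes exchangeable.
#'
#' @param nPos,nNeg Class sizes.
#' @param lengthRange Length range in residues, min >= 50 by default.
#' @param motifs Character vector of planted k-mers (default three 3-mers).
#' @param rate Expected motif copies per positive at `effectSize = 1`.
#' @param effectSize Multiplier on the planting rate (0 = null).
#' @param background Residue probabilities (length 20, default uniform).
#' @param seed RNG seed; the same seed reproduces the dataset byte for byte.
#' @return A [LabeledProteinSet-class]; the `motifAnnotation` attribute
#'   records, per record, the planted motifs and their 1-based offsets.
#' @examples
#' ds <- simulateProteins(5, 5, seed = 1)
#' table(labels(ds))
#' @export
simulateProteins <- function(nPos, nNeg, lengthRange = c(50L, 100L),
                             motifs = c("HKR", "WDE", "CMY"), rate = 1.5,
                             effectSize = 1, background = NULL, seed = 1L) {
    stopifnot(nPos >= 1, nNeg >= 1, rate >= 0, effectSize >= 0)
    if (lengthRange[1] < max(nchar(motifs)))
        stopf("motif longer than the minimum sequence length")
    if (is.null(background)) background <- rep(1 / 20, 20)
    stopifnot(length(background) == 20)
    n <- nPos + nNeg
    ann <- vector("list", n)
    withSeed(seed, {
        lens <- sample.int(lengthRange[2] - lengthRange[1] + 1L, n,
                           replace = TRUE) + lengthRange[1] - 1L
        seqs <- vapply(lens, function(L)
            paste(sample(AA_ALPHABET20, L, replace = TRUE,
                         prob = background), collapse = ""), character(1))
        for (i in seq_len(nPos)) {
            nCopies <- rpois(1, rate * effectSize)
            placed <- list(); occupied <- integer(0)
            L <- lens[i]
            for (cp in seq_len(nCopies)) {
                m <- sample(motifs, 1)
                w <- nchar(m)
                ok <- setdiff(seq_len(L - w + 1L),
                              unique(unlist(lapply(occupied, function(p)
                                  seq.int(p - w + 1L, p + w - 1L)))))
                ok <- ok[ok >= 1L]
                if (!length(ok)) break
                pos <- if (length(ok) == 1L) ok else sample(ok, 1)
                substr(seqs[i], pos, pos + w - 1L) <- m
                occupied <- c(occupied, pos)
                placed <- c(placed, list(list(motif = m, offset = pos)))
            }
            ann[[i]] <- placed
        }
    })
    ids <- c(sprintf("pos_%04d", seq_len(nPos)),
             sprintf("neg_%04d", seq_len(nNeg)))
    names(seqs) <- ids
    names(ann) <- ids
    ds <- LabeledProteinSet(seqs, c(rep(1L, nPos), rep(0L, nNeg)))
    attr(ds, "motifAnnotation") <- ann
    attr(ds, "config") <- list(nPos = nPos, nNeg = nNeg,
                               lengthRange = lengthRange, motifs = motifs,
                               rate = rate, effectSize = effectSize,
                               seed = seed)
    ds
}

#' Write a synthetic dataset as paired FASTA plus a ground-truth manifest
#'
#' @param ds Output of [simulateProteins()].
#' @param posPath,negPath FASTA output paths per class.
#' @param manifestPath JSON manifest path (generator config and planted
#'   motif positions).
#' @export
writeSyntheticDataset <- function(ds, posPath, negPath, manifestPath) {
    writeFasta(ds, c(posPath, negPath))
    jsonlite::write_json(list(config = attr(ds, "config"),
                              motifs = attr(ds, "motifAnnotation")),
                         manifestPath, auto_unbox = TRUE, digits = NA)
    invisible(c(posPath, negPath, manifestPath))
}

#' Three-block fixture with signal confined to block 1
#'
#' Returns three [FeatureBlock-class]s and labels, where block 1 columns are
#' class-shifted normals (shift 1.5 standard deviations) and blocks 2-3 are
#' pure noise. Used to check that fusion-weight learning puts its weight on
#' the informative block.
#'
#' @param seed RNG seed.
#' @param nPerClass Instances per class (default 60).
#' @param dimPerBlock Columns per block (default 20).
#' @param shift Class shift in block 1, in noise standard deviations.
#' @return List: `blocks` (list of 3 `FeatureBlock`s tagged glove/fasttext/
#'   cbow), `labels`, `params` (the generative parameters).
#' @export
deFitnessFixture <- function(seed = 1L, nPerClass = 60L, dimPerBlock = 20L,
                             shift = 1.5) {
    n <- 2L * nPerClass
    y <- rep(c(1L, 0L), each = nPerClass)
    ids <- sprintf("s%04d", seq_len(n))
    withSeed(seed, {
        mk <- function(informative, tag) {
            m <- matrix(rnorm(n * dimPerBlock), n, dimPerBlock)
            if (informative) m[y == 1L, ] <- m[y == 1L, ] + shift
            rownames(m) <- ids
            colnames(m) <- paste0(tag, "_", seq_len(dimPerBlock))
            new("FeatureBlock", matrix = m, encoder = tag)
        }
        blocks <- list(mk(TRUE, "glove"), mk(FALSE, "fasttext"),
                       mk(FALSE, "cbow"))
    })
    list(blocks = blocks, labels = y,
         params = list(seed = seed, nPerClass = nPerClass,
                       dimPerBlock = dimPerBlock, shift = shift,
                       informativeBlock = 1L))
}
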