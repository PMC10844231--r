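## FASTA input/output, sequence-level filtering and k-mer tokenisation.
## Parsing and serialisation delegate to Biostrings; the wrapper adds the
## header-first sanity check and the id convention (token before the first
## whitespace in the header).

#' Read a FASTA file of protein sequences
#'
#' Sequences are uppercased; wrapped sequence lines are concatenated. The id
#' is the header token before the first whitespace; any remaining description
#' is kept in the element metadata of the returned `AAStringSet`.
#'
#' @param path Path to a FASTA file.
#' @return An `AAStringSet` named by record id, with a `description`
#'   metadata column.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some description", "ACDEF"), f)
#' readFastaRecords(f)
#' @export
readFastaRecords <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    lines <- readLines(path, warn = FALSE)
    nonEmpty <- which(nzchar(trimws(lines)))
    if (length(nonEmpty) && !startsWith(trimws(lines[nonEmpty[1]]), ">"))
        stopf("malformed FASTA in '%s': sequence line before any header at line %d",
              path, nonEmpty[1])
    aas <- Biostrings::readAAStringSet(path)
    headers <- names(aas)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
    aas <- Biostrings::AAStringSet(toupper(as.character(aas)))
    names(aas) <- ids
    S4Vectors::mcols(aas)$description <- desc
    aas
}

#' Read a labeled dataset from paired FASTA files
#'
#' The canonical input convention: one FASTA of positives (DNA-binding
#' proteins, label 1) and one of negatives (label 0).
#'
#' @param posPath,negPath FASTA paths for the positive and negative class.
#' @return A [LabeledProteinSet-class].
#' @export
readLabeledFasta <- function(posPath, negPath) {
    pos <- readFastaRecords(posPath)
    neg <- readFastaRecords(negPath)
    LabeledProteinSet(c(pos, neg),
                      c(rep(1L, length(pos)), rep(0L, length(neg))))
}

#' Read a labeled dataset from one FASTA plus a TSV label table
#'
#' @param fastaPath FASTA path.
#' @param labelPath Two-column TSV `id<TAB>label` with label in {0,1}; no
#'   header.
#' @return A [LabeledProteinSet-class], in FASTA record order.
#' @export
readLabeledTSV <- function(fastaPath, labelPath) {
    aas <- readFastaRecords(fastaPath)
    tab <- read.delim(labelPath, header = FALSE,
                      col.names = c("id", "label"),
                      colClasses = c("character", "integer"))
    missing <- setdiff(names(aas), tab$id)
    if (length(missing))
        stopf("no label for ids: %s", paste(missing, collapse = ", "))
    LabeledProteinSet(aas, tab$label[match(names(aas), tab$id)])
}

#' Write sequences to FASTA
#'
#' @param x A `LabeledProteinSet` or `AAStringSet`.
#' @param path Output path. For a `LabeledProteinSet` with both classes and
#'   two paths given (`c(pos, neg)`), classes are written to separate files.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
    if (is(x, "LabeledProteinSet")) {
        if (length(path) == 2) {
            Biostrings::writeXStringSet(sequences(x)[labels(x) == 1L],
                                        path[1], width = width)
            Biostrings::writeXStringSet(sequences(x)[labels(x) == 0L],
                                        path[2], width = width)
            return(invisible(path))
        }
        x <- sequences(x)
    }
    Biostrings::writeXStringSet(x, path, width = width)
    invisible(path)
}

#' Filter a labeled dataset by length and residue alphabet
#'
#' Drops chains shorter than `minLen` residues and, when `dropUnknown`,
#' chains containing any character outside the 20 canonical amino acids
#' (X, B, Z, J, U, O, gaps, ...).
#'
#' @param ds A [LabeledProteinSet-class].
#' @param minLen Minimum chain length in residues (default 50).
#' @param dropUnknown Drop chains with non-canonical residues (default TRUE).
#' @return The filtered `LabeledProteinSet`, with a `dropped` attribute: a
#'   data.frame of dropped ids and reasons.
#' @examples
#' lps <- LabeledProteinSet(c(a = strrep("A", 49), b = strrep("A", 50)), c(1, 0))
#' filterSequences(lps)
#' @export
filterSequences <- function(ds, minLen = 50L, dropUnknown = TRUE) {
    stopifnot(is(ds, "LabeledProteinSet"))
    seqs <- as.character(sequences(ds))
    ids <- names(seqs)
    tooShort <- nchar(seqs) < minLen
    unknown <- if (dropUnknown) {
        vapply(strsplit(seqs, ""), function(ch)
            any(!ch %in% AA_ALPHABET20), logical(1))
    } else rep(FALSE, length(seqs))
    reason <- rep(NA_character_, length(seqs))
    reason[unknown]  <- "unknown residue"
    reason[tooShort] <- ifelse(unknown[tooShort],
                               "short; unknown residue", "below minimum length")
    keep <- !(tooShort | unknown)
    out <- ds[keep]
    attr(out, "dropped") <- data.frame(id = ids[!keep],
                                       reason = reason[!keep],
                                       stringsAsFactors = FALSE)
    out
}

#' Tokenise one sequence into overlapping k-mer words
#'
#' Windows are `substr(seq, i, i + k - 1)` for `i = 1, 1 + stride, ...` while
#' the window fits; for stride 1 that is `nchar(seq) - k + 1` tokens.
#'
#' @param seq Residue string.
#' @param k Word length in residues (default 3).
#' @param stride Step between window starts (default 1).
#' @return Character vector of tokens, in sequence order.
#' @examples
#' tokenizeSequence("ACDEF", k = 3)  # "ACD" "CDE" "DEF"
#' @export
tokenizeSequence <- function(seq, k = 3L, stride = 1L) {
    stopifnot(k >= 1L, stride >= 1L)
    L <- nchar(seq)
    if (L < k) stopf("sequence shorter than word length (%d < %d)", L, k)
    starts <- seq.int(1L, L - k + 1L, by = stride)
    substring(seq, starts, starts + k - 1L)
}

#' Build a token corpus from a labeled dataset
#'
#' @param ds A [LabeledProteinSet-class]; run [filterSequences()] first so
#'   every chain is at least `k` residues.
#' @param k,stride Tokeniser parameters, see [tokenizeSequence()].
#' @return A [TokenCorpus-class] with one sentence per record, record order
#'   preserved.
#' @export
buildCorpus <- function(ds, k = 3L, stride = 1L) {
    stopifnot(is(ds, "LabeledProteinSet"))
    seqs <- as.character(sequences(ds))
    sentences <- lapply(seq_along(seqs), function(i) {
        tryCatch(tokenizeSequence(seqs[i], k, stride),
                 error = function(e) stopf("record '%s': %s",
                                           names(seqs)[i], conditionMessage(e)))
    })
    new("TokenCorpus", sentences = sentences,
        vocabulary = unique(unlist(sentences, use.names = FALSE)),
        k = as.integer(k), stride = as.integer(stride),
        ids = names(seqs))
}
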