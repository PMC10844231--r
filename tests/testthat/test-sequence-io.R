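test_that("readFastaRecords parses ids, descriptions and wrapped lines", {
    f <- tempfile(fileext = ".fasta")
    writeLines(c(">p1 a DNA-binding protein", "acdef", "ghikl",
                 ">p2", "MNPQR"), f)
    aas <- readFastaRecords(f)
    expect_s4_class(aas, "AAStringSet")
    expect_identical(names(aas), c("p1", "p2"))
    expect_identical(as.character(aas[["p1"]]), "ACDEFGHIKL")
    expect_identical(S4Vectors::mcols(aas)$description,
                     c("a DNA-binding protein", ""))
})

test_that("readFastaRecords rejects malformed input", {
    f <- tempfile(fileext = ".fasta")
    writeLines(c("ACDEF", ">p1", "GHIKL"), f)
    expect_error(readFastaRecords(f), "sequence line before any header at line 1")
    expect_error(readFastaRecords(tempfile()), "file not found")
})

test_that("readLabeledFasta assigns class labels by file", {
    pos <- writeTempFasta(c(a = "ACDEFGHIK", b = "ACDEFGHIL"))
    neg <- writeTempFasta(c(c = "MNPQRSTVW"))
    ds <- readLabeledFasta(pos, neg)
    expect_identical(unname(labels(ds)), c(1L, 1L, 0L))
    expect_identical(names(sequences(ds)), c("a", "b", "c"))
})

test_that("readLabeledTSV matches labels by id and detects gaps", {
    f <- writeTempFasta(c(a = "ACDEF", b = "GHIKL"))
    lab <- tempfile(fileext = ".tsv")
    writeLines(c("b\t0", "a\t1"), lab)
    ds <- readLabeledTSV(f, lab)
    expect_identical(labels(ds), c(a = 1L, b = 0L))
    writeLines("a\t1", lab)
    expect_error(readLabeledTSV(f, lab), "no label for ids: b")
})

test_that("writeFasta round-trips and splits classes across two files", {
    ds <- LabeledProteinSet(c(p = "ACDEFGHIK", n = "MNPQRSTVW"), c(1, 0))
    one <- tempfile(fileext = ".fasta")
    writeFasta(ds, one)
    expect_identical(as.character(readFastaRecords(one)),
                     c(p = "ACDEFGHIK", n = "MNPQRSTVW"))
    two <- c(tempfile(fileext = ".fasta"), tempfile(fileext = ".fasta"))
    writeFasta(ds, two)
    expect_identical(names(readFastaRecords(two[1])), "p")
    expect_identical(names(readFastaRecords(two[2])), "n")
})

test_that("filterSequences applies the length and alphabet rules", {
    ds <- LabeledProteinSet(
        c(short = strrep("A", 49), exact = strrep("C", 50),
          longer = strrep("D", 51), withX = paste0(strrep("E", 60), "X")),
        c(1, 1, 0, 0))
    kept <- filterSequences(ds)
    expect_identical(names(sequences(kept)), c("exact", "longer"))
    dropped <- attr(kept, "dropped")
    expect_identical(dropped$id, c("short", "withX"))
    expect_identical(dropped$reason,
                     c("below minimum length", "unknown residue"))
    ## alphabet check can be disabled
    keptX <- filterSequences(ds, dropUnknown = FALSE)
    expect_true("withX" %in% names(sequences(keptX)))
})

test_that("tokenizeSequence slides a k-residue window", {
    expect_identical(tokenizeSequence("ACDEF", k = 3), c("ACD", "CDE", "DEF"))
    expect_identical(tokenizeSequence("ACDEF", k = 3, stride = 2),
                     c("ACD", "DEF"))
    expect_identical(tokenizeSequence("ACDEF", k = 1),
                     c("A", "C", "D", "E", "F"))
    expect_error(tokenizeSequence("AC", k = 3), "shorter than word length")
})

test_that("buildCorpus preserves record order and reports bad records", {
    ds <- LabeledProteinSet(c(a = "ACDEF", b = "CDEFG"), c(1, 0))
    corpus <- buildCorpus(ds, k = 3)
    expect_identical(corpus@ids, c("a", "b"))
    expect_identical(corpus@sentences[[2]], c("CDE", "DEF", "EFG"))
    expect_setequal(corpus@vocabulary,
                    c("ACD", "CDE", "DEF", "EFG"))
    bad <- LabeledProteinSet(c(a = "ACDEF", tiny = "AC"), c(1, 0))
    expect_error(buildCorpus(bad, k = 3), "record 'tiny'")
})

test_that("LabeledProteinSet enforces its invariants", {
    expect_error(LabeledProteinSet(c(a = "ACD", a = "ACD"), c(1, 0)),
                 "unique")
    expect_error(LabeledProteinSet(c(a = "ACD"), c(2)), "0 or 1")
    expect_error(LabeledProteinSet(c(a = "ACD", b = "ACD"), 1),
                 "one entry per sequence")
    ds <- LabeledProteinSet(c(a = "ACD", b = "CDE"), c(1, 0))
    sub <- ds[2]
    expect_identical(labels(sub), c(b = 0L))
    expect_identical(length(sub), 1L)
})
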