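test_that("FASTA reading validates, labels and preserves order", {
    f <- tempfile(fileext = ".fasta")
    writeLines(c(paste0(">", SAMPLE_ID), SAMPLE_SEQ), f)
    ps <- readPeptideFasta(f, "from_header_prefix")
    expect_s4_class(ps, "PeptideSet")
    expect_length(ps, 1)
    expect_identical(peptideIds(ps), SAMPLE_ID)
    expect_identical(unname(peptideLengths(ps)), 33L)
    expect_identical(as.character(peptideLabels(ps)[[1]]), "ACP")

    # wrapped lines and lowercase are normalized
    writeLines(c(">NACP_9 some description", "glws", "KIKE"), f)
    ps2 <- readPeptideFasta(f, "from_header_prefix")
    expect_identical(unname(peptideSequences(ps2)), "GLWSKIKE")
    expect_identical(as.character(peptideLabels(ps2)[[1]]), "NACP")

    # multi-record order preserved
    writeLines(c(">ACP_b", "AAA", ">ACP_a", "CCC"), f)
    expect_identical(peptideIds(readPeptideFasta(f, "unlabeled")),
                     c("ACP_b", "ACP_a"))
})

test_that("empty files, bad residues and duplicate ids are handled", {
    f <- tempfile(fileext = ".fasta")
    file.create(f)
    expect_length(readPeptideFasta(f, "unlabeled"), 0)

    writeLines(c(">x", "GLXQ"), f)
    expect_error(readPeptideFasta(f, "unlabeled"), "X")
    for (badChar in c("B", "J", "O", "U", "Z", "*")) {
        writeLines(c(">x", paste0("GL", badChar, "Q")), f)
        expect_error(readPeptideFasta(f, "unlabeled"), "non-canonical")
    }
    writeLines(c(">dup", "AAA", ">dup", "CCC"), f)
    expect_error(readPeptideFasta(f, "unlabeled"), "duplicate")
    writeLines(c("no header", "AAA"), f)
    expect_error(readPeptideFasta(f, "unlabeled"), "malformed")
    writeLines(c(">weird_1", "AAA"), f)
    expect_error(readPeptideFasta(f, "from_header_prefix"),
                 "neither ACP nor NACP")
})

test_that("label tables attach by id and missing ids are an error", {
    f <- tempfile(fileext = ".fasta")
    lt <- tempfile(fileext = ".tsv")
    writeLines(c(">p1", "AAA", ">p2", "CCC"), f)
    writeLines(c("p2\tNACP", "p1\tACP"), lt)
    ps <- readPeptideFasta(f, "from_table", labelPath = lt)
    expect_identical(as.character(peptideLabels(ps)),
                     c("ACP", "NACP"))
    writeLines("p1\tACP", lt)
    expect_error(readPeptideFasta(f, "from_table", labelPath = lt),
                 "missing id")
    expect_error(readPeptideFasta(f, "from_table"), "labelPath")
})

test_that("FASTA round-trip reproduces ids, sequences and labels", {
    seqs <- randomPeptides(25, seed = 11)
    labels <- sample(c("ACP", "NACP"), 25, replace = TRUE)
    ps <- peptideSet(seqs, labels, name = "rt")
    f <- tempfile(fileext = ".fasta")
    lt <- tempfile(fileext = ".tsv")
    writePeptideFasta(ps, f, labelPath = lt)
    back <- readPeptideFasta(f, "from_table", labelPath = lt)
    expect_identical(peptideIds(back), peptideIds(ps))
    expect_identical(peptideSequences(back), peptideSequences(ps))
    expect_identical(peptideLabels(back), peptideLabels(ps))
    # unwrapped: one header + one sequence line per record
    expect_length(readLines(f), 2 * length(ps))
    expect_error(writePeptideFasta(peptideSet(character(0)), f), "empty")
})

test_that("split sizes follow round-half-to-even on the training count", {
    cases <- list(c(344, 241, 103), c(2475, 1732, 743), c(10, 5, 5))
    classes <- list(c(138, 206), c(225, 2250), c(5, 5))
    for (i in seq_along(cases)) {
        nc <- classes[[i]]
        ps <- generatePeptides(nc[1], nc[2], lengthRange = c(5, 8),
                               seed = i)
        for (strat in c(TRUE, FALSE)) {
            frac <- if (cases[[i]][1] == 10) 0.5 else 0.7
            sp <- splitDataset(ps, frac, stratified = strat, seed = 42)
            expect_identical(length(sp$train), as.integer(cases[[i]][2]))
            expect_identical(length(sp$test), as.integer(cases[[i]][3]))
        }
    }
})

test_that("split is a seeded partition with stratified proportions", {
    ps <- generatePeptides(40, 80, lengthRange = c(5, 10), seed = 3)
    sp1 <- splitDataset(ps, 0.7, seed = 9)
    sp2 <- splitDataset(ps, 0.7, seed = 9)
    expect_identical(peptideIds(sp1$train), peptideIds(sp2$train))
    expect_length(intersect(peptideIds(sp1$train), peptideIds(sp1$test)), 0)
    expect_setequal(c(peptideIds(sp1$train), peptideIds(sp1$test)),
                    peptideIds(ps))
    # class proportions: 0.7*40 = 28, 0.7*80 = 56
    trainLab <- table(peptideLabels(sp1$train))
    expect_identical(as.integer(trainLab[["ACP"]]), 28L)
    expect_identical(as.integer(trainLab[["NACP"]]), 56L)
    sp3 <- splitDataset(ps, 0.7, seed = 10)
    expect_false(identical(peptideIds(sp1$train), peptideIds(sp3$train)))
    expect_error(splitDataset(ps, 1.2), "trainFraction")
    expect_error(splitDataset(ps, 0), "trainFraction")
})
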