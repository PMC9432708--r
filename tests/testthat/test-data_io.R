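test_that("save/load round-trips are cell-exact in both layouts", {
    set.seed(42)
    b <- matrix(round(runif(12), 6), 3, 4,
                dimnames = list(paste0("s", 1:3), paste0("cg0", 1:4)))
    b[2, 3] <- NA
    m <- MethylationExperiment(b, ages = c(25, 50, 75))
    for (layout in c("samples-in-rows", "cpgs-in-rows")) {
        path <- withr::local_tempfile(fileext = ".tsv")
        saveMethylationTable(m, path, layout = layout)
        m2 <- loadMethylationTable(path, layout = layout)
        expect_identical(cpgIds(m2), cpgIds(m))
        expect_identical(sampleIds(m2), sampleIds(m))
        expect_equal(betas(m2), betas(m))
        expect_equal(unname(ages(m2)), c(25, 50, 75))
        # a second save of the reloaded object is byte-identical
        path2 <- withr::local_tempfile(fileext = ".tsv")
        saveMethylationTable(m2, path2, layout = layout)
        expect_identical(readLines(path2), readLines(path))
    }
})

test_that("malformed tables are rejected with informative errors", {
    writeTable <- function(lines) {
        path <- withr::local_tempfile(fileext = ".tsv",
                                      .local_envir = parent.frame())
        writeLines(lines, path)
        path
    }
    # beta outside [0,1]
    p <- writeTable(c("sample_id\tage\tcgA\tcgB",
                      "s1\t30\t0.5\t1.7",
                      "s2\t40\t0.2\t0.3"))
    expect_error(loadMethylationTable(p), "out of \\[0, 1\\]")
    # unparseable cell names row and column
    p <- writeTable(c("sample_id\tage\tcgA",
                      "s1\t30\toops"))
    expect_error(loadMethylationTable(p), "oops.*cgA")
    # duplicate CpG label in the header (samples-in-rows)
    p <- writeTable(c("sample_id\tage\tcgA\tcgA",
                      "s1\t30\t0.5\t0.6"))
    expect_error(loadMethylationTable(p), "duplicate")
    # duplicate CpG label in the id column (cpgs-in-rows)
    p <- writeTable(c("ID_REF\ts1\ts2", "age\t30\t40",
                      "cgA\t0.5\t0.6", "cgA\t0.2\t0.3"))
    expect_error(loadMethylationTable(p, layout = "cpgs-in-rows"),
                 "duplicate CpG")
    # missing age column is fatal for the supervised loader only
    p <- writeTable(c("sample_id\tcgA", "s1\t0.5", "s2\t0.9"))
    expect_error(loadMethylationTable(p), "age column")
    m <- loadPredictionMatrix(p)
    expect_true(all(is.na(ages(m))))
    # missing tokens are accepted as NA
    p <- writeTable(c("sample_id\tage\tcgA\tcgB",
                      "s1\t30\tNA\t0.3",
                      "s2\t40\tNaN\t"))
    m <- loadMethylationTable(p)
    expect_identical(sum(is.na(betas(m))), 3L)
})

test_that("dropIncompleteCpgs keeps exactly the common complete set", {
    set.seed(7)
    mk <- function(naCells) {
        b <- matrix(runif(40), 4, 10,
                    dimnames = list(paste0("s", 1:4), paste0("cg", 1:10)))
        for (cell in naCells) b[cell[1], cell[2]] <- NA
        MethylationExperiment(b, ages = c(20, 35, 50, 65))
    }
    m1 <- mk(list(c(1, 2)))           # cg2 incomplete in m1
    m2 <- mk(list(c(3, 5), c(2, 9)))  # cg5, cg9 incomplete in m2
    res <- dropIncompleteCpgs(m1, m2)

    # brute-force oracle: scan every CpG in both matrices
    expected <- Filter(function(cg) {
        !anyNA(betas(m1)[, cg]) && !anyNA(betas(m2)[, cg])
    }, paste0("cg", 1:10))
    expect_identical(cpgIds(res[[1]]), expected)
    expect_identical(cpgIds(res[[2]]), expected)
    expect_length(expected, 7L)
    expect_identical(sampleIds(res[[1]]), sampleIds(m1))

    # single complete matrix is unchanged
    m3 <- mk(list())
    expect_identical(betas(dropIncompleteCpgs(m3)), betas(m3))

    # idempotent, and the retained set is order-insensitive
    again <- dropIncompleteCpgs(res[[1]], res[[2]])
    expect_identical(cpgIds(again[[1]]), expected)
    swapped <- dropIncompleteCpgs(m2, m1)
    expect_setequal(cpgIds(swapped[[1]]), expected)

    # empty intersection errors
    mAllNa <- mk(lapply(1:10, function(j) c(1, j)))
    expect_error(dropIncompleteCpgs(m1, mAllNa), "empty feature space")
})

test_that("annotateFeatures preserves order and blanks unknown CpGs", {
    ann <- c(cg16867657 = "ELOVL2", cg10501210 = "C1orf132",
             cg22454769 = "FHL2", cg04875128 = "OTUD7A",
             cg19283806 = "CCDC102B")
    fs <- featureSet(c("cg16867657", "cgUNKNOWN", "cg19283806"))
    out <- annotateFeatures(fs, ann)
    expect_identical(out$cpg_id, featureIds(fs))
    expect_identical(out$gene_symbol, c("ELOVL2", "", "CCDC102B"))

    # round-trip through the two-column table reader
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("cpg_id\tgene_symbol",
                 paste(names(ann), ann, sep = "\t")), path)
    ann2 <- loadAnnotationTable(path)
    full <- annotateFeatures(featureSet(names(ann)), ann2)
    expect_identical(full$gene_symbol,
                     c("ELOVL2", "C1orf132", "FHL2", "OTUD7A",
                       "CCDC102B"))
    # conflicting duplicate keys are rejected
    writeLines(c("cpg_id\tgene_symbol", "cgA\tX", "cgA\tY"), path)
    expect_error(loadAnnotationTable(path), "conflicting")
})

test_that("out-of-range and shape errors at construction", {
    b <- matrix(c(0.5, 1.7), 1, 2,
                dimnames = list("s1", c("cgA", "cgB")))
    expect_error(MethylationExperiment(b, ages = 30), "\\[0, 1\\]")
    b2 <- matrix(0.5, 2, 2,
                 dimnames = list(c("s1", "s2"), c("cgA", "cgB")))
    expect_error(MethylationExperiment(b2, ages = 30), "one entry per")
    expect_error(MethylationExperiment(b2, ages = c(-1, 30)),
                 "non-negative")
})
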