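test_that("omics matrices round-trip through delimited text in either orientation", {
    df <- data.frame(sample_id = c("S1", "S2", "S3"),
                     g1 = c(1.5, 2, NA), g2 = c(-1, 0.25, 3))
    tf <- writeTempMatrix(df)
    v <- readOmicsMatrix(tf)
    expect_s4_class(v, "OmicsView")
    expect_identical(sampleNames(v), c("S1", "S2", "S3"))
    expect_identical(featureNames(v), c("g1", "g2"))
    expect_equal(omicsValues(v)[, "g1"], c(S1 = 1.5, S2 = 2, S3 = NA))

    ## same data transposed, features in rows
    dft <- data.frame(feature_id = c("g1", "g2"),
                      S1 = c(1.5, -1), S2 = c(2, 0.25), S3 = c(NA, 3))
    tft <- writeTempMatrix(dft)
    vt <- readOmicsMatrix(tft, orientation = "features_in_rows")
    expect_equal(omicsValues(vt), omicsValues(v))

    ## comma dialect from .csv extension
    tfc <- writeTempMatrix(df, ext = ".csv", sep = ",")
    expect_equal(omicsValues(readOmicsMatrix(tfc)), omicsValues(v))

    ## write -> read reproduces IDs and values exactly
    full <- filterMissingFeatures(v, maxMissingRate = 0.5)
    out <- tempfile(fileext = ".tsv")
    writeOmicsMatrix(full, out)
    expect_equal(omicsValues(readOmicsMatrix(out)), omicsValues(full))
})

test_that("malformed matrices are rejected with informative errors", {
    dup <- data.frame(sample_id = c("S1", "S1", "S2"), g1 = 1:3)
    expect_error(readOmicsMatrix(writeTempMatrix(dup)), "S1")
    bad <- data.frame(sample_id = c("S1", "S2"), g1 = c("1.5", "oops"))
    expect_error(readOmicsMatrix(writeTempMatrix(bad)), "row 2.*g1|g1.*row 2")
    expect_error(readOmicsMatrix(tempfile()), "not found")
})

test_that("missing-rate filter uses a strict threshold, imputes the mean, and is idempotent", {
    set.seed(7)
    m <- matrix(rnorm(20 * 3), 20, 3,
                dimnames = list(sprintf("S%02d", 1:20), c("a", "b", "c")))
    m[1:2, 1] <- NA          # 10% missing -> dropped at 0.05
    m[1, 2] <- NA            # 5% exactly -> retained, mean-imputed
    v <- OmicsView(m)
    f <- filterMissingFeatures(v, maxMissingRate = 0.05)
    expect_identical(featureNames(f), c("b", "c"))
    expect_identical(attr(f, "dropped"), "a")
    expect_equal(omicsValues(f)["S01", "b"], mean(m[-1, 2]))

    ## fully observed matrix is untouched; filtering is idempotent
    clean <- OmicsView(matrix(rnorm(40), 20, 2,
                              dimnames = list(sprintf("S%02d", 1:20),
                                              c("u", "w"))))
    expect_equal(omicsValues(filterMissingFeatures(clean)),
                 omicsValues(clean))
    expect_equal(omicsValues(filterMissingFeatures(f)), omicsValues(f))

    allNA <- OmicsView(matrix(NA_real_, 10, 2,
                              dimnames = list(sprintf("S%02d", 1:10),
                                              c("a", "b"))))
    expect_error(filterMissingFeatures(allNA), "no features survive")
})

test_that("sample alignment returns the intersection in one common order", {
    mk <- function(ids) OmicsView(matrix(seq_along(ids), length(ids), 1,
                                         dimnames = list(ids, "f")))
    surv <- SurvivalTable(c("C", "D", "B", "A"), c(5, 6, 7, 8),
                          c(1L, 0L, 1L, 1L))
    al <- alignSamples(mk(c("A", "B", "C", "D")), mk(c("B", "C", "D")), surv)
    expect_identical(sampleNames(al$x), c("B", "C", "D"))
    expect_identical(sampleNames(al$y), sampleNames(al$x))
    expect_identical(sampleNames(al$surv), sampleNames(al$x))
    expect_equal(survivalTime(al$surv), c(7, 5, 6))

    ## identity when all inputs already share samples
    surv3 <- SurvivalTable(c("A", "B", "C"), 1:3, c(1L, 1L, 0L))
    al2 <- alignSamples(mk(c("A", "B", "C")), mk(c("A", "B", "C")), surv3)
    expect_identical(sampleNames(al2$x), c("A", "B", "C"))

    ## fewer than 3 shared samples is an error naming the counts
    expect_error(alignSamples(mk(c("A", "B", "C")), mk(c("B", "C", "D")),
                              SurvivalTable(c("B", "X", "Y"), 1:3,
                                            c(1L, 1L, 1L))),
                 "fewer than 3")
})

test_that("standardization centers, scales with n-1, drops constants, and is idempotent", {
    m <- matrix(c(1, 2, 3, 5, 5, 5, 0, 2, 4), 3, 3,
                dimnames = list(c("S1", "S2", "S3"), c("a", "const", "b")))
    expect_warning(s <- standardizeColumns(OmicsView(m)), "constant")
    expect_identical(featureNames(s), c("a", "b"))
    expect_identical(attr(s, "dropped"), "const")
    expect_equal(omicsValues(s)[, "a"], c(S1 = -1, S2 = 0, S3 = 1))
    s2 <- standardizeColumns(s)
    expect_equal(omicsValues(s2), omicsValues(s), tolerance = 1e-12)
    expect_error(standardizeColumns(OmicsView(
        matrix(c(NA, 1), 2, 1, dimnames = list(c("S1", "S2"), "a")))),
        "fully observed")
})

test_that("GMT parsing builds the union universe and flags malformed lines", {
    tf <- tempfile(fileext = ".gmt")
    writeLines(c("setA\tdesc\tg1\tg2", "setB\tdesc\tg2\tg3"), tf)
    db <- readGMT(tf)
    expect_identical(sort(geneUniverse(db)), c("g1", "g2", "g3"))
    expect_identical(geneSets(db)$setA, c("g1", "g2"))

    writeLines(c("setA\tdesc\tg1", "broken_line"), tf)
    expect_error(readGMT(tf), "line 2")
    writeLines(character(0), tf)
    expect_error(readGMT(tf), "no gene sets")
    writeLines("setA\tdesc\tg1\tg1\tg2", tf)
    expect_warning(db2 <- readGMT(tf), "duplicate")
    expect_identical(geneSets(db2)$setA, c("g1", "g2"))

    ## GMT round-trip
    out <- tempfile(fileext = ".gmt")
    writeGMT(db2, out)
    expect_identical(geneSets(readGMT(out)), geneSets(db2))
})

test_that("survival tables validate their invariants", {
    tf <- tempfile(fileext = ".tsv")
    write.table(data.frame(sample_id = c("S1", "S2"), time = c(3, 9),
                           event = c(1, 0)),
                tf, sep = "\t", quote = FALSE, row.names = FALSE)
    sv <- readSurvivalTable(tf)
    expect_equal(survivalTime(sv), c(3, 9))
    expect_error(SurvivalTable("S1", -2, 1L), "positive")
    expect_error(SurvivalTable("S1", 2, 3L), "0.*1|event")
    expect_error(SurvivalTable(c("S1", "S1"), c(1, 2), c(1L, 0L)),
                 "duplicate")
})
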