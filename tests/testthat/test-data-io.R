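test_that("a minimal WONDER-style rectangle parses into a surface", {
    lines <- c(wonderHeader,
               wonderRow(60, 1999, 12, 100000),
               wonderRow(61, 1999, 15, 100000),
               wonderRow(60, 2000, 11, 101000),
               wonderRow(61, 2000, 14, 101000))
    s <- readWonderExport(writeWonderLines(lines), "unit")
    expect_s4_class(s, "MortalitySurface")
    expect_identical(ages(s), 60:61)
    expect_identical(periods(s), 1999:2000)
    expect_identical(as.vector(deaths(s)), c(12, 15, 11, 14))
    expect_equal(population(s)[2, 2], 101000)
    expect_identical(stratumLabel(s), "unit")
})

test_that("a missing cell is an error naming the (age, year) cell", {
    lines <- c(wonderHeader,
               wonderRow(60, 1999, 12, 100000),
               wonderRow(61, 1999, 15, 100000),
               wonderRow(60, 2000, 11, 101000))
    expect_error(readWonderExport(writeWonderLines(lines), "unit"),
                 "61, 2000")
})

test_that("trailing notes block and CRLF endings do not change the parse", {
    data <- c(wonderHeader,
              wonderRow(60, 1999, 12, 100000),
              wonderRow(61, 1999, 15, 100000),
              wonderRow(60, 2000, 11, 101000),
              wonderRow(61, 2000, 14, 101000))
    notes <- c("\"Notes\"", "\"Query date: synthetic\"",
               "\"Caveats apply\"")
    plain <- readWonderExport(writeWonderLines(data), "s")
    withNotes <- readWonderExport(writeWonderLines(c(data, notes)), "s")
    crlf <- readWonderExport(writeWonderLines(c(data, notes), eol = "\r\n"),
                             "s")
    expect_identical(deaths(plain), deaths(withNotes))
    expect_identical(deaths(plain), deaths(crlf))
    expect_identical(population(plain), population(crlf))
})

test_that("suppressed cells are refused, listing the cells", {
    lines <- c(wonderHeader,
               wonderRow(60, 1999, "Suppressed", 100000),
               wonderRow(61, 1999, 15, 100000),
               wonderRow(60, 2000, 11, 101000),
               wonderRow(61, 2000, 14, "Unreliable"))
    err <- expect_error(readWonderExport(writeWonderLines(lines), "s"),
                        "suppressed")
    expect_match(conditionMessage(err), "age 60, year 1999")
    expect_match(conditionMessage(err), "age 61, year 2000")
})

test_that("non-numeric data values report the line number", {
    lines <- c(wonderHeader,
               wonderRow(60, 1999, 12, 100000),
               wonderRow(61, 1999, "twelve", 100000))
    expect_error(readWonderExport(writeWonderLines(lines), "s"),
                 "line 3")
})

test_that("rows outside a configured age/period window are dropped", {
    lines <- c(wonderHeader,
               wonderRow(59, 1999, 9, 90000),
               wonderRow(60, 1999, 12, 100000),
               wonderRow(61, 1999, 15, 100000),
               wonderRow(59, 2000, 8, 90000),
               wonderRow(60, 2000, 11, 101000),
               wonderRow(61, 2000, 14, 101000))
    s <- readWonderExport(writeWonderLines(lines), "s", ages = 60:61)
    expect_identical(ages(s), 60:61)
    expect_identical(dim(deaths(s)), c(2L, 2L))
})

test_that("the bundled synthetic export fixture parses", {
    path <- system.file("extdata", "synthetic_wonder_export.tsv",
                        package = "apcmort")
    s <- readWonderExport(path, "synthetic example")
    expect_identical(ages(s), 60:62)
    expect_identical(periods(s), 1999:2001)
})

test_that("prevalence CSV reading sorts, and rejects duplicates and bad ranges", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("year,percent", "1970,37.4", "1965,42.4"), path)
    p <- readPrevalenceCsv(path)
    expect_identical(years(p), c(1965L, 1970L))
    expect_equal(prevalence(p), c(42.4, 37.4))

    writeLines(c("year,percent", "1965,42.4", "1965,37.4"), path)
    expect_error(readPrevalenceCsv(path), "duplicate")

    writeLines(c("year,percent", "1965,105"), path)
    expect_error(readPrevalenceCsv(path), "\\[0, 100\\]")
})

test_that("rate series round-trip through CSV within 1e-9 relative", {
    s <- RateSeries(1999:2003, c(247.875, 250.1, pi * 100, 260.123456789,
                                 1e-3),
                    kind = "age_cohort_adjusted", linkVariant = "log")
    path <- withr::local_tempfile(fileext = ".csv")
    writeRateSeriesCsv(s, path)
    s2 <- readRateSeriesCsv(path)
    expect_identical(years(s2), years(s))
    expect_equal(rates(s2), rates(s), tolerance = 1e-9)
    expect_identical(s2@kind, "age_cohort_adjusted")
    expect_identical(s2@linkVariant, "log")

    one <- RateSeries(2000L, 50)
    writeRateSeriesCsv(one, path)
    expect_identical(length(readLines(path)), 2L)  # header + 1 row
})

test_that("an empty rate series cannot be constructed", {
    expect_error(RateSeries(integer(0), numeric(0)), "non-empty")
})

test_that("surfaces round-trip through tidy CSV losslessly", {
    s <- tinySurface()
    path <- withr::local_tempfile(fileext = ".csv")
    writeSurfaceCsv(s, path)
    s2 <- readSurfaceCsv(path, stratumLabel(s))
    expect_identical(ages(s2), ages(s))
    expect_identical(periods(s2), periods(s))
    expect_equal(deaths(s2), deaths(s))
    expect_equal(population(s2), population(s))
})

test_that("effect estimates round-trip through tidy CSV", {
    cfg <- tinyConfig()
    truth <- generateTrueEffects(cfg)
    path <- withr::local_tempfile(fileext = ".csv")
    writeEffectsCsv(truth, path)
    back <- readEffectsCsv(path)
    expect_equal(intercept(back), intercept(truth))
    expect_equal(ageEffects(back), ageEffects(truth))
    expect_equal(periodEffects(back), periodEffects(truth))
    expect_equal(cohortEffects(back), cohortEffects(truth))
})

test_that("surface validity enforces the Lexis-rectangle contract", {
    expect_error(
        MortalitySurface(matrix(-1, 2, 2), matrix(100, 2, 2), 60:61,
                         1999:2000),
        "non-negative")
    expect_error(
        MortalitySurface(matrix(5, 2, 2), matrix(0, 2, 2), 60:61,
                         1999:2000),
        "> 0")
    expect_error(
        MortalitySurface(matrix(200, 2, 2), matrix(100, 2, 2), 60:61,
                         1999:2000),
        "exceed")
    expect_error(
        MortalitySurface(matrix(5, 2, 2), matrix(100, 2, 2), c(60L, 62L),
                         1999:2000),
        "step 1")
})
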