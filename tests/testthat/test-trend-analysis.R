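test_that("linear interpolation reproduces knots and midpoints", {
    knots <- PrevalenceSeries(c(1999, 2001), c(30.5, 34.5))
    out <- interpolateAnnual(knots, 1999:2001)
    expect_equal(prevalence(out), c(30.5, 32.5, 34.5))
    expect_equal(prevalence(interpolateAnnual(knots, 2001L)), 34.5)
    expect_error(interpolateAnnual(knots, 1998:2001), "extrapolation")
})

test_that("interpolation agrees with a segment-search oracle on random knots", {
    set.seed(14)
    for (rep in 1:5) {
        ky <- sort(sample(1950:2010, 6))
        kv <- runif(6, 10, 60)
        knots <- PrevalenceSeries(ky, kv)
        targets <- seq.int(min(ky), max(ky))
        got <- prevalence(interpolateAnnual(knots, targets))
        oracle <- vapply(targets, function(t) {
            seg <- max(which(ky <= t))
            if (seg == length(ky)) return(kv[seg])
            kv[seg] + (kv[seg + 1] - kv[seg]) * (t - ky[seg]) /
                (ky[seg + 1] - ky[seg])
        }, numeric(1))
        expect_equal(got, oracle)
        # never exceeds the local knot envelope
        for (s in seq_len(length(ky) - 1)) {
            inSeg <- targets >= ky[s] & targets <= ky[s + 1]
            expect_true(all(got[inSeg] >= min(kv[s:(s + 1)]) - 1e-12))
            expect_true(all(got[inSeg] <= max(kv[s:(s + 1)]) + 1e-12))
        }
    }
})

test_that("pearsonCorrelation matches the textbook formula and t-test", {
    set.seed(21)
    x <- rnorm(20); y <- 0.6 * x + rnorm(20)
    res <- pearsonCorrelation(x, y)
    rOracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res@r, rOracle, tolerance = 1e-12)
    tOracle <- rOracle * sqrt((20 - 2) / (1 - rOracle^2))
    expect_equal(res@tStatistic, tOracle, tolerance = 1e-12)
    expect_identical(res@df, 18L)
    expect_equal(res@pValue, 2 * pt(-abs(tOracle), df = 18),
                 tolerance = 1e-12)
})

test_that("pearsonCorrelation handles exact and degenerate cases", {
    x <- c(1, 3, 4, 8)
    expect_equal(pearsonCorrelation(x, 2 * x + 1)@r, 1)
    expect_equal(pearsonCorrelation(x, -x)@r, -1)
    expect_error(pearsonCorrelation(x, rep(2, 4)), "constant")
    expect_error(pearsonCorrelation(1:2, 2:3), "at least 3")
    expect_error(pearsonCorrelation(1:4, 1:5), "equal length")
})

test_that("pearsonCorrelation is symmetric and affine-invariant", {
    set.seed(33)
    x <- rnorm(15); y <- rnorm(15)
    r <- pearsonCorrelation(x, y)@r
    expect_equal(pearsonCorrelation(y, x)@r, r, tolerance = 1e-12)
    expect_equal(pearsonCorrelation(3 * x - 7, y)@r, r, tolerance = 1e-12)
    expect_equal(pearsonCorrelation(x, -2 * y + 1)@r, -r,
                 tolerance = 1e-12)
})

test_that("rate/obesity correlation aligns by calendar year", {
    rs <- RateSeries(2000:2009, 100 + (1:10) * 3)
    exact <- PrevalenceSeries(2000:2009, 20 + (1:10) * 1.5)
    expect_equal(correlateRatesWithObesity(rs, exact)@r, 1)

    # same values supplied out of order: PrevalenceSeries sorts by year, so
    # alignment is by year, not by input position
    shuffle <- sample(10)
    shuffled <- PrevalenceSeries((2000:2009)[shuffle],
                                 (20 + (1:10) * 1.5)[shuffle])
    expect_equal(correlateRatesWithObesity(rs, shuffled)@r, 1)

    # partial overlap restricted to common years
    partial <- PrevalenceSeries(2005:2012, c(27.5 + (0:4) * 1.5, 1, 2, 3))
    res <- correlateRatesWithObesity(rs, partial)
    expect_identical(res@n, 5L)
    expect_equal(res@r, 1)

    expect_error(
        correlateRatesWithObesity(rs, PrevalenceSeries(2008:2009, c(1, 2))),
        "3 overlapping")
})

test_that("cohort/smoking pairing uses the window and birth-year alignment", {
    # linear declining cohort truth: smoking affine in the cohort effect
    cfg <- SyntheticConfig(orthogonalize = FALSE)
    truth <- generateTrueEffects(cfg)
    g <- cohortEffects(truth)
    knotYears <- c(1965, 1970, 1974, 1980, 1990)
    smoking <- PrevalenceSeries(knotYears,
                                40 + 20 * g[as.character(knotYears)],
                                label = "synthetic smoking")
    res <- correlateCohortEffectsWithSmoking(truth, smoking)
    expect_identical(res@n, 26L)  # 1965..1990 inclusive
    expect_equal(res@r, 1)

    # negative affine map flips the sign
    smokingNeg <- PrevalenceSeries(knotYears,
                                   40 - 20 * g[as.character(knotYears)])
    expect_equal(correlateCohortEffectsWithSmoking(truth, smokingNeg)@r, -1)

    # lag shifts the cohort side of the pairing
    lagged <- correlateCohortEffectsWithSmoking(truth, smoking, lag = 3L)
    expect_identical(lagged@n, 26L)
    expect_equal(lagged@r, 1)  # linear cohort effects: still exactly affine

    expect_error(
        correlateCohortEffectsWithSmoking(truth, smoking,
                                          cohortWindow = c(1900, 1990)),
        "cohort range")
})
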