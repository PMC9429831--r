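test_that("crude rates equal total deaths over total population, scaled", {
    s <- MortalitySurface(matrix(c(20, 30), 2, 1),
                          matrix(c(40000, 60000), 2, 1), 60:61, 2000L)
    expect_equal(rates(crudeRateSeries(s)), 50)  # 50 / 1e5

    # homogeneity: doubling the population halves every crude rate
    surf <- tinySurface()
    doubled <- MortalitySurface(deaths(surf), population(surf) * 2,
                                ages(surf), periods(surf))
    expect_equal(rates(crudeRateSeries(doubled)),
                 rates(crudeRateSeries(surf)) / 2)
})

test_that("crude rates equal a per-period brute-force sum", {
    surf <- tinySurface(seed = 5L)
    got <- rates(crudeRateSeries(surf))
    for (j in seq_along(periods(surf))) {
        num <- 0; den <- 0
        for (i in seq_along(ages(surf))) {
            num <- num + deaths(surf)[i, j]
            den <- den + population(surf)[i, j]
        }
        expect_equal(got[j], num / den * rateScale(surf))
    }
})

test_that("direct standardization reduces to known special cases", {
    ages <- 60:64
    # age-constant rates: standardized equals crude under any weights
    pop <- matrix(rep(c(1e5, 2e5, 3e5), length.out = 5 * 4), 5, 4)
    dth <- pop * 2e-3
    s <- MortalitySurface(dth, pop, ages, 2001:2004)
    stdU <- StandardPopulation(ages, rep(1, 5))
    expect_equal(rates(ageStandardizedSeries(s, stdU)),
                 rates(crudeRateSeries(s)))

    # weights concentrated (almost) on one age: that age's specific rate
    surf2 <- MortalitySurface(matrix(c(10, 40), 2, 1),
                              matrix(1e5, 2, 1), 60:61, 2000L)
    stdA <- StandardPopulation(60:61, c(1, 1e-12))
    expect_equal(rates(ageStandardizedSeries(surf2, stdA)), 10,
                 tolerance = 1e-9)
})

test_that("direct standardization matches the weighted-sum oracle", {
    surf <- tinySurface(seed = 8L)
    set.seed(8)
    w <- runif(length(ages(surf)), 0.5, 2)
    std <- StandardPopulation(ages(surf), w)
    got <- rates(ageStandardizedSeries(surf, std))
    wn <- w / sum(w)
    for (j in seq_along(periods(surf))) {
        oracle <- sum(wn * deaths(surf)[, j] / population(surf)[, j]) *
            rateScale(surf)
        expect_equal(got[j], oracle)
    }
})

test_that("standardization requires matching age support", {
    surf <- tinySurface()
    expect_error(
        ageStandardizedSeries(surf, StandardPopulation(41:50, rep(1, 10))),
        "match")
})

test_that("the age-cohort adjusted closed form evaluates both link variants", {
    est <- new("EffectEstimates", intercept = -7,
               ageEffects = setNames(c(-1, 0.5, 0.5), 60:62),
               periodEffects = setNames(c(-0.2, 0, 0.2), 2000:2002),
               cohortEffects = setNames(c(-0.6, 0.3, 0.3), 1938:1940),
               deviance = NA_real_, converged = TRUE, nIterations = 0L)
    # third period: s = -7 + 0.2 + 0.5 + 0.3 = -6
    logV <- ageCohortAdjustedSeries(est, "log")
    logitV <- ageCohortAdjustedSeries(est, "logit")
    expect_equal(rates(logV)[3], 1e5 * exp(-6))          # 247.875...
    expect_equal(rates(logV)[3], 247.875, tolerance = 1e-5)
    expect_equal(rates(logitV)[3], 1e5 * exp(-6) / (1 + exp(-6)))
    expect_equal(rates(logitV)[3], 247.262, tolerance = 1e-5)
    expect_identical(logitV@linkVariant, "logit")
})

test_that("all-zero effects with u = log(1e-3) give exactly 100 per 1e5", {
    est <- new("EffectEstimates", intercept = log(1e-3),
               ageEffects = setNames(numeric(3), 60:62),
               periodEffects = setNames(numeric(3), 2000:2002),
               cohortEffects = setNames(numeric(5), 1938:1942),
               deviance = NA_real_, converged = TRUE, nIterations = 0L)
    expect_equal(rates(ageCohortAdjustedSeries(est, "log")), rep(100, 3))
})

test_that("adjusted rates are monotone in the period effects", {
    est <- new("EffectEstimates", intercept = -7,
               ageEffects = setNames(c(-0.2, 0, 0.2), 60:62),
               periodEffects = setNames(c(-0.3, -0.1, 0.1, 0.3),
                                        2000:2003),
               cohortEffects = setNames(numeric(6), 1938:1943),
               deviance = NA_real_, converged = TRUE, nIterations = 0L)
    for (variant in c("logit", "log"))
        expect_true(all(diff(rates(
            ageCohortAdjustedSeries(est, variant))) > 0))
})

test_that("adjusted rates depend on beta and u only through their sum", {
    est <- generateTrueEffects(tinyConfig())
    # beta_j + c paired with u - c leaves s_j = u + beta_j + medians intact
    shift <- 0.37
    sFormula <- 1e5 * exp((intercept(est) - shift) +
                          (periodEffects(est) + shift) +
                          medianEffect(ageEffects(est)) +
                          medianEffect(cohortEffects(est)))
    expect_equal(unname(rates(ageCohortAdjustedSeries(est, "log"))),
                 unname(sFormula))
})

test_that("logit and log variants differ by under 0.5% at realistic rates", {
    cfg <- tinyConfig()
    surf <- simulateSurface(generateTrueEffects(cfg), cfg)
    fit <- fitIntrinsicEstimator(surf, buildDesign(40:49, 2001:2008))
    rLog <- rates(ageCohortAdjustedSeries(fit, "log"))
    rLogit <- rates(ageCohortAdjustedSeries(fit, "logit"))
    expect_true(all(rLog < 500))  # premise of the bound
    expect_true(all(abs(rLog - rLogit) / rLog < 0.005))
    expect_true(all(rLogit < rLog))  # inverse-logit is always the smaller
})

test_that("medianEffect follows the order-statistics definition", {
    expect_equal(medianEffect(c(1, 2, 3, 4)), 2.5)
    expect_equal(medianEffect(3), 3)
    set.seed(11)
    for (n in c(4, 9, 20)) {
        x <- rnorm(n)
        s <- sort(x)
        oracle <- if (n %% 2 == 1) s[(n + 1) / 2] else
            (s[n / 2] + s[n / 2 + 1]) / 2
        expect_equal(medianEffect(x), oracle)
    }
    expect_error(medianEffect(numeric(0)), "empty")
})
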