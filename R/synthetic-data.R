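#' Configure the synthetic mortality-surface generator
#'
#' The generator emulates the structure the APC analysis assumes: Poisson
#' death counts whose log rate is additive in a curvilinear (quadratic) age
#' effect, a piecewise-linear period effect with one breakpoint, and a
#' linearly declining cohort effect. Defaults describe a plausible
#' heart-disease-like stratum on the 25-84 x 1999-2018 grid: baseline death
#' proportion 1.5 per 1,000 person-years, age risk rising to a vertex at 80,
#' period risk flat before 2007 and rising afterwards, and cohort risk
#' declining 2 percent per birth year on the log scale.
#'
#' @param ages,periods integer grids (defaults \code{25:84},
#'   \code{1999:2018}).
#' @param baselineLogRate intercept on the log proportion scale (default
#'   \code{log(1.5e-3)}).
#' @param ageCurvature,ageVertex quadratic age effect
#'   \eqn{-c(\mathrm{age}-v)^2} before centering (defaults \code{8e-4}, 80).
#' @param periodBreak,periodSlope1,periodSlope2 breakpoint year and the log
#'   slopes before/after it (defaults 2007, 0, 0.025 per year).
#' @param cohortSlope log-rate slope per birth year (default \code{-0.02}).
#' @param populationPerCell person-years per cell, scalar or one value per
#'   age (default \code{1e6}).
#' @param seed RNG seed (default 20220817).
#' @param orthogonalize project the stacked true coefficients off the design
#'   null vector (default TRUE), making the truth the exact target of the
#'   Intrinsic Estimator.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
SyntheticConfig <- function(ages = 25:84, periods = 1999:2018,
                            baselineLogRate = log(1.5e-3),
                            ageCurvature = 8e-4, ageVertex = 80,
                            periodBreak = 2007, periodSlope1 = 0,
                            periodSlope2 = 0.025,
                            cohortSlope = -0.02,
                            populationPerCell = 1e6,
                            seed = 20220817L,
                            orthogonalize = TRUE) {
    new("SyntheticConfig",
        ages = as.integer(ages), periods = as.integer(periods),
        baselineLogRate = as.numeric(baselineLogRate),
        ageCurvature = as.numeric(ageCurvature),
        ageVertex = as.numeric(ageVertex),
        periodBreak = as.numeric(periodBreak),
        periodSlope1 = as.numeric(periodSlope1),
        periodSlope2 = as.numeric(periodSlope2),
        cohortSlope = as.numeric(cohortSlope),
        populationPerCell = as.numeric(populationPerCell),
        seed = as.integer(seed),
        orthogonalize = isTRUE(orthogonalize))
}

#' Generate ground-truth APC effects
#'
#' Deterministically evaluates the configured effect shapes, centers each
#' block, and (by default) projects the stacked coefficient vector off the
#' design's null vector so that the Intrinsic Estimator is a consistent
#' estimator of this truth. Without orthogonalization the generated effects
#' contain a component along the unidentified linear-trend direction, which
#' no APC estimator can recover — useful for demonstrating the
#' identification problem, not for recovery tests.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return an \linkS4class{EffectEstimates} (deviance NA) acting as ground
#'   truth. Errors if any implied cell death proportion leaves (0, 0.1).
#' @export
generateTrueEffects <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    ages <- config@ages; periods <- config@periods
    cohortYears <- seq.int(min(periods) - max(ages),
                           max(periods) - min(ages))

    a <- -config@ageCurvature * (ages - config@ageVertex)^2
    a <- a - mean(a)
    brk <- config@periodBreak
    b <- config@periodSlope1 * (pmin(periods, brk) - brk) +
        config@periodSlope2 * (pmax(periods, brk) - brk)
    b <- b - mean(b)
    g <- config@cohortSlope * (cohortYears - mean(cohortYears))
    g <- g - mean(g)

    truth <- new("EffectEstimates",
        intercept = config@baselineLogRate,
        ageEffects = setNames(a, ages),
        periodEffects = setNames(b, periods),
        cohortEffects = setNames(g, cohortYears),
        deviance = NA_real_, converged = TRUE, nIterations = 0L)

    if (config@orthogonalize) {
        design <- buildDesign(ages, periods)
        v <- design@nullVector
        theta <- .stackEffects(truth, design)
        theta <- theta - sum(theta * v) * v
        truth <- .expandEffects(theta, design, deviance = NA_real_,
                                converged = TRUE, nIterations = 0L)
    }

    rate <- exp(fittedLogRates(truth))
    if (any(rate <= 0) || any(rate >= 0.1))
        stop("rates implausible: configured shapes give cell death proportions outside (0, 0.1)")
    truth
}

#' Simulate a Poisson mortality surface from ground-truth effects
#'
#' Draws \code{deaths[i, j] ~ Poisson(population[i, j] * r[i, j])} with
#' \eqn{\log r_{ij} = u + \alpha_i + \beta_j + \gamma_{j-i}}, using a single
#' RNG stream seeded from \code{config@seed}; the same configuration always
#' reproduces the same surface.
#'
#' @param truth an \linkS4class{EffectEstimates}, typically from
#'   \code{\link{generateTrueEffects}}.
#' @param config the matching \linkS4class{SyntheticConfig} (grid,
#'   population profile, seed).
#' @return a \linkS4class{MortalitySurface} labelled as synthetic.
#' @export
simulateSurface <- function(truth, config) {
    stopifnot(is(truth, "EffectEstimates"), is(config, "SyntheticConfig"))
    if (!identical(as.integer(names(truth@ageEffects)), config@ages) ||
        !identical(as.integer(names(truth@periodEffects)), config@periods))
        stop("truth effect grid does not match the configuration grid")
    A <- length(config@ages); P <- length(config@periods)
    pop <- matrix(rep(config@populationPerCell, length.out = A), A, P)
    lambda <- pop * exp(fittedLogRates(truth))
    if (any(lambda > pop))
        stop("expected deaths exceed population in at least one cell")
    set.seed(config@seed)
    d <- matrix(stats::rpois(A * P, as.vector(lambda)), A, P)
    MortalitySurface(d, pop, config@ages, config@periods,
                     stratumLabel = "synthetic", rateScale = 1e5)
}

#' Simulate a prevalence series linked to an effect vector
#'
#' Builds \code{value_y = intercept + slope * effect_y + noise} with
#' Gaussian noise, clamped into [0, 100] percent, over the years naming
#' \code{linkedEffect}. Used to manufacture obesity-like series that track
#' the period effect and smoking-like series that track the cohort effect,
#' with the association strength under the caller's control.
#'
#' @param linkedEffect numeric vector named by calendar year (e.g. a slice
#'   of \code{periodEffects(truth)} or \code{cohortEffects(truth)}).
#' @param intercept,slope affine map from effect to percent.
#' @param noiseSd standard deviation of the Gaussian noise, in percent
#'   (default 0).
#' @param seed RNG seed (default 20220817).
#' @param label series label.
#' @return a \linkS4class{PrevalenceSeries}. Errors if every value was
#'   clamped to a bound (degenerate series).
#' @export
simulatePrevalence <- function(linkedEffect, intercept, slope, noiseSd = 0,
                               seed = 20220817L,
                               label = "synthetic prevalence") {
    if (is.null(names(linkedEffect)))
        stop("linkedEffect must be named by calendar year")
    if (!is.finite(slope) || noiseSd < 0)
        stop("slope must be finite and noiseSd non-negative")
    set.seed(as.integer(seed))
    raw <- intercept + slope * as.numeric(linkedEffect) +
        stats::rnorm(length(linkedEffect), 0, noiseSd)
    vals <- pmin(pmax(raw, 0), 100)
    if (all(vals == 0) || all(vals == 100))
        stop("degenerate series: every value clamped to a bound")
    PrevalenceSeries(as.integer(names(linkedEffect)), vals, label = label)
}
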