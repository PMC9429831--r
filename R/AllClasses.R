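#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
NULL

.isConsecutive <- function(x) {
    length(x) >= 1L && !anyNA(x) && all(diff(x) == 1L)
}

#' MortalitySurface: deaths and person-years on a Lexis grid
#'
#' An S4 container for a single-stratum mortality surface: death counts and
#' population (person-years) tabulated by single year of age (rows) and
#' calendar year (columns). Extends
#' \linkS4class{SummarizedExperiment} with two assays, \code{"deaths"} and
#' \code{"population"}; ages live in \code{rowData(x)$age}, calendar years in
#' \code{colData(x)$year}, and the stratum label and reporting scale in
#' \code{metadata(x)}.
#'
#' Cohorts run along the diagonals of the grid: the cell for age \eqn{a} in
#' year \eqn{y} belongs to the birth cohort \eqn{y - a}.
#'
#' @section Validity:
#' Both assays must be present with identical dimensions; ages and years must
#' each be strictly increasing in steps of one year; every population entry
#' must be positive; deaths must be non-negative whole numbers no larger than
#' the population of their cell.
#'
#' @seealso \code{\link{MortalitySurface}} (constructor),
#'   \code{\link{crudeRateSeries}}, \code{\link{fitIntrinsicEstimator}}
#' @exportClass MortalitySurface
setClass("MortalitySurface", contains = "SummarizedExperiment")

setValidity("MortalitySurface", function(object) {
    msgs <- character()
    if (!all(c("deaths", "population") %in% assayNames(object)))
        return("assays 'deaths' and 'population' are both required")
    d <- assay(object, "deaths")
    p <- assay(object, "population")
    ages <- rowData(object)$age
    yrs <- colData(object)$year
    if (is.null(ages) || is.null(yrs))
        return("rowData(x)$age and colData(x)$year are required")
    if (!.isConsecutive(as.integer(ages)))
        msgs <- c(msgs, "ages must be strictly increasing with step 1")
    if (!.isConsecutive(as.integer(yrs)))
        msgs <- c(msgs, "periods (years) must be strictly increasing with step 1")
    if (anyNA(d) || anyNA(p))
        msgs <- c(msgs, "deaths and population must not contain NA")
    else {
        if (any(p <= 0))
            msgs <- c(msgs, "all population entries must be > 0")
        if (any(d < 0))
            msgs <- c(msgs, "death counts must be non-negative")
        if (any(abs(d - round(d)) > 1e-8))
            msgs <- c(msgs, "death counts must be whole numbers")
        if (any(d > p))
            msgs <- c(msgs, "death counts cannot exceed population")
    }
    rs <- metadata(object)$rate_scale
    if (is.null(rs) || !is.numeric(rs) || length(rs) != 1L || rs <= 0)
        msgs <- c(msgs, "metadata(x)$rate_scale must be a single positive number")
    if (length(msgs)) msgs else TRUE
})

#' APCDesign: the effect-coded age-period-cohort design
#'
#' Holds the deviation-coded (sum-to-zero, last category omitted) design
#' matrix for the APC log-rate model, the index maps from columns to
#' (block, category), and the unit-norm basis vector of the design's
#' one-dimensional null space. Because cohort = period - age exactly, the
#' matrix has rank one less than its column count; every APC estimator is a
#' choice of solution along the null direction, and the Intrinsic Estimator
#' is the solution orthogonal to \code{nullVector(design)}.
#'
#' @slot matrix numeric design matrix with one row per (age, period) cell
#'   (ages varying fastest) and \code{1 + (A-1) + (P-1) + (C-1)} columns.
#' @slot ages,periods,cohorts integer category labels (calendar years) of the
#'   three blocks; \code{cohorts} spans \code{min(periods)-max(ages)} to
#'   \code{max(periods)-min(ages)}.
#' @slot columnMap data.frame with columns \code{block}
#'   (\code{"intercept"}, \code{"age"}, \code{"period"}, \code{"cohort"}) and
#'   \code{category} (the year labelling that column, NA for the intercept).
#' @slot nullVector unit-norm numeric vector spanning the null space, sign
#'   fixed so its first nonzero entry is positive.
#' @seealso \code{\link{buildDesign}}, \code{\link{nullVector}}
#' @exportClass APCDesign
setClass("APCDesign",
    representation(
        matrix = "matrix",
        ages = "integer",
        periods = "integer",
        cohorts = "integer",
        columnMap = "data.frame",
        nullVector = "numeric"
    )
)

setValidity("APCDesign", function(object) {
    msgs <- character()
    A <- length(object@ages); P <- length(object@periods)
    C <- length(object@cohorts)
    X <- object@matrix
    if (C != A + P - 1L)
        msgs <- c(msgs, "cohort count must equal A + P - 1")
    if (nrow(X) != A * P)
        msgs <- c(msgs, "design must have one row per (age, period) cell")
    if (ncol(X) != 1L + (A - 1L) + (P - 1L) + (C - 1L))
        msgs <- c(msgs, "column count must be 1 + (A-1) + (P-1) + (C-1)")
    if (nrow(object@columnMap) != ncol(X))
        msgs <- c(msgs, "columnMap must describe every column")
    v <- object@nullVector
    if (length(v) != ncol(X))
        msgs <- c(msgs, "nullVector length must equal the column count")
    else {
        if (abs(sqrt(sum(v^2)) - 1) > 1e-8)
            msgs <- c(msgs, "nullVector must have unit Euclidean norm")
        smax <- sqrt(max(colSums(X^2)))
        if (max(abs(X %*% v)) > 1e-8 * smax * sqrt(ncol(X)))
            msgs <- c(msgs, "matrix %*% nullVector must vanish")
    }
    if (length(msgs)) msgs else TRUE
})

#' EffectEstimates: a fitted (or true) set of APC effects
#'
#' The intercept plus centered age, period, and cohort effect vectors of the
#' Poisson APC model, on the log scale of the modelled death proportion
#' (deaths per person-year; the reporting scale is applied only when rates
#' are derived). Produced by \code{\link{fitIntrinsicEstimator}},
#' \code{\link{fitConstrained}}, or \code{\link{generateTrueEffects}}.
#'
#' Each effect vector is named by its category year and sums to zero (the
#' deviation-coding convention under which the APC null space is
#' one-dimensional).
#'
#' @slot intercept log baseline proportion (grand mean \eqn{u}).
#' @slot ageEffects,periodEffects,cohortEffects named, centered numeric
#'   vectors.
#' @slot deviance residual Poisson deviance of the fit (NA for generated
#'   ground truth).
#' @slot converged logical convergence flag.
#' @slot nIterations number of IRLS iterations used.
#' @exportClass EffectEstimates
setClass("EffectEstimates",
    representation(
        intercept = "numeric",
        ageEffects = "numeric",
        periodEffects = "numeric",
        cohortEffects = "numeric",
        deviance = "numeric",
        converged = "logical",
        nIterations = "integer"
    )
)

setValidity("EffectEstimates", function(object) {
    msgs <- character()
    for (nm in c("ageEffects", "periodEffects", "cohortEffects")) {
        v <- slot(object, nm)
        if (length(v) == 0L)
            msgs <- c(msgs, sprintf("%s must be non-empty", nm))
        else {
            if (is.null(names(v)))
                msgs <- c(msgs, sprintf("%s must be named by category year", nm))
            if (abs(sum(v)) > 1e-8 * max(1, max(abs(v))))
                msgs <- c(msgs, sprintf("%s must sum to zero", nm))
        }
    }
    if (length(object@intercept) != 1L)
        msgs <- c(msgs, "intercept must be a single number")
    if (length(object@deviance) != 1L ||
        (!is.na(object@deviance) && object@deviance < -1e-8))
        msgs <- c(msgs, "deviance must be a single non-negative number or NA")
    if (length(msgs)) msgs else TRUE
})

#' RateSeries: a per-calendar-year mortality rate series
#'
#' @slot years integer calendar years, strictly increasing.
#' @slot rates non-negative rates per \code{rateScale} person-years.
#' @slot rateScale reporting scale (default 100000).
#' @slot kind one of \code{"crude"}, \code{"age_adjusted"},
#'   \code{"age_cohort_adjusted"}.
#' @slot linkVariant for age-cohort adjusted series, whether the rate was
#'   mapped through the inverse logit (\code{"logit"}) or the exponential
#'   (\code{"log"}); \code{"none"} otherwise.
#' @exportClass RateSeries
setClass("RateSeries",
    representation(
        years = "integer",
        rates = "numeric",
        rateScale = "numeric",
        kind = "character",
        linkVariant = "character"
    )
)

setValidity("RateSeries", function(object) {
    msgs <- character()
    if (length(object@years) == 0L)
        msgs <- c(msgs, "series must be non-empty")
    if (length(object@years) != length(object@rates))
        msgs <- c(msgs, "years and rates must have equal length")
    if (length(object@years) > 1L && any(diff(object@years) <= 0))
        msgs <- c(msgs, "years must be strictly increasing")
    if (anyNA(object@rates) || any(object@rates < 0))
        msgs <- c(msgs, "rates must be non-negative")
    if (length(object@rateScale) != 1L || object@rateScale <= 0)
        msgs <- c(msgs, "rateScale must be a single positive number")
    if (!object@kind %in% c("crude", "age_adjusted", "age_cohort_adjusted"))
        msgs <- c(msgs, "kind must be crude, age_adjusted, or age_cohort_adjusted")
    if (!object@linkVariant %in% c("logit", "log", "none"))
        msgs <- c(msgs, "linkVariant must be logit, log, or none")
    if (length(msgs)) msgs else TRUE
})

#' PrevalenceSeries: a per-year prevalence series in percent
#'
#' @slot years integer years, strictly increasing.
#' @slot values prevalence in percent, each in [0, 100].
#' @slot label free-text description of the series.
#' @exportClass PrevalenceSeries
setClass("PrevalenceSeries",
    representation(years = "integer", values = "numeric", label = "character")
)

setValidity("PrevalenceSeries", function(object) {
    msgs <- character()
    if (length(object@years) != length(object@values))
        msgs <- c(msgs, "years and values must have equal length")
    if (length(object@years) > 1L && any(diff(object@years) <= 0))
        msgs <- c(msgs, "years must be strictly increasing")
    if (anyNA(object@values) || any(object@values < 0 | object@values > 100))
        msgs <- c(msgs, "values must be percentages in [0, 100]")
    if (length(msgs)) msgs else TRUE
})

#' StandardPopulation: age weights for direct standardization
#'
#' Weights are normalized to sum to one at construction; the age support must
#' match the surface being standardized.
#'
#' @slot ages integer ages.
#' @slot weights positive weights summing to 1.
#' @exportClass StandardPopulation
setClass("StandardPopulation",
    representation(ages = "integer", weights = "numeric")
)

setValidity("StandardPopulation", function(object) {
    msgs <- character()
    if (length(object@ages) != length(object@weights))
        msgs <- c(msgs, "ages and weights must have equal length")
    if (anyNA(object@weights) || any(object@weights <= 0))
        msgs <- c(msgs, "weights must all be positive")
    else if (abs(sum(object@weights) - 1) > 1e-8)
        msgs <- c(msgs, "weights must sum to 1")
    if (length(msgs)) msgs else TRUE
})

#' CorrelationResult: a Pearson correlation with its t-test
#'
#' @slot r sample Pearson correlation coefficient.
#' @slot n number of paired observations.
#' @slot tStatistic t statistic \eqn{r\sqrt{(n-2)/(1-r^2)}}.
#' @slot df degrees of freedom, \code{n - 2}.
#' @slot pValue two-sided p-value from the t distribution.
#' @slot pairLabel free-text description of the paired series.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
    representation(
        r = "numeric", n = "integer", tStatistic = "numeric",
        df = "integer", pValue = "numeric", pairLabel = "character"
    )
)

setValidity("CorrelationResult", function(object) {
    msgs <- character()
    if (abs(object@r) > 1 + 1e-12)
        msgs <- c(msgs, "|r| cannot exceed 1")
    if (object@n < 3L)
        msgs <- c(msgs, "n must be at least 3")
    if (object@df != object@n - 2L)
        msgs <- c(msgs, "df must equal n - 2")
    if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
        msgs <- c(msgs, "pValue must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' SyntheticConfig: parameters of the synthetic mortality-surface generator
#'
#' Describes a ground-truth APC structure: a quadratic (curvilinear) age
#' effect, a piecewise-linear period effect with a single breakpoint, and a
#' linearly declining cohort effect, plus the population at risk per cell and
#' the RNG seed. See \code{\link{generateTrueEffects}} and
#' \code{\link{simulateSurface}}.
#'
#' @slot ages,periods integer grids (defaults 25:84 and 1999:2018).
#' @slot baselineLogRate intercept \eqn{u} on the log proportion scale
#'   (default \code{log(1.5e-3)}).
#' @slot ageCurvature,ageVertex the age effect is
#'   \eqn{-c\,(\mathrm{age} - v)^2} before centering: increasing up to the
#'   vertex \eqn{v}, then flattening/declining.
#' @slot periodBreak,periodSlope1,periodSlope2 the period effect is linear
#'   with slope 1 before the breakpoint year and slope 2 after it,
#'   continuous at the break.
#' @slot cohortSlope log-rate change per birth year (negative = declining
#'   cohort risk).
#' @slot populationPerCell person-years per cell: a single number, or one
#'   value per age for an age-varying profile.
#' @slot seed RNG seed for the simulation stream.
#' @slot orthogonalize if TRUE (default), project the stacked true
#'   coefficients off the design's null vector so the Intrinsic Estimator is
#'   a consistent estimator of the truth.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
    representation(
        ages = "integer", periods = "integer",
        baselineLogRate = "numeric",
        ageCurvature = "numeric", ageVertex = "numeric",
        periodBreak = "numeric", periodSlope1 = "numeric",
        periodSlope2 = "numeric",
        cohortSlope = "numeric",
        populationPerCell = "numeric",
        seed = "integer",
        orthogonalize = "logical"
    )
)

setValidity("SyntheticConfig", function(object) {
    msgs <- character()
    if (!.isConsecutive(object@ages) || length(object@ages) < 3L)
        msgs <- c(msgs, "ages must be >= 3 consecutive years")
    if (!.isConsecutive(object@periods) || length(object@periods) < 3L)
        msgs <- c(msgs, "periods must be >= 3 consecutive years")
    npop <- length(object@populationPerCell)
    if (!npop %in% c(1L, length(object@ages)))
        msgs <- c(msgs, "populationPerCell must have length 1 or one value per age")
    if (any(object@populationPerCell <= 0))
        msgs <- c(msgs, "populationPerCell must be positive")
    if (length(msgs)) msgs else TRUE
})
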