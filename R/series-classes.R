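#' Construct a RateSeries
#'
#' @param years integer calendar years.
#' @param rates rates per \code{rateScale} person-years.
#' @param rateScale reporting scale (default 100000).
#' @param kind \code{"crude"}, \code{"age_adjusted"}, or
#'   \code{"age_cohort_adjusted"}.
#' @param linkVariant \code{"logit"}, \code{"log"}, or \code{"none"};
#'   meaningful only for age-cohort adjusted series.
#' @return a \linkS4class{RateSeries}.
#' @export
RateSeries <- function(years, rates, rateScale = 1e5, kind = "crude",
                       linkVariant = "none") {
    new("RateSeries", years = as.integer(years), rates = as.numeric(rates),
        rateScale = as.numeric(rateScale), kind = kind,
        linkVariant = linkVariant)
}

#' Construct a PrevalenceSeries
#'
#' Rows are sorted by year; duplicate years are an error.
#'
#' @param years integer years.
#' @param values prevalence in percent, each in [0, 100].
#' @param label free-text description.
#' @return a \linkS4class{PrevalenceSeries}.
#' @export
PrevalenceSeries <- function(years, values, label = "prevalence") {
    years <- as.integer(years)
    if (anyDuplicated(years))
        stop("duplicate years in prevalence series: ",
             paste(unique(years[duplicated(years)]), collapse = ", "))
    o <- order(years)
    new("PrevalenceSeries", years = years[o], values = as.numeric(values)[o],
        label = as.character(label))
}

#' Construct a StandardPopulation
#'
#' @param ages integer ages matching the surface to standardize.
#' @param weights positive weights; normalized internally to sum to 1.
#' @return a \linkS4class{StandardPopulation}.
#' @export
StandardPopulation <- function(ages, weights) {
    weights <- as.numeric(weights)
    if (anyNA(weights) || any(weights <= 0))
        stop("standard-population weights must all be positive")
    new("StandardPopulation", ages = as.integer(ages),
        weights = weights / sum(weights))
}

#' @rdname series-accessors
#' @export
setMethod("years", "RateSeries", function(x) x@years)

#' @rdname series-accessors
#' @export
setMethod("years", "PrevalenceSeries", function(x) x@years)

#' @rdname series-accessors
#' @export
setMethod("rates", "RateSeries", function(x) x@rates)

#' @rdname series-accessors
#' @export
setMethod("prevalence", "PrevalenceSeries", function(x) x@values)

#' @rdname series-accessors
#' @export
setMethod("rateScale", "RateSeries", function(x) x@rateScale)

#' @rdname series-accessors
#' @export
setMethod("ages", "StandardPopulation", function(x) x@ages)

#' Weights of a StandardPopulation
#' @param x a \linkS4class{StandardPopulation}.
#' @return normalized numeric weights summing to 1.
#' @export
stdWeights <- function(x) {
    stopifnot(is(x, "StandardPopulation"))
    x@weights
}

#' Label of a PrevalenceSeries
#' @param x a \linkS4class{PrevalenceSeries}.
#' @export
seriesLabel <- function(x) {
    stopifnot(is(x, "PrevalenceSeries"))
    x@label
}

setMethod("show", "RateSeries", function(object) {
    cat(sprintf("RateSeries (%s%s): %d years %d-%d, per %g\n",
        object@kind,
        if (object@linkVariant == "none") "" else
            paste0(", ", object@linkVariant, " link"),
        length(object@years), min(object@years), max(object@years),
        object@rateScale))
    print(setNames(round(object@rates, 2), object@years))
    invisible(NULL)
})

setMethod("show", "PrevalenceSeries", function(object) {
    cat(sprintf("PrevalenceSeries '%s': %d years %d-%d (%%)\n",
        object@label, length(object@years),
        min(object@years), max(object@years)))
    print(setNames(round(object@values, 2), object@years))
    invisible(NULL)
})

setMethod("show", "CorrelationResult", function(object) {
    cat(sprintf("Pearson correlation [%s]\n", object@pairLabel))
    cat(sprintf("  r = %.4f, n = %d, t = %.3f on %d df, two-sided p = %.4g\n",
        object@r, object@n, object@tStatistic, object@df, object@pValue))
    invisible(NULL)
})

#' Coerce a series to a tidy data.frame
#'
#' @param x a \linkS4class{RateSeries} or \linkS4class{PrevalenceSeries}.
#' @param row.names,optional,... passed through (unused).
#' @return a data.frame, one row per year.
#' @export
as.data.frame.RateSeries <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
    data.frame(year = x@years, rate_per_scale = x@rates,
               scale = x@rateScale, kind = x@kind, variant = x@linkVariant)
}

setMethod("as.data.frame", "RateSeries", as.data.frame.RateSeries)

#' @rdname as.data.frame.RateSeries
#' @export
as.data.frame.PrevalenceSeries <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
    data.frame(year = x@years, percent = x@values, label = x@label)
}

setMethod("as.data.frame", "PrevalenceSeries", as.data.frame.PrevalenceSeries)
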