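#' Construct a MortalitySurface
#'
#' Assemble death counts and person-years on a complete age x calendar-year
#' (Lexis) rectangle into a \linkS4class{MortalitySurface}. Ages and years
#' must be single-year and consecutive; the estimator requires the full
#' rectangle, so missing cells are rejected at construction.
#'
#' @param deaths integer matrix of death counts, ages in rows, years in
#'   columns.
#' @param population numeric matrix of person-years at risk, same shape.
#' @param ages integer vector of ages (e.g. \code{25:84}).
#' @param periods integer vector of calendar years (e.g. \code{1999:2018}).
#' @param stratumLabel free-text label for the stratum (e.g. \code{"male"},
#'   \code{"NH White"}).
#' @param rateScale reporting scale for derived rates; rates are "per
#'   \code{rateScale}" (default 100000).
#' @return a \linkS4class{MortalitySurface}.
#' @examples
#' s <- MortalitySurface(
#'     deaths = matrix(c(5, 7, 6, 8), 2, 2),
#'     population = matrix(1e5, 2, 2),
#'     ages = 60:61, periods = 1999:2000, stratumLabel = "example"
#' )
#' crudeRateSeries(s)
#' @export
MortalitySurface <- function(deaths, population, ages, periods,
                             stratumLabel = "unspecified",
                             rateScale = 1e5) {
    deaths <- as.matrix(deaths)
    population <- as.matrix(population)
    ages <- as.integer(ages)
    periods <- as.integer(periods)
    if (!identical(dim(deaths), dim(population)))
        stop("deaths and population must have identical dimensions")
    if (nrow(deaths) != length(ages) || ncol(deaths) != length(periods))
        stop("matrix dimensions must be length(ages) x length(periods)")
    dimnames(deaths) <- dimnames(population) <- list(ages, periods)
    se <- SummarizedExperiment(
        assays = list(deaths = deaths, population = population),
        rowData = DataFrame(age = ages),
        colData = DataFrame(year = periods),
        metadata = list(stratum_label = as.character(stratumLabel),
                        rate_scale = as.numeric(rateScale))
    )
    new("MortalitySurface", se)
}

#' @rdname MortalitySurface
#' @export
setMethod("ages", "MortalitySurface", function(x) as.integer(rowData(x)$age))

#' @rdname MortalitySurface
#' @export
setMethod("periods", "MortalitySurface",
    function(x) as.integer(colData(x)$year))

#' @rdname MortalitySurface
#' @export
setMethod("deaths", "MortalitySurface", function(x) assay(x, "deaths"))

#' @rdname MortalitySurface
#' @export
setMethod("population", "MortalitySurface",
    function(x) assay(x, "population"))

#' @rdname MortalitySurface
#' @export
setMethod("stratumLabel", "MortalitySurface",
    function(x) metadata(x)$stratum_label)

#' @rdname MortalitySurface
#' @export
setMethod("rateScale", "MortalitySurface",
    function(x) metadata(x)$rate_scale)

setMethod("show", "MortalitySurface", function(object) {
    a <- ages(object); p <- periods(object)
    cat(sprintf(
        "MortalitySurface: %d ages (%d-%d) x %d years (%d-%d), stratum '%s'\n",
        length(a), min(a), max(a), length(p), min(p), max(p),
        stratumLabel(object)))
    cat(sprintf("  total deaths %.0f over %.4g person-years (rates per %g)\n",
        sum(deaths(object)), sum(population(object)), rateScale(object)))
    cat(sprintf("  birth cohorts %d-%d along the diagonals\n",
        min(p) - max(a), max(p) - min(a)))
    invisible(NULL)
})
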