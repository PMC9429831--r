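#' Interpolate a sparse prevalence series to annual resolution
#'
#' Piecewise-linear interpolation between the observed knot years (via
#' \code{stats::approx}); knot years reproduce their observed values
#' exactly. Extrapolation outside the knot range is refused.
#'
#' @param series a \linkS4class{PrevalenceSeries} of knots.
#' @param targetYears integer years at which to evaluate; all must lie
#'   within \code{range(years(series))}.
#' @return a \linkS4class{PrevalenceSeries} over \code{targetYears}.
#' @examples
#' knots <- PrevalenceSeries(c(1999, 2001), c(30.5, 34.5))
#' prevalence(interpolateAnnual(knots, 1999:2001))  # 30.5 32.5 34.5
#' @export
interpolateAnnual <- function(series, targetYears) {
    stopifnot(is(series, "PrevalenceSeries"))
    targetYears <- as.integer(targetYears)
    if (length(series@years) < 2L)
        stop("need at least two knots to interpolate")
    if (any(targetYears < min(series@years) | targetYears > max(series@years)))
        stop(sprintf(
            "target years outside the knot range %d-%d (no extrapolation): %s",
            min(series@years), max(series@years),
            paste(targetYears[targetYears < min(series@years) |
                              targetYears > max(series@years)],
                  collapse = ", ")))
    vals <- stats::approx(series@years, series@values, xout = targetYears,
                          method = "linear", ties = "ordered")$y
    PrevalenceSeries(targetYears, vals, label = series@label)
}

#' Pearson correlation with its two-sided t-test
#'
#' Sample Pearson correlation between two equal-length vectors, with the
#' two-sided p-value from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2}
#' degrees of freedom (computed via \code{stats::cor.test}).
#'
#' @param x,y numeric vectors of equal length \eqn{n \ge 3}, neither
#'   constant.
#' @param pairLabel free-text description of the pairing.
#' @return a \linkS4class{CorrelationResult}.
#' @export
pearsonCorrelation <- function(x, y, pairLabel = "") {
    x <- as.numeric(x); y <- as.numeric(y)
    n <- length(x)
    if (length(y) != n)
        stop("x and y must have equal length")
    if (n < 3L)
        stop("need at least 3 paired observations")
    if (anyNA(x) || anyNA(y))
        stop("missing values in correlation input")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined for a constant input vector")
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    new("CorrelationResult",
        r = unname(ct$estimate), n = as.integer(n),
        tStatistic = unname(ct$statistic), df = as.integer(n - 2L),
        pValue = ct$p.value, pairLabel = pairLabel)
}

#' Correlate a mortality-rate series with obesity prevalence
#'
#' Aligns the two series by calendar year (intersection of their years,
#' which must contain at least 3 years) and computes the Pearson
#' correlation. The qualitative point of the comparison: crude and
#' age-standardized heart-disease rates correlate negatively with rising
#' obesity (the paradox), while the age-cohort adjusted series — the period
#' effect freed from the declining cohort effect — correlates positively.
#'
#' @param rateSeries a \linkS4class{RateSeries}.
#' @param obesity a \linkS4class{PrevalenceSeries} (annual; interpolate
#'   first if given at survey cycles).
#' @return a \linkS4class{CorrelationResult}.
#' @export
correlateRatesWithObesity <- function(rateSeries, obesity) {
    stopifnot(is(rateSeries, "RateSeries"), is(obesity, "PrevalenceSeries"))
    common <- intersect(rateSeries@years, obesity@years)
    if (length(common) < 3L)
        stop("fewer than 3 overlapping calendar years between the series")
    common <- sort(common)
    pearsonCorrelation(
        rateSeries@rates[match(common, rateSeries@years)],
        obesity@values[match(common, obesity@years)],
        pairLabel = sprintf("%s rate vs %s (%d-%d)", rateSeries@kind,
                            obesity@label, min(common), max(common)))
}

#' Correlate fitted cohort effects with historical smoking prevalence
#'
#' Pairs the estimated cohort effect of the cohort born in calendar year
#' \eqn{Y - \mathrm{lag}} with smoking prevalence observed (or interpolated)
#' in year \eqn{Y}, for every year of \code{cohortWindow}, then computes the
#' Pearson correlation. The default window 1965-1990 with zero lag matches
#' adult smoking prevalence in a year against the cohort born that year;
#' the cohort effect carries the historical exposure forward, so a
#' declining smoking series tracking a declining cohort effect yields a
#' strong positive correlation.
#'
#' @param estimates an \linkS4class{EffectEstimates} with cohort effects
#'   covering the (lag-shifted) window.
#' @param smoking a \linkS4class{PrevalenceSeries} of smoking knots covering
#'   the window; interpolated annually internally.
#' @param cohortWindow length-2 integer, first and last calendar year
#'   (default \code{c(1965, 1990)}).
#' @param lag integer years: smoking in year Y is paired with the cohort
#'   born in year \code{Y - lag} (default 0).
#' @return a \linkS4class{CorrelationResult}.
#' @export
correlateCohortEffectsWithSmoking <- function(estimates, smoking,
                                              cohortWindow = c(1965L, 1990L),
                                              lag = 0L) {
    stopifnot(is(estimates, "EffectEstimates"),
              is(smoking, "PrevalenceSeries"))
    cohortWindow <- as.integer(cohortWindow)
    if (length(cohortWindow) != 2L || cohortWindow[1] > cohortWindow[2])
        stop("cohortWindow must be c(first, last) with first <= last")
    yrs <- seq.int(cohortWindow[1], cohortWindow[2])
    cohortYears <- yrs - as.integer(lag)
    gammaYears <- as.integer(names(estimates@cohortEffects))
    if (!all(cohortYears %in% gammaYears))
        stop("cohort window (after lag shift) outside the estimated cohort range ",
             min(gammaYears), "-", max(gammaYears))
    smokingAnnual <- interpolateAnnual(smoking, yrs)
    g <- unname(estimates@cohortEffects[match(cohortYears, gammaYears)])
    if (length(g) == 0L)
        stop("empty cohort/smoking pairing")
    pearsonCorrelation(
        g, smokingAnnual@values,
        pairLabel = sprintf("cohort effects vs %s (%d-%d%s)", smoking@label,
                            cohortWindow[1], cohortWindow[2],
                            if (lag != 0L) sprintf(", lag %d", lag) else ""))
}
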