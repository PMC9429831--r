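#' Plot fitted age, period, and cohort effect curves
#'
#' Three base-graphics panels: age effects against age, period effects
#' against calendar year, and cohort effects against birth year, all on the
#' log-rate scale with a zero reference line.
#'
#' @param estimates an \linkS4class{EffectEstimates}.
#' @param main overall title.
#' @return invisibly, NULL.
#' @export
plotEffects <- function(estimates, main = "APC effect estimates") {
    stopifnot(is(estimates, "EffectEstimates"))
    old <- graphics::par(mfrow = c(1, 3), oma = c(0, 0, 2, 0))
    on.exit(graphics::par(old), add = TRUE)
    panels <- list(
        list(v = estimates@ageEffects, xlab = "Age", t = "Age effect"),
        list(v = estimates@periodEffects, xlab = "Calendar year",
             t = "Period effect"),
        list(v = estimates@cohortEffects, xlab = "Birth year",
             t = "Cohort effect"))
    for (pn in panels) {
        x <- as.integer(names(pn$v))
        graphics::plot(x, pn$v, type = "l", lwd = 2, xlab = pn$xlab,
                       ylab = "Effect (log rate)", main = pn$t)
        graphics::abline(h = 0, lty = 3, col = "grey40")
    }
    graphics::mtext(main, outer = TRUE, cex = 1.1)
    invisible(NULL)
}

#' Compare crude, age-adjusted, and age-cohort adjusted rate series
#'
#' Overlays any number of \linkS4class{RateSeries} on one set of axes, one
#' line per series, labelled by kind. The comparison that motivates the
#' whole analysis: a crude series can decline while the age-cohort adjusted
#' series rises, because the crude series absorbs the declining cohort
#' effect.
#'
#' @param ... \linkS4class{RateSeries} objects (or a single list of them).
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plotRateComparison <- function(..., main = "Mortality rate series") {
    series <- list(...)
    if (length(series) == 1L && is.list(series[[1]]) &&
        !is(series[[1]], "RateSeries"))
        series <- series[[1]]
    stopifnot(length(series) >= 1L,
              all(vapply(series, is, logical(1), "RateSeries")))
    allYears <- range(unlist(lapply(series, years)))
    allRates <- range(unlist(lapply(series, rates)))
    graphics::plot(NA, xlim = allYears, ylim = allRates,
                   xlab = "Calendar year",
                   ylab = sprintf("Rate per %g", series[[1]]@rateScale),
                   main = main)
    cols <- c("black", "firebrick", "steelblue", "darkgreen")
    labs <- character(length(series))
    for (i in seq_along(series)) {
        s <- series[[i]]
        graphics::lines(s@years, s@rates, lwd = 2,
                        col = cols[(i - 1) %% length(cols) + 1])
        labs[i] <- if (s@linkVariant == "none") s@kind else
            paste0(s@kind, " (", s@linkVariant, ")")
    }
    graphics::legend("topright", legend = labs, lwd = 2,
                     col = cols[(seq_along(series) - 1) %% length(cols) + 1],
                     bty = "n", cex = 0.8)
    invisible(NULL)
}
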