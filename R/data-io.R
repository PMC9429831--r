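.stripQuotes <- function(x) {
    x <- sub("^\\s*\"?", "", x)
    sub("\"?\\s*$", "", x)
}

.sentinels <- c("Suppressed", "Unreliable", "Not Applicable", "Missing")

.findColumn <- function(header, patterns, what) {
    h <- tolower(header)
    for (p in patterns) {
        hit <- grep(p, h)
        if (length(hit)) return(hit[1])
    }
    stop(sprintf("no column matching %s found in header: %s", what,
                 paste(header, collapse = " | ")))
}

#' Read a CDC-WONDER-style mortality export
#'
#' Parses the tab-separated export dialect used by the CDC WONDER mortality
#' query tool: a header row naming (at least) single-year-of-age, year,
#' deaths, and population columns; one data row per (age, year) cell; and an
#' optional trailing metadata block that starts at the first line whose
#' first field is empty or reads \code{"Notes"}. Fields may be
#' double-quoted; CRLF and LF line endings are both accepted.
#'
#' Suppressed or unreliable cells are a hard error (listing the affected
#' cells), never silently imputed: the estimator requires a complete Lexis
#' rectangle. After optional windowing, every (age, year) cell must be
#' present exactly once.
#'
#' @param path path to the export file.
#' @param stratumLabel label for the stratum the file covers.
#' @param ages,periods optional integer windows; rows outside are dropped.
#'   Default NULL keeps every age/year found.
#' @param rateScale reporting scale for the resulting surface.
#' @return a \linkS4class{MortalitySurface}.
#' @export
readWonderExport <- function(path, stratumLabel, ages = NULL, periods = NULL,
                             rateScale = 1e5) {
    lines <- sub("\r$", "", readLines(path, warn = FALSE))
    if (length(lines) < 2L)
        stop("file has no data rows: ", path)
    header <- .stripQuotes(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
    ageCol <- .findColumn(header, c("single.year.*age", "\\bage\\b", "age"),
                          "single-year-of-age")
    yearCol <- .findColumn(header, c("^year", "\\byear\\b", "period"),
                           "year")
    deathCol <- .findColumn(header, c("death"), "deaths")
    popCol <- .findColumn(header, c("population"), "population")

    rows <- list()
    for (ln in seq.int(2L, length(lines))) {
        fields <- .stripQuotes(strsplit(lines[ln], "\t", fixed = TRUE)[[1]])
        if (length(fields) == 0L || fields[1] == "" || fields[1] == "Notes")
            break                      # trailing notes/metadata block
        rows[[length(rows) + 1L]] <- list(line = ln, fields = fields)
    }
    if (length(rows) == 0L)
        stop("file has no data rows before the notes block: ", path)

    n <- length(rows)
    age <- year <- dth <- pop <- numeric(n)
    suppressed <- character()
    for (i in seq_len(n)) {
        f <- rows[[i]]$fields
        ln <- rows[[i]]$line
        getNum <- function(col, what) {
            val <- if (col <= length(f)) f[col] else ""
            if (val %in% .sentinels) return(NA_real_)
            num <- .parseNumeric(val)
            if (is.na(num))
                stop(sprintf("non-numeric %s value '%s' on line %d", what,
                             val, ln))
            num
        }
        a <- getNum(ageCol, "age"); y <- getNum(yearCol, "year")
        d <- getNum(deathCol, "deaths"); p <- getNum(popCol, "population")
        if (anyNA(c(d, p)))
            suppressed <- c(suppressed,
                            sprintf("(age %s, year %s)", f[ageCol],
                                    f[yearCol]))
        age[i] <- a; year[i] <- y; dth[i] <- d; pop[i] <- p
    }
    if (length(suppressed))
        stop("suppressed/unreliable cells cannot be used (the model needs a complete surface): ",
             paste(suppressed, collapse = ", "))

    .assembleSurface(age, year, dth, pop, ages, periods, stratumLabel,
                     rateScale)
}

.parseNumeric <- function(val) {
    suppressWarnings(as.numeric(gsub(",", "", val)))
}

.assembleSurface <- function(age, year, dth, pop, ages, periods,
                             stratumLabel, rateScale) {
    if (is.null(ages)) ages <- seq.int(min(age), max(age))
    if (is.null(periods)) periods <- seq.int(min(year), max(year))
    keep <- age %in% ages & year %in% periods
    age <- age[keep]; year <- year[keep]; dth <- dth[keep]; pop <- pop[keep]

    key <- paste(age, year)
    if (anyDuplicated(key))
        stop("duplicate (age, year) cells: ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
    want <- expand.grid(age = ages, year = periods)
    wantKey <- paste(want$age, want$year)
    missing <- setdiff(wantKey, key)
    if (length(missing))
        stop("missing (age, year) cells after filtering: ",
             paste(sprintf("(%s)", sub(" ", ", ", missing)), collapse = ", "))

    idx <- match(wantKey, key)
    D <- matrix(dth[idx], length(ages), length(periods))
    P <- matrix(pop[idx], length(ages), length(periods))
    MortalitySurface(D, P, ages, periods, stratumLabel = stratumLabel,
                     rateScale = rateScale)
}

#' Read a tidy mortality surface CSV
#'
#' Comma-separated with header columns \code{age, year, deaths, population},
#' one row per cell.
#'
#' @inheritParams readWonderExport
#' @return a \linkS4class{MortalitySurface}.
#' @export
readSurfaceCsv <- function(path, stratumLabel, ages = NULL, periods = NULL,
                           rateScale = 1e5) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("age", "year", "deaths", "population")
    if (!all(need %in% names(df)))
        stop("surface CSV must have columns: ", paste(need, collapse = ", "))
    for (nm in need)
        if (!is.numeric(df[[nm]]))
            stop("non-numeric values in column '", nm, "'")
    .assembleSurface(df$age, df$year, df$deaths, df$population, ages,
                     periods, stratumLabel, rateScale)
}

#' Write a mortality surface as tidy CSV
#'
#' One row per (age, year) cell with columns
#' \code{age, year, deaths, population}; the lossless inverse of
#' \code{\link{readSurfaceCsv}}.
#'
#' @param surface a \linkS4class{MortalitySurface}.
#' @param path output path.
#' @export
writeSurfaceCsv <- function(surface, path) {
    stopifnot(is(surface, "MortalitySurface"))
    df <- data.frame(
        age = rep(ages(surface), times = length(periods(surface))),
        year = rep(periods(surface), each = length(ages(surface))),
        deaths = as.vector(deaths(surface)),
        population = as.vector(population(surface)))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Read a two-column prevalence CSV
#'
#' Header plus rows of (year, percent). Rows are sorted by year; duplicate
#' years and percentages outside [0, 100] are errors.
#'
#' @param path input path.
#' @param label series label (defaults to the file name).
#' @return a \linkS4class{PrevalenceSeries}.
#' @export
readPrevalenceCsv <- function(path, label = basename(path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("prevalence CSV needs two columns (year, percent)")
    yr <- df[[1]]; pc <- df[[2]]
    if (!is.numeric(yr) || !is.numeric(pc))
        stop("non-numeric year or percent values in ", path)
    if (any(pc < 0 | pc > 100))
        stop("percent values outside [0, 100]: ",
             paste(pc[pc < 0 | pc > 100], collapse = ", "))
    PrevalenceSeries(yr, pc, label = label)
}

#' Write a rate series as tidy CSV
#'
#' Columns \code{year, rate_per_scale, scale, kind, variant}; numeric
#' values keep full precision so a write/read cycle round-trips within
#' 1e-9 relative.
#'
#' @param series a non-empty \linkS4class{RateSeries}.
#' @param path output path.
#' @export
writeRateSeriesCsv <- function(series, path) {
    stopifnot(is(series, "RateSeries"))
    if (length(series@years) == 0L)
        stop("refusing to write an empty rate series")
    utils::write.csv(as.data.frame(series), path, row.names = FALSE)
    invisible(path)
}

#' Read a rate series written by \code{\link{writeRateSeriesCsv}}
#'
#' @param path input path.
#' @return a \linkS4class{RateSeries}.
#' @export
readRateSeriesCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("year", "rate_per_scale", "scale")
    if (!all(need %in% names(df)))
        stop("rate-series CSV must have columns: ",
             paste(need, collapse = ", "))
    RateSeries(df$year, df$rate_per_scale, rateScale = df$scale[1],
               kind = if ("kind" %in% names(df)) df$kind[1] else "crude",
               linkVariant = if ("variant" %in% names(df)) df$variant[1]
                             else "none")
}

#' Write fitted effects as tidy CSV
#'
#' One row per coefficient with columns \code{block}
#' (intercept/age/period/cohort), \code{category} (year; empty for the
#' intercept), and \code{estimate}.
#'
#' @param estimates an \linkS4class{EffectEstimates}.
#' @param path output path.
#' @export
writeEffectsCsv <- function(estimates, path) {
    stopifnot(is(estimates, "EffectEstimates"))
    df <- data.frame(
        block = c("intercept",
                  rep("age", length(estimates@ageEffects)),
                  rep("period", length(estimates@periodEffects)),
                  rep("cohort", length(estimates@cohortEffects))),
        category = c(NA, names(estimates@ageEffects),
                     names(estimates@periodEffects),
                     names(estimates@cohortEffects)),
        estimate = c(estimates@intercept, unname(estimates@ageEffects),
                     unname(estimates@periodEffects),
                     unname(estimates@cohortEffects)))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Read effects written by \code{\link{writeEffectsCsv}}
#'
#' @param path input path.
#' @return an \linkS4class{EffectEstimates} (deviance NA: the file stores
#'   only the estimates).
#' @export
readEffectsCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    pick <- function(block) {
        rows <- df[df$block == block, ]
        setNames(rows$estimate, rows$category)
    }
    new("EffectEstimates",
        intercept = df$estimate[df$block == "intercept"][1],
        ageEffects = pick("age"), periodEffects = pick("period"),
        cohortEffects = pick("cohort"),
        deviance = NA_real_, converged = TRUE, nIterations = 0L)
}

#' Write a correlation result as a one-row CSV
#'
#' Columns \code{label, r, n, t, df, p}.
#'
#' @param result a \linkS4class{CorrelationResult}.
#' @param path output path.
#' @export
writeCorrelationCsv <- function(result, path) {
    stopifnot(is(result, "CorrelationResult"))
    utils::write.csv(
        data.frame(label = result@pairLabel, r = result@r, n = result@n,
                   t = result@tStatistic, df = result@df, p = result@pValue),
        path, row.names = FALSE)
    invisible(path)
}
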