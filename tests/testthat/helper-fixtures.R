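# Shared fixtures: everything is generated in code at test time.

# Small deterministic surface for unit tests (10 ages x 8 periods).
tinyConfig <- function(seed = 20220817L, populationPerCell = 1e6, ...) {
    SyntheticConfig(ages = 40:49, periods = 2001:2008,
                    populationPerCell = populationPerCell, seed = seed, ...)
}

tinySurface <- function(seed = 20220817L, populationPerCell = 1e6, ...) {
    cfg <- tinyConfig(seed = seed, populationPerCell = populationPerCell,
                      ...)
    simulateSurface(generateTrueEffects(cfg), cfg)
}

# The generator amplitudes used for parameter-recovery checks: every cell
# death proportion stays in the ~1e-3 decade, so no corner of the Lexis
# surface is starved of deaths.
recoveryConfig <- function(seed = 20220817L) {
    SyntheticConfig(populationPerCell = 1e7, baselineLogRate = log(3e-3),
                    ageCurvature = 1.5e-4, cohortSlope = -0.004,
                    seed = seed)
}

# Write WONDER-dialect lines to a temp file; returns the path.
writeWonderLines <- function(lines, eol = "\n") {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    con <- file(path, "wb")
    writeChar(paste0(paste(lines, collapse = eol), eol), con,
              eos = NULL)
    close(con)
    path
}

wonderHeader <- "\"Single-Year Ages Code\"\t\"Year\"\t\"Deaths\"\t\"Population\""

wonderRow <- function(age, year, deaths, pop) {
    sprintf("\"%d\"\t\"%d\"\t\"%s\"\t\"%s\"", age, year,
            as.character(deaths), as.character(pop))
}

# Closed-form null direction of the deviation-coded APC design: linear
# trends (+age, -period, +cohort) in actual years, intercept zero, each
# block's last category dropped. Independent of the eigen/SVD route.
closedFormNullVector <- function(ages, periods) {
    cohortYears <- seq.int(min(periods) - max(ages),
                           max(periods) - min(ages))
    v <- c(0,
           (ages - mean(ages))[-length(ages)],
           -(periods - mean(periods))[-length(periods)],
           (cohortYears - mean(cohortYears))[-length(cohortYears)])
    v / sqrt(sum(v^2))
}
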