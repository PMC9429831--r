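.poissonDeviance <- function(y, mu) {
    term <- ifelse(y > 0, y * log(y / mu), 0)
    2 * sum(term - (y - mu))
}

## Expand a deviation-coded coefficient vector (intercept first) into
## full-length, named, centered effect vectors via the negative-sum rule.
.expandEffects <- function(theta, design, deviance = NA_real_,
                           converged = TRUE, nIterations = 0L) {
    cm <- design@columnMap
    u <- theta[cm$block == "intercept"]
    expandBlock <- function(block, labels) {
        th <- theta[cm$block == block]
        setNames(c(th, -sum(th)), labels)
    }
    new("EffectEstimates",
        intercept = unname(u),
        ageEffects = expandBlock("age", design@ages),
        periodEffects = expandBlock("period", design@periods),
        cohortEffects = expandBlock("cohort", design@cohorts),
        deviance = deviance, converged = converged,
        nIterations = as.integer(nIterations))
}

## Inverse of .expandEffects: stack effects into the deviation-coded
## parameter vector (dropping each block's last category).
.stackEffects <- function(estimates, design) {
    c(estimates@intercept,
      unname(estimates@ageEffects[-length(estimates@ageEffects)]),
      unname(estimates@periodEffects[-length(estimates@periodEffects)]),
      unname(estimates@cohortEffects[-length(estimates@cohortEffects)]))
}

.checkSurfaceDesign <- function(surface, design) {
    if (!identical(ages(surface), design@ages) ||
        !identical(periods(surface), design@periods))
        stop("surface and design must share identical age and period grids")
    invisible(NULL)
}

## IRLS for the Poisson log-link model with offset, fitted in an arbitrary
## column basis Z (already full rank). Returns coefficients in that basis.
.irlsPoisson <- function(Z, y, offset, maxIter, tol) {
    mu <- y + 0.5                      # robust to zero-death cells
    eta <- log(mu)
    dev <- .poissonDeviance(y, mu)
    cf <- NULL
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        if (any(!is.finite(mu)) || any(mu <= 0))
            stop("degenerate IRLS weights (fitted means left (0, Inf))")
        z <- eta + (y - mu) / mu - offset
        fit <- lm.wfit(Z, z, w = mu)
        if (anyNA(fit$coefficients))
            stop("working design is rank deficient within IRLS")
        cf <- fit$coefficients
        eta <- offset + drop(Z %*% cf)
        mu <- exp(eta)
        devNew <- .poissonDeviance(y, mu)
        if (is.finite(devNew) &&
            abs(devNew - dev) / (abs(dev) + 0.1) < tol) {
            dev <- devNew
            converged <- TRUE
            break
        }
        dev <- devNew
    }
    list(coefficients = cf, deviance = dev, converged = converged,
         iterations = iter)
}

#' Fit the APC model by the Intrinsic Estimator
#'
#' Fits the Poisson log-rate model
#' \deqn{\log r_{ijk} = u + \alpha_i + \beta_j + \gamma_k}
#' to a mortality surface, with deaths as the outcome and log person-years
#' as the offset (the model is fitted on the proportion scale; the reporting
#' scale enters only when rates are derived). The APC design is rank
#' deficient by one, so the likelihood has a one-dimensional flat: the
#' Intrinsic Estimator is the unique maximizer orthogonal to the design's
#' null vector.
#'
#' The fit takes the principal-components route: the null eigenvector of
#' \eqn{X^\top X} is dropped, iteratively reweighted least squares runs in
#' the reduced (non-null) eigenbasis, and the coefficients are mapped back.
#' The result is therefore orthogonal to \code{nullVector(design)} by
#' construction, and every estimable function (fitted rates, second
#' differences of effects) matches any just-identified constrained fit; see
#' \code{\link{fitConstrained}}.
#'
#' @param surface a \linkS4class{MortalitySurface}.
#' @param design the matching \linkS4class{APCDesign} from
#'   \code{\link{buildDesign}}.
#' @param maxIter maximum IRLS iterations (default 100).
#' @param tol relative deviance-change convergence tolerance (default 1e-8).
#' @return an \linkS4class{EffectEstimates}. If IRLS does not converge the
#'   result is returned with \code{converged(fit) = FALSE} and a warning.
#' @examples
#' cfg <- SyntheticConfig(ages = 40:49, periods = 2001:2008)
#' truth <- generateTrueEffects(cfg)
#' surf <- simulateSurface(truth, cfg)
#' fit <- fitIntrinsicEstimator(surf, buildDesign(40:49, 2001:2008))
#' ageEffects(fit)
#' @export
fitIntrinsicEstimator <- function(surface, design, maxIter = 100L,
                                  tol = 1e-8) {
    .checkSurfaceDesign(surface, design)
    X <- design@matrix
    y <- as.vector(deaths(surface))
    offs <- log(as.vector(population(surface)))

    e <- eigen(crossprod(X), symmetric = TRUE)
    keep <- e$values >= 1e-8 * max(e$values)
    if (sum(!keep) != 1L)
        stop("design does not have exactly one null dimension")
    U <- e$vectors[, keep, drop = FALSE]

    res <- .irlsPoisson(X %*% U, y, offs, maxIter = maxIter, tol = tol)
    if (!res$converged)
        warning(sprintf(
            "IRLS did not converge within %d iterations (relative deviance tolerance %g)",
            maxIter, tol))
    theta <- drop(U %*% res$coefficients)
    .expandEffects(theta, design, deviance = res$deviance,
                   converged = res$converged, nIterations = res$iterations)
}

#' Fit the APC model under an equality constraint on two cohorts
#'
#' Resolves the APC identification problem by the classical route instead of
#' the Intrinsic Estimator: two chosen cohort effects are constrained to be
#' equal, which removes the one flat direction and gives a just-identified
#' Poisson fit (via \code{stats::glm.fit}). Any such fit shares all
#' estimable functions (fitted log-rates, second differences, deviance) with
#' the Intrinsic Estimator, which makes it the natural validation oracle.
#'
#' @param surface a \linkS4class{MortalitySurface}.
#' @param design the matching \linkS4class{APCDesign}.
#' @param constraint two distinct cohort birth years (present in
#'   \code{cohorts(design)}) whose effects are set equal; default the first
#'   two cohorts.
#' @param maxIter,tol IRLS control passed to \code{glm.fit}.
#' @return an \linkS4class{EffectEstimates} with
#'   \code{cohortEffects[constraint[1]] == cohortEffects[constraint[2]]}.
#' @export
fitConstrained <- function(surface, design,
                           constraint = cohorts(design)[1:2],
                           maxIter = 100L, tol = 1e-8) {
    .checkSurfaceDesign(surface, design)
    constraint <- as.integer(constraint)
    if (length(constraint) != 2L || constraint[1] == constraint[2])
        stop("constraint must name two distinct cohort years")
    if (!all(constraint %in% design@cohorts))
        stop("constraint cohorts must be present in the design")

    cm <- design@columnMap
    p <- ncol(design@matrix)
    C <- length(design@cohorts)
    ## contrast c with c' theta = gamma_{k1} - gamma_{k2}, in the
    ## deviation-coded parameter space (last cohort = negative sum)
    gammaDir <- function(k) {
        idx <- match(k, design@cohorts)
        v <- numeric(p)
        if (idx < C) v[which(cm$block == "cohort")[idx]] <- 1
        else v[cm$block == "cohort"] <- -1
        v
    }
    cvec <- gammaDir(constraint[1]) - gammaDir(constraint[2])
    ## orthonormal basis of {theta : c' theta = 0}
    N <- qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]

    y <- as.vector(deaths(surface))
    offs <- log(as.vector(population(surface)))
    fit <- suppressWarnings(glm.fit(
        x = design@matrix %*% N, y = y, family = poisson(),
        offset = offs,
        control = list(epsilon = tol, maxit = maxIter, trace = FALSE)))
    if (!fit$converged)
        warning("constrained Poisson fit did not converge")
    theta <- drop(N %*% fit$coefficients)
    .expandEffects(theta, design, deviance = fit$deviance,
                   converged = fit$converged, nIterations = fit$iter)
}

#' Fitted log-rates (log proportion scale) on the Lexis grid
#'
#' Evaluates \eqn{u + \alpha_i + \beta_j + \gamma_{j-i}} for every cell of
#' the age x period grid. Fitted log-rates are estimable: they agree across
#' the Intrinsic Estimator and all constrained fits of the same data.
#'
#' @param estimates an \linkS4class{EffectEstimates}.
#' @return numeric matrix (ages x periods) of log death proportions, with
#'   age/year dimnames.
#' @export
fittedLogRates <- function(estimates) {
    a <- estimates@ageEffects
    b <- estimates@periodEffects
    g <- estimates@cohortEffects
    agesV <- as.integer(names(a))
    yearsV <- as.integer(names(b))
    m <- estimates@intercept + outer(a, b, "+")
    cohortYear <- outer(agesV, yearsV, function(i, j) j - i)
    m <- m + matrix(g[as.character(cohortYear)], nrow = length(agesV))
    dimnames(m) <- list(agesV, yearsV)
    m
}

#' @rdname EffectEstimates-accessors
#' @export
setMethod("intercept", "EffectEstimates", function(x) x@intercept)

#' @rdname EffectEstimates-accessors
#' @export
setMethod("ageEffects", "EffectEstimates", function(x) x@ageEffects)

#' @rdname EffectEstimates-accessors
#' @export
setMethod("periodEffects", "EffectEstimates", function(x) x@periodEffects)

#' @name EffectEstimates-accessors
#' @title Accessors for EffectEstimates
#' @description Extract the intercept and the centered age, period, and
#'   cohort effect vectors (named by category year) from an
#'   \linkS4class{EffectEstimates}.
#' @rdname EffectEstimates-accessors
#' @export
setMethod("cohortEffects", "EffectEstimates", function(x) x@cohortEffects)

#' Deviance and convergence of a fit
#' @param x an \linkS4class{EffectEstimates}.
#' @return \code{fitDeviance}: the residual Poisson deviance;
#'   \code{converged}: the convergence flag.
#' @export
fitDeviance <- function(x) {
    stopifnot(is(x, "EffectEstimates"))
    x@deviance
}

#' @rdname fitDeviance
#' @export
converged <- function(x) {
    stopifnot(is(x, "EffectEstimates"))
    x@converged
}

setMethod("show", "EffectEstimates", function(object) {
    a <- names(object@ageEffects); p <- names(object@periodEffects)
    k <- names(object@cohortEffects)
    cat("EffectEstimates (log proportion scale)\n")
    cat(sprintf("  intercept u = %.4f\n", object@intercept))
    cat(sprintf("  age effects:    %d categories (%s-%s), range % .3f to % .3f\n",
        length(a), a[1], a[length(a)],
        min(object@ageEffects), max(object@ageEffects)))
    cat(sprintf("  period effects: %d categories (%s-%s), range % .3f to % .3f\n",
        length(p), p[1], p[length(p)],
        min(object@periodEffects), max(object@periodEffects)))
    cat(sprintf("  cohort effects: %d categories (%s-%s), range % .3f to % .3f\n",
        length(k), k[1], k[length(k)],
        min(object@cohortEffects), max(object@cohortEffects)))
    if (!is.na(object@deviance))
        cat(sprintf("  deviance %.4f, converged %s after %d iterations\n",
            object@deviance, object@converged, object@nIterations))
    invisible(NULL)
})
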