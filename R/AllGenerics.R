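#' @rdname MortalitySurface
#' @param x an object.
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @rdname MortalitySurface
#' @export
setGeneric("periods", function(x) standardGeneric("periods"))

#' @rdname MortalitySurface
#' @export
setGeneric("deaths", function(x) standardGeneric("deaths"))

#' @rdname MortalitySurface
#' @export
setGeneric("population", function(x) standardGeneric("population"))

#' @rdname MortalitySurface
#' @export
setGeneric("stratumLabel", function(x) standardGeneric("stratumLabel"))

#' @rdname MortalitySurface
#' @export
setGeneric("rateScale", function(x) standardGeneric("rateScale"))

#' Extract the null-space basis vector
#'
#' For an \linkS4class{APCDesign}, returns the stored unit null vector. For a
#' plain matrix, computes the right-singular vector belonging to the single
#' zero singular value (relative tolerance \code{tol} against the largest
#' singular value), with the sign fixed so the first nonzero entry is
#' positive. A matrix with no null dimension, or with two or more, is an
#' error that reports the tail of the singular-value spectrum.
#'
#' @param x an \linkS4class{APCDesign} or a numeric matrix.
#' @param ... further arguments (\code{tol} for the matrix method).
#' @return unit-norm numeric vector \code{v} with \code{x \%*\% v = 0}.
#' @examples
#' d <- buildDesign(60:64, 2000:2004)
#' v <- nullVector(d)
#' max(abs(designMatrix(d) %*% v))  # ~ 0
#' @export
setGeneric("nullVector", function(x, ...) standardGeneric("nullVector"))

#' @rdname APCDesign-accessors
#' @param x an \linkS4class{APCDesign}.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname APCDesign-accessors
#' @export
setGeneric("cohorts", function(x) standardGeneric("cohorts"))

#' @rdname APCDesign-accessors
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))

#' @rdname EffectEstimates-accessors
#' @param x an \linkS4class{EffectEstimates}.
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @rdname EffectEstimates-accessors
#' @export
setGeneric("ageEffects", function(x) standardGeneric("ageEffects"))

#' @rdname EffectEstimates-accessors
#' @export
setGeneric("periodEffects", function(x) standardGeneric("periodEffects"))

#' @rdname EffectEstimates-accessors
#' @export
setGeneric("cohortEffects", function(x) standardGeneric("cohortEffects"))

#' @rdname series-accessors
#' @param x a \linkS4class{RateSeries} or \linkS4class{PrevalenceSeries}.
#' @export
setGeneric("years", function(x) standardGeneric("years"))

#' @rdname series-accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))

#' @rdname series-accessors
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))
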