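## Deviation (sum-to-zero) coding, last category omitted: a row in category c
## scores +1 in column c (c < L), and -1 in every column when c is the
## omitted last category. The full-length effect vector is recovered with the
## negative-sum rule, so recovered effects always sum to zero.
.deviationCode <- function(idx, L) {
    n <- length(idx)
    M <- matrix(0, n, L - 1L)
    inner <- idx < L
    M[cbind(which(inner), idx[inner])] <- 1
    M[!inner, ] <- -1
    M
}

.checkConsecutiveYears <- function(x, what) {
    if (length(x) < 3L)
        stop(sprintf("need at least 3 %s (one-dimensional null space is only guaranteed for non-degenerate designs)", what))
    if (anyNA(x) || any(diff(x) != 1L))
        stop(sprintf("%s must be consecutive single years", what))
    invisible(x)
}

#' Build the deviation-coded APC design
#'
#' Constructs the design matrix of the age-period-cohort Poisson log-rate
#' model \deqn{\log r_{ijk} = u + \alpha_i + \beta_j + \gamma_k,}
#' on a grid of consecutive single-year ages and calendar years. The birth
#' cohort of a cell is \code{period - age}, so with \eqn{A} ages and \eqn{P}
#' periods there are \eqn{C = A + P - 1} cohorts. Each block is deviation
#' (sum-to-zero) coded with its last category omitted, giving
#' \code{1 + (A-1) + (P-1) + (C-1)} columns; rows are the \eqn{A \times P}
#' cells with age varying fastest (matching \code{as.vector} on an
#' age-by-period matrix).
#'
#' Because \code{cohort = period - age} exactly, the matrix has a
#' one-dimensional null space; its unit basis vector is computed from the
#' eigendecomposition of \eqn{X^\top X} and stored in the result (eigenvalues
#' below \code{1e-8} times the largest are treated as null, and exactly one
#' must be).
#'
#' @param ages consecutive integer ages, at least 3 (e.g. \code{25:84}).
#' @param periods consecutive integer calendar years, at least 3
#'   (e.g. \code{1999:2018}).
#' @return an \linkS4class{APCDesign}.
#' @examples
#' d <- buildDesign(25:84, 1999:2018)
#' range(cohorts(d))   # 1915 1993
#' ncol(designMatrix(d))  # 157
#' @export
buildDesign <- function(ages, periods) {
    ages <- .checkConsecutiveYears(as.integer(ages), "ages")
    periods <- .checkConsecutiveYears(as.integer(periods), "periods")
    A <- length(ages); P <- length(periods)
    cohortYears <- seq.int(min(periods) - max(ages), max(periods) - min(ages))
    C <- length(cohortYears)

    ageIdx <- rep(seq_len(A), times = P)
    perIdx <- rep(seq_len(P), each = A)
    cohIdx <- match(periods[perIdx] - ages[ageIdx], cohortYears)

    X <- cbind(1, .deviationCode(ageIdx, A), .deviationCode(perIdx, P),
               .deviationCode(cohIdx, C))
    columnMap <- data.frame(
        block = c("intercept", rep("age", A - 1L), rep("period", P - 1L),
                  rep("cohort", C - 1L)),
        category = c(NA_integer_, ages[-A], periods[-P],
                     cohortYears[-C])
    )
    colnames(X) <- ifelse(is.na(columnMap$category), "(Intercept)",
                          paste(columnMap$block, columnMap$category,
                                sep = "_"))
    v <- .nullFromEigen(X)
    new("APCDesign", matrix = X, ages = ages, periods = periods,
        cohorts = cohortYears, columnMap = columnMap, nullVector = v)
}

## Null basis via eigendecomposition of X'X (deterministic, symmetric).
.nullFromEigen <- function(X, tol = 1e-8) {
    e <- eigen(crossprod(X), symmetric = TRUE)
    lam <- e$values
    isNull <- lam < tol * max(lam)
    if (sum(isNull) != 1L)
        stop(sprintf(
            "expected exactly one null dimension, found %d (eigenvalue tail: %s)",
            sum(isNull),
            paste(signif(rev(tail(sort(lam, decreasing = TRUE),
                                  min(4, length(lam)))), 3),
                  collapse = ", ")))
    .fixSign(e$vectors[, which(isNull)])
}

.fixSign <- function(v) {
    v <- v / sqrt(sum(v^2))
    first <- which(abs(v) > 1e-12)[1]
    if (!is.na(first) && v[first] < 0) v <- -v
    v
}

#' @rdname nullVector
#' @export
setMethod("nullVector", "APCDesign", function(x, ...) x@nullVector)

#' @rdname nullVector
#' @param tol relative tolerance on singular values: a singular value below
#'   \code{tol} times the largest counts as zero (default \code{1e-8}).
#' @export
setMethod("nullVector", "matrix", function(x, tol = 1e-8, ...) {
    s <- svd(x, nu = 0)
    d <- s$d
    isNull <- d < tol * d[1]
    tail_ <- paste(signif(tail(d, min(4, length(d))), 3), collapse = ", ")
    if (sum(isNull) == 0L)
        stop("no null dimension at tolerance ", tol,
             " (singular-value tail: ", tail_, ")")
    if (sum(isNull) > 1L)
        stop(sum(isNull), " null dimensions at tolerance ", tol,
             " (singular-value tail: ", tail_, ")")
    .fixSign(s$v[, which(isNull)])
})

#' @rdname APCDesign-accessors
#' @export
setMethod("designMatrix", "APCDesign", function(x) x@matrix)

#' @rdname APCDesign-accessors
#' @export
setMethod("ages", "APCDesign", function(x) x@ages)

#' @rdname APCDesign-accessors
#' @export
setMethod("periods", "APCDesign", function(x) x@periods)

#' @name APCDesign-accessors
#' @title Accessors for APCDesign
#' @description Extract the design matrix, category labels, and column map
#'   of an \linkS4class{APCDesign}.
#' @rdname APCDesign-accessors
#' @export
setMethod("cohorts", "APCDesign", function(x) x@cohorts)

#' @rdname APCDesign-accessors
#' @export
setMethod("columnMap", "APCDesign", function(x) x@columnMap)

setMethod("show", "APCDesign", function(object) {
    cat(sprintf(
        "APCDesign: ages %d-%d, periods %d-%d, cohorts %d-%d\n",
        min(object@ages), max(object@ages),
        min(object@periods), max(object@periods),
        min(object@cohorts), max(object@cohorts)))
    cat(sprintf(
        "  %d x %d deviation-coded matrix, rank %d (one null dimension)\n",
        nrow(object@matrix), ncol(object@matrix), ncol(object@matrix) - 1L))
    invisible(NULL)
})

#' Second differences of an effect vector
#'
#' \code{v[t+1] - 2 v[t] + v[t-1]} for interior points. Second differences
#' are estimable functions of APC effects: they take the same value under
#' every identifying constraint, so they are the natural quantity on which
#' to compare the Intrinsic Estimator with constrained fits.
#'
#' @param effects numeric vector of length at least 3.
#' @return numeric vector of length \code{length(effects) - 2}.
#' @examples
#' secondDifferences(c(0, 1, 4, 9))  # 2 2
#' @export
secondDifferences <- function(effects) {
    if (length(effects) < 3L)
        stop("need at least 3 values to form second differences")
    diff(effects, differences = 2L)
}
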