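#' Combine per-imputation estimates with Rubin's rules
#'
#' Given `m` per-imputation estimates `Q_i` and within-imputation variances
#' `U_i`, computes the pooled estimate `Q_bar = mean(Q_i)`, the average
#' within-imputation variance `W_bar = mean(U_i)`, the between-imputation
#' variance `B = var(Q_i)` (divisor `m - 1`), the total variance
#' `T = W_bar + (1 + 1/m) B`, the relative increase in variance
#' `r = (1 + 1/m) B / W_bar`, the degrees of freedom
#' `nu = (m - 1)(1 + 1/r)^2`, and the fraction of missing information
#' `lambda = (r + 2/(nu + 3)) / (r + 1)`.  The two-sided p-value and the
#' confidence interval use `Q_bar / sqrt(T)` against a Student t reference
#' with `nu` degrees of freedom.  When `B = 0` the result collapses to
#' complete-data (normal) inference.
#'
#' @param estimates numeric vector of `m >= 2` per-imputation estimates.
#' @param variances numeric vector of matching positive variances.
#' @param level confidence level (default 0.95).
#' @return a [PooledResult-class].
#' @examples
#' poolEstimates(c(0, 1), c(1, 1))
#' @export
poolEstimates <- function(estimates, variances, level = 0.95) {
    m <- length(estimates)
    if (m < 2L) stop("need at least 2 imputations to pool")
    if (length(variances) != m) stop("estimates and variances differ in length")
    if (any(!is.finite(variances)) || any(variances <= 0))
        stop("within-imputation variances must be positive and finite")
    qBar <- mean(estimates)
    wBar <- mean(variances)
    b <- var(estimates)
    tVar <- wBar + (1 + 1 / m) * b
    r <- (1 + 1 / m) * b / wBar
    if (r > 0) {
        nu <- (m - 1) * (1 + 1 / r)^2
        lambda <- (r + 2 / (nu + 3)) / (r + 1)
    } else {
        nu <- Inf
        lambda <- 0
    }
    tcrit <- qt((1 + level) / 2, df = nu)
    ci <- qBar + c(-1, 1) * tcrit * sqrt(tVar)
    p <- 2 * pt(-abs(qBar / sqrt(tVar)), df = nu)
    new("PooledResult", estimate = qBar, wBar = wBar, b = b, tVar = tVar,
        r = r, nu = nu, lambda = lambda,
        ci = setNames(ci, c("lower", "upper")), p = p, m = as.integer(m),
        level = level, scale = "identity")
}

#' Rubin pooling on the Fisher-z scale
#'
#' The sample inbreeding coefficient is an intraclass correlation, whose
#' normality improves under Fisher's transformation `z = atanh(f)`.  Each
#' estimate is transformed, its variance mapped by the delta method
#' (`Var(z) = Var(f) / (1 - f^2)^2`), pooling is performed on the z scale,
#' and the pooled estimate and interval are back-transformed with `tanh`.
#' The variance components (`wBar`, `b`, `tVar`, and hence `r`, `lambda`)
#' refer to the z scale.
#'
#' @param estimates per-imputation inbreeding coefficients, all strictly
#'   inside (-1, 1).
#' @param variances matching positive variances (identity scale).
#' @param level confidence level.
#' @return a [PooledResult-class] with `scale = "fisher.z"`.
#' @export
poolFisherZ <- function(estimates, variances, level = 0.95) {
    if (any(abs(estimates) >= 1))
        stop("|f| = 1 gives an infinite Fisher z; pool on the identity scale")
    z <- atanh(estimates)
    vz <- variances / (1 - estimates^2)^2
    pz <- poolEstimates(z, vz, level = level)
    new("PooledResult", estimate = tanh(pz@estimate), wBar = pz@wBar,
        b = pz@b, tVar = pz@tVar, r = pz@r, nu = pz@nu, lambda = pz@lambda,
        ci = setNames(tanh(pz@ci), c("lower", "upper")), p = pz@p,
        m = pz@m, level = level, scale = "fisher.z")
}

#' @rdname PooledResult-accessors
#' @param x a `PooledResult`.
#' @export
pooledEstimate <- function(x) x@estimate

#' Accessors for PooledResult
#' @rdname PooledResult-accessors
#' @export
pooledCI <- function(x) x@ci

#' @rdname PooledResult-accessors
#' @export
pooledP <- function(x) x@p

#' @rdname PooledResult-accessors
#' @export
relativeVarianceIncrease <- function(x) x@r

#' @rdname PooledResult-accessors
#' @export
missingInfoFraction <- function(x) x@lambda

setMethod("show", "PooledResult", function(object) {
    cat(sprintf("PooledResult (m = %d, %s scale)\n", object@m, object@scale))
    cat(sprintf("  f = %.4f  %g%% CI (%.4f, %.4f)  p = %.4g\n",
                object@estimate, 100 * object@level, object@ci[1L],
                object@ci[2L], object@p))
    cat(sprintf("  W = %.5g  B = %.5g  T = %.5g\n",
                object@wBar, object@b, object@tVar))
    cat(sprintf("  r = %.3f  nu = %.1f  lambda = %.3f\n",
                object@r, object@nu, object@lambda))
    invisible(NULL)
})

#' Pool the inbreeding coefficient over an imputation set
#'
#' Estimates the inbreeding coefficient and its variance on each completed
#' data set of an [ImputedPanelSet-class] (for `marker`, default the
#' imputation target), with the variance evaluated at the completed sample
#' size (all individuals), and combines them with Rubin's rules.  When any
#' completed copy gives |f| = 1, Fisher-z pooling is impossible and the
#' identity scale is used with a warning.
#'
#' @param set an `ImputedPanelSet`.
#' @param marker marker to pool (default: the target).
#' @param level confidence level.
#' @param scale `"identity"` (default) or `"fisher.z"`.
#' @return a [PooledResult-class].
#' @export
poolInbreeding <- function(set, marker = NULL, level = 0.95,
                           scale = c("identity", "fisher.z")) {
    scale <- match.arg(scale)
    stopifnot(is(set, "ImputedPanelSet"))
    if (is.null(marker)) marker <- set@target
    ests <- vapply(set@completions, function(cm) {
        e <- estimateInbreeding(tabulateCounts(cm[marker, ]))
        c(fHat(e), varF(e))
    }, numeric(2))
    if (anyNA(ests))
        stop("undefined estimate or variance in a completed copy for marker ",
             marker)
    if (scale == "fisher.z" && any(abs(ests[1L, ]) >= 1)) {
        warning("|f| = 1 in a completed copy; falling back to identity scale")
        scale <- "identity"
    }
    if (scale == "fisher.z")
        poolFisherZ(ests[1L, ], ests[2L, ], level = level)
    else
        poolEstimates(ests[1L, ], ests[2L, ], level = level)
}

#' Hardy-Weinberg test by multiple imputation
#'
#' End-to-end inference for Hardy-Weinberg proportions in the presence of
#' missing calls: for each requested marker with missing data, impute
#' (`model = "random"` for marginal draws; otherwise chained equations
#' with intensities and/or LD covariates), estimate the inbreeding
#' coefficient and its variance on every completed copy, and pool with
#' Rubin's rules.  Markers without missing calls are pooled over identical
#' copies and reproduce complete-case inference.  Markers that cannot be
#' imputed (monomorphic-observed, entirely missing) are reported with `NA`
#' statistics and flagged in the `skipped` column.
#'
#' @param panel a `GenoPanel`.
#' @param markers marker ids (default: all markers with missings).
#' @param model `"both"`, `"intensities"`, `"snps"` or `"random"`.
#' @param m number of imputations (default 50).
#' @param iterations chained-equation sweeps (default 10).
#' @param ldThreshold,maxCovariates LD covariate selection controls.
#' @param ridge L2 penalty for the logit fits.
#' @param level confidence level.
#' @param scale pooling scale, `"identity"` or `"fisher.z"`.
#' @param seed optional integer seed.
#' @return `data.frame` with columns marker, m, f_pooled, se, ci_low,
#'   ci_high, p, r, lambda, nu, n_missing, model, skipped.
#' @export
miHWPTest <- function(panel, markers = NULL,
                      model = c("both", "intensities", "snps", "random"),
                      m = 50L, iterations = 10L, ldThreshold = 0.5,
                      maxCovariates = 10L, ridge = 1e-4, level = 0.95,
                      scale = c("identity", "fisher.z"), seed = NULL) {
    model <- match.arg(model)
    scale <- match.arg(scale)
    if (!is.null(seed)) set.seed(seed)
    cl <- genotypeCalls(panel)
    if (is.null(markers))
        markers <- rownames(cl)[rowSums(is.na(cl)) > 0L]
    rows <- lapply(markers, function(mk) {
        base <- data.frame(marker = mk, m = as.integer(m), f_pooled = NA_real_,
                           se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                           p = NA_real_, r = NA_real_, lambda = NA_real_,
                           nu = NA_real_, n_missing = sum(is.na(cl[mk, ])),
                           model = model, skipped = FALSE)
        res <- tryCatch({
            set <- if (model == "random") {
                imputeRandom(panel[mk, ], m = m)
            } else {
                covs <- if (model == "intensities") character(0)
                        else as.character(selectCovariates(
                            panel, mk, ldThreshold = ldThreshold,
                            maxCovariates = maxCovariates))
                useInt <- model %in% c("intensities", "both") &&
                    isTRUE(hasIntensities(panel, mk)[[1L]])
                if (model == "intensities" && !useInt)
                    stop("no intensities available for marker ", mk)
                sub <- panel[unique(c(mk, covs)), ]
                imputeChained(sub, mk, covariates = covs,
                              useIntensities = useInt, m = m,
                              iterations = iterations, ridge = ridge)
            }
            poolInbreeding(set, marker = mk, level = level, scale = scale)
        }, error = function(e) NULL)
        if (is.null(res)) {
            base$skipped <- TRUE
            return(base)
        }
        base$f_pooled <- pooledEstimate(res)
        base$se <- sqrt(res@tVar)
        base$ci_low <- res@ci[[1L]]; base$ci_high <- res@ci[[2L]]
        base$p <- res@p; base$r <- res@r; base$lambda <- res@lambda
        base$nu <- res@nu
        base
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
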