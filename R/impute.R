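#' Multiple imputation by random draws from the observed genotypes
#'
#' Fills every missing call of every marker by an independent draw from
#' that marker's observed empirical genotype distribution, `m` times.
#' This is the imputation model implied by the MCAR assumption; it never
#' imputes a genotype category that was not observed at the marker.
#'
#' @param x a `GenoPanel`, or an integer dosage vector (0/1/2/`NA`) for a
#'   single marker.
#' @param m number of imputations (default 50).
#' @param seed optional integer seed; recorded in the result.
#' @param ... unused.
#' @return an [ImputedPanelSet-class].
#' @examples
#' calls <- rep(c(0L, 1L, 2L, NA), c(46L, 32L, 20L, 48L))
#' set <- imputeRandom(calls, m = 5, seed = 7)
#' @rdname imputeRandom
#' @export
setMethod("imputeRandom", "GenoPanel", function(x, m = 50L, seed = NULL, ...) {
    m <- as.integer(m)
    if (m < 2L) stop("m must be at least 2")
    if (!is.null(seed)) set.seed(seed)
    cl <- genotypeCalls(x)
    missIdx <- lapply(seq_len(nrow(cl)), function(i) which(is.na(cl[i, ])))
    obsVals <- lapply(seq_len(nrow(cl)), function(i) cl[i, !is.na(cl[i, ])])
    for (i in seq_len(nrow(cl)))
        if (length(missIdx[[i]]) && length(obsVals[[i]]) == 0L)
            stop("marker ", rownames(cl)[i], " is entirely missing; cannot impute")
    target <- rownames(cl)[which.max(vapply(missIdx, length, integer(1)))]
    completions <- vector("list", m)
    traces <- matrix(NA_real_, nrow = 1L, ncol = m)
    ti <- match(target, rownames(cl))
    for (k in seq_len(m)) {
        cm <- cl
        for (i in seq_len(nrow(cl))) {
            if (length(missIdx[[i]]))
                cm[i, missIdx[[i]]] <- sample(obsVals[[i]],
                                              length(missIdx[[i]]),
                                              replace = TRUE)
        }
        completions[[k]] <- cm
        traces[1L, k] <- tryCatch(fHat(estimateInbreeding(tabulateCounts(cm[ti, ]))),
                                  error = function(e) NA_real_)
    }
    new("ImputedPanelSet", source = x, completions = completions,
        traces = setNames(list(traces), target), target = target,
        method = "random",
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        params = list(m = m))
})

#' @rdname imputeRandom
#' @export
setMethod("imputeRandom", "numeric", function(x, m = 50L, seed = NULL, ...) {
    imputeRandom(GenoPanel(matrix(x, nrow = 1L,
                                  dimnames = list("marker", NULL))),
                 m = m, seed = seed)
})

#' Multiple imputation of genotype calls by chained equations
#'
#' MICE-style multiple imputation of a target marker's missing calls from
#' allele intensities and/or covariate markers in linkage disequilibrium,
#' with ridge-penalized multinomial logit models (see
#' [fitMultinomialLogit()]).  Incomplete covariates are imputed alongside
#' the target (non-monotone missingness).
#'
#' For each of the `m` streams: every incomplete variable is initialized
#' by marginal draws from its observed calls; then for `iterations`
#' sweeps, the incomplete variables are visited in order of increasing
#' missingness, the multinomial logit of each variable on the currently
#' completed other variables (plus the variable's own intensity channels,
#' if requested) is refit on its observed rows, a coefficient vector is
#' drawn from the asymptotic normal distribution of the penalized fit,
#' and each missing call is drawn from the resulting category
#' probabilities.  A variable with a single observed category, or whose
#' model fit fails, falls back to marginal draws.  Covariate markers enter
#' the linear predictor as allele dosage plus a heterozygote indicator
#' (equivalent to unordered-category coding when all three genotypes are
#' observed).
#'
#' Imputed categories are always a subset of the categories observed at
#' the marker; observed data are never modified.  The per-sweep inbreeding
#' coefficient of the target is recorded per stream for convergence
#' inspection ([convergenceTrace()]).
#'
#' @param panel a `GenoPanel`.
#' @param target target marker identifier (must have at least one missing
#'   and two observed genotype categories).
#' @param covariates covariate marker ids, or `NULL` to select them by LD
#'   ([selectCovariates()]).
#' @param useIntensities logical; include each variable's own intensity
#'   channels as predictors (default: use them when present).
#' @param m number of imputations (default 50).
#' @param iterations chained-equation sweeps per stream (default 10).
#' @param ridge L2 penalty scale (default `1e-4`).
#' @param ldThreshold,maxCovariates covariate selection controls, used when
#'   `covariates` is `NULL`.
#' @param seed optional integer seed.
#' @return an [ImputedPanelSet-class].
#' @export
imputeChained <- function(panel, target, covariates = NULL,
                          useIntensities = NULL, m = 50L, iterations = 10L,
                          ridge = 1e-4, ldThreshold = 0.5, maxCovariates = 10L,
                          seed = NULL) {
    m <- as.integer(m); iterations <- as.integer(iterations)
    if (m < 2L) stop("m must be at least 2")
    if (iterations < 1L) stop("iterations must be at least 1")
    if (!is.null(seed)) set.seed(seed)
    cl <- genotypeCalls(panel)
    stopifnot(target %in% rownames(cl))
    if (is.null(covariates))
        covariates <- as.character(selectCovariates(panel, target,
                                                    ldThreshold = ldThreshold,
                                                    maxCovariates = maxCovariates))
    covariates <- setdiff(covariates, target)
    if (is.null(useIntensities))
        useIntensities <- isTRUE(hasIntensities(panel, target)[[1L]])
    allMiss <- covariates[vapply(covariates,
                                 function(v) all(is.na(cl[v, ])), logical(1))]
    if (length(allMiss)) {
        warning("dropping entirely missing covariate(s): ",
                paste(allMiss, collapse = ", "))
        covariates <- setdiff(covariates, allMiss)
    }
    vars <- c(target, covariates)
    tgtObs <- cl[target, !is.na(cl[target, ])]
    if (length(unique(tgtObs)) < 2L)
        stop("target marker has fewer than 2 observed genotype categories")
    nmis <- vapply(vars, function(v) sum(is.na(cl[v, ])), integer(1))
    incomplete <- vars[nmis > 0L]
    incomplete <- incomplete[order(nmis[match(incomplete, vars)])]
    A <- intensityA(panel); B <- intensityB(panel)

    predictorFrame <- function(cm, v, rows) {
        X <- list()
        for (o in setdiff(vars, v)) {
            d <- cm[o, rows]
            nm <- make.names(o)
            X[[paste0("d_", nm)]] <- as.numeric(d)
            X[[paste0("h_", nm)]] <- as.numeric(d == 1L)
        }
        if (useIntensities && !is.null(A) &&
            isTRUE(hasIntensities(panel, v)[[1L]])) {
            X[["intA"]] <- A[v, rows]
            X[["intB"]] <- B[v, rows]
        }
        if (!length(X)) NULL else as.data.frame(X)
    }

    completions <- vector("list", m)
    traces <- matrix(NA_real_, nrow = iterations, ncol = m)
    warned <- character(0)
    for (k in seq_len(m)) {
        cm <- cl
        for (v in incomplete) {
            mi <- which(is.na(cm[v, ]))
            ov <- cm[v, -mi]
            cm[v, mi] <- sample(ov, length(mi), replace = TRUE)
        }
        for (it in seq_len(iterations)) {
            for (v in incomplete) {
                mi <- which(is.na(cl[v, ]))
                oi <- which(!is.na(cl[v, ]))
                yobs <- cl[v, oi]
                cats <- sort(unique(yobs))
                if (length(cats) < 2L) {
                    cm[v, mi] <- sample(yobs, length(mi), replace = TRUE)
                    next
                }
                Xobs <- predictorFrame(cm, v, oi)
                drawn <- tryCatch({
                    lf <- suppressWarnings(
                        fitMultinomialLogit(factor(yobs, levels = cats),
                                            Xobs, ridge = ridge))
                    Xmis <- if (is.null(Xobs)) NULL else
                        predictorFrame(cm, v, mi)
                    pr <- predictCategoryProbs(lf, newdata = Xmis,
                                               coefVec = drawCoefficients(lf),
                                               n = length(mi))
                    catNum <- as.integer(lf$categories)
                    vapply(seq_len(nrow(pr)), function(r)
                        sample(catNum, 1L, prob = pr[r, ]), integer(1))
                }, error = function(e) {
                    warned <<- unique(c(warned, paste0(v, ": ", conditionMessage(e))))
                    sample(yobs, length(mi), replace = TRUE)
                })
                cm[v, mi] <- drawn
            }
            traces[it, k] <- tryCatch(
                fHat(estimateInbreeding(tabulateCounts(cm[target, ]))),
                error = function(e) NA_real_)
        }
        completions[[k]] <- cm
    }
    if (length(warned))
        warning("model fallback to marginal draws for: ",
                paste(utils::head(warned, 3L), collapse = "; "))
    new("ImputedPanelSet", source = panel, completions = completions,
        traces = setNames(list(traces), target), target = target,
        method = "chained",
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        params = list(m = m, iterations = iterations, ridge = ridge,
                      covariates = covariates,
                      useIntensities = useIntensities))
}

#' @rdname ImputedPanelSet-accessors
#' @export
setMethod("completions", "ImputedPanelSet", function(x) x@completions)

#' Accessors for ImputedPanelSet
#' @param x an `ImputedPanelSet`.
#' @param marker marker identifier (default: the imputation target).
#' @rdname ImputedPanelSet-accessors
#' @export
imputationCount <- function(x) length(x@completions)

#' Per-iteration inbreeding-coefficient traces
#'
#' Returns the iterations-by-m matrix of the target marker's inbreeding
#' coefficient after each chained-equation sweep, for convergence
#' (no-trend, good-mixing) inspection.  Random-draw imputations have a
#' single row.
#'
#' @param x an `ImputedPanelSet`.
#' @param marker traced marker id (default: the target).
#' @return numeric matrix, `iterations` rows and `m` columns.
#' @rdname convergenceTrace
#' @export
setMethod("convergenceTrace", "ImputedPanelSet", function(x, marker = NULL) {
    if (is.null(marker)) marker <- x@target
    if (!marker %in% names(x@traces))
        stop("no trace recorded for marker ", marker)
    x@traces[[marker]]
})

setMethod("show", "ImputedPanelSet", function(object) {
    cat(sprintf("ImputedPanelSet: m = %d (%s imputation)\n",
                length(object@completions), object@method))
    cat(sprintf("  target marker: %s; seed: %s\n", object@target,
                ifelse(is.na(object@seed), "unset", object@seed)))
    src <- genotypeCalls(object@source)
    cat(sprintf("  panel: %d markers x %d individuals, %d missing calls imputed\n",
                nrow(src), ncol(src), sum(is.na(src))))
    invisible(NULL)
})
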