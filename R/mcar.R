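#' Per-channel t tests comparing intensities of missing vs observed calls
#'
#' Under MCAR, individuals with a missing call should have the same mean
#' allele intensities as individuals with an observed call.  This runs a
#' two-sample t test per channel, either with pooled variance
#' (`equalVariance = TRUE`) or as Welch's test with Satterthwaite degrees
#' of freedom.
#'
#' @param a,b numeric intensity vectors (one value per individual).
#' @param missing logical indicator of a missing genotype call.
#' @param equalVariance assume homoscedasticity?
#' @return `data.frame` with rows `A` and `B`: statistic, df, p.value.
#' @export
intensityTTests <- function(a, b, missing, equalVariance = FALSE) {
    stopifnot(length(a) == length(missing), length(b) == length(missing))
    missing <- as.logical(missing)
    if (sum(missing) < 2L || sum(!missing) < 2L)
        stop("insufficient group size: both groups need at least 2 members")
    one <- function(x) {
        ht <- t.test(x[missing], x[!missing], var.equal = equalVariance)
        data.frame(statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p.value = ht$p.value)
    }
    out <- rbind(A = one(a), B = one(b))
    out$channel <- rownames(out)
    out[, c("channel", "statistic", "df", "p.value")]
}

#' Two-sample Hotelling T-squared test on the intensity plane
#'
#' Compares the mean intensity vector (A, B) of individuals with a missing
#' call against those with an observed call.  With `pooled = TRUE` the
#' classical pooled-covariance T-squared is used, with
#' `T2 * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))` referred to an
#' `F(p, n1 + n2 - p - 1)` distribution.  With `pooled = FALSE` the
#' Behrens-Fisher statistic `d' (S1/n1 + S2/n2)^{-1} d` is referred to an F
#' distribution with Yao's approximate degrees of freedom.
#'
#' @param a,b numeric intensity vectors per individual.
#' @param missing logical missing-call indicator.
#' @param pooled assume equal group covariance matrices?
#' @return an object of class `"htest"` (statistic is T-squared).
#' @export
hotellingT2 <- function(a, b, missing, pooled = TRUE) {
    stopifnot(length(a) == length(missing), length(b) == length(missing))
    missing <- as.logical(missing)
    X1 <- cbind(A = a, B = b)[missing, , drop = FALSE]
    X2 <- cbind(A = a, B = b)[!missing, , drop = FALSE]
    n1 <- nrow(X1); n2 <- nrow(X2); p <- 2L
    if (n1 < 3L || n2 < 3L)
        stop("insufficient group size: each group needs at least 3 members")
    d <- colMeans(X1) - colMeans(X2)
    S1 <- stats::cov(X1); S2 <- stats::cov(X2)
    if (pooled) {
        Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
        Si <- .safeSolve(Sp)
        t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% Si %*% d)
        df2 <- n1 + n2 - p - 1
        fstat <- t2 * df2 / (p * (n1 + n2 - 2))
        meth <- "Hotelling two-sample T2 (pooled covariance)"
    } else {
        W <- S1 / n1 + S2 / n2
        Wi <- .safeSolve(W)
        t2 <- drop(t(d) %*% Wi %*% d)
        # Yao (1965) approximate degrees of freedom
        q1 <- drop(t(d) %*% Wi %*% (S1 / n1) %*% Wi %*% d) / t2
        q2 <- drop(t(d) %*% Wi %*% (S2 / n2) %*% Wi %*% d) / t2
        nu <- 1 / (q1^2 / (n1 - 1) + q2^2 / (n2 - 1))
        df2 <- nu - p + 1
        fstat <- t2 * df2 / (nu * p)
        meth <- "Hotelling two-sample T2 (Yao unpooled approximation)"
    }
    structure(list(statistic = c("T2" = t2),
                   parameter = c(df1 = p, df2 = df2),
                   p.value = stats::pf(fstat, p, df2, lower.tail = FALSE),
                   method = meth, data.name = "intensity channels A, B"),
              class = "htest")
}

.safeSolve <- function(S) {
    out <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(out)) {
        ch <- colnames(S)[which.min(diag(S))]
        stop(sprintf("singular covariance matrix (degenerate channel '%s')", ch))
    }
    out
}

#' Contingency test of a covariate marker's genotypes by missingness status
#'
#' Under MCAR, the genotype distribution of a correlated neighbouring
#' marker should not differ between individuals with and without a call at
#' the target.  Builds the 2-by-k table of missingness status against
#' covariate genotype (individuals missing the covariate are dropped) and
#' applies the chi-square test when all expected cell counts are at least
#' 5, otherwise Fisher's exact test.
#'
#' @param missing logical missing-call indicator for the target marker.
#' @param covariate integer dosage vector of the covariate marker.
#' @return an object of class `"htest"`.
#' @export
covariateContingency <- function(missing, covariate) {
    stopifnot(length(missing) == length(covariate))
    missing <- as.logical(missing)
    keep <- !is.na(covariate)
    if (!any(keep)) stop("covariate is entirely missing")
    tab <- table(missing = missing[keep], genotype = covariate[keep])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2L)
        stop("covariate has fewer than 2 observed genotype categories")
    if (nrow(tab) < 2L) {
        # no variation in missingness among covariate-observed individuals
        return(structure(list(statistic = c(p = NA_real_), p.value = 1,
                              method = "degenerate table", data.name = "table"),
                         class = "htest"))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= 5)) {
        ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    } else {
        ht <- tryCatch(fisher.test(tab, workspace = 2e6),
                       error = function(e)
                           suppressWarnings(chisq.test(tab, correct = FALSE,
                                                       simulate.p.value = TRUE,
                                                       B = 10000)))
    }
    ht
}

#' MCAR diagnostic report for a panel
#'
#' For every marker with intensities and at least `minMissing` missing
#' calls, runs the per-channel t tests (pooled and Welch), both Hotelling
#' T-squared variants, and (when a covariate marker is available) the
#' genotype contingency test, all comparing individuals with a missing
#' call against those with an observed call.
#'
#' @param panel a `GenoPanel` with intensity assays.
#' @param minMissing minimum missing-group size for a marker to be tested
#'   (default 15).
#' @param ldThreshold minimum dosage r-squared for the contingency
#'   covariate; the best-correlated marker above it is used.
#' @return `data.frame` with one row per eligible marker.
#' @export
mcarReport <- function(panel, minMissing = 15L, ldThreshold = 0.5) {
    cl <- genotypeCalls(panel)
    A <- intensityA(panel); B <- intensityB(panel)
    if (is.null(A) || is.null(B))
        stop("panel carries no intensity assays")
    eligible <- which(rowSums(is.na(cl)) >= minMissing &
                      rowSums(is.na(cl)) <= ncol(cl) - 3L &
                      hasIntensities(panel))
    rows <- lapply(eligible, function(i) {
        miss <- is.na(cl[i, ])
        tp <- intensityTTests(A[i, ], B[i, ], miss, equalVariance = TRUE)
        tw <- intensityTTests(A[i, ], B[i, ], miss, equalVariance = FALSE)
        hp <- hotellingT2(A[i, ], B[i, ], miss, pooled = TRUE)
        hu <- hotellingT2(A[i, ], B[i, ], miss, pooled = FALSE)
        contP <- NA_real_; covId <- NA_character_
        covs <- tryCatch(
            selectCovariates(panel, rownames(cl)[i], ldThreshold = ldThreshold,
                             maxCovariates = 1L),
            warning = function(w) character(0))
        if (length(covs)) {
            covId <- covs[1L]
            contP <- tryCatch(
                covariateContingency(miss, cl[covId, ])$p.value,
                error = function(e) NA_real_)
        }
        data.frame(marker = rownames(cl)[i],
                   nMissing = sum(miss), nObserved = sum(!miss),
                   tA = tp$statistic[1L], pA = tp$p.value[1L],
                   tB = tp$statistic[2L], pB = tp$p.value[2L],
                   tAWelch = tw$statistic[1L], pAWelch = tw$p.value[1L],
                   tBWelch = tw$statistic[2L], pBWelch = tw$p.value[2L],
                   T2Pooled = unname(hp$statistic), pT2Pooled = hp$p.value,
                   T2Unpooled = unname(hu$statistic), pT2Unpooled = hu$p.value,
                   covariate = covId, pContingency = contP)
    })
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(marker = character(0))
    rownames(out) <- NULL
    out
}
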