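#' Genotype counts
#'
#' Tabulates allele dosages into the four-category genotype count vector
#' `(AA, AB, BB, NN)`, where `AA` is the homozygote for the first allele,
#' `NN` the number of missing calls.  For a panel, one row per marker.
#'
#' @param x integer dosage vector (0/1/2/`NA`) or a `GenoPanel`.
#' @param ... unused.
#' @return named numeric vector of length 4, or a markers-by-4 matrix.
#' @examples
#' tabulateCounts(c(0, 1, 2, NA))
#' @rdname tabulateCounts
#' @export
setMethod("tabulateCounts", "numeric", function(x, ...) {
    c(AA = sum(x == 0, na.rm = TRUE), AB = sum(x == 1, na.rm = TRUE),
      BB = sum(x == 2, na.rm = TRUE), NN = sum(is.na(x)))
})

#' @rdname tabulateCounts
#' @export
setMethod("tabulateCounts", "integer", function(x, ...)
    tabulateCounts(as.numeric(x)))

#' @rdname tabulateCounts
#' @export
setMethod("tabulateCounts", "logical", function(x, ...) {
    # all-NA vectors arrive as logical; treat as all-missing dosages
    stopifnot(all(is.na(x)))
    c(AA = 0, AB = 0, BB = 0, NN = length(x))
})

#' @rdname tabulateCounts
#' @export
setMethod("tabulateCounts", "GenoPanel", function(x, ...) {
    t(apply(genotypeCalls(x), 1L, tabulateCounts))
})

.checkCounts <- function(counts) {
    if (length(counts) == 3L) counts <- c(counts, 0)
    if (length(counts) != 4L)
        stop("counts must be (AA, AB, BB) or (AA, AB, BB, NN)")
    counts <- setNames(as.numeric(counts), c("AA", "AB", "BB", "NN"))
    # fractional counts are tolerated so expected (model) compositions can
    # be fed straight back into the estimator
    if (any(counts < 0)) stop("counts must be non-negative")
    counts
}

#' Genotype frequencies under the inbreeding model
#'
#' The one-parameter extension of Hardy-Weinberg proportions: with allele
#' frequencies `p` and `q = 1 - p`, the genotype frequencies are
#' `(p^2 + p*q*f, 2*p*q*(1 - f), q^2 + p*q*f)`.  `f = 0` recovers HWP
#' exactly; positive `f` depletes heterozygotes, negative `f` inflates
#' them.  `f` must lie in `[max(-p/q, -q/p), 1]` for all three frequencies
#' to be non-negative.
#'
#' @param p allele frequency in (0, 1).
#' @param f inbreeding coefficient.
#' @return numeric vector `(AA, AB, BB)` summing to one.
#' @examples
#' genotypeFreqs(0.5, 0)    # exact HWP
#' genotypeFreqs(0.2, 0.5)
#' @export
genotypeFreqs <- function(p, f) {
    stopifnot(length(p) == 1L, length(f) == 1L, p > 0, p < 1)
    q <- 1 - p
    lo <- max(-p / q, -q / p)
    if (f < lo - 1e-12 || f > 1 + 1e-12)
        stop(sprintf("f = %g outside the admissible range [%g, 1] for p = %g",
                     f, lo, p))
    c(AA = p^2 + p * q * f, AB = 2 * p * q * (1 - f), BB = q^2 + p * q * f)
}

#' ML estimate of the inbreeding coefficient
#'
#' Maximum-likelihood estimation of the inbreeding coefficient f from
#' genotype counts at a diallelic marker:
#' `f_hat = 1 - (n_AB / n) / (2 * p_hat * q_hat)` with the allele frequency
#' estimated from the observed genotypes.  The large-sample variance is
#' `Var(f) = (1-f)^2 (1-2f) / n_var + f (1-f)(2-f) / (2 n_var p q)`,
#' evaluated at the estimates.  `nVar` selects the sample size used in the
#' variance denominator: `"observed"` (the default, the number of
#' non-missing genotypes) or `"total"` (observed plus missing, the
#' convention under which the variance refers to the full panel), or an
#' explicit number.
#'
#' @param x genotype counts `(AA, AB, BB)` or `(AA, AB, BB, NN)` (use
#'   [tabulateCounts()] to build them from calls), or a `GenoPanel` for a
#'   per-marker table.
#' @param nVar `"observed"`, `"total"`, or a positive number.
#' @param ... unused.
#' @return an [InbreedingEstimate-class] (counts input) or a `data.frame`
#'   with one row per marker (panel input; markers where the estimate is
#'   undefined get `NA` rows).
#' @examples
#' estimateInbreeding(c(AA = 46, AB = 32, BB = 20, NN = 48))
#' @rdname estimateInbreeding
#' @export
setMethod("estimateInbreeding", "numeric", function(x, nVar = "observed", ...) {
    counts <- .checkCounts(x)
    n <- sum(counts[1:3])
    if (n < 2) stop("need at least 2 observed genotypes")
    p <- (2 * counts[["AA"]] + counts[["AB"]]) / (2 * n)
    q <- 1 - p
    if (p <= 0 || p >= 1)
        stop("monomorphic marker: inbreeding coefficient undefined (2*p*q = 0)")
    f <- 1 - (counts[["AB"]] / n) / (2 * p * q)
    nv <- if (identical(nVar, "observed")) n
          else if (identical(nVar, "total")) n + counts[["NN"]]
          else as.numeric(nVar)
    v <- (1 - f)^2 * (1 - 2 * f) / nv + f * (1 - f) * (2 - f) / (2 * nv * p * q)
    # the large-sample variance degenerates to 0 at |f| = 1 (and can go
    # negative just inside the boundary); it is undefined there
    if (!is.na(v) && v <= 0) v <- NA_real_
    new("InbreedingEstimate", fHat = unname(f), varF = unname(v),
        nObs = as.integer(n), nVar = unname(nv), pHat = unname(p),
        counts = counts)
})

#' @rdname estimateInbreeding
#' @export
setMethod("estimateInbreeding", "GenoPanel", function(x, nVar = "observed", ...) {
    cnt <- tabulateCounts(x)
    rows <- lapply(seq_len(nrow(cnt)), function(i) {
        e <- tryCatch(estimateInbreeding(cnt[i, ], nVar = nVar),
                      error = function(e) NULL)
        if (is.null(e))
            data.frame(marker = rownames(cnt)[i], fHat = NA_real_,
                       varF = NA_real_, nObs = sum(cnt[i, 1:3]),
                       nMissing = cnt[i, 4L], pHat = NA_real_)
        else
            data.frame(marker = rownames(cnt)[i], fHat = fHat(e),
                       varF = varF(e), nObs = e@nObs, nMissing = cnt[i, 4L],
                       pHat = e@pHat)
    })
    do.call(rbind, rows)
})

#' @rdname InbreedingEstimate-accessors
#' @param x an `InbreedingEstimate`.
#' @export
fHat <- function(x) x@fHat

#' Accessors for InbreedingEstimate
#' @rdname InbreedingEstimate-accessors
#' @export
varF <- function(x) x@varF

setMethod("show", "InbreedingEstimate", function(object) {
    cat("InbreedingEstimate\n")
    cat(sprintf("  f_hat = %.4f  (SE %.4f, n_var = %g)\n",
                object@fHat, sqrt(object@varF), object@nVar))
    cat(sprintf("  counts AA/AB/BB/NN = %d/%d/%d/%d, p_hat = %.4f\n",
                object@counts[["AA"]], object@counts[["AB"]],
                object@counts[["BB"]], object@counts[["NN"]], object@pHat))
    invisible(NULL)
})

#' Wald confidence interval for the inbreeding coefficient
#'
#' `f_hat +/- z * sqrt(varF)`.  The interval is deliberately not truncated
#' to `[-1, 1]`.
#'
#' @param est an [InbreedingEstimate-class].
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @examples
#' waldCI(estimateInbreeding(c(46, 32, 20, 48), nVar = "total"))
#' @export
waldCI <- function(est, level = 0.95) {
    stopifnot(is(est, "InbreedingEstimate"))
    if (is.na(est@varF)) stop("variance undefined; no interval")
    z <- qnorm((1 + level) / 2)
    se <- sqrt(est@varF)
    setNames(est@fHat + c(-1, 1) * z * se, c("lower", "upper"))
}

#' Chi-square test for Hardy-Weinberg proportions
#'
#' Goodness-of-fit chi-square statistic (no continuity correction) of the
#' observed genotype counts against the HWP expected counts
#' `n * (p^2, 2pq, q^2)`, referred to a chi-square distribution with one
#' degree of freedom.  Algebraically the statistic equals `n * f_hat^2`.
#'
#' @param counts genotype counts `(AA, AB, BB[, NN])`; missings are ignored.
#' @return an object of class `"htest"`.
#' @examples
#' chisqHWP(c(46, 32, 20))
#' @export
chisqHWP <- function(counts) {
    counts <- .checkCounts(counts)
    n <- sum(counts[1:3])
    if (n < 2) stop("need at least 2 observed genotypes")
    p <- (2 * counts[["AA"]] + counts[["AB"]]) / (2 * n)
    q <- 1 - p
    if (p <= 0 || p >= 1) stop("monomorphic marker: test undefined")
    expected <- n * c(p^2, 2 * p * q, q^2)
    stat <- sum((counts[1:3] - expected)^2 / expected)
    structure(list(statistic = c("X-squared" = stat),
                   parameter = c(df = 1),
                   p.value = pchisq(stat, df = 1, lower.tail = FALSE),
                   method = "Chi-square test for HWP (no continuity correction)",
                   data.name = deparse(substitute(counts))),
              class = "htest")
}

#' Exact test for Hardy-Weinberg proportions
#'
#' Two-sided exact test based on the conditional (Levene-Haldane)
#' distribution of the heterozygote count given the sample size and the
#' allele counts.  The p-value sums the probabilities of all outcomes no
#' more probable than the observed table.
#'
#' @param counts genotype counts `(AA, AB, BB[, NN])`; missings are ignored.
#' @return an object of class `"htest"` with the exact p-value.
#' @examples
#' exactHWP(c(46, 32, 20))
#' @export
exactHWP <- function(counts) {
    counts <- .checkCounts(counts)
    n <- sum(counts[1:3])
    nA <- 2 * counts[["AA"]] + counts[["AB"]]
    nB <- 2 * n - nA
    if (nA == 0 || nB == 0) stop("monomorphic marker: test undefined")
    nABs <- seq(nA %% 2, min(nA, nB), by = 2)
    # log conditional probability of each possible heterozygote count
    logp <- lgamma(n + 1) -
        lgamma((nA - nABs) / 2 + 1) - lgamma(nABs + 1) -
        lgamma((nB - nABs) / 2 + 1) +
        nABs * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
    prob <- exp(logp - max(logp))
    prob <- prob / sum(prob)
    pobs <- prob[match(counts[["AB"]], nABs)]
    pval <- min(1, sum(prob[prob <= pobs * (1 + 1e-7)]))
    structure(list(statistic = c(n_AB = counts[["AB"]]),
                   p.value = pval,
                   method = "Exact test for HWP (two-sided)",
                   data.name = deparse(substitute(counts))),
              class = "htest")
}

#' Per-marker HWP test table for a panel
#'
#' Complete-case Hardy-Weinberg testing of every marker: genotype counts,
#' inbreeding coefficient with standard error and Wald interval, and the
#' chi-square or exact p-value.  Monomorphic or under-observed markers get
#' `NA` statistics.
#'
#' @param panel a `GenoPanel`.
#' @param method `"chisq"` or `"exact"`.
#' @param nVar variance convention passed to [estimateInbreeding()].
#' @param level confidence level for the interval.
#' @return `data.frame` with one row per marker.
#' @export
hwpTest <- function(panel, method = c("chisq", "exact"), nVar = "observed",
                    level = 0.95) {
    method <- match.arg(method)
    cnt <- tabulateCounts(panel)
    rows <- lapply(seq_len(nrow(cnt)), function(i) {
        co <- cnt[i, ]
        base <- data.frame(marker = rownames(cnt)[i], nAA = co[[1L]],
                           nAB = co[[2L]], nBB = co[[3L]], nMissing = co[[4L]],
                           fHat = NA_real_, se = NA_real_, ciLow = NA_real_,
                           ciHigh = NA_real_, statistic = NA_real_,
                           p = NA_real_)
        est <- tryCatch(estimateInbreeding(co, nVar = nVar),
                        error = function(e) NULL)
        if (is.null(est)) return(base)
        base$fHat <- fHat(est)
        if (!is.na(varF(est))) {
            base$se <- sqrt(varF(est))
            ci <- waldCI(est, level)
            base$ciLow <- ci[[1L]]; base$ciHigh <- ci[[2L]]
        }
        ht <- tryCatch(
            if (method == "chisq") chisqHWP(co) else exactHWP(co),
            error = function(e) NULL)
        if (!is.null(ht)) {
            base$statistic <- unname(ht$statistic)
            base$p <- ht$p.value
        }
        base
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
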