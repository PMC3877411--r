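#' Dosage r-squared between two markers
#'
#' Squared Pearson correlation of allele dosages over pairwise-complete
#' individuals — the usual composite proxy for linkage disequilibrium
#' r-squared when haplotype phase is unknown.  Symmetric under allele
#' relabeling at either marker.
#'
#' @param g1,g2 integer dosage vectors of equal length.
#' @return r-squared in \[0, 1\]; 0 with a warning when either marker shows
#'   no variation on the complete pairs.
#' @examples
#' ldR2(c(0, 1, 2, 0), c(0, 1, 2, 1))
#' @export
ldR2 <- function(g1, g2) {
    stopifnot(length(g1) == length(g2))
    ok <- !is.na(g1) & !is.na(g2)
    if (sum(ok) < 2L)
        stop("need at least 2 pairwise-complete individuals")
    x <- g1[ok]; y <- g2[ok]
    if (var(x) == 0 || var(y) == 0) {
        warning("no variation on the complete pairs; r-squared undefined, returning 0")
        return(0)
    }
    cor(x, y)^2
}

#' Select LD covariate markers for imputation
#'
#' Ranks all other markers by dosage r-squared with the target and keeps
#' those at or above `ldThreshold`, in decreasing order, capped at
#' `maxCovariates`.  The target itself and perfect duplicates
#' (r-squared indistinguishable from 1, which would give a degenerate
#' diagonal contingency structure) are excluded.  When no marker passes
#' and the panel has intensities for the target, the empty result carries
#' `attr(, "fallback") = "intensities"`.
#'
#' @param panel a `GenoPanel`.
#' @param target target marker identifier.
#' @param ldThreshold minimum r-squared (default 0.5).
#' @param maxCovariates cap on the number of covariates (default 10).
#' @return character vector of marker ids, ordered by decreasing
#'   r-squared, with attribute `r2`.
#' @export
selectCovariates <- function(panel, target, ldThreshold = 0.5,
                             maxCovariates = 10L) {
    cl <- genotypeCalls(panel)
    stopifnot(target %in% rownames(cl))
    others <- setdiff(rownames(cl), target)
    r2 <- vapply(others, function(mk) {
        tryCatch(suppressWarnings(ldR2(cl[target, ], cl[mk, ])),
                 error = function(e) NA_real_)
    }, numeric(1))
    keep <- !is.na(r2) & r2 >= ldThreshold & r2 < 1 - 1e-9
    sel <- others[keep][order(r2[keep], decreasing = TRUE)]
    sel <- utils::head(sel, maxCovariates)
    out <- sel
    attr(out, "r2") <- unname(r2[match(sel, others)])
    if (!length(sel) && isTRUE(hasIntensities(panel, target)[[1L]]))
        attr(out, "fallback") <- "intensities"
    out
}
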