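#' Compare discarding against multiple imputation under a deletion regime
#'
#' Desk-scale replication of the deletion simulation design: a complete
#' panel is degraded with [applyMissingness()], the inbreeding coefficient
#' of every affected marker is estimated three ways — on the complete data
#' (the reference), on the observed calls with missings discarded, and by
#' multiple imputation — and the root mean squared error of the two
#' incomplete-data estimators against the complete-data estimate is
#' aggregated over affected markers and replicates.  Markers rendered
#' monomorphic or unusable by deletion are skipped and counted.
#'
#' @param panel a complete `GenoPanel`.
#' @param mechanism,probs,snpFraction deletion regime, as in
#'   [applyMissingness()].
#' @param replicates number of independent deletion replicates.
#' @param model,m,iterations,ldThreshold,maxCovariates imputation settings
#'   passed to [miHWPTest()].
#' @param seed optional integer seed.
#' @return list with `rmseDiscard`, `rmseMI`, `overallMissingRate`,
#'   `nScored`, `nSkipped`, and the per-marker error table `details`.
#' @export
runRegime <- function(panel, mechanism, probs, snpFraction = 0.25,
                      replicates = 20L, model = "snps", m = 10L,
                      iterations = 5L, ldThreshold = 0.5, maxCovariates = 10L,
                      seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    clFull <- genotypeCalls(panel)
    fFull <- vapply(rownames(clFull), function(mk)
        tryCatch(fHat(estimateInbreeding(tabulateCounts(clFull[mk, ]))),
                 error = function(e) NA_real_), numeric(1))
    errD <- errM <- numeric(0)
    missRates <- numeric(0)
    nSkipped <- 0L
    details <- list()
    for (rep_ in seq_len(replicates)) {
        del <- applyMissingness(panel, mechanism = mechanism, probs = probs,
                                snpFraction = snpFraction)
        deg <- del$panel
        clDeg <- genotypeCalls(deg)
        missRates <- c(missRates, mean(is.na(clDeg)))
        scored <- del$affected[rowSums(is.na(clDeg[del$affected, ,
                                                   drop = FALSE])) > 0L]
        scored <- scored[!is.na(fFull[scored])]
        if (!length(scored)) next
        mi <- miHWPTest(deg, markers = scored, model = model, m = m,
                        iterations = iterations, ldThreshold = ldThreshold,
                        maxCovariates = maxCovariates)
        for (mk in scored) {
            fd <- tryCatch(fHat(estimateInbreeding(tabulateCounts(clDeg[mk, ]))),
                           error = function(e) NA_real_)
            fm <- mi$f_pooled[mi$marker == mk]
            if (is.na(fd) || is.na(fm)) {
                nSkipped <- nSkipped + 1L
                next
            }
            errD <- c(errD, fd - fFull[mk])
            errM <- c(errM, fm - fFull[mk])
            details[[length(details) + 1L]] <-
                data.frame(replicate = rep_, marker = mk, fComplete = fFull[mk],
                           fDiscard = fd, fMI = fm)
        }
    }
    list(rmseDiscard = sqrt(mean(errD^2)), rmseMI = sqrt(mean(errM^2)),
         overallMissingRate = mean(missRates), nScored = length(errD),
         nSkipped = nSkipped,
         details = if (length(details)) do.call(rbind, details) else NULL)
}

#' Classify significance reversals between discarding and imputation
#'
#' Tests every marker with missing calls twice for Hardy-Weinberg
#' proportions — a chi-square test discarding missings and a Rubin-pooled
#' test after multiple imputation — and classifies each as
#' `both.nonsignificant`, `both.significant`, `only.discarding`
#' (significant only when missings are discarded) or `only.imputed`.
#' The reversal percentage is the share of testable markers whose verdict
#' changes.
#'
#' @param panel a `GenoPanel` with missing calls.
#' @param alpha significance level (default 0.05).
#' @param model,m,iterations,ldThreshold,maxCovariates,seed imputation
#'   settings, as in [miHWPTest()].
#' @return list with `table` (per-marker classification) and
#'   `reversalPercent`.
#' @export
significanceReversalReport <- function(panel, alpha = 0.05, model = "snps",
                                       m = 10L, iterations = 5L,
                                       ldThreshold = 0.5, maxCovariates = 10L,
                                       seed = NULL) {
    cl <- genotypeCalls(panel)
    withMiss <- rownames(cl)[rowSums(is.na(cl)) > 0L]
    if (!length(withMiss))
        return(list(table = data.frame(), reversalPercent = 0))
    disc <- hwpTest(panel[withMiss, ], method = "chisq")
    mi <- miHWPTest(panel, markers = withMiss, model = model, m = m,
                    iterations = iterations, ldThreshold = ldThreshold,
                    maxCovariates = maxCovariates, seed = seed)
    tab <- data.frame(marker = withMiss,
                      pDiscard = disc$p[match(withMiss, disc$marker)],
                      pImputed = mi$p[match(withMiss, mi$marker)])
    tab <- tab[!is.na(tab$pDiscard) & !is.na(tab$pImputed), , drop = FALSE]
    sd_ <- tab$pDiscard <= alpha
    si <- tab$pImputed <= alpha
    tab$class <- ifelse(sd_ & si, "both.significant",
                 ifelse(!sd_ & !si, "both.nonsignificant",
                 ifelse(sd_, "only.discarding", "only.imputed")))
    rev_ <- mean(tab$class %in% c("only.discarding", "only.imputed")) * 100
    list(table = tab, reversalPercent = rev_)
}
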