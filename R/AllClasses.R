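#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData rowRanges
#' @importFrom stats var cor pchisq pnorm pt qnorm qt rnorm runif rbinom
#'   rmultinom chisq.test fisher.test t.test setNames complete.cases
#'   model.matrix terms as.formula predict coef vcov quantile sd
#' @importFrom utils read.table write.table head
NULL

# sentinel used in genotype call matrices: calls are integer dosages of the
# second (alternate) allele; NA marks a no-call.

#' GenoPanel: a diallelic SNP genotype panel
#'
#' `GenoPanel` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are markers, columns are individuals.  The `"calls"` assay holds
#' integer allele dosages (0 = homozygous for the first allele, 1 =
#' heterozygous, 2 = homozygous for the second allele, `NA` = missing call).
#' Optional `"intensityA"` and `"intensityB"` assays hold the two raw
#' signal channels from which genotypes are called; for any marker they are
#' either fully observed or fully absent, since completeness of the
#' intensities is a precondition of the missingness diagnostics.
#' `rowData` carries the two allele symbols (`ref`, `alt`); dosage counts
#' the `alt` allele.  All downstream statistics depend only on the genotype
#' counts, which are symmetric under allele relabeling, so the coding
#' convention is cosmetic.
#'
#' @seealso [GenoPanel()] for construction, [readVcfPanel()],
#'   [readMatrixPanel()] for readers.
#' @aliases GenoPanel-class
#' @exportClass GenoPanel
setClass("GenoPanel", contains = "RangedSummarizedExperiment")

.validGenoPanel <- function(object) {
    msg <- character()
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        return("assay 'calls' is required")
    cl <- SummarizedExperiment::assay(object, "calls")
    bad <- !is.na(cl) & !(cl %in% c(0L, 1L, 2L))
    if (any(bad))
        msg <- c(msg, "non-missing calls must be 0, 1 or 2")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("ref", "alt") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'ref' and 'alt' allele symbols")
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr) > 1L) {
        sp <- split(GenomicRanges::start(rr),
                    as.character(GenomicRanges::seqnames(rr)))
        if (!all(vapply(sp, function(p) all(diff(p) > 0), logical(1))))
            msg <- c(msg, "marker positions must be strictly increasing within a chromosome")
    }
    for (a in c("intensityA", "intensityB")) {
        if (a %in% SummarizedExperiment::assayNames(object)) {
            x <- SummarizedExperiment::assay(object, a)
            partial <- apply(x, 1L, function(r) any(is.na(r)) && !all(is.na(r)))
            if (any(partial))
                msg <- c(msg, sprintf(
                    "assay '%s' must be complete (or entirely absent) per marker", a))
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("GenoPanel", .validGenoPanel)

#' Maximum-likelihood inbreeding coefficient estimate
#'
#' Container for the ML estimate of the inbreeding coefficient f at one
#' diallelic marker, with its large-sample variance, the genotype counts it
#' was computed from, the observed sample size and the sample size used in
#' the variance denominator.
#'
#' @slot fHat estimated inbreeding coefficient, in \[-1, 1\].
#' @slot varF large-sample variance of `fHat` (`NA` when undefined).
#' @slot nObs number of observed (non-missing) genotypes.
#' @slot nVar sample size used in the variance denominator.
#' @slot pHat estimated frequency of the first allele.
#' @slot counts named numeric of genotype counts (`AA`, `AB`, `BB`, `NN`).
#'
#' @aliases InbreedingEstimate-class
#' @exportClass InbreedingEstimate
setClass("InbreedingEstimate",
    representation(fHat = "numeric", varF = "numeric", nObs = "integer",
                   nVar = "numeric", pHat = "numeric", counts = "numeric"))

setValidity("InbreedingEstimate", function(object) {
    msg <- character()
    if (abs(object@fHat) > 1 + 1e-8)
        msg <- c(msg, "fHat must lie in [-1, 1]")
    if (!is.na(object@varF) && object@varF < 0)
        msg <- c(msg, "varF must be positive when defined")
    if (length(msg)) msg else TRUE
})

#' Rubin-pooled inference for the inbreeding coefficient
#'
#' Result of combining per-imputation estimates and variances with Rubin's
#' rules: pooled estimate, within/between/total variance, relative increase
#' in variance `r`, degrees of freedom `nu`, fraction of missing
#' information `lambda`, confidence interval and two-sided p-value.
#' When `scale == "fisher.z"` the pooling was performed on the
#' atanh-transformed scale and `estimate`/`ci` are back-transformed;
#' variance components then refer to the z scale.
#'
#' @slot estimate pooled inbreeding coefficient.
#' @slot wBar average within-imputation variance.
#' @slot b between-imputation variance (divisor m - 1).
#' @slot tVar total variance, `wBar + (1 + 1/m) * b`.
#' @slot r relative increase in variance due to missing data.
#' @slot nu Student-t degrees of freedom of the pooled test.
#' @slot lambda fraction of missing information.
#' @slot ci two-sided confidence interval at `level`.
#' @slot p two-sided p-value for f = 0.
#' @slot m number of imputations pooled.
#' @slot level confidence level of `ci`.
#' @slot scale `"identity"` or `"fisher.z"`.
#'
#' @aliases PooledResult-class
#' @exportClass PooledResult
setClass("PooledResult",
    representation(estimate = "numeric", wBar = "numeric", b = "numeric",
                   tVar = "numeric", r = "numeric", nu = "numeric",
                   lambda = "numeric", ci = "numeric", p = "numeric",
                   m = "integer", level = "numeric", scale = "character"))

setValidity("PooledResult", function(object) {
    msg <- character()
    if (object@m < 2L) msg <- c(msg, "m must be at least 2")
    if (object@tVar < object@wBar - 1e-12)
        msg <- c(msg, "total variance cannot be smaller than within variance")
    if (object@r < 0) msg <- c(msg, "r must be non-negative")
    if (object@lambda < 0 || object@lambda >= 1)
        msg <- c(msg, "lambda must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' A set of multiply imputed genotype panels
#'
#' Holds the `m` completed call matrices produced by an imputation run,
#' together with the source panel, per-iteration traces of the target
#' marker's inbreeding coefficient (for convergence inspection), and the
#' run's provenance (method, seed, parameters).  Observed entries are
#' identical across all completions and to the source; imputed entries are
#' always genotype categories observed at that marker.
#'
#' @slot source the input `GenoPanel`.
#' @slot completions list of `m` completed integer call matrices.
#' @slot traces list (by traced marker) of iterations-by-m matrices of
#'   per-sweep inbreeding coefficients.
#' @slot target identifier of the target marker.
#' @slot method `"chained"` or `"random"`.
#' @slot seed integer seed the run was started from (`NA` if unset).
#' @slot params list of tuning parameters (m, iterations, ridge, ...).
#'
#' @aliases ImputedPanelSet-class
#' @exportClass ImputedPanelSet
setClass("ImputedPanelSet",
    representation(source = "GenoPanel", completions = "list",
                   traces = "list", target = "character", method = "character",
                   seed = "integer", params = "list"))

setValidity("ImputedPanelSet", function(object) {
    msg <- character()
    src <- SummarizedExperiment::assay(object@source, "calls")
    obs <- !is.na(src)
    for (k in seq_along(object@completions)) {
        cm <- object@completions[[k]]
        if (!identical(dim(cm), dim(src))) {
            msg <- c(msg, "completion dimensions differ from source")
            break
        }
        if (any(cm[obs] != src[obs], na.rm = TRUE)) {
            msg <- c(msg, "observed entries were modified by imputation")
            break
        }
    }
    if (length(msg)) msg else TRUE
})
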