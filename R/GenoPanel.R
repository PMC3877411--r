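#' Construct a GenoPanel
#'
#' Builds a [GenoPanel-class] from a call matrix and marker metadata.
#'
#' @param calls integer matrix of allele dosages, markers in rows and
#'   individuals in columns; entries 0, 1, 2 or `NA`.  Row and column names
#'   become marker and individual identifiers (defaults are generated).
#' @param chrom chromosome per marker (recycled; default `"1"`).
#' @param pos 1-based position per marker, strictly increasing within a
#'   chromosome.  Defaults to an even 2 kb grid.
#' @param ref,alt allele symbols per marker; dosage counts `alt`.
#' @param intensityA,intensityB optional numeric matrices (same shape as
#'   `calls`) with the two signal channels.
#'
#' @return a `GenoPanel`.
#' @examples
#' gp <- GenoPanel(rbind(snp1 = c(0, 1, 2, NA)))
#' genotypeCalls(gp)
#' @export
GenoPanel <- function(calls, chrom = "1", pos = NULL, ref = NULL, alt = NULL,
                      intensityA = NULL, intensityB = NULL) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (is.null(rownames(calls)))
        rownames(calls) <- sprintf("snp%04d", seq_len(nrow(calls)))
    if (is.null(colnames(calls)))
        colnames(calls) <- sprintf("ind%04d", seq_len(ncol(calls)))
    k <- nrow(calls)
    if (is.null(pos)) pos <- 2000L * seq_len(k)
    if (is.null(ref)) ref <- rep("A", k)
    if (is.null(alt)) alt <- rep("B", k)
    chrom <- rep_len(as.character(chrom), k)
    rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(as.integer(pos), width = 1L))
    names(rr) <- rownames(calls)
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(ref = as.character(ref),
                                                 alt = as.character(alt))
    assays <- list(calls = calls)
    if (!is.null(intensityA)) {
        stopifnot(identical(dim(intensityA), dim(calls)))
        a <- as.matrix(intensityA); dimnames(a) <- dimnames(calls)
        assays$intensityA <- a
    }
    if (!is.null(intensityB)) {
        stopifnot(identical(dim(intensityB), dim(calls)))
        b <- as.matrix(intensityB); dimnames(b) <- dimnames(calls)
        assays$intensityB <- b
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, rowRanges = rr,
        colData = S4Vectors::DataFrame(row.names = colnames(calls)))
    new("GenoPanel", se)
}

#' Genotype call matrix
#'
#' Integer dosage matrix (markers x individuals) of a panel; `NA` marks a
#' missing call.
#'
#' @param x a `GenoPanel`.
#' @return integer matrix.
#' @rdname genotypeCalls
#' @export
setMethod("genotypeCalls", "GenoPanel", function(x)
    SummarizedExperiment::assay(x, "calls"))

#' Allele intensity channels
#'
#' Accessors for the per-marker two-channel signal matrices.  Return `NULL`
#' when the panel carries no intensities.
#'
#' @param x a `GenoPanel`.
#' @return numeric matrix (markers x individuals) or `NULL`.
#' @rdname intensities
#' @export
setMethod("intensityA", "GenoPanel", function(x) {
    if ("intensityA" %in% SummarizedExperiment::assayNames(x))
        SummarizedExperiment::assay(x, "intensityA") else NULL
})

#' @rdname intensities
#' @export
setMethod("intensityB", "GenoPanel", function(x) {
    if ("intensityB" %in% SummarizedExperiment::assayNames(x))
        SummarizedExperiment::assay(x, "intensityB") else NULL
})

#' @rdname GenoPanel
#' @param x a `GenoPanel`.
#' @export
markerIds <- function(x) rownames(x)

#' @rdname GenoPanel
#' @export
individualIds <- function(x) colnames(x)

#' @rdname GenoPanel
#' @export
nMarkers <- function(x) nrow(x)

#' @rdname GenoPanel
#' @export
nIndividuals <- function(x) ncol(x)

#' Per-marker missing-call rate
#' @param x a `GenoPanel`.
#' @return named numeric vector of missing fractions.
#' @export
missingRate <- function(x) rowMeans(is.na(genotypeCalls(x)))

#' Marker alleles
#' @param x a `GenoPanel`.
#' @return `DataFrame` with columns `ref` and `alt`.
#' @export
panelAlleles <- function(x) SummarizedExperiment::rowData(x)[, c("ref", "alt")]

#' Does a marker carry intensity data?
#' @param x a `GenoPanel`.
#' @param marker marker identifier(s); default all markers.
#' @return logical vector.
#' @export
hasIntensities <- function(x, marker = markerIds(x)) {
    a <- intensityA(x); b <- intensityB(x)
    if (is.null(a) || is.null(b))
        return(setNames(rep(FALSE, length(marker)), marker))
    setNames(!apply(is.na(a[marker, , drop = FALSE]), 1L, any) &
             !apply(is.na(b[marker, , drop = FALSE]), 1L, any), marker)
}

setMethod("show", "GenoPanel", function(object) {
    cl <- genotypeCalls(object)
    cat(sprintf("GenoPanel: %d markers x %d individuals\n",
                nrow(cl), ncol(cl)))
    cat(sprintf("  missing calls: %.1f%% overall (%d markers with missings)\n",
                100 * mean(is.na(cl)), sum(rowSums(is.na(cl)) > 0)))
    cat(sprintf("  intensities: %s\n",
                if (is.null(intensityA(object))) "absent" else "present"))
    invisible(NULL)
})
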