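#' Generate a complete synthetic genotype panel
#'
#' Draws a complete (no missing calls) diallelic panel.  Markers outside
#' LD blocks are sampled independently from the inbreeding-model trinomial
#' `(p^2 + pqf, 2pq(1 - f), q^2 + pqf)`.  Markers inside an LD block are
#' generated from a two-haplotype-pool model: a Markov chain of haplotype
#' alleles with pairwise haplotype frequencies solved from the target
#' r-squared and the two minor allele frequencies, two independent
#' haplotypes per individual; this gives per-locus Hardy-Weinberg
#' proportions (f = 0 inside blocks) and adjacent-marker dosage
#' correlation close to the target.
#'
#' @param nIndividuals number of individuals.
#' @param nMarkers number of markers.
#' @param maf minor allele frequency: scalar, per-marker vector, or a
#'   range `c(lo, hi)` sampled uniformly (values in (0, 0.5]).
#' @param f inbreeding coefficient per marker (scalar or vector); must lie
#'   in the admissible range for the marker's maf.  Ignored (forced 0)
#'   inside LD blocks.
#' @param ldBlocks optional list of blocks, each `list(size =, r2 =)`;
#'   blocks occupy the leading markers in order.
#' @param seed optional integer seed.
#' @return a complete `GenoPanel`.
#' @examples
#' gp <- genGenotypes(100, 5, maf = 0.3, f = 0.1, seed = 1)
#' @export
genGenotypes <- function(nIndividuals, nMarkers, maf = c(0.1, 0.5), f = 0,
                         ldBlocks = NULL, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    nIndividuals <- as.integer(nIndividuals); nMarkers <- as.integer(nMarkers)
    mafs <- if (length(maf) == nMarkers) maf
            else if (length(maf) == 1L) rep(maf, nMarkers)
            else runif(nMarkers, min(maf), max(maf))
    if (any(mafs <= 0 | mafs > 0.5))
        stop("maf values must lie in (0, 0.5]")
    fs <- rep_len(f, nMarkers)
    for (i in seq_len(nMarkers)) {
        lo <- max(-mafs[i] / (1 - mafs[i]), -(1 - mafs[i]) / mafs[i])
        if (fs[i] < lo || fs[i] > 1)
            stop(sprintf("f = %g infeasible for maf = %g (admissible [%g, 1])",
                         fs[i], mafs[i], lo))
    }
    calls <- matrix(NA_integer_, nMarkers, nIndividuals)
    blockIdx <- integer(0)
    if (!is.null(ldBlocks)) {
        at <- 1L
        for (blk in ldBlocks) {
            idx <- seq.int(at, length.out = blk$size)
            if (max(idx) > nMarkers) stop("LD blocks exceed the marker count")
            calls[idx, ] <- .genLDBlock(nIndividuals, mafs[idx], blk$r2)
            fs[idx] <- 0
            blockIdx <- c(blockIdx, idx)
            at <- at + blk$size
        }
    }
    for (i in setdiff(seq_len(nMarkers), blockIdx)) {
        pr <- genotypeFreqs(mafs[i], fs[i])
        calls[i, ] <- sample(0:2, nIndividuals, replace = TRUE, prob = pr)
    }
    nts <- c("A", "C", "G", "T")
    ref <- sample(nts, nMarkers, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1L), character(1))
    rownames(calls) <- sprintf("snp%04d", seq_len(nMarkers))
    colnames(calls) <- sprintf("ind%04d", seq_len(nIndividuals))
    gp <- GenoPanel(calls, ref = ref, alt = alt)
    SummarizedExperiment::rowData(gp)$maf <- mafs
    SummarizedExperiment::rowData(gp)$f <- fs
    gp
}

# haplotype chain for one LD block: minor-allele indicators with pairwise
# r between neighbours; D clamped to the feasible range, so very high
# targets with unequal mafs may be attenuated
.genLDBlock <- function(nInd, mafs, r2) {
    r <- sqrt(r2)
    k <- length(mafs)
    # simulate 2*nInd haplotypes jointly as a Markov chain over loci
    H <- matrix(0L, nrow = k, ncol = 2L * nInd)
    H[1L, ] <- rbinom(2L * nInd, 1L, mafs[1L])
    for (j in seq_len(k)[-1L]) {
        p1 <- mafs[j - 1L]; p2 <- mafs[j]
        D <- r * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
        Dmax <- min(p1 * (1 - p2), (1 - p1) * p2)
        D <- min(D, Dmax - 1e-12)
        pGiven1 <- (p1 * p2 + D) / p1          # P(minor_j | minor_{j-1})
        pGiven0 <- (p2 * (1 - p1) - D) / (1 - p1)
        pr <- ifelse(H[j - 1L, ] == 1L, pGiven1, pGiven0)
        H[j, ] <- rbinom(2L * nInd, 1L, pr)
    }
    H[, seq_len(nInd)] + H[, nInd + seq_len(nInd)]
}

#' Simulate allele-intensity clouds for a panel
#'
#' Attaches two-channel intensities: each genotype has a cluster mean in
#' the (A, B) plane and isotropic Gaussian noise.  Defaults place the
#' three clouds the way array data looks — first-allele homozygotes high
#' in A, heterozygotes on the diagonal, second-allele homozygotes high in
#' B — with common standard deviation 0.25 so the clouds are well
#' separated but adjacent clouds share a boundary region.  A per-individual
#' sample-quality factor `exp(-|N(0, brightness)|)` attenuates both
#' channels, emulating the dim samples whose points drift off the clouds
#' toward the origin; set `brightness = 0` for pure isotropic clouds.
#'
#' @param panel a complete `GenoPanel`.
#' @param means 3x2 matrix of cluster means, rows = dosage 0/1/2,
#'   columns = channels (A, B).
#' @param sd common isotropic standard deviation.
#' @param brightness scale of the per-individual signal attenuation
#'   (default 0.35).
#' @param seed optional integer seed.
#' @return the panel with intensity assays attached.
#' @export
genIntensities <- function(panel,
                           means = rbind(c(2, 0.2), c(1.1, 1.1), c(0.2, 2)),
                           sd = 0.25, brightness = 0.35, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    cl <- genotypeCalls(panel)
    if (anyNA(cl)) stop("panel must be complete to simulate intensities")
    gam <- exp(-abs(rnorm(ncol(cl), 0, brightness)))
    gamM <- matrix(gam, nrow(cl), ncol(cl), byrow = TRUE)
    A <- gamM * (means[cl + 1L, 1L] + rnorm(length(cl), 0, sd))
    B <- gamM * (means[cl + 1L, 2L] + rnorm(length(cl), 0, sd))
    dim(A) <- dim(B) <- dim(cl)
    dimnames(A) <- dimnames(B) <- dimnames(cl)
    out <- panel
    SummarizedExperiment::assay(out, "intensityA", withDimnames = FALSE) <- A
    SummarizedExperiment::assay(out, "intensityB", withDimnames = FALSE) <- B
    S4Vectors::metadata(out)$intensityMeans <- means
    S4Vectors::metadata(out)$intensitySd <- sd
    out
}

#' Delete genotype calls under a chosen missingness mechanism
#'
#' Degrades a complete panel for simulation studies.  A fraction
#' `snpFraction` of markers is selected uniformly at random; on each
#' affected marker calls are deleted according to the mechanism:
#'
#' * `"MCAR"` — every call independently with probability `probs[1]`
#'   (missing completely at random).
#' * `"MNAR"` — with genotype-specific probabilities
#'   `probs = c(pi_AA, pi_AB, pi_BB)`; equal probabilities recover MCAR,
#'   unequal ones make missingness depend on the unobserved value.
#' * `"MAR"` — from the intensity plane (requires intensity assays):
#'   deletion probability rises as a call's classification margin (the
#'   distance to its second-nearest cluster mean minus the distance to the
#'   nearest) shrinks, concentrating no-calls at the boundaries between
#'   the genotype clouds; `probs[1]` is the margin width at which the
#'   deletion probability is 1/2.  This depends only on the observed
#'   intensities, hence missing-at-random.
#'
#' @param panel a complete `GenoPanel` (with intensities for `"MAR"`).
#' @param mechanism `"MCAR"`, `"MNAR"` or `"MAR"`.
#' @param probs mechanism parameter (see above).
#' @param snpFraction fraction of markers affected (default 1).
#' @param sharpness slope of the margin-to-probability map for `"MAR"`.
#' @param seed optional integer seed.
#' @return list with elements `panel` (degraded `GenoPanel`), `truth`
#'   (the complete call matrix) and `affected` (marker ids).
#' @export
applyMissingness <- function(panel, mechanism = c("MCAR", "MNAR", "MAR"),
                             probs, snpFraction = 1, sharpness = 0.1,
                             seed = NULL) {
    mechanism <- match.arg(mechanism)
    if (!is.null(seed)) set.seed(seed)
    cl <- genotypeCalls(panel)
    if (anyNA(cl)) stop("panel must be complete before deletion")
    if (any(probs < 0) || (mechanism != "MAR" && any(probs > 1)))
        stop("deletion probabilities must lie in [0, 1]")
    k <- nrow(cl)
    nAff <- round(snpFraction * k)
    affected <- sort(sample(seq_len(k), nAff))
    deg <- cl
    if (mechanism == "MAR") {
        means <- S4Vectors::metadata(panel)$intensityMeans
        if (is.null(means)) means <- rbind(c(2, 0.2), c(1.1, 1.1), c(0.2, 2))
        A <- intensityA(panel); B <- intensityB(panel)
        if (is.null(A)) stop("MAR deletion needs intensity assays")
        w <- probs[1L]
        for (i in affected) {
            dst <- vapply(seq_len(nrow(means)), function(g)
                sqrt((A[i, ] - means[g, 1L])^2 + (B[i, ] - means[g, 2L])^2),
                numeric(ncol(cl)))
            srt <- t(apply(dst, 1L, sort))
            margin <- srt[, 2L] - srt[, 1L]
            pdel <- stats::plogis((w - margin) / sharpness)
            deg[i, runif(ncol(cl)) < pdel] <- NA_integer_
        }
    } else {
        pg <- if (mechanism == "MCAR") rep(probs[1L], 3L) else rep_len(probs, 3L)
        for (i in affected) {
            pdel <- pg[cl[i, ] + 1L]
            deg[i, runif(ncol(cl)) < pdel] <- NA_integer_
        }
    }
    degPanel <- panel
    SummarizedExperiment::assay(degPanel, "calls", withDimnames = FALSE) <- deg
    list(panel = degPanel, truth = cl, affected = rownames(cl)[affected])
}
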