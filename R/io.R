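#' Read a genotype panel from VCF
#'
#' Reads the GT field of a VCF 4.x file into a [GenoPanel-class].  Only
#' diallelic SNP records are accepted; multi-allelic or non-SNP records are
#' skipped with a warning.  Phasing separators are ignored and the dosage
#' counts the ALT allele; `./.` and `.|.` (or any GT containing `.`) map to
#' a missing call.
#'
#' @param path path to a VCF file.
#' @param genome genome label passed to [VariantAnnotation::readVcf()].
#' @return a `GenoPanel`.
#' @export
readVcfPanel <- function(path, genome = "unknown") {
    vcf <- VariantAnnotation::readVcf(path, genome = genome)
    if (ncol(vcf) == 0L)
        stop("no individuals: the VCF contains zero sample columns")
    alt <- VariantAnnotation::alt(vcf)
    ref <- VariantAnnotation::ref(vcf)
    altChar <- S4Vectors::unstrsplit(
        methods::as(alt, "CharacterList"), sep = ",")
    ok <- S4Vectors::elementNROWS(alt) == 1L &
        BiocGenerics::width(ref) == 1L & nchar(altChar) == 1L
    if (any(!ok)) {
        warning(sprintf("skipping %d non-diallelic-SNP record(s): %s",
                        sum(!ok),
                        paste(utils::head(rownames(vcf)[!ok], 5L), collapse = ", ")))
        vcf <- vcf[ok, ]
        altChar <- altChar[ok]
    }
    if (nrow(vcf) == 0L) stop("no diallelic SNP records in ", path)
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("malformed VCF: no GT genotype field")
    dose <- .gtToDosage(gt)
    rr <- SummarizedExperiment::rowRanges(vcf)
    GenoPanel(dose,
              chrom = as.character(GenomicRanges::seqnames(rr)),
              pos = GenomicRanges::start(rr),
              ref = as.character(VariantAnnotation::ref(vcf)),
              alt = altChar)
}

.gtToDosage <- function(gt) {
    g <- gsub("|", "/", gt, fixed = TRUE)
    map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    d <- map[g]   # anything else (no-calls, unexpected codes) -> NA
    dim(d) <- dim(gt)
    dimnames(d) <- dimnames(gt)
    d
}

#' Write a genotype panel to VCF
#'
#' Emits a minimal VCF 4.2 with only the GT format field, suitable for
#' round-tripping a [GenoPanel-class] through [readVcfPanel()].
#'
#' @param panel a `GenoPanel`.
#' @param path output file path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
writeVcfPanel <- function(panel, path) {
    cl <- genotypeCalls(panel)
    gt <- matrix(c("0/0", "0/1", "1/1")[cl + 1L], nrow = nrow(cl))
    gt[is.na(cl)] <- "./."
    dimnames(gt) <- dimnames(cl)
    hdr <- VariantAnnotation::VCFHeader(samples = colnames(cl))
    VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
        Number = "1", Type = "String", Description = "Genotype",
        row.names = "GT")
    VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
        fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                          row.names = "fileformat"))
    rd <- SummarizedExperiment::rowData(panel)
    vcf <- VariantAnnotation::VCF(
        rowRanges = SummarizedExperiment::rowRanges(panel),
        colData = S4Vectors::DataFrame(row.names = colnames(cl)),
        exptData = list(header = hdr),
        fixed = S4Vectors::DataFrame(
            REF = Biostrings::DNAStringSet(.asDNA(rd$ref)),
            ALT = IRanges::CharacterList(as.list(.asDNA(rd$alt))),
            QUAL = rep(NA_real_, nrow(cl)),
            FILTER = rep(".", nrow(cl))),
        geno = S4Vectors::SimpleList(GT = gt))
    VariantAnnotation::writeVcf(vcf, path)
    invisible(path)
}

# placeholder alleles like "A"/"B" are already valid IUPAC letters; anything
# else becomes N so the DNAStringSet constructor cannot fail
.asDNA <- function(x) {
    x <- toupper(as.character(x))
    x[!x %in% c("A", "C", "G", "T", "B", "N")] <- "N"
    x
}

#' Read a genotype panel from a delimited matrix
#'
#' Reads a delimited table with individuals in rows and markers in columns.
#' Entries are either numeric dosages (`0`, `1`, `2`) or two-letter
#' genotype symbols (e.g. `GG`, `GT`, `TT`); the missing token is
#' configurable.  For symbolic columns the alleles are sorted
#' alphabetically and the dosage counts the second allele, so `GG`, `GT`,
#' `TT` map to 0, 1, 2.  The header row and first column define marker and
#' individual names.
#'
#' @param path path to a CSV (`.csv`) or TSV file.
#' @param missingCode token marking a missing call (default `"NA"`).
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return a `GenoPanel`.
#' @export
readMatrixPanel <- function(path, missingCode = "NA", sep = NULL) {
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                             colClasses = "character", check.names = FALSE,
                             na.strings = NULL, comment.char = "")
    if (nrow(tab) == 0L) stop("no individuals in ", path)
    k <- ncol(tab)
    calls <- matrix(NA_integer_, nrow = k, ncol = nrow(tab),
                    dimnames = list(colnames(tab), rownames(tab)))
    ref <- alt <- character(k)
    for (j in seq_len(k)) {
        col <- .parseGenoColumn(tab[[j]], missingCode,
                                marker = colnames(tab)[j],
                                individuals = rownames(tab))
        calls[j, ] <- col$dosage
        ref[j] <- col$ref; alt[j] <- col$alt
    }
    GenoPanel(calls, ref = ref, alt = alt)
}

.parseGenoColumn <- function(x, missingCode, marker, individuals) {
    x <- trimws(x)
    miss <- x == missingCode
    v <- x[!miss]
    if (all(v %in% c("0", "1", "2"))) {
        d <- rep(NA_integer_, length(x))
        d[!miss] <- as.integer(v)
        return(list(dosage = d, ref = "A", alt = "B"))
    }
    if (!all(nchar(v) == 2L)) {
        bad <- which(!miss & !(nchar(x) == 2L))[1L]
        stop(sprintf("invalid genotype '%s' at row '%s', column '%s'",
                     x[bad], individuals[bad], marker))
    }
    letters2 <- sort(unique(unlist(strsplit(v, ""))))
    if (length(letters2) > 2L)
        stop(sprintf("more than two alleles (%s) in column '%s'",
                     paste(letters2, collapse = ","), marker))
    if (length(letters2) == 1L) letters2 <- c(letters2, letters2)
    a1 <- substr(v, 1L, 1L); a2 <- substr(v, 2L, 2L)
    second <- letters2[2L]
    d <- rep(NA_integer_, length(x))
    d[!miss] <- (a1 == second) + (a2 == second)
    list(dosage = d, ref = letters2[1L], alt = letters2[2L])
}

#' Write a panel as a delimited genotype matrix
#'
#' Inverse of [readMatrixPanel()]: individuals in rows, markers in columns,
#' symbolic genotypes built from the marker alleles.
#'
#' @param panel a `GenoPanel`.
#' @param path output path; `.csv` selects comma separation.
#' @param missingCode token written for missing calls.
#' @return `path`, invisibly.
#' @export
writeMatrixPanel <- function(panel, path, missingCode = "NA") {
    cl <- genotypeCalls(panel)
    rd <- SummarizedExperiment::rowData(panel)
    sym <- matrix(missingCode, nrow = nrow(cl), ncol = ncol(cl),
                  dimnames = dimnames(cl))
    for (j in seq_len(nrow(cl))) {
        g <- c(paste0(rd$ref[j], rd$ref[j]), paste0(rd$ref[j], rd$alt[j]),
               paste0(rd$alt[j], rd$alt[j]))
        ok <- !is.na(cl[j, ])
        sym[j, ok] <- g[cl[j, ok] + 1L]
    }
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    out <- data.frame(id = colnames(cl), t(sym), check.names = FALSE)
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a long-format allele-intensity table
#'
#' Expects a delimited file with columns `individual`, `marker`, `A`, `B`.
#'
#' @param path path to the table.
#' @param sep separator (default tab).
#' @return a data.frame with the four columns.
#' @export
readIntensityTable <- function(path, sep = "\t") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("individual", "marker", "A", "B")
    if (!all(need %in% colnames(tab)))
        stop("intensity table must have columns: ", paste(need, collapse = ", "))
    tab[need]
}

#' Attach allele intensities to a panel
#'
#' Joins a long-format intensity table (see [readIntensityTable()]) to a
#' panel by individual and marker identifier.  Every marker present in the
#' table must cover all of the panel's individuals; markers absent from the
#' table are left without intensities.
#'
#' @param panel a `GenoPanel`.
#' @param tab data.frame with columns `individual`, `marker`, `A`, `B`.
#' @return the panel with `intensityA`/`intensityB` assays.
#' @export
addIntensities <- function(panel, tab) {
    cl <- genotypeCalls(panel)
    A <- B <- matrix(NA_real_, nrow(cl), ncol(cl), dimnames = dimnames(cl))
    tab <- tab[tab$marker %in% rownames(cl), , drop = FALSE]
    if (!all(tab$individual %in% colnames(cl)))
        stop("intensity table names individuals absent from the panel")
    idx <- cbind(match(tab$marker, rownames(cl)),
                 match(tab$individual, colnames(cl)))
    A[idx] <- tab$A
    B[idx] <- tab$B
    covered <- unique(tab$marker)
    part <- covered[apply(is.na(A[covered, , drop = FALSE]), 1L, any)]
    if (length(part))
        stop("incomplete intensities for marker(s): ",
             paste(utils::head(part, 5L), collapse = ", "))
    se <- panel
    SummarizedExperiment::assay(se, "intensityA", withDimnames = FALSE) <- A
    SummarizedExperiment::assay(se, "intensityB", withDimnames = FALSE) <- B
    methods::validObject(se)
    se
}
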