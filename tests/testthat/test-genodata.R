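test_that("GenoPanel validity enforces call codes and increasing positions", {
    expect_s4_class(GenoPanel(rbind(c(0, 1, 2, NA))), "GenoPanel")
    expect_error(GenoPanel(rbind(c(0, 3, 2, NA))), "0, 1 or 2")
    expect_error(GenoPanel(rbind(a = c(0, 1), b = c(1, 2)), pos = c(10, 10)),
                 "strictly increasing")
})

test_that("tabulateCounts partitions the panel and is permutation-invariant", {
    expect_equal(tabulateCounts(c(0, 1, 2, NA)), c(AA = 1, AB = 1, BB = 1, NN = 1))
    expect_equal(tabulateCounts(rep(NA_integer_, 5)), c(AA = 0, AB = 0, BB = 0, NN = 5))
    set.seed(1)
    for (i in 1:20) {
        x <- sample(c(0:2, NA), 30, replace = TRUE)
        expect_equal(tabulateCounts(x), tabulateCounts(sample(x)))
        expect_equal(sum(tabulateCounts(x)), 30)
    }
})

test_that("matrix reader maps dosage and symbolic codings", {
    tf <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,m1,m2", "i1,0,NA", "i2,2,1"), tf)
    p <- readMatrixPanel(tf)
    expect_equal(unname(genotypeCalls(p)["m1", ]), c(0L, 2L))
    expect_equal(unname(genotypeCalls(p)["m2", ]), c(NA_integer_, 1L))

    tf2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,m1", "i1,AA", "i2,AB", "i3,BB"), tf2)
    expect_equal(unname(genotypeCalls(readMatrixPanel(tf2))["m1", ]), 0:2)

    # heterozygotes in either letter order; dosage counts the
    # alphabetically-second allele
    tf3 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,m1", "i1,TG", "i2,GG", "i3,TT"), tf3)
    p3 <- readMatrixPanel(tf3)
    expect_equal(unname(genotypeCalls(p3)["m1", ]), c(1L, 0L, 2L))
    expect_equal(as.character(panelAlleles(p3)$alt), "T")

    tf4 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,m1", "i1,AA", "i2,XYZ"), tf4)
    expect_error(readMatrixPanel(tf4), "i2.*m1")
})

test_that("the shipped 146-individual fixture reproduces the worked counts", {
    p <- readMatrixPanel(system.file("extdata", "synthetic_gt_snp.csv",
                                     package = "HardyMI"))
    expect_equal(nIndividuals(p), 146L)
    expect_equal(unname(tabulateCounts(genotypeCalls(p)["rs0001", ])),
                 c(46, 32, 20, 48))
})

test_that("VCF round-trip preserves the call matrix exactly", {
    calls <- rbind(snpA = c(0L, 1L, 2L), snpB = c(NA, 0L, 1L))
    colnames(calls) <- c("s1", "s2", "s3")
    p <- GenoPanel(calls, chrom = "7", pos = c(101L, 309L),
                   ref = c("G", "C"), alt = c("T", "A"))
    tf <- withr::local_tempfile(fileext = ".vcf")
    writeVcfPanel(p, tf)
    p2 <- readVcfPanel(tf)
    expect_identical(genotypeCalls(p2), genotypeCalls(p))
    expect_equal(as.character(panelAlleles(p2)$ref), c("G", "C"))
    # a second round trip is byte-stable on the GT matrix
    tf2 <- withr::local_tempfile(fileext = ".vcf")
    writeVcfPanel(p2, tf2)
    expect_identical(genotypeCalls(readVcfPanel(tf2)), genotypeCalls(p))
})

test_that("VCF reader skips multi-allelic records and rejects empty files", {
    tf <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3\ts4",
        "1\t100\tsnp1\tG\tT\t.\t.\t.\tGT\t0/0\t0|1\t1/1\t./.",
        "1\t200\tsnp2\tA\tC,G\t.\t.\t.\tGT\t0/0\t0/1\t0/2\t1/1"), tf)
    expect_warning(p <- readVcfPanel(tf), "skipping 1")
    expect_equal(nMarkers(p), 1L)
    expect_equal(unname(genotypeCalls(p)["snp1", ]), c(0L, 1L, 2L, NA))

    tf0 <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
        "1\t100\tsnp1\tG\tT\t.\t.\t."), tf0)
    expect_error(readVcfPanel(tf0), "no individuals")
})

test_that("matrix round-trip preserves calls through symbolic coding", {
    set.seed(3)
    p <- genGenotypes(25, 6, maf = 0.4, f = 0)
    cl <- genotypeCalls(p)
    cl[1, 1:5] <- NA
    p <- GenoPanel(cl, ref = as.character(panelAlleles(p)$ref),
                   alt = as.character(panelAlleles(p)$alt))
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeMatrixPanel(p, tf)
    p2 <- readMatrixPanel(tf)
    # symbolic coding sorts alleles alphabetically, so dosages may flip
    # (0 <-> 2) per marker; counts are the invariant representation
    for (mk in markerIds(p)) {
        a <- tabulateCounts(genotypeCalls(p)[mk, ])
        b <- tabulateCounts(genotypeCalls(p2)[mk, ])
        expect_true(identical(unname(a), unname(b)) ||
                    identical(unname(a), unname(b[c(3, 2, 1, 4)])))
    }
})

test_that("intensity tables join by identifier, not row order", {
    p <- GenoPanel(rbind(m1 = c(0L, 1L, 2L)),
                   intensityA = NULL, intensityB = NULL)
    colnames(p) <- c("x", "y", "z")
    tab <- data.frame(individual = c("z", "x", "y"), marker = "m1",
                      A = c(3, 1, 2), B = c(30, 10, 20))
    p2 <- addIntensities(p, tab)
    expect_equal(unname(intensityA(p2)["m1", ]), c(1, 2, 3))
    expect_equal(unname(intensityB(p2)["m1", ]), c(10, 20, 30))
    expect_error(addIntensities(p, tab[1:2, ]), "incomplete intensities")
})
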