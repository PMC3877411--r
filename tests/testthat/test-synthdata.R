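test_that("generated genotype frequencies follow the inbreeding model", {
    set.seed(25)
    gp <- genGenotypes(4000, 1, maf = 0.5, f = 0)
    cnt <- tabulateCounts(genotypeCalls(gp)[1, ])
    # 3-sigma multinomial band around (0.25, 0.5, 0.25)
    for (i in 1:3) {
        p0 <- c(0.25, 0.5, 0.25)[i]
        expect_lt(abs(cnt[[i]] / 4000 - p0), 3 * sqrt(p0 * (1 - p0) / 4000))
    }
    gp1 <- genGenotypes(500, 3, maf = 0.3, f = 1)
    expect_true(all(tabulateCounts(gp1)[, "AB"] == 0))
    expect_error(genGenotypes(10, 1, maf = 0.2, f = -0.5), "infeasible")
    expect_error(genGenotypes(10, 1, maf = 0.7), "maf")
})

test_that("estimateInbreeding recovers the configured f without bias", {
    set.seed(26)
    for (cfg in list(c(maf = 0.3, f = 0.2), c(maf = 0.4, f = 0))) {
        reps <- 120
        fh <- numeric(reps)
        for (r in seq_len(reps)) {
            gp <- genGenotypes(1000, 1, maf = cfg[["maf"]], f = cfg[["f"]])
            fh[r] <- fHat(estimateInbreeding(tabulateCounts(genotypeCalls(gp)[1, ])))
        }
        expect_lt(abs(mean(fh) - cfg[["f"]]), 3 * sd(fh) / sqrt(reps))
    }
})

test_that("LD blocks hit the target dosage correlation within 0.1", {
    set.seed(27)
    for (r2 in c(0.5, 0.8)) {
        gp <- genGenotypes(3000, 3, maf = 0.3, f = 0,
                           ldBlocks = list(list(size = 3, r2 = r2)))
        cl <- genotypeCalls(gp)
        expect_lt(abs(ldR2(cl[1, ], cl[2, ]) - r2), 0.1)
        expect_lt(abs(ldR2(cl[2, ], cl[3, ]) - r2), 0.1)
        # per-locus HWP inside blocks
        f1 <- fHat(estimateInbreeding(tabulateCounts(cl[1, ])))
        expect_lt(abs(f1), 0.1)
    }
})

test_that("intensity clouds collapse to exact points without noise and flip with means", {
    gp <- genGenotypes(50, 1, maf = 0.4, f = 0, seed = 28)
    g0 <- genIntensities(gp, sd = 0, brightness = 0)
    cl <- genotypeCalls(g0)[1, ]
    expect_equal(unname(intensityA(g0)[1, cl == 0]), rep(2, sum(cl == 0)))
    expect_equal(unname(intensityB(g0)[1, cl == 2]), rep(2, sum(cl == 2)))
    swapped <- genIntensities(gp, means = rbind(c(0.2, 2), c(1.1, 1.1), c(2, 0.2)),
                              sd = 0, brightness = 0)
    expect_equal(unname(intensityA(swapped)[1, cl == 2]), rep(2, sum(cl == 2)))
})

test_that("default intensity clouds support near-perfect genotype recovery", {
    set.seed(29)
    gp <- genIntensities(genGenotypes(400, 1, maf = 0.4, f = 0))
    cl <- factor(genotypeCalls(gp)[1, ])
    dat <- data.frame(A = intensityA(gp)[1, ], B = intensityB(gp)[1, ])
    fit <- MASS::lda(dat, grouping = cl)
    acc <- mean(predict(fit)$class == cl)
    expect_gt(acc, 0.95)
})

test_that("deletion regimes honour their probabilities and keep the truth record", {
    set.seed(30)
    gp <- genGenotypes(2000, 8, maf = 0.3, f = 0)
    # zero deletion is the identity
    del0 <- applyMissingness(gp, "MNAR", probs = c(0, 0, 0), snpFraction = 1)
    expect_identical(genotypeCalls(del0$panel), genotypeCalls(gp))
    # MCAR at 0.25 on a quarter of markers: ~6% missing overall
    del1 <- applyMissingness(gp, "MCAR", probs = 0.25, snpFraction = 0.25)
    expect_equal(length(del1$affected), 2L)
    expect_lt(abs(mean(is.na(genotypeCalls(del1$panel))) - 0.0625), 0.02)
    # per-genotype deletion rates within binomial 3 sigma
    del2 <- applyMissingness(gp, "MNAR", probs = c(0.05, 0.75, 0.05),
                             snpFraction = 1)
    cl <- genotypeCalls(del2$panel); tru <- del2$truth
    for (g in 0:2) {
        pi0 <- c(0.05, 0.75, 0.05)[g + 1]
        idx <- tru == g
        rate <- mean(is.na(cl[idx]))
        expect_lt(abs(rate - pi0), 3 * sqrt(pi0 * (1 - pi0) / sum(idx)))
    }
    # truth and degraded panel agree wherever a call survived
    obs <- !is.na(cl)
    expect_identical(cl[obs], tru[obs])
})

test_that("the MNAR heterozygote-deletion bias matches the reweighting formula", {
    # retention (0.95, 0.25, 0.95) of HWP(maf = 0.2) genotype frequencies,
    # renormalized, gives an expected complete-case f of about 0.42
    keep <- c(0.95, 0.25, 0.95)
    fr <- genotypeFreqs(0.2, 0) * keep
    fr <- fr / sum(fr)
    pPrime <- fr[[1]] + fr[[2]] / 2
    fExpected <- 1 - fr[[2]] / (2 * pPrime * (1 - pPrime))
    expect_equal(fExpected, 0.4255, tolerance = 1e-3)
    set.seed(31)
    gp <- genGenotypes(200000, 1, maf = 0.2, f = 0)
    del <- applyMissingness(gp, "MNAR", probs = 1 - keep, snpFraction = 1)
    fh <- fHat(estimateInbreeding(tabulateCounts(genotypeCalls(del$panel)[1, ])))
    expect_lt(abs(fh - fExpected), 0.02)
})

test_that("boundary-MAR deletion is visible to the intensity diagnostics", {
    set.seed(32)
    gp <- genIntensities(genGenotypes(150, 12, maf = c(0.1, 0.5), f = 0))
    delMAR <- applyMissingness(gp, "MAR", probs = 0.55, snpFraction = 1)
    delMCAR <- applyMissingness(gp, "MCAR", probs = 0.35, snpFraction = 1)
    pMAR <- mcarReport(delMAR$panel, minMissing = 10)$pT2Pooled
    pMCAR <- mcarReport(delMCAR$panel, minMissing = 10)$pT2Pooled
    expect_lt(mean(pMAR), mean(pMCAR))
    expect_lt(mean(pMAR), 0.1)
})
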