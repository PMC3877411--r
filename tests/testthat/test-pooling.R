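test_that("hand-computed two-imputation example pools exactly", {
    pr <- poolEstimates(c(0, 1), c(1, 1))
    expect_equal(pooledEstimate(pr), 0.5)
    expect_equal(pr@wBar, 1)
    expect_equal(pr@b, 0.5)
    expect_equal(pr@tVar, 1.75)
    expect_equal(pr@r, 0.75)
    expect_equal(pr@nu, (7 / 3)^2)
    expect_equal(pr@lambda, (0.75 + 2 / ((7 / 3)^2 + 3)) / 1.75)
})

test_that("degenerate agreement collapses to complete-data inference", {
    pr <- poolEstimates(rep(0.3, 10), rep(0.01, 10))
    expect_equal(pooledEstimate(pr), 0.3)
    expect_equal(pr@b, 0)
    expect_equal(pr@tVar, 0.01)
    expect_equal(pr@r, 0)
    expect_equal(pr@lambda, 0)
    # normal-reference interval and p, as for complete data
    expect_equal(unname(pr@ci), 0.3 + c(-1, 1) * qnorm(0.975) * 0.1)
    expect_equal(pr@p, 2 * pnorm(-3))
})

test_that("pooling identities hold for random inputs", {
    set.seed(16)
    for (i in 1:500) {
        m <- sample(2:60, 1)
        est <- rnorm(m, 0.2, 0.2)
        v <- runif(m, 1e-4, 0.02)
        pr <- poolEstimates(est, v)
        expect_equal(pr@tVar, pr@wBar + (1 + 1 / m) * pr@b, tolerance = 1e-12)
        expect_equal(pr@r, (1 + 1 / m) * pr@b / pr@wBar, tolerance = 1e-12)
        expect_equal(pr@nu, (m - 1) * (1 + 1 / pr@r)^2, tolerance = 1e-12)
        expect_equal(pr@lambda, (pr@r + 2 / (pr@nu + 3)) / (pr@r + 1),
                     tolerance = 1e-12)
        expect_gte(pr@tVar, pr@wBar)
        expect_true(pr@lambda >= 0 && pr@lambda < 1)
    }
})

test_that("the printed missing-information pair is an exact identity", {
    # r = 0.283 with m = 50 forces lambda = 0.222 through the formulas,
    # independent of the data
    r <- 0.283; m <- 50
    nu <- (m - 1) * (1 + 1 / r)^2
    lambda <- (r + 2 / (nu + 3)) / (r + 1)
    expect_equal(round(lambda, 3), 0.222)
})

test_that("lambda grows with r at fixed m", {
    m <- 20
    lam <- vapply(seq(0.05, 3, by = 0.05), function(r) {
        nu <- (m - 1) * (1 + 1 / r)^2
        (r + 2 / (nu + 3)) / (r + 1)
    }, numeric(1))
    expect_true(all(diff(lam) > 0))
})

test_that("input validation rejects unusable pooling inputs", {
    expect_error(poolEstimates(0.5, 0.1), "at least 2")
    expect_error(poolEstimates(c(0.1, 0.2), c(0.1, -0.1)), "positive")
    expect_error(poolEstimates(c(0.1, 0.2), c(0.1, 0)), "positive")
})

test_that("Fisher-z pooling is a bijection that agrees at f = 0", {
    przero <- poolFisherZ(c(0, 0, 0), rep(0.01, 3))
    priden <- poolEstimates(c(0, 0, 0), rep(0.01, 3))
    expect_equal(pooledEstimate(przero), pooledEstimate(priden))
    expect_equal(przero@p, priden@p)
    pr <- poolFisherZ(rep(0.5, 4), rep(0.01, 4))
    expect_equal(pooledEstimate(pr), 0.5)
    expect_error(poolFisherZ(c(0.2, 1), c(0.01, 0.01)), "infinite")
    # near-agreement of the two scales for the worked example
    set.seed(17)
    setR <- imputeRandom(workedCalls(), m = 50, seed = 18)
    fi <- poolInbreeding(setR, scale = "identity")
    fz <- poolInbreeding(setR, scale = "fisher.z")
    expect_lt(abs(pooledEstimate(fi) - pooledEstimate(fz)), 0.01)
})

test_that("pooling at the |f| = 1 boundary is reported as undefined", {
    # only homozygotes observed: every completed copy has f = 1, where the
    # large-sample variance degenerates, so pooling fails on either scale
    calls <- rep(c(0L, 2L, NA), c(40L, 4L, 10L))
    set <- imputeRandom(calls, m = 5, seed = 19)
    expect_error(poolInbreeding(set, scale = "fisher.z"), "undefined")
    expect_error(poolInbreeding(set, scale = "identity"), "undefined")
})

test_that("markers without missings reproduce complete-case inference", {
    calls <- rep(c(0L, 1L, 2L), c(46L, 32L, 20L))
    set <- imputeRandom(calls, m = 5, seed = 20)
    pr <- poolInbreeding(set)
    est <- estimateInbreeding(c(46, 32, 20))
    expect_equal(pooledEstimate(pr), fHat(est))
    expect_equal(pr@tVar, varF(est))
    expect_equal(pr@r, 0)
    z <- fHat(est) / sqrt(varF(est))
    expect_equal(pr@p, 2 * pnorm(-abs(z)))
})

test_that("miHWPTest composes imputation and pooling per marker", {
    set.seed(21)
    gp <- ldPanel(seed = 22)
    del <- applyMissingness(gp, "MCAR", probs = 0.2, snpFraction = 1, seed = 23)
    tab <- miHWPTest(del$panel, model = "random", m = 10, seed = 24)
    expect_equal(sort(tab$marker), sort(markerIds(gp)))
    expect_true(all(!tab$skipped))
    expect_true(all(tab$lambda >= 0 & tab$lambda < 1, na.rm = TRUE))
    expect_true(all(tab$r >= 0, na.rm = TRUE))
    # an unimputable (monomorphic-observed) marker is flagged, not fatal
    cl <- genotypeCalls(gp)
    cl["snp0004", ] <- c(rep(0L, 100), rep(NA, 100))
    p2 <- GenoPanel(cl)
    tab2 <- miHWPTest(p2, markers = "snp0004", model = "random", m = 5)
    expect_true(tab2$skipped)
    expect_true(is.na(tab2$f_pooled))
})
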