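test_that("ldR2 matches direct correlation and is symmetric under flips", {
    g <- c(0L, 1L, 2L, 0L)
    expect_equal(ldR2(g, g), 1)
    expect_equal(ldR2(g, 2L - g), 1)
    # brute-force value for the mixed pair (0,0),(1,1),(2,2),(0,1)
    expect_equal(ldR2(c(0, 1, 2, 0), c(0, 1, 2, 1)), 8 / 11)
    expect_equal(ldR2(c(0, 1, 2, 0), c(0, 1, 2, 1)),
                 cor(c(0, 1, 2, 0), c(0, 1, 2, 1))^2)
    expect_warning(r0 <- ldR2(c(0, 0, 0, 1), c(1, 1, 1, NA)), "no variation")
    expect_equal(r0, 0)
    # pairwise-complete semantics
    expect_equal(ldR2(c(0, 1, 2, NA), c(0, 1, 2, 0)), 1)
})

test_that("covariate selection applies the threshold, ordering, cap and exclusions", {
    set.seed(10)
    base <- sample(0:2, 100, replace = TRUE, prob = c(.25, .5, .25))
    flip <- function(x, k) { i <- sample(100, k); x[i] <- sample(0:2, k, TRUE); x }
    calls <- rbind(t = base, dup = base, c1 = flip(base, 10), c2 = flip(base, 30),
                   c3 = sample(0:2, 100, TRUE))
    p <- GenoPanel(calls)
    sel <- selectCovariates(p, "t", ldThreshold = 0.5)
    expect_false("dup" %in% sel)        # perfect duplicate excluded
    expect_false("t" %in% sel)          # self excluded
    r2 <- attr(sel, "r2")
    expect_true(all(diff(r2) <= 0))     # descending order
    expect_true(all(r2 >= 0.5))
    expect_equal(length(selectCovariates(p, "t", ldThreshold = 0.5,
                                         maxCovariates = 1L)), 1L)
    # nothing passes an impossible threshold; intensity fallback is flagged
    p2 <- genIntensities(genGenotypes(50, 2, maf = 0.4, f = 0, seed = 2))
    sel2 <- selectCovariates(p2, "snp0001", ldThreshold = 0.999)
    expect_length(sel2, 0L)
    expect_equal(attr(sel2, "fallback"), "intensities")
})

test_that("intercept-only multinomial fit returns the category frequencies", {
    y <- rep(c(0, 1, 2), c(50, 30, 20))
    lf <- fitMultinomialLogit(y, NULL)
    pr <- predictCategoryProbs(lf, n = 1)
    expect_equal(sort(unname(pr[1, ])), sort(c(0.5, 0.3, 0.2)), tolerance = 1e-3)
    expect_equal(lf$reference, "0")
})

test_that("two observed categories reduce to binary logistic regression", {
    set.seed(11)
    x <- rnorm(200)
    y <- rbinom(200, 1, plogis(-0.4 + 1.2 * x)) * 2L   # categories 0 and 2
    lf <- fitMultinomialLogit(y, data.frame(x = x), ridge = 0)
    gl <- glm(I(y == setdiff(c("0", "2"), lf$reference)) ~ x, family = binomial)
    expect_equal(unname(lf$coef[1, ]), unname(coef(gl)), tolerance = 1e-3)
})

test_that("ridge keeps perfectly separating fits finite and near-deterministic", {
    x <- rep(c(0, 1), each = 30)
    y <- rep(c(0, 2), each = 30)
    lf <- fitMultinomialLogit(y, data.frame(x = x), ridge = 1e-4)
    pr <- predictCategoryProbs(lf, data.frame(x = c(0, 1)))
    expect_gt(pr[1, "0"], 0.99)
    expect_gt(pr[2, "2"], 0.99)
    expect_true(all(is.finite(lf$vcov)))
})

test_that("collinear predictors are dropped with a warning", {
    set.seed(12)
    x <- rnorm(100)
    y <- sample(0:2, 100, replace = TRUE)
    expect_warning(lf <- fitMultinomialLogit(y, data.frame(a = x, b = 2 * x)),
                   "collinear")
    expect_length(lf$predictors, 1L)
})

test_that("coefficient draws vary but stay centred on the fit", {
    set.seed(13)
    x <- rnorm(300)
    y <- rbinom(300, 2, plogis(x))
    lf <- fitMultinomialLogit(y, data.frame(x = x))
    draws <- replicate(200, drawCoefficients(lf))
    mu <- as.vector(t(lf$coef))
    expect_equal(rowMeans(draws), mu, tolerance = 0.15)
    expect_true(all(apply(draws, 1, sd) > 0))
})

test_that("random imputation preserves observed data and category support", {
    set1 <- imputeRandom(workedCalls(), m = 10, seed = 1)
    src <- genotypeCalls(set1@source)
    for (cm in completions(set1)) {
        expect_identical(cm[!is.na(src)], src[!is.na(src)])
        expect_false(anyNA(cm))
    }
    # categories never observed are never imputed
    calls2 <- rep(c(0L, 2L, NA), c(10L, 10L, 10L))
    set2 <- imputeRandom(calls2, m = 10, seed = 2)
    for (cm in completions(set2)) expect_true(all(cm %in% c(0L, 2L)))
    # identical seed, identical result; different seed differs
    setA <- imputeRandom(workedCalls(), m = 5, seed = 99)
    setB <- imputeRandom(workedCalls(), m = 5, seed = 99)
    expect_identical(completions(setA), completions(setB))
    expect_error(imputeRandom(rep(NA_real_, 4), m = 5), "entirely missing")
    # no missings: m identical copies
    set3 <- imputeRandom(c(0L, 1L, 2L, 2L), m = 3, seed = 3)
    expect_identical(completions(set3)[[1]], completions(set3)[[2]])
})

test_that("chained imputation respects immutability, support and reproducibility", {
    set.seed(14)
    gp <- ldPanel(seed = 100)
    del <- applyMissingness(gp, "MNAR", probs = c(0.05, 0.6, 0.05),
                            snpFraction = 1, seed = 101)
    deg <- del$panel
    s1 <- imputeChained(deg, "snp0001", m = 4, iterations = 3, seed = 7)
    s2 <- imputeChained(deg, "snp0001", m = 4, iterations = 3, seed = 7)
    expect_identical(completions(s1), completions(s2))
    src <- genotypeCalls(deg)
    obs <- !is.na(src)
    modelVars <- c("snp0001", s1@params$covariates)
    for (cm in completions(s1)) {
        expect_identical(cm[obs], src[obs])
        # model variables are fully completed, from their observed support;
        # markers outside the model keep their missing entries
        for (mk in modelVars) {
            seen <- unique(src[mk, obs[mk, ]])
            expect_false(anyNA(cm[mk, ]))
            expect_true(all(cm[mk, ] %in% seen))
        }
        for (mk in setdiff(rownames(src), modelVars))
            expect_identical(cm[mk, ], src[mk, ])
    }
    tr <- convergenceTrace(s1)
    expect_equal(dim(tr), c(3L, 4L))
    expect_true(all(is.finite(tr)))
})

test_that("a marker with only homozygotes observed is imputed toward f = 1", {
    # low-MAF marker whose few heterozygotes were all deleted: the model
    # cannot impute a category it never saw, driving the pooled f to 1
    calls <- rep(c(0L, 2L, NA), c(80L, 6L, 24L))
    p <- GenoPanel(matrix(calls, nrow = 1, dimnames = list("m", NULL)))
    set <- imputeRandom(p, m = 10, seed = 5)
    for (cm in completions(set)) {
        expect_true(all(cm %in% c(0L, 2L)))
        expect_equal(fHat(estimateInbreeding(tabulateCounts(cm["m", ]))), 1)
    }
    # at f = 1 the large-sample variance degenerates, so Rubin pooling is
    # undefined and the marker must be reported as such
    expect_error(poolInbreeding(set), "undefined")
    tab <- miHWPTest(p, model = "random", m = 5, seed = 6)
    expect_true(tab$skipped)
})

test_that("zero-missing chained imputation returns identical copies", {
    gp <- ldPanel(n = 60, seed = 15)
    set <- imputeChained(gp, "snp0001", covariates = "snp0002",
                        m = 3, iterations = 2, seed = 8)
    expect_identical(completions(set)[[1]], genotypeCalls(gp))
    expect_identical(completions(set)[[2]], genotypeCalls(gp))
})
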