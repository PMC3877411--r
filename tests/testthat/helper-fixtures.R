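`%||%` <- function(a, b) if (is.null(a)) b else a

# fixtures built in code; the worked single-SNP example has genotype
# counts 46/32/20 observed (GG/GT/TT) plus 48 missing calls over 146
# individuals

workedCounts <- function() c(AA = 46, AB = 32, BB = 20, NN = 48)

workedCalls <- function() rep(c(0L, 1L, 2L, NA), c(46L, 32L, 20L, 48L))

workedPanel <- function() {
    GenoPanel(matrix(workedCalls(), nrow = 1L,
                     dimnames = list("rs0001", sprintf("ind%03d", 1:146))),
              ref = "G", alt = "T")
}

# small complete HWP panel with one LD pair in front
ldPanel <- function(n = 200L, k = 4L, maf = 0.3, r2 = 0.85, seed = NULL) {
    genGenotypes(n, k, maf = maf, f = 0,
                 ldBlocks = list(list(size = 2L, r2 = r2)), seed = seed)
}

# independent brute-force oracle for the exact HWP test: enumerate every
# genotype table with the same n and allele count via plain factorials
exactOracle <- function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB
    nA <- 2 * nAA + nAB
    tabs <- expand.grid(aa = 0:n, ab = 0:n)
    tabs$bb <- n - tabs$aa - tabs$ab
    tabs <- tabs[tabs$bb >= 0 & (2 * tabs$aa + tabs$ab) == nA, ]
    pr <- apply(tabs, 1L, function(t3)
        factorial(n) / (factorial(t3[1]) * factorial(t3[2]) * factorial(t3[3])) *
        2^t3[2] * factorial(nA) * factorial(2 * n - nA) / factorial(2 * n))
    pr <- pr / sum(pr)
    pobs <- pr[tabs$ab == nAB]
    sum(pr[pr <= pobs + 1e-12])
}
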