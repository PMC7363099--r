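test_that("Pearson slope test reproduces the least-squares oracle", {
    x <- c(-1, 0, 1, 2); p <- c(0, 1, 1, 2)
    res <- pearsonTest(x, p)
    fit <- summary(lm(p ~ x))$coefficients["x", ]
    expect_equal(res$effect, unname(fit["Estimate"]))
    expect_equal(res$statistic, unname(fit["t value"]), tolerance = 1e-10)
    expect_equal(res$p_value, unname(fit["Pr(>|t|)"]), tolerance = 1e-10)
    expect_equal(res$effect, 0.6)
    expect_equal(res$effect / res$statistic, 0.141421, tolerance = 1e-5)
    expect_equal(res$df, 2)
    # zero covariance by symmetry
    res0 <- pearsonTest(c(-1, 0, 1), c(1, 0, 1))
    expect_equal(res0$effect, 0)
    expect_equal(res0$statistic, 0)
    expect_equal(res0$p_value, 1)
    expect_error(pearsonTest(1:2, 1:2), "at least 3")
})

test_that("Pearson t equals the textbook correlation t-test", {
    set.seed(21)
    for (i in 1:20) {
        n <- sample(5:100, 1)
        x <- rnorm(n); p <- 0.3 * x + rnorm(n)
        r <- cor(x, p)
        expect_equal(pearsonTest(x, p)$statistic,
                     r * sqrt((n - 2) / (1 - r^2)), tolerance = 1e-10)
    }
})

test_that("Pearson statistic is multiplicative-invariant up to sign", {
    set.seed(8)
    x <- rnorm(40); p <- 0.2 * x + rnorm(40)
    base <- pearsonTest(x, p)
    for (a in c(0.5, 2, 10, -3)) {
        sc <- pearsonTest(a * x, p)
        expect_equal(sc$statistic, sign(a) * base$statistic,
                     tolerance = 1e-12)
        expect_equal(sc$p_value, base$p_value, tolerance = 1e-12)
        expect_equal(sc$effect, base$effect / a, tolerance = 1e-12)
    }
})

test_that("Spearman test is the Pearson test on average ranks", {
    expect_equal(spearmanTest(c(1, 2, 3, 4), c(2, 1, 4, 3))$effect, 0.6)
    expect_equal(spearmanTest(1:10, (1:10)^3)$effect, 1)
    set.seed(3)
    x <- rnorm(30); p <- rnorm(30)
    expect_equal(spearmanTest(x, p)$p_value,
                 spearmanTest(exp(x), p)$p_value)  # increasing transform
    expect_equal(spearmanTest(x, p)$effect,
                 unname(cor(x, p, method = "spearman")), tolerance = 1e-12)
})

test_that("flagged degenerate SNPs yield NA rather than dropping", {
    res <- pearsonTest(rep(1, 10), rnorm(10))
    expect_true(is.na(res$p_value))
    expect_equal(res$flag, "zero-variance")
})

test_that("genome scan reduces to single tests and preserves SNP order", {
    sim <- smallSim(m = 25, n = 40)
    adj <- adjustGenotypes(sim$genotypes, 3)
    for (meth in c("pearson", "kendall", "spearman")) {
        sc <- genomeScan(adj, sim$phenotype, meth)
        expect_equal(nrow(sc), 25)
        expect_equal(sc$snp_id, rownames(adj))
        single <- switch(meth,
            pearson = pearsonTest(adjustedMatrix(adj)[7, ], sim$phenotype),
            kendall = kendallTest(adjustedMatrix(adj)[7, ], sim$phenotype),
            spearman = spearmanTest(adjustedMatrix(adj)[7, ], sim$phenotype))
        expect_equal(sc$p_value[7], single$p_value, tolerance = 1e-12)
        expect_equal(sc$effect[7], single$effect, tolerance = 1e-12)
    }
})

test_that("sample alignment is by id: permuting phenotype order changes nothing", {
    sim <- smallSim(m = 15, n = 30)
    adj <- adjustGenotypes(sim$genotypes, 2)
    sc1 <- genomeScan(adj, sim$phenotype, "kendall")
    sc2 <- genomeScan(adj, sample(sim$phenotype), "kendall")
    expect_equal(sc1$p_value, sc2$p_value)
    expect_error(genomeScan(adj, unname(sim$phenotype)), "names")
    expect_error(genomeScan(adj, sim$phenotype[-1]), "missing for sample")
})

test_that("Kendall scans are identical under a positive encoding rescale", {
    sim <- smallSim(m = 30, n = 50)
    basis <- axesOfVariation(sampleCovariance(sim$genotypes), 4)
    a1 <- adjustGenotypes(sim$genotypes, basis)
    a2 <- adjustGenotypes(transformMultiplicative(sim$genotypes, 2), basis)
    expect_equal(genomeScan(a1, sim$phenotype, "kendall")$p_value,
                 genomeScan(a2, sim$phenotype, "kendall")$p_value)
})

test_that("delta-p is the signed p-value difference with strict SNP matching", {
    sim <- smallSim(m = 20, n = 40)
    adj <- adjustGenotypes(sim$genotypes, 2)
    sc <- genomeScan(adj, sim$phenotype, "kendall")
    expect_equal(deltaP(sc, sc)$delta_p, rep(0, 20))
    sc2 <- sc; sc2$p_value <- rev(sc2$p_value)
    expect_equal(deltaP(sc, sc2)$delta_p, sc$p_value - rev(sc$p_value))
    bad <- sc[c(2:20, 1), ]
    expect_error(deltaP(sc, bad), "identical SNP set")
})
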