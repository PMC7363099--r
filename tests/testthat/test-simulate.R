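test_that("Hardy-Weinberg draws follow the class probabilities", {
    q <- 0.25
    expect_equal((1 - q)^2, 0.5625)
    set.seed(2)
    g <- drawHweGenotypes(1e6, q, E1)
    freq <- tabulate(g + 1, 3) / 1e6
    expect_lt(max(abs(freq - c((1 - q)^2, 2 * q * (1 - q), q^2))), 0.002)
    # q -> 0 limit: (1-q)^2 -> 1, essentially all homozygous major
    g0 <- drawHweGenotypes(1000, 1e-6, E1)
    expect_true(mean(g0 == 0) > 0.99)
    expect_error(drawHweGenotypes(10, 0), "minor allele frequency")
    expect_error(drawHweGenotypes(10, 0.6), "minor allele frequency")
})

test_that("phenotype model partitions unit variance with genetic share pi", {
    set.seed(12)
    g <- attr(drawHweGenotypes(1e5, 0.25), "counts")
    for (pi in c(0, 0.05, 0.5, 1)) {
        p <- simulatePhenotype(g, pi, 0.25)
        # sample variance within 3 standard errors of 1
        se <- sqrt(2 / (length(p) - 1))  # approx SE of sample var of N(0,1)
        expect_equal(var(p), 1, tolerance = 3 * se + 0.01)
    }
    # boundary structure: pi = 1 is deterministic given the genotype
    p1 <- simulatePhenotype(g[1:100], 1, 0.25)
    expect_equal(p1, g[1:100] * sqrt(1 / (2 * 0.25 * 0.75)))
    expect_error(simulatePhenotype(g, 0.5, 1), "strictly")
    expect_error(simulatePhenotype(c(0, 3), 0.5, 0.25), "minor-allele-count")
})

test_that("shuffling respects the rate and its exact boundary cases", {
    set.seed(30)
    g <- drawHweGenotypes(300, 0.25, E1)
    expect_identical(shuffleCopy(g, 0), g)
    full <- shuffleCopy(g, 1)
    expect_equal(sort(full), sort(g))   # kappa = 1: pure permutation
    half <- shuffleCopy(g, 0.5)
    expect_equal(sum(half != g) <= 150, TRUE)
    # exactly round(kappa*n) positions are eligible to change
    set.seed(30)
    sel <- sample.int(300, 150)         # replay the draw of target positions
    set.seed(30)
    half2 <- shuffleCopy(g, 0.5)
    expect_identical(half2[-sel], g[-sel])
})

test_that("datasets are reproducible and structured as causal SNP plus copies", {
    cfg <- simulationConfig(m = 30, n = 40, q = 0.25, pi = 0.05,
                            kappa = 0.5, seed = 99)
    d1 <- generateDataset(cfg)
    d2 <- generateDataset(cfg)
    expect_identical(genotypeMatrix(d1$genotypes), genotypeMatrix(d2$genotypes))
    expect_identical(d1$phenotype, d2$phenotype)
    expect_equal(d1$truth$nPermuted, c(0L, rep(20L, 29)))
    expect_equal(dim(d1$genotypes), c(30L, 40L))
    expect_equal(length(unique(rowData(d1$genotypes)$chrom)), 12L)
    # kappa = 0: every SNP equals the causal SNP, so Kendall p is constant
    d0 <- generateDataset(simulationConfig(m = 5, n = 30, kappa = 0, seed = 1))
    sc <- genomeScan(adjustGenotypes(d0$genotypes, 0), d0$phenotype, "kendall")
    expect_equal(length(unique(sc$p_value)), 1L)
    # rho is an alias for kappa
    expect_equal(simulationConfig(m = 2, n = 5, rho = 0.3)$kappa, 0.3)
})

test_that("association strength decays as the shuffling rate grows", {
    meanAbsTau <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(k) {
        sim <- generateDataset(simulationConfig(m = 40, n = 150, q = 0.25,
                                                pi = 0.5, kappa = k,
                                                seed = 17))
        g <- genotypeMatrix(sim$genotypes)
        mean(abs(apply(g, 1, function(x) kendallTau(x, sim$phenotype)$tau)))
    })
    expect_true(all(diff(meanAbsTau) <= 0.005))  # non-increasing up to noise
})
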