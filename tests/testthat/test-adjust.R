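test_that("sample covariance is invariant to additive shifts and scales as alpha^2", {
    set.seed(11)
    g <- matrix(rnorm(20), 5, 4)
    C <- sampleCovariance(g)
    expect_equal(C, t(C))
    expect_equal(sampleCovariance(g + 3.7), C)
    expect_equal(sampleCovariance(2.5 * g), 2.5^2 * C)
    # identical sample columns: off-diagonal equals the shared diagonal
    gg <- cbind(g[, 1], g[, 1])
    CC <- sampleCovariance(gg)
    expect_equal(CC[1, 2], CC[1, 1])
    expect_error(sampleCovariance(g[1, , drop = FALSE]), "at least 2 SNPs")
})

test_that("eigenvectors from g, alpha*g and g+beta span the same subspace", {
    sim <- smallSim(m = 40, n = 15)
    g <- genotypeMatrix(sim$genotypes)
    K <- 3
    V0 <- basisVectors(axesOfVariation(sampleCovariance(g), K))
    for (gt in list(2 * g, g + 1, -0.5 * g + 4)) {
        V1 <- basisVectors(axesOfVariation(sampleCovariance(gt), K))
        # principal angles via singular values of V0' V1
        sv <- svd(crossprod(V0, V1))$d
        expect_true(all(abs(sv - 1) < 1e-8))
    }
})

test_that("axesOfVariation recovers known structure and validates K", {
    n <- 6
    expect_equal(ncol(basisVectors(axesOfVariation(diag(n), 0))), 0)
    # complete basis of the identity: projector is the identity
    B <- axesOfVariation(diag(n), n)
    expect_equal(tcrossprod(basisVectors(B)), diag(n), tolerance = 1e-10)
    # rank-1 matrix: leading eigenvector is +/- v
    set.seed(4)
    v <- rnorm(n); v <- v / sqrt(sum(v^2))
    got <- basisVectors(axesOfVariation(tcrossprod(v), 1))[, 1]
    expect_equal(abs(sum(got * v)), 1, tolerance = 1e-10)
    expect_error(axesOfVariation(diag(n), n + 1), "K")
    expect_error(axesOfVariation(matrix(1:4, 2), 1), "symmetric")
})

test_that("adjustment boundary cases: K = 0 identity, K = n annihilation", {
    sim <- smallSim(m = 12, n = 10)
    g <- sim$genotypes
    a0 <- adjustGenotypes(g, 0)
    expect_equal(adjustedMatrix(a0), genotypeMatrix(g))
    expect_equal(unname(deltaK(a0)), rep(1, 10))
    an <- suppressMessages(adjustGenotypes(g, 10))
    expect_equal(max(abs(adjustedMatrix(an))), 0, tolerance = 1e-10)
    expect_equal(unname(deltaK(an)), rep(0, 10), tolerance = 1e-10)
})

test_that("adjustment commutes with scaling, is idempotent, and obeys the additive shift law", {
    sim <- smallSim(m = 30, n = 20)
    g <- sim$genotypes
    basis <- axesOfVariation(sampleCovariance(g), 4)
    adj <- adjustGenotypes(g, basis)
    # alpha-commutativity
    adjA <- adjustGenotypes(transformMultiplicative(g, 2.5), basis)
    expect_equal(adjustedMatrix(adjA), 2.5 * adjustedMatrix(adj),
                 tolerance = 1e-10)
    # residual of residual: projector idempotence
    again <- adjustGenotypes(adj, basis)
    expect_equal(adjustedMatrix(again), adjustedMatrix(adj),
                 tolerance = 1e-10)
    # additive shift survives only through the Delta^K remainder
    beta <- 1.75
    adjB <- adjustGenotypes(transformAdditive(g, beta), basis)
    shift <- adjustedMatrix(adjB) - adjustedMatrix(adj)
    expected <- matrix(beta * deltaK(adj), nrow = nrow(g), ncol = ncol(g),
                       byrow = TRUE)
    expect_equal(unname(shift), unname(expected), tolerance = 1e-10)
    expect_error(adjustGenotypes(g, axesOfVariation(diag(5), 2)),
                 "samples")
})

test_that("rank-preservation ratio counts sign-preserved nonzero pairs", {
    expect_equal(rankPreservationRatio(matrix(c(1, 2, 3), 1),
                                       matrix(c(1, 3, 2), 1))$ratio, 2 / 3)
    m <- matrix(rnorm(40), 4, 10)
    expect_equal(rankPreservationRatio(m, m)$ratio, 1)
    expect_equal(rankPreservationRatio(m, -m)$ratio, 0)
    expect_error(rankPreservationRatio(m, m[, 1:5]), "dimensions")
    expect_error(rankPreservationRatio(matrix(1, 2, 3), matrix(2, 2, 3)),
                 "degenerate")
    # per-SNP breakdown averages to the overall ratio on equal-count rows
    rp <- rankPreservationRatio(m, m + rnorm(40, sd = 2))
    expect_equal(rp$nPreserved / rp$nPairs, rp$ratio)
    expect_length(rp$perSNP, 4)
})
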