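test_that("encoding maps genotype classes to the chosen values", {
    calls <- GenotypeCalls(matrix(c("AA", "Aa", "aa"), 1))
    expect_equal(as.vector(genotypeMatrix(encodeGenotypes(calls, E1))),
                 c(0, 1, 2))
    expect_equal(as.vector(genotypeMatrix(encodeGenotypes(calls, E2))),
                 c(-1, 0, 1))
    # constant calls map to a constant column under any encoding
    const <- GenotypeCalls(matrix(c("AA", "AA"), 1))
    enc <- Encoding(c(7, 3, 5), "odd")
    expect_equal(as.vector(genotypeMatrix(encodeGenotypes(const, enc))),
                 c(7, 7))
})

test_that("invalid encodings and missing calls are rejected with context", {
    expect_error(Encoding(c(0, 1, 1)), "distinct")
    calls <- makeCalls(3, 4, missing = 1)
    expect_error(encodeGenotypes(calls, E1), "missing genotype call at SNP")
    expect_error(GenotypeCalls(matrix("AB", 1, 1)), "invalid genotype token")
})

test_that("multiplicative and additive transformations act entrywise", {
    g <- EncodedGenotypes(matrix(c(0, 1, 2, 1), 2), E1)
    expect_equal(as.vector(genotypeMatrix(transformMultiplicative(g, 2))),
                 c(0, 2, 4, 2))
    expect_equal(as.vector(genotypeMatrix(transformMultiplicative(g, -1))),
                 c(0, -1, -2, -1))
    expect_error(transformMultiplicative(g, 0), "nonzero")

    g2 <- EncodedGenotypes(matrix(c(-1, 0, 1, 0), 2), E2)
    shifted <- transformAdditive(g2, 1)
    expect_equal(as.vector(genotypeMatrix(shifted)), c(0, 1, 2, 1))
    expect_equal(sort(encodingValues(shifted)), c(0, 1, 2))
    # beta = 0 is the identity; {1,2,3} + 1 = {2,3,4}
    expect_equal(genotypeMatrix(transformAdditive(g, 0)), genotypeMatrix(g))
    g3 <- EncodedGenotypes(matrix(c(1, 2, 3), 1), Encoding(c(1, 2, 3), "A"))
    expect_equal(as.vector(genotypeMatrix(transformAdditive(g3, 1))),
                 c(2, 3, 4))
})

test_that("recoding between arbitrary encodings preserves genotype classes", {
    sim <- smallSim(m = 10, n = 20)
    g1 <- sim$genotypes
    g2 <- recodeGenotypes(g1, E2)
    # class-wise: same pattern, shifted values (E2 = E1 - 1)
    expect_equal(genotypeMatrix(g2), genotypeMatrix(g1) - 1,
                 ignore_attr = FALSE)
    # non-affine target encoding still maps class-by-class
    weird <- recodeGenotypes(g1, Encoding(c(10, -3, 2), "W"))
    w <- genotypeMatrix(weird); v <- genotypeMatrix(g1)
    expect_equal(sum(w == 10), sum(v == 0))
    expect_equal(sum(w == -3), sum(v == 1))
    expect_equal(sum(w == 2), sum(v == 2))
})
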