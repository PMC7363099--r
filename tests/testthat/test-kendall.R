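test_that("tau-a pair counting matches hand-enumerated examples", {
    expect_equal(kendallTau(1:3, 1:3)$tau, 1)
    expect_equal(kendallTau(1:3, 3:1)$tau, -1)
    ct <- kendallTau(c(1, 2, 3, 4), c(2, 1, 4, 3))
    expect_equal(ct$nc, 4)
    expect_equal(ct$nd, 2)
    expect_equal(ct$tau, 1 / 3)
    expect_error(kendallTau(1, 1), "two observations")
    expect_error(kendallTau(c(1, NA), c(1, 2)), "missing")
})

test_that("merge-sort counting equals the brute-force pair counter, ties included", {
    set.seed(123)
    for (i in 1:300) {
        n <- sample(2:200, 1)
        # mix continuous and heavily tied integer data
        x <- if (i %% 2) rnorm(n) else sample(0:5, n, TRUE)
        y <- if (i %% 3) rnorm(n) else sample(0:3, n, TRUE)
        got <- kendallTau(x, y)
        want <- bruteForceCounts(x, y)
        expect_identical(c(got$nc, got$nd), c(want$nc, want$nd))
    }
})

test_that("tau and the z statistic agree with the reference implementation", {
    set.seed(5)
    x <- rnorm(80); y <- rnorm(80)
    expect_equal(kendallTau(x, y)$tau, unname(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
    # tie-corrected z equals cor.test's normal-approximation statistic
    xt <- sample(0:2, 80, TRUE)
    ref <- suppressWarnings(cor.test(xt, y, method = "kendall"))
    got <- kendallTest(xt, y, tieCorrection = TRUE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("null sigma_n and degenerate/small-sample handling follow the model", {
    expect_equal(kendallSigma(20), sqrt(90 / 3420), tolerance = 1e-9)
    res <- kendallTest(rep(1, 30), rnorm(30))
    expect_true(is.na(res$p_value))
    expect_equal(res$flag, "all-tied")
    expect_warning(kendallTest(rnorm(10), rnorm(10)), "n >= 20")
    # tau = 0 gives z = 0 and two-sided p = 1 (balanced half-reversal)
    x <- 1:20
    y <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 11:20)
    res0 <- kendallTest(x, y)
    tau0 <- kendallTau(x, y)$tau
    expect_equal(res0$statistic, tau0 / kendallSigma(20))
    expect_equal(kendallTest(x, x)$p_value, 2 * pnorm(-1 / kendallSigma(20)))
})

test_that("Kendall counts are exactly invariant under positive scaling", {
    set.seed(31)
    x <- rnorm(100); y <- rnorm(100)
    base <- kendallTau(x, y)
    for (a in c(0.5, 2, 10)) {
        sc <- kendallTau(a * x, y)
        expect_identical(c(sc$nc, sc$nd), c(base$nc, base$nd))
    }
    # negative scaling swaps concordant and discordant pairs
    neg <- kendallTau(-x, y)
    expect_identical(neg$nc, base$nd)
    expect_identical(neg$nd, base$nc)
})
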