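#' Kendall's tau (tau-a) with O(n log n) pair counting
#'
#' Counts concordant and discordant observation pairs with a merge-sort
#' inversion count (Knight's algorithm) rather than the naive O(n^2) double
#' loop, and returns the tau-a estimate
#' \deqn{\hat\tau_n = 2 (n_c - n_d) / (n (n-1)).}
#' Pairs tied in either coordinate are counted in neither \eqn{n_c} nor
#' \eqn{n_d}.
#'
#' @param x,y numeric vectors of equal length n >= 2, no missing values.
#' @return A list with `tau`, integer-valued `nc` and `nd`, and the tie pair
#'   counts `tiedX`, `tiedY`, `tiedXY` (pairs tied in x, in y, in both).
#' @examples
#' kendallTau(c(1, 2, 3, 4), c(2, 1, 4, 3))  # nc = 4, nd = 2, tau = 1/3
#' @export
kendallTau <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
        stop("'x' and 'y' must be finite with no missing values")
    cts <- .kendall_counts(x, y)
    n <- length(x)
    cts$tau <- 2 * (cts$nc - cts$nd) / (n * (n - 1))
    cts[c("tau", "nc", "nd", "tiedX", "tiedY", "tiedXY")]
}

#' Null standard deviation of Kendall's tau-a
#'
#' \deqn{\sigma_n = \sqrt{2 (2n + 5) / (9 n (n - 1))},}
#' the standard deviation of \eqn{\hat\tau_n} under independence (no ties);
#' it depends only on the sample size.
#'
#' @param n sample size (>= 2).
#' @return numeric, \eqn{\sigma_n}.
#' @examples
#' kendallSigma(20)   # sqrt(90/3420)
#' @export
kendallSigma <- function(n) {
    if (any(n < 2)) stop("'n' must be at least 2")
    sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
}

# one-row association-result DataFrame shared by all single-SNP tests
.assocResult <- function(method, effect, statistic, p_value, df, n,
                         flag = "ok", encoding = NA_character_,
                         snp_id = NA_character_) {
    DataFrame(snp_id = snp_id, method = method, encoding = encoding,
              effect = effect, statistic = statistic, p_value = p_value,
              df = df, n = n, flag = flag,
              neglog10_p = ifelse(is.na(p_value), NA_real_,
                                  -log10(pmax(p_value, .Machine$double.xmin))))
}

#' Kendall rank-correlation association test for one SNP
#'
#' Tests H0: tau = 0 between a vector of (adjusted) genotype values and a
#' continuous phenotype using the asymptotically normal statistic
#' \eqn{z = \hat\tau_n / \sigma_n} and a two-sided p-value
#' \eqn{2 (1 - \Phi(|z|))}.  Being rank-based, the test makes no
#' distributional assumption on the phenotype and is invariant under any
#' strictly increasing transformation of either variable — in particular
#' under a positive multiplicative genotype re-encoding.
#'
#' @param x numeric genotype values (typically one row of
#'   [adjustedMatrix()]).
#' @param p numeric phenotype values, same length.
#' @param tieCorrection if `TRUE`, replace the no-tie null variance by the
#'   tie-corrected variance of \eqn{S = n_c - n_d} (run-length correction
#'   for ties in either variable).  Default `FALSE`: the plain
#'   \eqn{\sigma_n}, which assumes no ties.
#' @return One-row `DataFrame` with `method`, `effect` (\eqn{\hat\tau_n}),
#'   `statistic` (z), `p_value`, `n`, `flag`.  All-tied input yields NA
#'   with flag `"all-tied"`.
#' @examples
#' set.seed(1)
#' kendallTest(rnorm(50), rnorm(50))
#' @export
kendallTest <- function(x, p, tieCorrection = FALSE) {
    x <- as.numeric(x); p <- as.numeric(p)
    n <- length(x)
    if (length(p) != n) stop("'x' and 'p' must have equal length")
    if (n < 2L) stop("need at least two observations")
    if (n < 20L)
        warning(sprintf(
            "n = %d: the normal approximation for Kendall's test is intended for n >= 20",
            n))
    if (all(x == x[1L]) || all(p == p[1L]))
        return(.assocResult("kendall", NA_real_, NA_real_, NA_real_,
                            NA_real_, n, flag = "all-tied"))
    ct <- kendallTau(x, p)
    if (tieCorrection) {
        S <- ct$nc - ct$nd
        z <- S / sqrt(.kendallTieVariance(x, p, n))
    } else {
        z <- ct$tau / kendallSigma(n)
    }
    .assocResult("kendall", ct$tau, z, 2 * pnorm(-abs(z)), NA_real_, n)
}

# Null variance of S = nc - nd with tie correction (run-length formula)
.kendallTieVariance <- function(x, p, n) {
    tt <- as.numeric(table(x)); uu <- as.numeric(table(p))
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tt * (tt - 1) * (2 * tt + 5))
    vu <- sum(uu * (uu - 1) * (2 * uu + 5))
    (v0 - vt - vu) / 18 +
        sum(tt * (tt - 1) * (tt - 2)) * sum(uu * (uu - 1) * (uu - 2)) /
            (9 * n * (n - 1) * (n - 2)) +
        sum(tt * (tt - 1)) * sum(uu * (uu - 1)) / (2 * n * (n - 1))
}
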