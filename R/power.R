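#' Analytic power of the Pearson slope test
#'
#' For a true standardized slope theta, approximating the t statistic by a
#' normal with unit variance shifted by theta / SE_n, the two-sided power
#' at significance 0.05 is
#' \deqn{B_p(\theta) = 1 - \Phi(c - \theta/SE_n) + \Phi(-c - \theta/SE_n)}
#' with critical value c = 1.96.  SE_n depends on the data, so the curve is
#' evaluated per supplied SNP and averaged (a scan conventionally supplies
#' the SE values of its first 20 SNPs).
#'
#' @param theta numeric grid of alternative effect sizes.
#' @param seValues positive per-SNP standard errors SE_n (e.g.
#'   `effect / statistic` from a Pearson [genomeScan()] table, or via
#'   [scanSE()]).
#' @param alpha significance level.  The critical value is the printed 1.96
#'   when `alpha = 0.05` and \eqn{\Phi^{-1}(1-\alpha/2)} otherwise.
#' @return `data.frame` with `theta`, `power` (mean across SNPs),
#'   `powerSD` (spread across SNPs), `method`, `nSNPs`.
#' @examples
#' powerPearson(c(0, 0.1, 0.2), seValues = c(0.09, 0.1))
#' @export
powerPearson <- function(theta, seValues, alpha = 0.05) {
    seValues <- as.numeric(seValues)
    if (length(seValues) == 0L || anyNA(seValues) || any(seValues <= 0))
        stop("'seValues' must be positive standard errors")
    crit <- if (isTRUE(all.equal(alpha, 0.05))) 1.96 else qnorm(1 - alpha / 2)
    B <- vapply(theta, function(th) {
        b <- 1 - pnorm(crit - th / seValues) + pnorm(-crit - th / seValues)
        c(mean(b), if (length(seValues) > 1L) sd(b) else 0)
    }, numeric(2))
    data.frame(theta = theta, power = B[1L, ], powerSD = B[2L, ],
               method = "pearson", nSNPs = length(seValues))
}

#' Analytic power of the Kendall tau test
#'
#' \deqn{B_k(\theta) = 1 - \Phi(c - \theta/\sigma_n) +
#'       \Phi(-c - \theta/\sigma_n)}
#' with \eqn{\sigma_n} from [kendallSigma()] and c = 1.96 at alpha = 0.05.
#' Because \eqn{\sigma_n} depends only on the sample size, the curve is the
#' same for every SNP and dataset of that size.
#'
#' @param theta numeric grid of alternative tau values.
#' @param n sample size (>= 2).
#' @param alpha significance level (see [powerPearson()]).
#' @return `data.frame` with `theta`, `power`, `method`, `n`.
#' @examples
#' powerKendall(c(0, 0.1, 0.2), n = 300)
#' @export
powerKendall <- function(theta, n, alpha = 0.05) {
    sn <- kendallSigma(n)
    crit <- if (isTRUE(all.equal(alpha, 0.05))) 1.96 else qnorm(1 - alpha / 2)
    data.frame(theta = theta,
               power = 1 - pnorm(crit - theta / sn) +
                       pnorm(-crit - theta / sn),
               method = "kendall", n = n)
}

#' Per-SNP standard errors from a Pearson scan table
#'
#' Convenience extractor: SE_n = effect / statistic for the first `nSNPs`
#' non-flagged rows of a Pearson scan, the plug-in values used by
#' [powerPearson()].
#'
#' @param scan a Pearson [genomeScan()] table.
#' @param nSNPs how many leading SNPs to use (default 20).
#' @return numeric vector of standard errors.
#' @export
scanSE <- function(scan, nSNPs = 20L) {
    if (!all(scan$method == "pearson"))
        stop("'scan' must come from a Pearson genomeScan()")
    ok <- scan$flag == "ok" & !is.na(scan$statistic) & scan$statistic != 0
    se <- (scan$effect / scan$statistic)[ok]
    head(abs(se), nSNPs)
}
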