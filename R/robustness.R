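#' Central moments about a fixed center
#'
#' \eqn{m_r = (1/n) \sum_i (x_i - c)^r}.  The default center is 0, not the
#' sample mean: the robustness criterion for encoding differences is
#' \eqn{\Delta p_i = 0}, so moments of the \eqn{\Delta p} distribution are
#' taken about that fixed reference point.
#'
#' @param x numeric vector, non-empty, no NA.
#' @param r moment order, one of 2, 3, 4.
#' @param center reference point (default 0; pass `mean(x)` for ordinary
#'   central moments).
#' @return numeric, \eqn{m_r}.
#' @examples
#' centralMoment(c(1, 2, 3, 4), 2)  # 7.5 about zero
#' @export
centralMoment <- function(x, r, center = 0) {
    if (length(x) == 0L) stop("'x' must be non-empty")
    if (anyNA(x)) stop("'x' must not contain NA (drop them first)")
    if (!r %in% c(2, 3, 4)) stop("'r' must be 2, 3 or 4")
    mean((x - center)^r)
}

#' Adjusted Fisher-Pearson skewness G1
#'
#' \deqn{G_1 = \frac{\sqrt{n(n-1)}}{n-2}\; \frac{m_3}{m_2^{3/2}},}
#' with moments taken about `center` (default 0, see [centralMoment()]).
#' As a rule of thumb a distribution with \eqn{|G_1| \le 0.5} is
#' approximately symmetric; applied to \eqn{\Delta p}, a G1 near zero means
#' the test has no systematic p-value bias toward either encoding.
#'
#' @param x numeric vector, n >= 3, no NA.
#' @param center reference point (default 0).
#' @return numeric G1, or NA (with a warning) if the second moment is zero.
#' @export
skewnessG1 <- function(x, center = 0) {
    n <- length(x)
    if (n < 3L) stop("skewness G1 needs at least 3 values")
    m2 <- centralMoment(x, 2, center)
    if (m2 == 0) {
        warning("degenerate input: zero second moment, G1 is NA")
        return(NA_real_)
    }
    sqrt(n * (n - 1)) / (n - 2) * centralMoment(x, 3, center) / m2^1.5
}

#' Unbiased excess kurtosis G2
#'
#' \deqn{G_2 = \frac{(n-1)(n+1)}{(n-2)(n-3)} \frac{m_4}{m_2^2}
#'        - \frac{3 (n-1)^2}{(n-2)(n-3)},}
#' with moments about `center` (default 0).  G2 = 0 is mesokurtic (normal
#' reference), G2 < 0 platykurtic, G2 > 0 leptokurtic.  Applied to
#' \eqn{\Delta p}, a larger G2 means p-value differences concentrate at
#' zero — i.e. the test is more robust to the genotype encoding.
#'
#' @param x numeric vector, n >= 4, no NA.
#' @param center reference point (default 0).
#' @return numeric G2, or NA (with a warning) if the second moment is zero.
#' @examples
#' kurtosisG2(c(-1, 1, -1, 1))  # -6 about zero
#' @export
kurtosisG2 <- function(x, center = 0) {
    n <- length(x)
    if (n < 4L) stop("kurtosis G2 needs at least 4 values")
    m2 <- centralMoment(x, 2, center)
    if (m2 == 0) {
        warning("degenerate input: zero second moment, G2 is NA")
        return(NA_real_)
    }
    (n - 1) * (n + 1) / ((n - 2) * (n - 3)) * centralMoment(x, 4, center) / m2^2 -
        3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Moment summary of an encoding p-value-difference distribution
#'
#' Computes skewness G1 and excess kurtosis G2 of the \eqn{\Delta p}
#' distribution about the fixed center 0, together with histogram-ready
#' binned counts (Freedman-Diaconis bins by default).  NA entries (SNPs
#' flagged by the scan) are excluded and counted.
#'
#' @param deltap a `DataFrame` from [deltaP()] or a plain numeric vector.
#' @param breaks histogram break specification passed to [graphics::hist()]
#'   semantics via `hist(plot = FALSE)`; default `"FD"`.
#' @return list with `G1`, `G2`, `nUsed`, `nNA`, `center` (0), `histogram`
#'   (`data.frame` of bin midpoints and counts), `binSpec`, and the
#'   method/encoding metadata when available.
#' @examples
#' set.seed(1)
#' robustnessReport(rnorm(1000, sd = 0.05))[c("G1", "G2", "nUsed")]
#' @export
robustnessReport <- function(deltap, breaks = "FD") {
    meta <- list()
    x <- if (is(deltap, "DataFrame")) {
        meta <- metadata(deltap)
        deltap$delta_p
    } else as.numeric(deltap)
    nNA <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (length(x) < 4L)
        stop("need at least 4 non-NA delta-p values")
    if (all(x == 0)) {
        warning("all delta-p values are zero: moments are degenerate")
        return(c(list(G1 = NA_real_, G2 = NA_real_, nUsed = length(x),
                      nNA = nNA, center = 0, flag = "degenerate",
                      histogram = NULL, binSpec = breaks), meta))
    }
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    c(list(G1 = skewnessG1(x, center = 0),
           G2 = kurtosisG2(x, center = 0),
           nUsed = length(x), nNA = nNA, center = 0, flag = "ok",
           histogram = data.frame(mid = h$mids, count = h$counts),
           binSpec = breaks), meta)
}
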