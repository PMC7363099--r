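#' Pearson slope test for one SNP
#'
#' Fits the simple linear regression p_j = b0 + b * x_j + e_j and tests
#' H0: b = 0 with
#' \deqn{\hat b = cov(x, p) / var(x), \qquad
#'       SE_n = \sqrt{\sum_j (p_j - \hat p_j)^2 /
#'                    \{(n-2) \sum_j (x_j - \bar x)^2\}},}
#' where \eqn{\hat p_j = \bar p + \hat b (x_j - \bar x)}.  The statistic
#' \eqn{\hat b / SE_n} follows t(n-2) under the null; the p-value is
#' two-sided.  The statistic is invariant under a multiplicative genotype
#' re-encoding (up to sign for negative factors) but not, after PCA
#' adjustment with K >= 1, under an additive shift.
#'
#' @param x numeric genotype values (typically one row of
#'   [adjustedMatrix()]); must not be constant.
#' @param p numeric phenotype values, same length, n >= 3.
#' @return One-row `DataFrame` with `method`, `effect` (\eqn{\hat b}),
#'   `statistic` (t), `p_value`, `df` = n - 2, `n`, `flag`.  Constant `x`
#'   (or constant `p`) yields NA with flag `"zero-variance"`.
#' @examples
#' pearsonTest(c(-1, 0, 1, 2), c(0, 1, 1, 2))  # b = 0.6, t = 4.243
#' @export
pearsonTest <- function(x, p) {
    x <- as.numeric(x); p <- as.numeric(p)
    n <- length(x)
    if (length(p) != n) stop("'x' and 'p' must have equal length")
    if (n < 3L) stop("Pearson's test needs at least 3 observations (df = n - 2)")
    xc <- x - mean(x); pc <- p - mean(p)
    Sxx <- sum(xc^2)
    if (Sxx == 0 || sum(pc^2) == 0)
        return(.assocResult("pearson", NA_real_, NA_real_, NA_real_,
                            n - 2, n, flag = "zero-variance"))
    b <- sum(xc * pc) / Sxx
    rss <- sum((pc - b * xc)^2)
    se <- sqrt(rss / ((n - 2) * Sxx))
    tval <- if (se > 0) b / se else sign(b) * Inf
    .assocResult("pearson", b, tval, 2 * pt(-abs(tval), n - 2), n - 2, n)
}

#' Spearman rank-correlation test for one SNP
#'
#' Replaces both variables by their ranks (average ranks for ties) and
#' applies the Pearson t-test to the ranks; the reported effect is
#' Spearman's \eqn{\hat\rho}, the Pearson correlation of the ranks.
#' Provided as a second non-parametric comparator alongside
#' [kendallTest()].
#'
#' @inheritParams pearsonTest
#' @return One-row `DataFrame` as for [pearsonTest()] with `method`
#'   `"spearman"` and `effect` \eqn{\hat\rho}.
#' @examples
#' spearmanTest(c(1, 2, 3, 4), c(2, 1, 4, 3))  # rho = 0.6
#' @export
spearmanTest <- function(x, p) {
    x <- as.numeric(x); p <- as.numeric(p)
    if (length(p) != length(x)) stop("'x' and 'p' must have equal length")
    res <- pearsonTest(rank(x), rank(p))
    res$method <- "spearman"
    if (res$flag == "ok")
        res$effect <- cor(rank(x), rank(p))
    res
}

#' Per-SNP association scan over an adjusted genotype matrix
#'
#' Runs the chosen single-SNP test on every row of an adjusted (or encoded)
#' genotype matrix against one continuous phenotype, reconciling samples by
#' id.  Monomorphic/degenerate SNPs get NA p-values with a flag rather than
#' dropping rows, so scans under different encodings stay positionally
#' comparable.
#'
#' @param adj an [AdjustedGenotypes] (or [EncodedGenotypes]) object.
#' @param pheno named numeric phenotype vector; names are sample ids and
#'   are matched to `colnames(adj)` (order-free).
#' @param method `"kendall"` (default), `"pearson"` or `"spearman"`.
#' @param tieCorrection passed to the Kendall variance (see
#'   [kendallTest()]).
#' @return A `DataFrame` with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `method`, `encoding`, `effect`, `statistic`, `p_value`, `df`, `n`,
#'   `flag`, `neglog10_p` — directly writable as a Manhattan-plot table
#'   (see [writeScan()]).
#' @examples
#' sim <- generateDataset(simulationConfig(m = 20, n = 60, seed = 7))
#' adj <- adjustGenotypes(sim$genotypes, 2)
#' head(genomeScan(adj, sim$phenotype, method = "kendall"))
#' @export
genomeScan <- function(adj, pheno,
                       method = c("kendall", "pearson", "spearman"),
                       tieCorrection = FALSE) {
    method <- match.arg(method)
    gm <- if (is(adj, "AdjustedGenotypes")) adjustedMatrix(adj)
          else if (is(adj, "EncodedGenotypes")) genotypeMatrix(adj)
          else as.matrix(adj)
    if (nrow(gm) == 0L) stop("empty genotype matrix")
    encLab <- if (is(adj, "AdjustedGenotypes") || is(adj, "EncodedGenotypes"))
        encodingLabel(adj) else NA_character_
    p <- .reconcilePhenotype(pheno, colnames(gm))
    n <- length(p)
    if (n < 3L) stop("need at least 3 samples")
    if (method == "kendall" && n < 20L)
        warning(sprintf(
            "n = %d: the normal approximation for Kendall's test is intended for n >= 20", n))

    rd <- if (is(adj, "SummarizedExperiment")) rowData(adj) else NULL
    chrom <- if (!is.null(rd) && "chrom" %in% names(rd)) rd$chrom
             else rep(NA_character_, nrow(gm))
    pos <- if (!is.null(rd) && "pos" %in% names(rd)) rd$pos
           else rep(NA_integer_, nrow(gm))

    if (method == "kendall") {
        out <- .scanKendall(gm, p, tieCorrection)
    } else {
        rm <- gm
        pp <- p
        if (method == "spearman") {
            rm <- t(apply(gm, 1L, rank))
            pp <- rank(p)
        }
        out <- .scanPearson(rm, pp)
        if (method == "spearman") {
            out$df <- ifelse(is.na(out$p_value), NA_real_, n - 2)
            sx <- apply(rm, 1L, sd)
            out$effect <- ifelse(sx > 0 & sd(pp) > 0,
                as.vector((rm - rowMeans(rm)) %*% (pp - mean(pp))) /
                    ((n - 1) * sx * sd(pp)), NA_real_)
        }
    }
    DataFrame(snp_id = rownames(gm), chrom = chrom, pos = pos,
              method = method, encoding = encLab,
              effect = unname(out$effect), statistic = unname(out$statistic),
              p_value = unname(out$p_value), df = unname(out$df), n = n,
              flag = unname(out$flag),
              neglog10_p = ifelse(is.na(out$p_value), NA_real_,
                                  -log10(pmax(out$p_value,
                                              .Machine$double.xmin))))
}

.reconcilePhenotype <- function(pheno, sampleIds) {
    pheno <- unlist(pheno)
    if (is.null(names(pheno)))
        stop("phenotype vector must carry sample ids as names")
    missing <- setdiff(sampleIds, names(pheno))
    if (length(missing))
        stop(sprintf("phenotype missing for sample(s): %s",
                     paste(head(missing, 5), collapse = ", ")))
    p <- as.numeric(pheno[sampleIds])
    if (anyNA(p) || any(!is.finite(p)))
        stop("phenotype values must be finite and non-missing")
    p
}

.scanKendall <- function(gm, p, tieCorrection) {
    m <- nrow(gm); n <- length(p)
    effect <- statistic <- p_value <- rep(NA_real_, m)
    flag <- rep("ok", m)
    sn <- kendallSigma(n)
    pConst <- all(p == p[1L])
    for (i in seq_len(m)) {
        x <- gm[i, ]
        if (pConst || all(x == x[1L])) { flag[i] <- "all-tied"; next }
        ct <- .kendall_counts(x, p)
        tau <- 2 * (ct$nc - ct$nd) / (n * (n - 1))
        z <- if (tieCorrection) (ct$nc - ct$nd) / sqrt(.kendallTieVariance(x, p, n))
             else tau / sn
        effect[i] <- tau; statistic[i] <- z
        p_value[i] <- 2 * pnorm(-abs(z))
    }
    list(effect = effect, statistic = statistic, p_value = p_value,
         df = rep(NA_real_, m), flag = flag)
}

# vectorized per-row simple-regression slope t-test
.scanPearson <- function(gm, p) {
    m <- nrow(gm); n <- length(p)
    xc <- gm - rowMeans(gm)
    pc <- p - mean(p)
    Sxx <- rowSums(xc^2)
    Spp <- sum(pc^2)
    Sxp <- as.vector(xc %*% pc)
    ok <- Sxx > 0 & Spp > 0
    b <- ifelse(ok, Sxp / Sxx, NA_real_)
    rss <- pmax(Spp - b^2 * Sxx, 0)
    se <- sqrt(rss / ((n - 2) * Sxx))
    tval <- ifelse(ok, ifelse(se > 0, b / se, sign(b) * Inf), NA_real_)
    list(effect = b, statistic = tval,
         p_value = ifelse(ok, 2 * pt(-abs(tval), n - 2), NA_real_),
         df = ifelse(ok, n - 2, NA_real_),
         flag = ifelse(ok, "ok", "zero-variance"))
}

#' Per-SNP p-value differences between two encodings
#'
#' The robustness criterion of the package: for each SNP i,
#' \eqn{\Delta p_i = p_{i,E1} - p_{i,E2}}, the signed difference between
#' the p-values obtained under two genotype encodings.  A method is
#' encoding-robust when the \eqn{\Delta p_i} distribution concentrates at
#' zero.  NA p-values (flagged SNPs) propagate to NA differences.
#'
#' @param scan1,scan2 scan tables from [genomeScan()] over the same SNPs in
#'   the same order (same method, different encodings).
#' @return A `DataFrame` with `snp_id` and `delta_p`; `metadata()` records
#'   the method and the two encoding labels.
#' @examples
#' sim <- generateDataset(simulationConfig(m = 30, n = 60, seed = 3))
#' a1 <- adjustGenotypes(sim$genotypes, 2)
#' a2 <- adjustGenotypes(transformAdditive(sim$genotypes, -1, "E2"), 2)
#' dp <- deltaP(genomeScan(a1, sim$phenotype, "pearson"),
#'              genomeScan(a2, sim$phenotype, "pearson"))
#' summary(dp$delta_p)
#' @export
deltaP <- function(scan1, scan2) {
    if (nrow(scan1) != nrow(scan2) ||
        !identical(as.character(scan1$snp_id), as.character(scan2$snp_id)))
        stop("scans must cover the identical SNP set in identical order")
    if (length(unique(scan1$method)) == 1L &&
        length(unique(scan2$method)) == 1L &&
        scan1$method[1L] != scan2$method[1L])
        stop("scans were produced by different test methods")
    out <- DataFrame(snp_id = scan1$snp_id,
                     delta_p = scan1$p_value - scan2$p_value)
    metadata(out) <- list(method = as.character(scan1$method[1L]),
                          encoding1 = as.character(scan1$encoding[1L]),
                          encoding2 = as.character(scan2$encoding[1L]))
    out
}
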