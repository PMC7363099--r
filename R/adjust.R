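#' Sample-by-sample covariance of an encoded genotype matrix
#'
#' Forms the n-by-n covariance (default) or correlation matrix between
#' sample columns, computed across the m SNPs with per-column centering
#' (`stats::cov` on the m-by-n matrix).  Its eigenvectors define the axes of
#' variation used for stratification correction.  Because column means
#' absorb any additive shift and covariance is bilinear, the eigenvectors
#' are invariant under both encoding transformations (a multiplicative
#' factor only scales the eigenvalues).
#'
#' @param g an [EncodedGenotypes] object (or plain m-by-n numeric matrix).
#' @param type `"covariance"` (default) or `"correlation"`.
#' @param standardizeRows if `TRUE`, center each SNP row and scale it to
#'   unit variance before forming the matrix (EIGENSTRAT-style per-SNP
#'   standardization; constant rows are left as zeros).  Default `FALSE`:
#'   the adjustment operates on raw encoded values.
#' @return n-by-n symmetric numeric matrix.
#' @export
sampleCovariance <- function(g, type = c("covariance", "correlation"),
                             standardizeRows = FALSE) {
    type <- match.arg(type)
    gm <- if (is(g, "EncodedGenotypes")) genotypeMatrix(g) else as.matrix(g)
    if (nrow(gm) < 2L)
        stop("at least 2 SNPs are required to form a sample covariance matrix")
    if (standardizeRows) {
        mu <- rowMeans(gm)
        s <- apply(gm, 1L, sd)
        s[s == 0] <- Inf   # constant rows contribute nothing
        gm <- (gm - mu) / s
    }
    C <- if (type == "covariance") cov(gm) else {
        # guard correlation against zero-variance sample columns
        v <- apply(gm, 2L, sd)
        if (any(v == 0))
            stop("correlation matrix undefined: some sample column has zero variance")
        cor(gm)
    }
    (C + t(C)) / 2
}

#' Leading axes of variation of a covariance matrix
#'
#' Computes the top-K eigenvectors of a symmetric matrix, ordered by
#' non-increasing eigenvalue (ties keep the eigensolver's original order).
#' The sign of each eigenvector is fixed by making its largest-magnitude
#' component positive; downstream computations use only the projector VV',
#' which is sign-invariant.
#'
#' @param C n-by-n symmetric matrix (from [sampleCovariance()]).
#' @param K number of axes to retain, between 0 and n.
#' @return An [EigenBasis].
#' @export
axesOfVariation <- function(C, K) {
    C <- as.matrix(C)
    n <- ncol(C)
    if (nrow(C) != n || max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
        stop("'C' must be a symmetric square matrix")
    K <- as.integer(K)
    if (is.na(K) || K < 0L || K > n)
        stop(sprintf("'K' must be an integer in [0, %d]", n))
    if (K == 0L)
        return(new("EigenBasis", vectors = matrix(numeric(0), n, 0L),
                   eigenvalues = numeric(0)))
    eig <- eigen(C, symmetric = TRUE)
    ord <- order(-eig$values, seq_len(n))   # stable: value desc, index asc
    V <- eig$vectors[, ord[seq_len(K)], drop = FALSE]
    for (k in seq_len(K)) {
        top <- which.max(abs(V[, k]))
        if (V[top, k] < 0) V[, k] <- -V[, k]
    }
    new("EigenBasis", vectors = V, eigenvalues = eig$values[ord[seq_len(K)]])
}

#' PCA-based genotype adjustment (stratification correction)
#'
#' Residualizes each SNP row against the top-K axes of variation: with V the
#' n-by-K matrix of eigenvectors, the adjusted genotype is
#' \deqn{g^{adj}_{ij} = g_{ij} - \sum_{\ell} (VV')_{j\ell}\, g_{i\ell},}
#' i.e. row-wise right-multiplication by the residual projector (I - VV').
#' The per-sample remainder
#' \deqn{\Delta^K_j = 1 - \sum_{\ell} (VV')_{j\ell}}
#' is returned alongside; under an additive encoding shift beta the adjusted
#' values move by beta * Delta_j^K (not by beta), which is the source of the
#' encoding dependence of value-based tests.  Boundary cases: K = 0 leaves
#' the matrix untouched with Delta = 1; K = n zeroes it with Delta = 0.
#'
#' Monomorphic (constant) SNP rows pass through the adjustment; they are
#' flagged in `rowData(result)$monomorphic` and downstream tests report NA
#' for them.
#'
#' Delta_j^K is expected in \[0, 1\]; values outside that range (possible in
#' principle for unusual eigenbases) are reported via a message, never
#' clamped.
#'
#' @param g an [EncodedGenotypes], an [AdjustedGenotypes] (re-adjustment,
#'   e.g. for idempotence checks), or a plain numeric matrix.
#' @param basis an [EigenBasis], or a single integer K, in which case the
#'   basis is computed from `g` via [sampleCovariance()] and
#'   [axesOfVariation()].
#' @return An [AdjustedGenotypes]; `deltaK(x)` retrieves the remainder.
#' @examples
#' e1 <- Encoding(c(0, 1, 2), "E1")
#' set.seed(1)
#' g <- EncodedGenotypes(matrix(sample(0:2, 60, TRUE), 10), e1)
#' adj <- adjustGenotypes(g, 2)
#' deltaK(adj)
#' @export
adjustGenotypes <- function(g, basis) {
    gm <- if (is(g, "EncodedGenotypes")) genotypeMatrix(g)
          else if (is(g, "AdjustedGenotypes")) adjustedMatrix(g)
          else as.matrix(g)
    encLab <- if (is(g, "EncodedGenotypes") || is(g, "AdjustedGenotypes"))
        encodingLabel(g) else "unlabeled"
    n <- ncol(gm)
    if (is.numeric(basis) && length(basis) == 1L)
        basis <- axesOfVariation(sampleCovariance(gm), basis)
    stopifnot(is(basis, "EigenBasis"))
    V <- basisVectors(basis)
    if (nrow(V) != n)
        stop(sprintf("basis is over %d samples but genotype matrix has %d",
                     nrow(V), n))
    K <- ncol(V)
    if (K == 0L) {
        adj <- gm
        delta <- rep(1, n)
    } else {
        P <- tcrossprod(V)
        adj <- gm - gm %*% P
        delta <- 1 - rowSums(P)
    }
    if (any(delta < -1e-8 | delta > 1 + 1e-8))
        message(sprintf(
            "Delta^K outside [0, 1] for %d sample(s) (range [%.4g, %.4g]); reported as computed",
            sum(delta < -1e-8 | delta > 1 + 1e-8), min(delta), max(delta)))
    mono <- apply(gm, 1L, function(r) all(r == r[1L]))
    if (is(g, "SummarizedExperiment")) {
        rd <- rowData(g)
        rd$monomorphic <- mono
    } else {
        rd <- DataFrame(monomorphic = mono, row.names = rownames(gm))
    }
    cd <- DataFrame(deltaK = delta, row.names = colnames(gm))
    new("AdjustedGenotypes",
        SummarizedExperiment(assays = SimpleList(adjusted = adj),
                             rowData = rd, colData = cd),
        K = K, encodingLabel = encLab, eigenvalues = eigenValues(basis))
}

#' Fraction of sample pairs whose adjusted-genotype order survives an
#' encoding change
#'
#' For every SNP i and unordered sample pair (j, k), compares the sign of
#' the adjusted-genotype difference delta_jk = g^adj_ij - g^adj_ik between
#' two adjusted matrices (typically the same data adjusted under two
#' encodings related by an additive shift).  Pairs with delta exactly zero
#' in the reference matrix are excluded from numerator and denominator.
#' A ratio near 1 means the ranking — hence Kendall's tau — is essentially
#' unchanged by the encoding.
#'
#' @param adj1 reference [AdjustedGenotypes] (or numeric matrix).
#' @param adj2 comparison [AdjustedGenotypes] (or numeric matrix), same
#'   shape.
#' @return A list with `ratio` (overall preserved fraction), `perSNP`
#'   (named numeric vector of per-SNP fractions, NA where a SNP has no
#'   nonzero pairs), `nPairs` (pairs counted) and `nPreserved`.
#' @examples
#' rankPreservationRatio(matrix(c(1, 2, 3), 1), matrix(c(1, 3, 2), 1))$ratio
#' @export
rankPreservationRatio <- function(adj1, adj2) {
    a1 <- if (is(adj1, "AdjustedGenotypes")) adjustedMatrix(adj1) else as.matrix(adj1)
    a2 <- if (is(adj2, "AdjustedGenotypes")) adjustedMatrix(adj2) else as.matrix(adj2)
    if (!all(dim(a1) == dim(a2)))
        stop("adjusted matrices must have identical dimensions")
    n <- ncol(a1)
    if (n < 2L) stop("need at least two samples to form pairs")
    jj <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    kk <- unlist(lapply(seq_len(n - 1L), function(j) (j + 1L):n),
                 use.names = FALSE)
    npres <- nden <- numeric(nrow(a1))
    for (i in seq_len(nrow(a1))) {
        d1 <- a1[i, jj] - a1[i, kk]
        nz <- d1 != 0
        d2 <- a2[i, jj] - a2[i, kk]
        npres[i] <- sum(sign(d1[nz]) == sign(d2[nz]))
        nden[i] <- sum(nz)
    }
    if (sum(nden) == 0)
        stop("degenerate input: all pairwise differences are zero")
    list(ratio = sum(npres) / sum(nden),
         perSNP = setNames(ifelse(nden > 0, npres / nden, NA_real_),
                           rownames(a1)),
         nPairs = sum(nden), nPreserved = sum(npres))
}
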