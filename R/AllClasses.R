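#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata `metadata<-` SimpleList
#' @importFrom stats cov cor pt pnorm qnorm rnorm var sd setNames complete.cases
#' @importFrom utils read.table write.table head packageVersion
#' @importFrom graphics hist
#' @useDynLib tauGWAS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

GENOTYPE_CLASSES <- c("AA", "Aa", "aa")

#' Numeric encoding of the three bi-allelic genotype classes
#'
#' An `Encoding` assigns three pairwise-distinct real numbers to the
#' homozygous-major (`AA`), heterozygous (`Aa`) and homozygous-minor (`aa`)
#' genotype classes.  The two encodings in common use are the minor-allele
#' count `{0, 1, 2}` and the zero-dominance convention `{-1, 0, 1}`; any
#' triple of distinct values is a valid encoding, and any two encodings of
#' the same data are related by a multiplicative factor, an additive shift,
#' or a combination of the two.
#'
#' @slot values numeric(3), the values assigned to (AA, Aa, aa).
#' @slot label character(1), a short display name such as `"E1"`.
#' @export
setClass("Encoding",
    representation(values = "numeric", label = "character"),
    validity = function(object) {
        if (length(object@values) != 3L)
            return("'values' must have length 3 (AA, Aa, aa)")
        if (anyNA(object@values) || any(!is.finite(object@values)))
            return("'values' must be finite and non-missing")
        if (anyDuplicated(object@values))
            return("encoding values must be pairwise distinct (an encoding must distinguish genotypes)")
        if (length(object@label) != 1L)
            return("'label' must be a single string")
        TRUE
    })

#' @param values numeric(3), values for (AA, Aa, aa).
#' @param label single string naming the encoding.
#' @return An `Encoding` object.
#' @examples
#' Encoding(c(0, 1, 2), "E1")
#' Encoding(c(-1, 0, 1), "E2")
#' @rdname Encoding-class
#' @export
Encoding <- function(values, label = paste(values, collapse = ",")) {
    new("Encoding", values = as.numeric(values), label = as.character(label))
}

setMethod("show", "Encoding", function(object) {
    cat(sprintf("Encoding \"%s\": AA=%g, Aa=%g, aa=%g\n", object@label,
        object@values[1L], object@values[2L], object@values[3L]))
})

#' Top-K axes of variation of the sample covariance matrix
#'
#' Holds the leading `K` eigenvectors (the "axes of variation") of the
#' n-by-n sample covariance matrix of an encoded genotype matrix, with their
#' eigenvalues in non-increasing order.  `K = 0` (empty basis) and `K = n`
#' (complete basis) are both valid.
#'
#' @slot vectors n-by-K matrix of orthonormal eigenvector columns.
#' @slot eigenvalues numeric(K), sorted non-increasing.
#' @export
setClass("EigenBasis",
    representation(vectors = "matrix", eigenvalues = "numeric"),
    validity = function(object) {
        K <- ncol(object@vectors)
        if (length(object@eigenvalues) != K)
            return("number of eigenvalues must equal number of eigenvector columns")
        if (K > 0L && is.unsorted(rev(object@eigenvalues)))
            return("eigenvalues must be sorted in non-increasing order")
        if (K > 0L) {
            gram <- crossprod(object@vectors)
            if (max(abs(gram - diag(K))) > 1e-8)
                return("eigenvector columns must be orthonormal")
        }
        TRUE
    })

setMethod("show", "EigenBasis", function(object) {
    cat(sprintf("EigenBasis: %d axes of variation over %d samples\n",
        ncol(object@vectors), nrow(object@vectors)))
    if (length(object@eigenvalues))
        cat("  eigenvalues:", paste(signif(head(object@eigenvalues, 5), 4),
            collapse = ", "),
            if (length(object@eigenvalues) > 5) "..." else "", "\n")
})

#' Categorical genotype calls for m SNPs across n samples
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass whose single assay
#' `"calls"` is an m-by-n character matrix with entries `"AA"`, `"Aa"`,
#' `"aa"`, or `NA` for missing.  Optional `chrom`/`pos` columns (1-based
#' positions) live in `rowData`.
#'
#' @export
setClass("GenotypeCalls", contains = "SummarizedExperiment",
    validity = function(object) {
        if (!"calls" %in% names(assays(object)))
            return("assay 'calls' is required")
        x <- assay(object, "calls")
        if (!is.character(x))
            return("assay 'calls' must be a character matrix")
        bad <- !is.na(x) & !(x %in% GENOTYPE_CLASSES)
        if (any(bad))
            return(sprintf("invalid genotype token(s): %s",
                paste(unique(x[bad]), collapse = ", ")))
        if (anyDuplicated(rownames(object)))
            return("SNP ids must be unique")
        if (anyDuplicated(colnames(object)))
            return("sample ids must be unique")
        TRUE
    })

#' Construct a GenotypeCalls object
#'
#' @param calls m-by-n character matrix of `"AA"`/`"Aa"`/`"aa"`/`NA` calls.
#' @param snpIds,sampleIds optional identifier vectors; default to the
#'   dimnames of `calls` or generated `snp1..m` / `s1..n`.
#' @param chrom,pos optional per-SNP chromosome labels and 1-based positions.
#' @return A `GenotypeCalls` object.
#' @examples
#' calls <- matrix(c("AA", "Aa", "aa", "AA"), nrow = 2,
#'                 dimnames = list(c("snp1", "snp2"), c("s1", "s2")))
#' GenotypeCalls(calls)
#' @export
GenotypeCalls <- function(calls, snpIds = rownames(calls),
                          sampleIds = colnames(calls),
                          chrom = NULL, pos = NULL) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "character"
    if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(nrow(calls)))
    if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(ncol(calls)))
    dimnames(calls) <- list(snpIds, sampleIds)
    rd <- DataFrame(row.names = snpIds)
    if (!is.null(chrom)) rd$chrom <- chrom
    if (!is.null(pos)) rd$pos <- as.integer(pos)
    new("GenotypeCalls", SummarizedExperiment(
        assays = SimpleList(calls = calls), rowData = rd))
}

setMethod("show", "GenotypeCalls", function(object) {
    x <- assay(object, "calls")
    cat(sprintf("GenotypeCalls: %d SNPs x %d samples (%d missing calls)\n",
        nrow(object), ncol(object), sum(is.na(x))))
})

#' Numerically encoded genotype matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass whose assay
#' `"genotypes"` is the m-by-n numeric matrix g_ij obtained by applying an
#' [Encoding] (possibly followed by multiplicative/additive transformations)
#' to categorical calls.
#'
#' @slot encoding the [Encoding] in force; its three values are the only
#'   values that occur in the matrix.
#' @export
setClass("EncodedGenotypes", contains = "SummarizedExperiment",
    representation(encoding = "Encoding"),
    validity = function(object) {
        if (!"genotypes" %in% names(assays(object)))
            return("assay 'genotypes' is required")
        g <- assay(object, "genotypes")
        if (!is.numeric(g))
            return("assay 'genotypes' must be numeric")
        if (anyNA(g))
            return("encoded genotypes must not contain missing values")
        if (!all(g %in% object@encoding@values))
            return("every entry must equal one of the three encoding values")
        TRUE
    })

#' Construct an EncodedGenotypes object
#'
#' @param g m-by-n numeric matrix whose entries are encoding values.
#' @param encoding the [Encoding] the entries follow.
#' @param snpIds,sampleIds optional identifiers (default: dimnames of `g`).
#' @param rowData optional `DataFrame` of per-SNP metadata (chrom/pos).
#' @return An `EncodedGenotypes` object.
#' @export
EncodedGenotypes <- function(g, encoding, snpIds = rownames(g),
                             sampleIds = colnames(g), rowData = NULL) {
    g <- as.matrix(g)
    if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(nrow(g)))
    if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(ncol(g)))
    dimnames(g) <- list(snpIds, sampleIds)
    if (is.null(rowData)) rowData <- DataFrame(row.names = snpIds)
    new("EncodedGenotypes", SummarizedExperiment(
        assays = SimpleList(genotypes = g), rowData = rowData),
        encoding = encoding)
}

setMethod("show", "EncodedGenotypes", function(object) {
    cat(sprintf("EncodedGenotypes: %d SNPs x %d samples, encoding \"%s\" {%s}\n",
        nrow(object), ncol(object), object@encoding@label,
        paste(object@encoding@values, collapse = ", ")))
})

#' PCA-adjusted (residualized) genotype matrix
#'
#' Encoded genotypes after removal of the top-K axes of variation: each SNP
#' row is right-multiplied by the residual projector (I - VV'), which turns
#' the ordinal values into continuous ones.  The per-sample remainder
#' Delta_j^K = 1 - sum_l (VV')_{jl} — which governs how an additive encoding
#' shift beta survives adjustment (shift becomes beta * Delta_j^K) — is kept
#' in `colData(x)$deltaK`.
#'
#' @slot K integer, number of axes removed.
#' @slot encodingLabel label of the encoding the source matrix carried.
#' @slot eigenvalues eigenvalues of the K axes used.
#' @export
setClass("AdjustedGenotypes", contains = "SummarizedExperiment",
    representation(K = "integer", encodingLabel = "character",
                   eigenvalues = "numeric"),
    validity = function(object) {
        if (!"adjusted" %in% names(assays(object)))
            return("assay 'adjusted' is required")
        if (!"deltaK" %in% names(colData(object)))
            return("colData column 'deltaK' is required")
        if (object@K < 0L || object@K > ncol(object))
            return("K must lie in [0, n]")
        TRUE
    })

setMethod("show", "AdjustedGenotypes", function(object) {
    cat(sprintf(
        "AdjustedGenotypes: %d SNPs x %d samples, K=%d axes removed (encoding \"%s\")\n",
        nrow(object), ncol(object), object@K, object@encodingLabel))
    dk <- colData(object)$deltaK
    cat(sprintf("  Delta^K remainder: mean %.4f, range [%.4f, %.4f]\n",
        mean(dk), min(dk), max(dk)))
})
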