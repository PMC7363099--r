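#' Encode categorical genotype calls numerically
#'
#' Maps the genotype classes AA / Aa / aa to the three values of an
#' [Encoding].  The calls must be complete: any missing entry is an error
#' naming the offending SNP and sample (use [dropMissing()] first).
#'
#' @param calls a [GenotypeCalls] object with no missing entries.
#' @param encoding an [Encoding].
#' @return An [EncodedGenotypes] object of the same shape, carrying over any
#'   `rowData` (chrom/pos).
#' @examples
#' calls <- GenotypeCalls(matrix(c("AA", "Aa", "aa", "AA"), nrow = 2,
#'     dimnames = list(c("snp1", "snp2"), c("s1", "s2"))))
#' encodeGenotypes(calls, Encoding(c(0, 1, 2), "E1"))
#' @export
encodeGenotypes <- function(calls, encoding) {
    stopifnot(is(calls, "GenotypeCalls"), is(encoding, "Encoding"))
    x <- callMatrix(calls)
    if (anyNA(x)) {
        idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "missing genotype call at SNP '%s', sample '%s'; run dropMissing() first",
            rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
    }
    g <- matrix(encoding@values[match(x, GENOTYPE_CLASSES)],
                nrow = nrow(x), dimnames = dimnames(x))
    EncodedGenotypes(g, encoding, rowData = rowData(calls))
}

#' Multiplicative and additive encoding transformations
#'
#' Any two encodings of the same genotype data are related by g' = alpha * g
#' and/or g' = g + beta.  `transformMultiplicative` rescales an encoded
#' matrix by a nonzero factor alpha; `transformAdditive` shifts it by beta.
#' Both return a new [EncodedGenotypes] whose [Encoding] values are
#' transformed accordingly (so the class invariant — every entry is an
#' encoding value — is preserved).
#'
#' @param g an [EncodedGenotypes] object.
#' @param alpha nonzero multiplicative factor (alpha = 0 would collapse the
#'   three genotype classes and is rejected).
#' @param beta additive shift.
#' @param label label for the transformed encoding; a default is derived
#'   from the input label.
#' @return An [EncodedGenotypes] with transformed values.
#' @examples
#' e2 <- Encoding(c(-1, 0, 1), "E2")
#' g <- EncodedGenotypes(matrix(c(-1, 0, 1, 1), 2), e2)
#' transformAdditive(g, 1)   # now on {0, 1, 2}
#' @export
transformMultiplicative <- function(g, alpha,
        label = sprintf("%g*%s", alpha, encodingLabel(g))) {
    stopifnot(is(g, "EncodedGenotypes"))
    if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
        alpha == 0)
        stop("'alpha' must be a single nonzero finite number")
    enc <- Encoding(alpha * encodingValues(g), label)
    EncodedGenotypes(alpha * genotypeMatrix(g), enc, rowData = rowData(g))
}

#' Re-encode a genotype matrix under a different encoding
#'
#' Maps each entry by its genotype class: the value the current encoding
#' assigns to AA/Aa/aa is replaced by the value the target encoding
#' assigns.  Unlike [transformMultiplicative()]/[transformAdditive()], the
#' two encodings need not be affinely related.
#'
#' @param g an [EncodedGenotypes] object.
#' @param encoding target [Encoding].
#' @return An [EncodedGenotypes] under `encoding`.
#' @export
recodeGenotypes <- function(g, encoding) {
    stopifnot(is(g, "EncodedGenotypes"), is(encoding, "Encoding"))
    gm <- genotypeMatrix(g)
    idx <- match(gm, encodingValues(g))
    out <- matrix(encoding@values[idx], nrow = nrow(gm),
                  dimnames = dimnames(gm))
    EncodedGenotypes(out, encoding, rowData = rowData(g))
}

#' @rdname transformMultiplicative
#' @export
transformAdditive <- function(g, beta,
        label = sprintf("%s%+g", encodingLabel(g), beta)) {
    stopifnot(is(g, "EncodedGenotypes"))
    if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
        stop("'beta' must be a single finite number")
    enc <- Encoding(encodingValues(g) + beta, label)
    EncodedGenotypes(genotypeMatrix(g) + beta, enc, rowData = rowData(g))
}
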