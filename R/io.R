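#' Read a genotype matrix from TSV or VCF
#'
#' TSV layout: a header line, first column `snp_id`, optional `chrom` and
#' `pos` columns, then one column per sample.  Entries may be minor-allele
#' counts `{0,1,2}`, the `{-1,0,1}` convention (detected by the presence of
#' -1), or two-letter calls `AA`/`Aa`/`aa`; empty fields, `NA` and `./.`
#' are missing.  VCF input uses the GT field only: `0/0` is homozygous
#' major, `0/1` (either phasing) heterozygous, `1/1` homozygous minor;
#' multi-allelic or non-diploid records are rejected with the offending
#' record named.  Positions stay 1-based.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`; default guessed from the extension.
#' @return A [GenotypeCalls] object.
#' @export
readGenotypes <- function(path, format = c("auto", "tsv", "vcf")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
            "vcf" else "tsv"
    if (format == "vcf") .readGenotypesVcf(path) else .readGenotypesTsv(path)
}

.readGenotypesTsv <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    tab <- read.table(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE,
                      na.strings = c("NA", "", "./."))
    if (!ncol(tab) >= 2L)
        stop(sprintf("%s: expected snp_id plus at least one sample column", path))
    meta <- intersect(c("chrom", "pos"), names(tab))
    idCol <- names(tab)[1L]
    sampleCols <- setdiff(names(tab), c(idCol, meta))
    raw <- as.matrix(tab[, sampleCols, drop = FALSE])
    tokens <- unique(raw[!is.na(raw)])
    calls <- if (all(tokens %in% GENOTYPE_CLASSES)) {
        raw
    } else if (all(tokens %in% c("-1", "0", "1", "2"))) {
        off <- if (any(tokens == "-1")) 2L else 1L  # {-1,0,1} vs {0,1,2}
        cls <- matrix(GENOTYPE_CLASSES[as.integer(raw) + off],
                      nrow = nrow(raw))
        cls[is.na(raw)] <- NA_character_
        cls
    } else {
        bad <- setdiff(tokens, c(GENOTYPE_CLASSES, "-1", "0", "1", "2"))
        firstBad <- which(raw %in% bad, arr.ind = FALSE)[1L]
        stop(sprintf("%s: unknown genotype token '%s' (line %d)",
                     path, raw[firstBad],
                     (firstBad - 1L) %% nrow(raw) + 2L))
    }
    GenotypeCalls(calls, snpIds = tab[[idCol]], sampleIds = sampleCols,
                  chrom = if ("chrom" %in% meta) tab$chrom else NULL,
                  pos = if ("pos" %in% meta) as.integer(tab$pos) else NULL)
}

.readGenotypesVcf <- function(path) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix)))   # single-record VCFs drop to a vector
        fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi))
        stop(sprintf("multi-allelic record(s) not supported: %s at %s:%s",
                     fix[which(multi)[1L], "ID"],
                     fix[which(multi)[1L], "CHROM"],
                     fix[which(multi)[1L], "POS"]))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    core <- gsub("\\|", "/", gt)
    map <- c("0/0" = "AA", "0/1" = "Aa", "1/0" = "Aa", "1/1" = "aa",
             "./." = NA_character_, "." = NA_character_)
    known <- is.na(core) | core %in% names(map)
    if (!all(known)) {
        idx <- which(!known, arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "unsupported GT '%s' (non-diploid or allele > 1) at record %s, sample %s",
            core[idx[1L], idx[2L]], rownames(core)[idx[1L]],
            colnames(core)[idx[2L]]))
    }
    calls <- matrix(map[core], nrow = nrow(core), dimnames = dimnames(core))
    calls[is.na(core)] <- NA_character_
    ids <- fix[, "ID"]
    blank <- is.na(ids) | ids == "."
    ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
    GenotypeCalls(calls, snpIds = ids, sampleIds = colnames(gt),
                  chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
}

#' Read a phenotype table
#'
#' Tab-separated: header, first column sample id, subsequent columns
#' numeric traits.  Samples are identified by id, never by position.
#'
#' @param path input file.
#' @return `data.frame` with sample ids as row names, one column per trait.
#' @export
readPhenotypes <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      na.strings = c("NA", ""))
    if (anyDuplicated(tab[[1L]])) stop("duplicate sample ids in phenotype table")
    rownames(tab) <- as.character(tab[[1L]])
    tab[[1L]] <- NULL
    for (j in seq_along(tab)) tab[[j]] <- as.numeric(tab[[j]])
    tab
}

#' Extract one trait as a named phenotype vector
#'
#' @param phenos `data.frame` from [readPhenotypes()].
#' @param trait trait (column) name.
#' @return named numeric vector keyed by sample id.
#' @export
phenotypeVector <- function(phenos, trait) {
    if (!trait %in% names(phenos))
        stop(sprintf("trait '%s' not found; available: %s", trait,
                     paste(names(phenos), collapse = ", ")))
    setNames(phenos[[trait]], rownames(phenos))
}

#' Write genotype calls or encoded genotypes as TSV
#'
#' Inverse of the TSV reader: first column `snp_id`, then `chrom`/`pos` if
#' present, then sample columns (`AA`/`Aa`/`aa` for calls, numeric values
#' for encoded matrices).
#'
#' @param x a [GenotypeCalls] or [EncodedGenotypes] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path) {
    mat <- if (is(x, "GenotypeCalls")) callMatrix(x) else genotypeMatrix(x)
    out <- data.frame(snp_id = rownames(mat), check.names = FALSE)
    rd <- rowData(x)
    if ("chrom" %in% names(rd)) out$chrom <- rd$chrom
    if ("pos" %in% names(rd)) out$pos <- rd$pos
    out <- cbind(out, as.data.frame(mat, check.names = FALSE))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a scan (or any DataFrame) as a plot-ready TSV
#'
#' @param x a `DataFrame`/`data.frame`, e.g. from [genomeScan()] or
#'   [deltaP()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScan <- function(x, path) {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Write adjusted genotypes with a JSON metadata sidecar
#'
#' Emits `<prefix>.adjusted.tsv` (matrix, full double precision) and
#' `<prefix>.adjusted.json` (K, encoding label, eigenvalues, the Delta^K
#' vector).
#'
#' @param adj an [AdjustedGenotypes] object.
#' @param prefix output path prefix.
#' @return character(2) of the written paths, invisibly.
#' @export
writeAdjusted <- function(adj, prefix) {
    stopifnot(is(adj, "AdjustedGenotypes"))
    mat <- adjustedMatrix(adj)
    tsv <- paste0(prefix, ".adjusted.tsv")
    out <- cbind(data.frame(snp_id = rownames(mat)),
                 as.data.frame(mat, check.names = FALSE))
    write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    side <- paste0(prefix, ".adjusted.json")
    jsonlite::write_json(
        list(K = numAxes(adj), encoding = encodingLabel(adj),
             eigenvalues = eigenValues(adj), deltaK = as.list(deltaK(adj))),
        side, auto_unbox = TRUE, digits = NA)
    invisible(c(tsv, side))
}

#' Remove SNPs and samples with missing data
#'
#' Dataset hygiene before encoding: iteratively (to a fixpoint) removes
#' every SNP row containing a missing genotype call, then every sample with
#' a missing value in the selected trait(s).  Removal counts are reported
#' via `message()`; an empty result is an error.
#'
#' @param calls a [GenotypeCalls] object.
#' @param phenos optional phenotype `data.frame` ([readPhenotypes()]) or
#'   named vector.
#' @param trait optional trait name(s) to screen; default: all columns.
#' @return list with the filtered `calls` and (if supplied) `phenos`
#'   restricted to the surviving samples.
#' @export
dropMissing <- function(calls, phenos = NULL, trait = NULL) {
    stopifnot(is(calls, "GenotypeCalls"))
    mat <- callMatrix(calls)
    ph <- NULL
    if (!is.null(phenos)) {
        ph <- if (is.null(dim(phenos)))
            data.frame(trait = phenos, row.names = names(phenos))
        else phenos
        if (!is.null(trait)) ph <- ph[, trait, drop = FALSE]
        keep <- intersect(colnames(mat), rownames(ph))
        mat <- mat[, keep, drop = FALSE]
        ph <- ph[keep, , drop = FALSE]
    }
    m0 <- nrow(mat); n0 <- ncol(mat)
    repeat {
        snpKeep <- rowSums(is.na(mat)) == 0L
        mat <- mat[snpKeep, , drop = FALSE]
        sampleKeep <- if (is.null(ph)) rep(TRUE, ncol(mat))
            else rowSums(is.na(ph[colnames(mat), , drop = FALSE])) == 0L
        if (all(snpKeep) && all(sampleKeep)) break
        mat <- mat[, sampleKeep, drop = FALSE]
        if (!is.null(ph)) ph <- ph[colnames(mat), , drop = FALSE]
    }
    if (nrow(mat) == 0L || ncol(mat) == 0L)
        stop("no SNPs/samples survive missing-data filtering; inspect the input")
    message(sprintf("dropMissing: kept %d/%d SNPs and %d/%d samples",
                    nrow(mat), m0, ncol(mat), n0))
    rd <- rowData(calls)[rownames(mat), , drop = FALSE]
    out <- GenotypeCalls(mat,
        chrom = if ("chrom" %in% names(rd)) rd$chrom else NULL,
        pos = if ("pos" %in% names(rd)) rd$pos else NULL)
    if (is.null(phenos)) list(calls = out) else list(calls = out, phenos = ph)
}
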