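#' Configuration for the genotype-phenotype simulator
#'
#' Bundles and validates the simulator parameters: a single causal SNP is
#' drawn under Hardy-Weinberg equilibrium at minor allele frequency `q`,
#' the phenotype is generated from it by a variance-partition model in
#' which a fraction `pi` of unit phenotype variance is genetic, and every
#' further SNP is a partially shuffled copy of the causal SNP with
#' shuffling rate `kappa` — so the whole panel carries the same, tunable
#' degree of true association.
#'
#' @param m number of SNPs (>= 1).
#' @param n sample size (>= 2).
#' @param q minor allele frequency, in (0, 0.5].
#' @param pi rate of variation attributable to the causal genotype, in
#'   \[0, 1\].
#' @param kappa shuffling rate in \[0, 1\]: the fraction of each copy's n
#'   genotypes that is randomly permuted (`rho` is an accepted alias).
#' @param encoding [Encoding] for the emitted genotype matrix.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @param nChrom fictitious chromosome count used to block SNPs for
#'   Manhattan-style display (default 12).
#' @param rho alias for `kappa`.
#' @return A validated `SimulationConfig` list.
#' @examples
#' simulationConfig(m = 100, n = 300, q = 0.25, pi = 0.05, kappa = 0.5,
#'                  seed = 1)
#' @export
simulationConfig <- function(m, n, q = 0.25, pi = 0.05, kappa = 0.5,
                             encoding = Encoding(c(0, 1, 2), "E1"),
                             seed = 1L, nChrom = 12L, rho = NULL) {
    if (!is.null(rho)) kappa <- rho
    m <- as.integer(m); n <- as.integer(n)
    stopifnot(m >= 1L, n >= 2L)
    if (!(q > 0 && q <= 0.5))
        stop("'q' (minor allele frequency) must lie in (0, 0.5]")
    if (!(pi >= 0 && pi <= 1)) stop("'pi' must lie in [0, 1]")
    if (!(kappa >= 0 && kappa <= 1)) stop("'kappa' must lie in [0, 1]")
    stopifnot(is(encoding, "Encoding"))
    structure(list(m = m, n = n, q = q, pi = pi, kappa = kappa,
                   encoding = encoding, seed = as.integer(seed),
                   nChrom = as.integer(nChrom)),
              class = c("SimulationConfig", "list"))
}

#' Hardy-Weinberg genotype draws
#'
#' Draws n independent genotypes with class probabilities (1-q)^2 for AA,
#' 2q(1-q) for Aa and q^2 for aa, then encodes them.  Uses R's current RNG
#' stream; seed it (or use [generateDataset()]) for reproducibility.
#'
#' @param n number of samples.
#' @param q minor allele frequency in (0, 0.5].
#' @param encoding [Encoding] applied to the draws.
#' @return numeric vector of n encoded genotypes, with the minor-allele
#'   counts attached as attribute `"counts"`.
#' @examples
#' set.seed(1)
#' table(drawHweGenotypes(1000, 0.25, Encoding(c(0, 1, 2), "E1")))
#' @export
drawHweGenotypes <- function(n, q, encoding = Encoding(c(0, 1, 2), "E1")) {
    if (!(q > 0 && q <= 0.5))
        stop("'q' (minor allele frequency) must lie in (0, 0.5]")
    stopifnot(is(encoding, "Encoding"))
    counts <- sample.int(3L, n, replace = TRUE,
                         prob = c((1 - q)^2, 2 * q * (1 - q), q^2)) - 1L
    structure(encoding@values[counts + 1L], counts = counts)
}

#' Phenotype from a causal genotype under the variance-partition model
#'
#' \deqn{p_j = \sqrt{1 - \pi}\,\varepsilon_j +
#'       g_j \sqrt{\pi / (2 q (1 - q))}, \qquad
#'       \varepsilon_j \sim N(0, 1),}
#' with the causal genotype g on the minor-allele-count scale {0, 1, 2},
#' whose Hardy-Weinberg variance is 2q(1-q).  The two terms then partition
#' unit phenotype variance, with genetic share pi; the phenotype law does
#' not depend on the output encoding chosen for the genotype matrix.
#'
#' @param gCausal causal genotypes as minor-allele counts in {0, 1, 2}.
#' @param pi genetic variance share in \[0, 1\].
#' @param q minor allele frequency in (0, 1) used for the variance
#'   normalization.
#' @return numeric phenotype vector (named like `gCausal` if it has names).
#' @examples
#' set.seed(1)
#' g <- attr(drawHweGenotypes(500, 0.25), "counts")
#' var(simulatePhenotype(g, pi = 0.05, q = 0.25))  # close to 1
#' @export
simulatePhenotype <- function(gCausal, pi, q) {
    if (!(q > 0 && q < 1))
        stop("'q' must lie strictly in (0, 1): genotype variance 2q(1-q) must be positive")
    if (!(pi >= 0 && pi <= 1)) stop("'pi' must lie in [0, 1]")
    g <- as.numeric(gCausal)
    if (!all(g %in% 0:2))
        stop("'gCausal' must be on the minor-allele-count scale {0, 1, 2}")
    n <- length(g)
    p <- sqrt(1 - pi) * rnorm(n) + g * sqrt(pi / (2 * q * (1 - q)))
    names(p) <- names(gCausal)
    p
}

#' Partially shuffled copy of a genotype vector
#'
#' Duplicates a genotype vector, selects round(kappa * n) target positions
#' uniformly at random (round-half-up) and overwrites each with the
#' genotype of a randomly drawn sample (source positions drawn without
#' replacement from all n).  Positions outside the target subset are
#' untouched.  The boundary cases are exact: kappa = 0 returns an
#' identical copy and kappa = 1 a uniform random permutation of the whole
#' vector (value multiset conserved).  At intermediate kappa the copy's
#' value counts fluctuate around the original's — each position still
#' carries a Hardy-Weinberg draw, but SNP copies are not constrained to
#' share one multiset, so the panel's sample covariance retains a
#' non-degenerate mean direction (see the package vignette).
#'
#' @param g genotype vector.
#' @param kappa shuffling rate in \[0, 1\].
#' @return vector of the same length as `g`.
#' @export
shuffleCopy <- function(g, kappa) {
    if (!(kappa >= 0 && kappa <= 1)) stop("'kappa' must lie in [0, 1]")
    n <- length(g)
    nsel <- as.integer(floor(kappa * n + 0.5))   # round half up
    if (nsel >= 1L) {
        sel <- sample.int(n, nsel)
        g[sel] <- g[sample.int(n, nsel)]
    }
    g
}

#' Generate a complete simulated genotype-phenotype dataset
#'
#' Composes the simulator: (1) draw the causal SNP (SNP 1) under
#' Hardy-Weinberg equilibrium at MAF `q`; (2) generate the phenotype from
#' it via [simulatePhenotype()]; (3) emit SNPs 2..m as independent
#' [shuffleCopy()]s of the causal SNP at rate `kappa`.  A single seeded RNG
#' stream drives all draws in that documented order, so the dataset is
#' bit-reproducible from `config$seed`.  SNPs are split evenly into
#' `nChrom` fictitious chromosome blocks (display convention only).
#'
#' @param config a [simulationConfig()].
#' @return list with `genotypes` ([EncodedGenotypes] with chrom/pos
#'   rowData), `phenotype` (named numeric vector), `truth` (`DataFrame`
#'   with per-SNP `nPermuted`: 0 for the causal SNP, round(kappa n)
#'   otherwise), and `config`.
#' @examples
#' sim <- generateDataset(simulationConfig(m = 50, n = 100, seed = 42))
#' sim$genotypes
#' @export
generateDataset <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    n <- config$n; m <- config$m
    causal <- drawHweGenotypes(n, config$q, config$encoding)
    counts <- attr(causal, "counts")
    pheno <- simulatePhenotype(counts, config$pi, config$q)
    nsel <- as.integer(floor(config$kappa * n + 0.5))
    cmat <- matrix(0L, nrow = m, ncol = n)
    cmat[1L, ] <- counts
    if (m > 1L)
        for (i in 2:m) cmat[i, ] <- shuffleCopy(counts, config$kappa)
    g <- matrix(config$encoding@values[cmat + 1L], nrow = m)
    snpIds <- paste0("snp", seq_len(m))
    sampleIds <- paste0("s", seq_len(n))
    dimnames(g) <- list(snpIds, sampleIds)
    names(pheno) <- sampleIds
    block <- floor((seq_len(m) - 1L) * config$nChrom / m)  # even split
    pos <- as.integer(unlist(lapply(split(seq_len(m), block), seq_along),
                             use.names = FALSE))
    rd <- DataFrame(chrom = paste0("chr", block + 1L), pos = pos,
                    row.names = snpIds)
    list(genotypes = EncodedGenotypes(g, config$encoding, rowData = rd),
         phenotype = pheno,
         truth = DataFrame(snp_id = snpIds,
                           nPermuted = c(0L, rep(nsel, m - 1L))[seq_len(m)]),
         config = config)
}
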