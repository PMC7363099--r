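# tauGWAS

Encoding-robust association testing for continuous phenotypes after
PCA-based stratification correction.

## The problem

Genotypes of a bi-allelic SNP (AA / Aa / aa) are categorical; to test them
against a quantitative trait they must be encoded numerically, and several
conventions coexist — the minor-allele count E1 = {0, 1, 2}, the
zero-dominance form E2 = {−1, 0, 1}, and in principle any triple of distinct
values (any two encodings differ by a multiplicative factor α and/or an
additive shift β). Once population stratification is corrected by removing
the top K principal components from the encoded matrix, genotypes become
continuous, and the standard Pearson slope test becomes sensitive to that
arbitrary choice: with V the n × K eigenvector matrix of the sample
covariance,

    g_adj = g (I − V Vᵀ),
    (α g)_adj = α g_adj,                       (scale: harmless)
    (g + β)_adj = g_adj + β Δᴷ,   Δᴷⱼ = 1 − Σₗ (V Vᵀ)ⱼₗ,   (shift: not harmless)

so an additive re-encoding survives adjustment through the non-constant
per-sample remainder Δᴷ and changes Pearson p-values whenever K ≥ 1.

tauGWAS implements the non-parametric alternative: a per-SNP association
test on Kendall's tau-a,

    τ̂ₙ = 2 (n_c − n_d) / (n (n − 1)),     z = τ̂ₙ / σₙ,
    σₙ = sqrt( 2 (2n + 5) / (9 n (n − 1)) ),

with concordant/discordant pairs counted by an O(n log n) merge-sort
inversion count. Because the test uses only the *ordering* of adjusted
genotypes, it is exactly invariant under positive rescaling and empirically
almost invariant under additive shifts (roughly 90% of sample-pair orderings
survive the E2 → E1 shift at K = 5). The package ships the full evaluation
apparatus: the PCA adjustment with Δᴷ, Pearson and Spearman comparators,
genome scans, per-SNP p-value differences Δpᵢ = p_{i,E1} − p_{i,E2} with
fixed-center skewness/kurtosis summaries, sample-pair rank-preservation
ratios, analytic power curves, a fully specified genotype–phenotype
simulator, and TSV/VCF readers for real data. Audience: anyone running GWAS
or genomic-prediction pipelines on PCA-adjusted genotypes who wants results
that do not depend on an arbitrary encoding convention.

## Worked example

```r
library(tauGWAS)

sim <- generateDataset(simulationConfig(m = 2000, n = 300, q = 0.25,
                                        pi = 0.05, kappa = 0.5, seed = 42))
res <- runPipeline(sim$genotypes, sim$phenotype, K = 5,
                   methods = c("kendall", "pearson"))

res$adjusted$E1
#> AdjustedGenotypes: 2000 SNPs x 300 samples, K=5 axes removed (encoding "E1")
#>   Delta^K remainder: mean 0.9783, range [-0.4758, 1.6245]

head(as.data.frame(res$scans$kendall$E1)[, c(1, 2, 6, 7, 8)], 3)
#>   snp_id chrom      effect statistic    p_value
#> 1   snp1  chr1 0.080802676 2.0871350 0.03687594
#> 2   snp2  chr1 0.012218506 0.3156043 0.75230288
#> 3   snp3  chr1 0.009855072 0.2545567 0.79906547

res$rankPreservation$ratio       # 0.8653
res$moments$kendall[c("G1","G2")]  # G1  1.426, G2  0.273
res$moments$pearson[c("G1","G2")]  # G1  1.294, G2 -0.472

powerKendall(0.2, n = 300)$power   # 0.9993
```

Reading the numbers: SNP 1 is the causal variant (smallest p); the other
SNPs are half-shuffled copies of it. 86.5% of sample-pair orderings of the
adjusted genotypes survive the additive shift between E2 = {−1,0,1} and
E1 = {0,1,2}. The encoding p-value differences Δp from Kendall's test have
higher kurtosis (0.27, near-mesokurtic) than Pearson's (−0.47, platykurtic:
a flat/bimodal Δp distribution), i.e. Kendall p-values concentrate at zero
difference — the encoding-robustness ordering the package is built to
demonstrate. At n = 300 the analytic Kendall power at effect θ = 0.2 is
0.9993 (σ₃₀₀ ≈ 0.0387). Skewness of a single run fluctuates with the seed
(all SNPs share one causal template); the kurtosis ordering is the stable
signal — see the vignette.

A thin CLI over the same functions is in `inst/scripts/taugwas-cli.R`
(`simulate`, `adjust`, `scan`, `robustness`, `power`, `run`).

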