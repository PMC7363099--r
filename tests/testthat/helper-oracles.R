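# Independent oracles and small fixture builders shared across tests.

# O(n^2) all-pairs concordance counter: the brute-force oracle for the
# merge-sort implementation.  Pairs tied in either coordinate fall in
# neither count.
bruteForceCounts <- function(x, y) {
    s <- sign(outer(x, x, "-")) * sign(outer(y, y, "-"))
    up <- upper.tri(s)
    list(nc = as.numeric(sum(s[up] == 1)),
         nd = as.numeric(sum(s[up] == -1)))
}

E1 <- Encoding(c(0, 1, 2), "E1")
E2 <- Encoding(c(-1, 0, 1), "E2")

# small deterministic calls matrix with ids
makeCalls <- function(m = 4, n = 6, seed = 101, missing = 0) {
    set.seed(seed)
    x <- matrix(sample(c("AA", "Aa", "aa"), m * n, TRUE,
                       prob = c(.55, .35, .10)), m, n)
    if (missing > 0) x[sample(length(x), missing)] <- NA_character_
    GenotypeCalls(x, snpIds = paste0("snp", 1:m),
                  sampleIds = paste0("s", 1:n))
}

# seeded simulated dataset small enough for unit tests
smallSim <- function(m = 50, n = 60, seed = 7, kappa = 0.5,
                     encoding = E1) {
    generateDataset(simulationConfig(m = m, n = n, q = 0.25, pi = 0.05,
                                     kappa = kappa, encoding = encoding,
                                     seed = seed))
}
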