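# Brute-force Gaussian density classifier: evaluates prior * N(x; mu_k, Sigma)
# for every class and returns the argmax label. Independent oracle for the
# linear-discriminant path (same model parameters, different computation).
brute_gaussian_classify <- function(means, sigma, priors, x) {
  inv <- solve(sigma)
  logdens <- vapply(seq_len(nrow(means)), function(k) {
    d <- x - means[k, ]
    log(priors[k]) - 0.5 * drop(t(d) %*% inv %*% d)
  }, numeric(1))
  rownames(means)[which.max(logdens)]
}

# A two-haplotype frequency map (1-segment vs 2-segment) for sampling tests
two_hap_freqs <- function(p = 0.7) {
  mono <- rccx_haplotype("B", "A2", "deletion")
  bi <- rccx_haplotype(c("A", "B"), c("A1P", "A2"),
                       c("insertion", "deletion"))
  list(haplotypes = list(mono = mono, bi = bi),
       freqs = c(mono = p, bi = 1 - p))
}

# Wide measured-GCN frame with exact integer values for a list of genotypes
exact_measured <- function(genotypes, ids = NULL) {
  tr <- genotype_truth(genotypes, ids)
  tr[c("sample_id", rccx_assays())]
}
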