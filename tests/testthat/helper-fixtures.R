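# builders shared across test files; everything is generated in code

# embryo_sample straight from a genes x slices matrix
make_embryo <- function(expr, id = "e1", genotype = "wt",
                        timepoint = "c14D", qc_mask = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) {
    rownames(expr) <- sprintf("g%02d", seq_len(nrow(expr)))
  }
  if (is.null(qc_mask)) qc_mask <- rep(TRUE, ncol(expr))
  structure(list(embryo_id = id, genotype = genotype,
                 timepoint = timepoint, expr = expr, qc_mask = qc_mask),
            class = "embryo_sample")
}

# random unit-mass distribution with n atoms at slice centers
random_distribution <- function(n) {
  v <- runif(n)
  v[sample(n, max(1, n %/% 4))] <- 0    # some empty slices
  if (sum(v) == 0) v[1] <- 1
  to_distribution(v)
}

# a small cohort config used by several tests
tiny_cohort <- function(n_genes = 60, sigma = 0.1, seed = 42,
                        genotypes = c("wt", "bcd_minus"),
                        qc_fail_rate = 0.02) {
  cohort_config(n_genes = n_genes, genotypes = genotypes,
                noise_sigma = sigma, qc_fail_rate = qc_fail_rate,
                seed = seed)
}
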