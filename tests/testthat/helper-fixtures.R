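# Shared fixtures and independent oracles, built in code at test time.

# Random Poisson count matrix with distinct gene/sample names.
rand_cm <- function(n_genes, n_samples, lambda = 50, seed = 1,
                    prefix = c("g", "s")) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(paste0(prefix[1], seq_len(n_genes)),
                              paste0(prefix[2], seq_len(n_samples))))
  count_matrix(m)
}

# Brute-force Benjamini-Hochberg step-up from the definition: sort
# ascending, q_(i) = min_{k >= i} p_(k) * m / k capped at 1, restore order.
# Kept deliberately naive and independent of stats::p.adjust.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (k in i:m) best <- min(best, ps[k] * m / k)
    q[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-sided "sum of probabilities <= observed" p-value from a full pmf
# vector over support 0..length(pmf)-1.
enum_two_sided <- function(pmf, obs) {
  sum(pmf[pmf <= pmf[obs + 1] * (1 + 1e-7)])
}

# A de_result-producing dummy caller factory (ignores the data).
const_p_caller <- function(p_fun) {
  function(cmA, cmB, fdr) {
    p <- p_fun(length(cmA$gene_ids))
    countgof:::de_result(cmA$gene_ids, p, fdr, "dummy")
  }
}
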