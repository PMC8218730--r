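# Shared fixtures: small matrices and configs built in code.

tiny_counts <- function(values = NULL, genes = NULL, samples = NULL) {
  if (is.null(values)) {
    values <- matrix(c(5, 3, 0,
                       8, 0, 2), nrow = 3,
                     dimnames = list(c("Actb", "Cd19", "Lyz2"), c("s1", "s2")))
  }
  if (!is.null(genes)) rownames(values) <- genes
  if (!is.null(samples)) colnames(values) <- samples
  expr_matrix(values, "counts")
}

# config with no true effects (global null), small and fast
null_config <- function(n_genes = 150, seed = 1, ...) {
  sim_config(n_genes = n_genes, seed = seed,
             phenotype_effect_genes = stats::setNames(numeric(0), integer(0)),
             td_effect_genes = stats::setNames(numeric(0), integer(0)), ...)
}

# brute-force Holm step-down straight from the definition
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# brute-force exact two-sided Mann-Whitney p by full enumeration
mwu_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}
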