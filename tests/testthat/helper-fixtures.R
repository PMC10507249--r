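# shared fixtures: small simulation configs and independent oracles

small_sim <- function(seed = 1L, ...) {
  sim_config(n_genes = 2000L, n_rising = 100L, n_falling = 80L,
             n_oocyte_specific = 100L, n_detect_artifacts = 20L,
             n_bias_artifacts = 30L, seed = seed, ...)
}

tiny_counts <- function() {
  m <- matrix(c(0L, 1L, 2L, 3L, 4L, 5L), 3, 2, byrow = TRUE,
              dimnames = list(c("gene_a", "gene_b", "ERCC-00096"),
                              c("c1", "c2")))
  count_matrix(m)
}

# independent BH oracle: literal step-up definition, no cummin tricks
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    j <- which(o == i)  # rank of p[i]
    q[i] <- min(1, min(p[o][seq(j, n)] * n / seq(j, n)))
  }
  q
}

# independent eigendecomposition PCA oracle (cells x genes input)
pca_oracle <- function(x) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  e <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  list(loadings = e$vectors, scores = xc %*% e$vectors,
       var = e$values)
}

# exact label-permutation (hypergeometric) oracle for the 2x2 table
perm_prop_oracle <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  ks <- max(0, K - n2):min(n1, K)
  pr <- stats::dhyper(ks, n1, n2, K)
  obs <- abs(k1 / n1 - k2 / n2)
  sum(pr[abs(ks / n1 - (K - ks) / n2) >= obs - 1e-12])
}

# brute-force Spearman via explicit average ranks
spearman_oracle <- function(a, b) {
  stats::cor(rank(a, ties.method = "average"),
             rank(b, ties.method = "average"))
}
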