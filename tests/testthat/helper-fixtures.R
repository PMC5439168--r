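# Shared fixtures built in code.

# Four-animal nuclear family: two unrelated founders and two full sibs.
nuclear_pedigree <- function() {
  pedigree(c("S", "D", "O1", "O2"),
           c(NA, NA, "S", "S"),
           c(NA, NA, "D", "D"))
}

# Small hierarchical design with genotypes, used across module tests.
small_dataset <- function(seed = 7, n_snps = 300) {
  cfg <- sim_config(n_sires = 12, n_dams = 20, family_size_mean = 10,
                    family_size_range = c(4, 20), n_snps = n_snps,
                    genotyped_families = 10,
                    genotyped_sibs_range = c(4, 8), seed = seed)
  simulate_dataset(cfg)
}

# Phenotype table with the analysis-scale response attached.
with_std_response <- function(ds) {
  ph <- ds$phenotypes
  ph$y <- standardize(ph$weight)$values
  ph
}

# Dense GLS solutions for the marginal model y ~ X b + Z u + Q c + e,
# V = Z K Z' s2u + Q Q' s2c + diag(s2e / w). Independent oracle for the
# mixed-model equations.
dense_gls <- function(y, X, Z, K, s2u, Q = NULL, s2c = NULL, s2e = 1,
                      w = rep(1, length(y))) {
  V <- Z %*% K %*% t(Z) * s2u + diag(s2e / w)
  if (!is.null(Q)) V <- V + Q %*% t(Q) * s2c
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  u <- s2u * K %*% t(Z) %*% Vi %*% r
  cc <- if (is.null(Q)) NULL else s2c * t(Q) %*% Vi %*% r
  list(fixed = as.numeric(b), genetic = as.numeric(u),
       common = if (is.null(cc)) NULL else as.numeric(cc))
}
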