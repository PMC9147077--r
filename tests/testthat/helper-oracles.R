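# Independent oracles used to cross-check the package's implementations.
# These deliberately take different computational routes than the package.

# Classical CCA via SVD whitening: center both blocks, take the left
# singular bases of each, and read canonical correlations off the singular
# values of the cross-product of the bases.
cca_svd_oracle <- function(X, Y) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sx <- svd(Xc)
  sy <- svd(Yc)
  kx <- sum(sx$d > 1e-10 * sx$d[1])
  ky <- sum(sy$d > 1e-10 * sy$d[1])
  svd(crossprod(sx$u[, seq_len(kx), drop = FALSE],
                sy$u[, seq_len(ky), drop = FALSE]))$d
}

# Exhaustive fixed-reallocation p-value by bitmask enumeration over all
# subsets of the pooled dCt values with the original group-1 size.
randomization_p_oracle <- function(d_c, d_t) {
  pooled <- c(d_c, d_t)
  n <- length(pooled)
  n1 <- length(d_c)
  obs <- abs(mean(d_c) - mean(d_t))
  stats <- c()
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(members) != n1) next
    g1 <- pooled[members]
    g2 <- pooled[-members]
    stats <- c(stats, abs(mean(g1) - mean(g2)))
  }
  mean(stats >= obs - 1e-12)
}

# Homogeneity by its defining sum: squared Pearson correlations between
# each variable and the block's first principal component (via prcomp).
homogeneity_pc_oracle <- function(X) {
  pc1 <- prcomp(X, center = TRUE, scale. = TRUE)$x[, 1]
  sum(apply(X, 2, function(x) cor(x, pc1)^2))
}

# Small deterministic single-cultivar design used across tests.
tiny_design <- function(seed = 1, ...) {
  designConfig(cultivars = "cv1", rng_seed = seed, ...)
}

# Strong-association study with near-zero noise, for sign/direction checks.
quiet_effect <- function(design, ...) {
  effectConfig(design, cq_noise_sd = 1e-9, block_factor_sd = 0,
               trait_noise_sd = 1e-9, ...)
}
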