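# Independent oracles and small fixture builders used across the suite.

# PCA oracle through the eigendecomposition of the covariance/correlation
# matrix -- a different numerical route than the SVD the implementation uses.
oracle_pca <- function(x, standardize = TRUE) {
  xs <- scale(as.matrix(x), center = TRUE, scale = standardize)
  S <- crossprod(xs) / (nrow(xs) - 1)
  e <- eigen(S, symmetric = TRUE)
  scores <- xs %*% e$vectors
  for (j in seq_len(ncol(e$vectors))) {
    v <- e$vectors[, j]
    if (v[which.max(abs(v))] < 0) {
      e$vectors[, j] <- -v
      scores[, j] <- -scores[, j]
    }
  }
  list(values = e$values, vectors = e$vectors, scores = scores)
}

# Resolve the residual sign ambiguity between two PCA routes: when an axis's
# two largest |loadings| are numerically tied, each route may canonicalize to
# the opposite orientation; align oracle axes to the implementation by the
# sign of the score dot product before comparing.
align_signs <- function(oracle_scores, impl_scores) {
  for (j in seq_len(ncol(oracle_scores))) {
    if (sum(oracle_scores[, j] * impl_scores[, j]) < 0)
      oracle_scores[, j] <- -oracle_scores[, j]
  }
  oracle_scores
}

# Hand-written type-7 quantile: interpolation at position 1 + (n - 1) p.
oracle_quantile <- function(values, p) {
  x <- sort(values)
  h <- 1 + (length(x) - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Minimal hand-built trait table: n species with plausible values, one biome
# unless given. Deterministic.
make_trait_table <- function(n = 10, biome = "TF",
                             families = sprintf("F%02d", seq_len(n))) {
  i <- seq_len(n)
  trait_table(data.frame(
    species_id = sprintf("sp%03d", i), biome = biome,
    family = families, genus = sprintf("G%03d", i),
    LA = 20 + 5 * i, LDMC = 0.3 + 0.01 * i, SLA = 100 + 10 * i,
    LNC = 15 + i, STD = 0.4 + 0.01 * i, MPH = 5 + i, MDBH = 8 + i,
    FLT = 100 + 10 * i, FRT = 150 + 10 * i, FLD = 60 + 2 * i,
    FRD = 50 + 2 * i))
}

# Scores data frame usable by bin_species()/convergence_report() directly.
make_scores <- function(PC1, PC2, family = NULL,
                        species_id = sprintf("sp%03d", seq_along(PC1))) {
  if (is.null(family)) family <- sprintf("F%02d", seq_along(PC1))
  data.frame(species_id = species_id, biome = "TF", family = family,
             PC1 = PC1, PC2 = PC2)
}

# Small, fast simulation config for pipeline-level tests.
small_sim <- function(seed = 5) {
  sim_config(n_species = c(TF = 12, SF = 10, WF = 8, CF = 6), seed = seed)
}
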