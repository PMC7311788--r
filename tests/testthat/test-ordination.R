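# PCA correctness against an independent eigen-oracle, sign canonicalization,
# the nested two-stage ordination and its bookkeeping.

test_that("pca matches the eigendecomposition oracle on random matrices", {
  for (i in 1:30) {
    set.seed(3000 + i)
    n <- sample(7:30, 1)
    p <- sample(2:6, 1)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    for (std in c(TRUE, FALSE)) {
      res <- niche_pca(x, standardize = std)
      orc <- oracle_pca(x, standardize = std)
      expect_lt(max(abs(res$eigenvalues - pmax(orc$values, 0))), 1e-8)
      expect_lt(max(abs(res$scores - align_signs(orc$scores, res$scores))),
                1e-8)
    }
  }
})

test_that("two perfectly correlated columns give a rank-1 standardized PCA", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10))
  res <- niche_pca(x, standardize = TRUE)
  expect_equal(res$eigenvalues, c(2, 0))
  expect_equal(res$percent_variance, c(100, 0))
})

test_that("standardized eigenvalues conserve total variance", {
  set.seed(99)
  for (p in c(3, 4, 6)) {
    x <- matrix(rnorm(40 * p), 40, p)
    res <- niche_pca(x, standardize = TRUE)
    expect_lt(abs(sum(res$eigenvalues) - p), 1e-8)
    expect_lt(abs(sum(res$percent_variance) - 100), 1e-8)
  }
})

test_that("degenerate inputs are rejected or padded as declared", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("ok", "flat")))
  x[, 2] <- 5
  expect_error(niche_pca(x), "flat")
  expect_error(niche_pca(matrix(rnorm(4), 2, 2)), "3 observations")
  wide <- matrix(rnorm(4 * 6), 4, 6)
  res <- niche_pca(wide, standardize = TRUE)
  expect_length(res$eigenvalues, 6)
  expect_true(all(res$eigenvalues[4:6] == 0))
})

test_that("sign canonicalization makes the top loading positive and is idempotent", {
  set.seed(7)
  res <- niche_pca(matrix(rnorm(60), 20, 3))
  for (j in 1:3) {
    v <- res$rotation[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_identical(fix_sign(res), res)
  flipped <- res
  flipped$rotation[, 1] <- -flipped$rotation[, 1]
  flipped$scores[, 1] <- -flipped$scores[, 1]
  refixed <- fix_sign(flipped)
  expect_equal(refixed$rotation, res$rotation)
  expect_equal(refixed$scores, res$scores)
})

test_that("dimension PCA finds plant size on PC1 and stem density on PC2", {
  set.seed(21)
  n <- 50
  z <- rnorm(n)
  block <- cbind(MPH = z + rnorm(n, 0, 0.15),
                 MDBH = z + rnorm(n, 0, 0.15),
                 STD = rnorm(n))
  expect_gt(cor(block[, "MPH"], block[, "MDBH"]), 0.9)
  res <- niche_pca(block, standardize = TRUE)
  orc <- oracle_pca(block)
  expect_lt(max(abs(res$eigenvalues - pmax(orc$values, 0))), 1e-8)
  expect_true(dominant_variable(res, 1) %in% c("MPH", "MDBH", "MPH+MDBH"))
  expect_equal(dominant_variable(res, 2), "STD")
})

test_that("dominant-variable ties within tolerance are reported jointly", {
  res <- structure(list(
    variable_names = c("MPH", "MDBH", "STD"),
    rotation = cbind(PC1 = c(0.7071, 0.7071, 1e-9))), class = "pca_result")
  expect_equal(dominant_variable(res, 1), "MPH+MDBH")
})

test_that("the per-dimension gradients are centered and variance-ordered", {
  cm <- generate_community(small_sim(3))
  dp <- dimension_pca(log10_transform(cm$traits))
  grad_cols <- grep("^pc[12]\\.", names(dp$gradients), value = TRUE)
  expect_length(grad_cols, 6)
  for (col in grad_cols)
    expect_lt(abs(mean(dp$gradients[[col]])), 1e-10)
  for (r in dp$results)
    expect_gte(r$percent_variance[1], r$percent_variance[2])
  expect_error(dimension_pca(cm$traits), "log10")
})

test_that("the second PCA is isotropic on independent gradients", {
  set.seed(31)
  n <- 2000
  g <- data.frame(species_id = sprintf("s%04d", 1:n), biome = "TF",
                  family = "F01", genus = "G001")
  for (col in c("pc1.leaf_economy", "pc2.leaf_economy",
                "pc1.mechanical_support", "pc2.mechanical_support",
                "pc1.reproductive_phenology", "pc2.reproductive_phenology"))
    g[[col]] <- rnorm(n)
  space <- pca_of_pcas(g)
  expect_true(all(abs(space$eigenvalues - 1) < 0.2))
  expect_true(all(abs(space$percent_variance - 100 / 6) < 3))
})

test_that("a planted cross-gradient correlation dominates the niche-space PC1", {
  set.seed(32)
  n <- 300
  z <- rnorm(n)
  g <- data.frame(species_id = sprintf("s%04d", 1:n), biome = "TF",
                  family = "F01", genus = "G001",
                  pc1.leaf_economy = z + rnorm(n, 0, 0.45),
                  pc2.leaf_economy = rnorm(n),
                  pc1.mechanical_support = rnorm(n),
                  pc2.mechanical_support = -z + rnorm(n, 0, 0.45),
                  pc1.reproductive_phenology = rnorm(n),
                  pc2.reproductive_phenology = rnorm(n))
  space <- pca_of_pcas(g)
  l <- space$loadings[, 1]
  names(l) <- space$gradient_names
  top2 <- names(sort(abs(l), decreasing = TRUE))[1:2]
  expect_setequal(top2, c("pc1.leaf_economy", "pc2.mechanical_support"))
  expect_lt(l["pc1.leaf_economy"] * l["pc2.mechanical_support"], 0)
})

test_that("percent variance and eigenvalues agree under standardization", {
  cm <- generate_community(small_sim(9))
  space <- build_niche_space(cm$traits)
  expect_lt(max(abs(space$percent_variance * 6 / 100 - space$eigenvalues)),
            1e-8)
})

test_that("misaligned gradients are rejected listing the offending species", {
  cm <- generate_community(small_sim(4))
  dp <- dimension_pca(log10_transform(cm$traits))
  g <- dp$gradients
  g$pc1.leaf_economy[3] <- NA
  expect_error(pca_of_pcas(g), g$species_id[3])
})

test_that("reported variance shares are invariant to row permutation", {
  cm <- generate_community(small_sim(8))
  space <- build_niche_space(cm$traits)
  set.seed(1)
  perm <- sample(nrow(cm$traits))
  shuffled <- trait_table(as.data.frame(cm$traits)[perm, ])
  space2 <- build_niche_space(shuffled)
  expect_equal(space$eigenvalues, space2$eigenvalues, tolerance = 1e-10)
  expect_equal(space$percent_variance, space2$percent_variance,
               tolerance = 1e-10)
})

test_that("a tiny biome yields trailing zero eigenvalues with a warning", {
  tiny <- make_trait_table(6, biome = "CF")
  set.seed(2)
  for (col in trait_names())
    tiny[[col]] <- tiny[[col]] * exp(rnorm(6, 0, 0.05))
  tiny$LDMC <- pmin(tiny$LDMC, 1)
  expect_warning(space <- build_niche_space(tiny), "fewer observations")
  expect_length(space$eigenvalues, 6)
  expect_equal(space$eigenvalues[6], 0)
})

test_that("space summaries carry the fixed report schema", {
  cm <- generate_community(small_sim(12))
  space <- build_niche_space(cm$traits)
  summ <- summarize_space(space)
  expect_equal(summ$space$quantity,
               c("eigenvalue", "percent",
                 "pc1.leaf_economy", "pc2.leaf_economy",
                 "pc1.mechanical_support", "pc2.mechanical_support",
                 "pc1.reproductive_phenology", "pc2.reproductive_phenology"))
  expect_true(all(c("PC1", "PC1_scaled", "PC2", "PC2_scaled")
                  %in% names(summ$space)))
  for (d in unique(summ$dimensions$dimension))
    expect_lte(sum(summ$dimensions$percent[summ$dimensions$dimension == d]),
               100 + 1e-8)
})
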