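# Binning, central-plot selection and the family/species convergence ratio.

test_that("binning uses half-open origin-anchored cells", {
  b <- bin_species(make_scores(c(0.2, 0.5), c(-0.3, 0.5)))
  # (0.2, -0.3) -> [0, 0.5) x [-0.5, 0)
  expect_equal(b$ix[1], 0)
  expect_equal(b$iy[1], -1)
  # boundary score (0.5, 0.5) belongs to [0.5, 1.0) x [0.5, 1.0)
  expect_equal(b$ix[2], 1)
  expect_equal(b$iy[2], 1)
  expect_error(bin_species(make_scores(0, 0), width = 0), "positive")
  expect_error(bin_species(make_scores(0, 0), width = -1), "positive")
})

test_that("binning partitions the species set", {
  set.seed(41)
  sc <- make_scores(rnorm(80), rnorm(80))
  b <- bin_species(sc)
  expect_equal(sum(table(b$cell)), 80)
  expect_equal(anyDuplicated(b$species_id), 0)
})

test_that("shifting scores by one width shifts cell indices by one", {
  set.seed(42)
  sc <- make_scores(rnorm(40), rnorm(40))
  b1 <- bin_species(sc, width = 0.5)
  sc2 <- sc
  sc2$PC1 <- sc2$PC1 + 0.5
  sc2$PC2 <- sc2$PC2 - 0.5
  b2 <- bin_species(sc2, width = 0.5)
  expect_equal(b2$ix, b1$ix + 1L)
  expect_equal(b2$iy, b1$iy - 1L)
})

test_that("convergence ratio is families over species", {
  expect_equal(convergence_ratio(c("A", "B", "C", "D", "E")), 1.0)
  expect_equal(convergence_ratio(c("A", "A", "B", "B")), 0.5)
  expect_equal(convergence_ratio(c("A", "A", "A")), 1 / 3)
  expect_error(convergence_ratio(character(0)), "empty")
})

test_that("ratio moves as members join a plot", {
  set.seed(43)
  for (i in 1:25) {
    fams <- sample(LETTERS[1:6], sample(2:12, 1), replace = TRUE)
    r0 <- convergence_ratio(fams)
    expect_true(r0 > 0 && r0 <= 1)
    expect_equal(r0 == 1, !anyDuplicated(fams) > 0)
    r_same <- convergence_ratio(c(fams, fams[1]))
    expect_lt(r_same, r0)
    r_new <- convergence_ratio(c(fams, "ZZ"))
    expect_gte(r_new, r0 - 1 / (length(fams) + 1))
  }
})

test_that("central plots are the nearest multi-species cells, oracle-checked", {
  set.seed(44)
  # clustered scores: many multi-species cells near the origin
  sc <- make_scores(rnorm(60, 0, 0.8), rnorm(60, 0, 0.8),
                    family = sample(sprintf("F%02d", 1:20), 60, replace = TRUE))
  b <- bin_species(sc, 0.5)
  plots <- select_central_plots(b, k = 8)
  expect_lte(nrow(plots), 8)
  expect_true(all(plots$n_species >= 2))
  # brute-force oracle: enumerate cells, filter, sort by center distance
  agg <- aggregate(list(n = b$species_id),
                   by = list(ix = b$ix, iy = b$iy), FUN = length)
  agg <- agg[agg$n >= 2, ]
  cx <- (agg$ix + 0.5) * 0.5
  cy <- (agg$iy + 0.5) * 0.5
  d <- sqrt(cx^2 + cy^2)
  ang <- atan2(cy, cx) %% (2 * pi)
  agg <- agg[order(d, ang, agg$ix, agg$iy), ]
  expected <- head(paste(agg$ix, agg$iy, sep = ","), 8)
  expect_equal(paste(plots$ix, plots$iy, sep = ","), expected)
  expect_equal(plots$plot_id, as.character(as.roman(seq_len(nrow(plots)))))
})

test_that("exactly eight multi-species cells are all returned", {
  pc1 <- c(rep(0.1, 2), rep(0.6, 2), rep(-0.4, 2), rep(-0.9, 2),
           rep(0.1, 2), rep(0.6, 2), rep(-0.4, 2), rep(-0.9, 2))
  pc2 <- c(rep(0.1, 8), rep(-0.4, 8))
  sc <- make_scores(pc1, pc2,
                    family = sprintf("F%02d", 1:16))
  plots <- select_central_plots(bin_species(sc), k = 8)
  expect_equal(nrow(plots), 8)
  expect_true(all(plots$n_species == 2))
})

test_that("an all-singleton space is flagged as not assessable", {
  sc <- make_scores(seq(0, 9) * 0.7, seq(0, 9) * 0.7)
  expect_warning(plots <- select_central_plots(bin_species(sc)),
                 "not assessable")
  expect_equal(nrow(plots), 0)
  rep <- convergence_report(sc)
  expect_false(rep$assessable)
  expect_true(is.na(rep$mean_ratio))
})

test_that("planted convergent clusters beat a family-permutation null", {
  set.seed(45)
  n_clustered <- 20
  centers <- rbind(c(0.2, 0.2), c(-0.3, 0.2), c(0.2, -0.3), c(-0.3, -0.3))
  pc1 <- c(rep(centers[, 1], each = 5) + runif(n_clustered, 0, 0.05),
           rnorm(40, 0, 2))
  pc2 <- c(rep(centers[, 2], each = 5) + runif(n_clustered, 0, 0.05),
           rnorm(40, 0, 2))
  fams <- c(rep(sprintf("F%02d", 1:5), 4),             # clusters: 5 families
            sample(sprintf("F%02d", 6:20), 40, replace = TRUE))
  sc <- make_scores(pc1, pc2, family = fams)
  nul <- convergence_null(sc, n_perm = 500)
  expect_gt(nul$observed, nul$null_mean)
  expect_true(nul$p_value >= 0 && nul$p_value <= 1)
})
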