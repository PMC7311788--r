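# The latent-factor community generator: determinism, invariants, the
# closed-form implied correlation structure and planted ground truth.

test_that("default community echoes the configuration and passes invariants", {
  cm <- generate_community(sim_config(seed = 1))
  expect_equal(nrow(cm$traits), 215)
  expect_equal(as.vector(table(cm$traits$biome)[c("TF", "SF", "WF", "CF")]),
               c(90, 70, 49, 6))
  expect_lte(length(unique(cm$traits$family)), 55)
  expect_lte(length(unique(cm$traits$genus)), 116)
  expect_silent(validate_trait_table(cm$traits))
  expect_true(all(cm$records$abundance > 20))
  w <- cm$windows
  expect_true(all(w$flower_first >= 1 & w$flower_last <= 12))
  expect_true(all(w$flower_first <= w$flower_last))
  expect_true(all(w$fruit_first >= w$flower_first))
  expect_true(all(w$fruit_first <= w$fruit_last & w$fruit_last <= 12))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_community(sim_config(seed = 9))
  b <- generate_community(sim_config(seed = 9))
  expect_identical(a$traits, b$traits)
  expect_identical(a$windows, b$windows)
  c <- generate_community(sim_config(seed = 10))
  expect_false(isTRUE(all.equal(a$traits$SLA, c$traits$SLA)))
})

test_that("zero noise collapses measured-trait blocks onto the latent factors", {
  cfg <- sim_config(n_species = c(TF = 40), noise_sd = 0, seed = 3)
  cm <- generate_community(cfg)
  logt <- log10_transform(cm$traits)
  for (blockcols in list(c("LA", "LDMC", "SLA", "LNC"),
                         c("STD", "MPH", "MDBH"))) {
    m <- scale(as.matrix(logt[blockcols]), scale = FALSE)
    sv <- svd(m)$d
    # two latent factors (economics, stature) reach each measured block
    expect_lt(sv[3] / sv[1], 1e-10)
  }
})

test_that("sample trait correlations match the loadings-implied closed form", {
  cfg <- sim_config(n_species = c(TF = 500), seed = 4)
  cm <- generate_community(cfg)
  measured <- c("LA", "LDMC", "SLA", "LNC", "STD", "MPH", "MDBH")
  emp <- cor(log10(as.matrix(cm$traits[measured])))
  implied <- nichetable:::implied_trait_correlation(cfg)
  expect_lt(max(abs(emp - implied[measured, measured])), 0.1)
})

test_that("phenology windows are valid and duration tracks its latent", {
  cfg <- sim_config(seed = 6)
  set.seed(6)
  hi <- generate_phenology(cfg, rep(2, 200), "SF")
  lo <- generate_phenology(cfg, rep(-2, 200), "SF")
  for (w in list(hi, lo)) {
    expect_true(all(w$flower_first >= 1 & w$flower_last <= 12))
    expect_true(all(w$fruit_first >= w$flower_first & w$fruit_last <= 12))
  }
  dur_hi <- mean(w <- hi$flower_last - hi$flower_first)
  dur_lo <- mean(lo$flower_last - lo$flower_first)
  expect_gt(dur_hi, dur_lo)
  set.seed(8)
  w1 <- generate_phenology(cfg, rep(0.5, 10), "TF")
  set.seed(8)
  w2 <- generate_phenology(cfg, rep(0.5, 10), "TF")
  expect_identical(w1, w2)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_species = c(TF = 0)), "positive")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(n_species = c(XX = 10)), "biome")
  expect_error(sim_config(latent_shifts = list(economics = c(TF = 1))),
               "economics, stature and duration")
})

test_that("planted clusters store ground truth and honor their geometry", {
  set.seed(13)
  cm <- generate_community(small_sim(13))
  expect_error(plant_convergent_cluster(cm, 3, 5), "exceed")
  expect_error(plant_convergent_cluster(cm, 500, 2), "not enough")

  pl <- plant_convergent_cluster(cm, 5, 5, radius = 0)
  expect_length(pl$planted$species_id, 5)
  expect_equal(length(unique(pl$planted$families)), 5)
  key <- paste(pl$traits$species_id, pl$traits$biome)
  rows <- match(paste(pl$planted$species_id, pl$planted$biome), key)
  planted_traits <- as.matrix(pl$traits[rows, trait_names()])
  # radius 0: trait-identical species
  expect_equal(max(apply(planted_traits, 2, function(v) diff(range(v)))), 0)

  set.seed(14)
  cm2 <- generate_community(small_sim(13))
  pl2 <- plant_convergent_cluster(cm2, 5, 5, radius = 0.05)
  rows2 <- match(paste(pl2$planted$species_id, pl2$planted$biome),
                 paste(pl2$traits$species_id, pl2$traits$biome))
  lat2 <- as.matrix(pl2$latent[rows2, c("economics", "stature", "duration")])
  expect_lt(max(dist(lat2)), 0.05 * 2 * sqrt(3) + 1e-12)
  expect_silent(validate_trait_table(pl2$traits))
})

test_that("shrinking the planting radius shrinks niche-space spread", {
  spread <- vapply(c(0.4, 0.02), function(r) {
    set.seed(15)
    cm <- generate_community(small_sim(15))
    pl <- plant_convergent_cluster(cm, 5, 5, radius = r)
    sp <- suppressWarnings(build_niche_space(pl$traits))
    key <- paste(sp$scores$species_id, sp$scores$biome)
    rows <- match(paste(pl$planted$species_id, pl$planted$biome), key)
    max(dist(sp$scores[rows, c("PC1", "PC2")]))
  }, numeric(1))
  expect_lt(spread[2], spread[1])
})
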