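# Latent-factor community simulator. Traits are generated on the log10 scale
# from three species-level latent gradients and back-transformed, so the
# pipeline's log10 step exactly linearizes the factor model:
#
#   economics — the acquisitive/conservative axis (SLA-, LNC-, LDMC+, STD+
#               toward the conservative end; tropical communities sit there),
#   stature   — plant size and leaf size (MPH+, MDBH+, LA+; largest in the
#               tropics),
#   duration  — length of the flowering/fruiting season, expressed through
#               integer month windows (longest in the tropics).
#
# Placing STD on the economics latent and LA on the stature latent gives the
# combined niche space its two characteristic axes (SLA paired with stem
# density; leaf area paired with plant size), with biome signal on both.

#' Default log10-scale trait model
#'
#' One row per measured trait: the latent gradient it loads on, the base
#' (log10 mean), the loading and the residual noise sd at the reference
#' noise level (`noise_sd = 0.2`).
#'
#' @return Data frame with columns `trait`, `latent`, `base`, `loading`,
#'   `noise`.
#' @export
default_trait_model <- function() {
  data.frame(
    trait   = c("LA",     "LDMC",     "SLA",       "LNC",       "STD",
                "MPH",    "MDBH"),
    latent  = c("stature", "economics", "economics", "economics", "economics",
                "stature", "stature"),
    base    = c(1.60, -0.48, 2.10, 1.25, -0.22, 0.95, 1.10),
    loading = c(0.40, 0.05, -0.30, -0.12, 0.05, 0.35, 0.40),
    noise   = c(0.20, 0.05, 0.15, 0.12, 0.04, 0.06, 0.06))
}

#' Simulation configuration for four-biome communities
#'
#' Defaults emulate the sampled totals of a latitudinal four-forest design:
#' 90 + 70 + 49 + 6 = 215 woody species drawn from pools of 55 families and
#' 116 genera, with the cold-temperate community deliberately tiny so the
#' degenerate small-biome path is exercised. Biome shifts move the three
#' latent gradients monotonically from tropical to cold-temperate (tropical:
#' large leaves and stature, dense stems, low SLA, long seasons; temperate
#' the reverse) and are non-proportional across latents so the between-biome
#' structure is genuinely two-dimensional. `noise_sd` rescales all residual
#' noise relative to the reference level 0.2; at 0 the measured-trait blocks
#' collapse onto the latent factors exactly.
#'
#' @param n_species Named per-biome species counts.
#' @param family_pool,genus_pool Sizes of the abstract family (F01...) and
#'   genus (G001...) pools.
#' @param noise_sd Global residual noise level; reference 0.2.
#' @param latent_shifts Named list of per-biome latent mean shifts.
#' @param trait_model See [default_trait_model()].
#' @param phenology List: per-biome flowering peak month (`flower_peak`,
#'   the month the window is centered on; tropical seasons start earlier),
#'   sd of the species-level jitter around that peak (`peak_jitter`,
#'   months), linear month-duration links `flower_dur` / `fruit_dur`
#'   (intercept and slope on the duration latent), month noise sd at the
#'   reference level (`month_noise`), and the possible lags of the fruiting
#'   peak after the flowering peak (`fruit_lag`, months).
#' @param abundance List: `min` (smallest generated abundance, kept above
#'   the >20-individuals sampling rule), and negative-binomial `mu`, `size`
#'   for the long-tailed excess.
#' @param seed Optional seed applied by [generate_community()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_species = c(TF = 90, SF = 70, WF = 49, CF = 6),
                       family_pool = 55, genus_pool = 116,
                       noise_sd = 0.2,
                       latent_shifts = list(
                         economics = c(TF = 1.2, SF = 0.2, WF = -0.2, CF = -1.2),
                         stature   = c(TF = 1.0, SF = 0.9, WF = -0.9, CF = -1.0),
                         duration  = c(TF = 0.7, SF = 0.7, WF = -0.5, CF = -0.9)),
                       trait_model = default_trait_model(),
                       phenology = list(
                         flower_peak = c(TF = 5.5, SF = 6, WF = 6, CF = 6.5),
                         peak_jitter = 1,
                         flower_dur = c(intercept = 4, slope = 1.5),
                         fruit_dur = c(intercept = 4, slope = 1.3),
                         month_noise = 0.3,
                         fruit_lag = 1:2),
                       abundance = list(min = 21, mu = 60, size = 0.8),
                       seed = NULL) {
  if (is.null(names(n_species)) || !all(names(n_species) %in% biome_codes()))
    stop("n_species must be named with biome codes")
  if (any(n_species < 1)) stop("per-biome species counts must be positive")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(c("economics", "stature", "duration") %in% names(latent_shifts)))
    stop("latent_shifts must define economics, stature and duration")
  for (l in latent_shifts)
    if (!all(names(n_species) %in% names(l)))
      stop("latent shifts must cover every simulated biome")
  if (!all(trait_model$latent %in% c("economics", "stature")))
    stop("trait_model latents must be 'economics' or 'stature'")
  if (any(trait_model$noise < 0)) stop("trait noise must be >= 0")
  structure(list(n_species = n_species, family_pool = family_pool,
                 genus_pool = genus_pool, noise_sd = noise_sd,
                 latent_shifts = latent_shifts, trait_model = trait_model,
                 phenology = phenology, abundance = abundance, seed = seed),
            class = "sim_config")
}

# Correlation matrix among the measured traits implied by the factor model
# (log10 scale, within one biome, unit latent variance). Used to check the
# generator against its own closed form.
implied_trait_correlation <- function(config) {
  tm <- config$trait_model
  scale <- if (config$noise_sd == 0) 0 else config$noise_sd / 0.2
  k <- nrow(tm)
  cov <- matrix(0, k, k, dimnames = list(tm$trait, tm$trait))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    shared <- if (tm$latent[i] == tm$latent[j]) tm$loading[i] * tm$loading[j] else 0
    cov[i, j] <- shared + if (i == j) (tm$noise[i] * scale)^2 else 0
  }
  stats::cov2cor(cov)
}

# Deterministic part of the log10 trait matrix given latent values.
latent_to_log_traits <- function(tm, latents) {
  out <- vapply(seq_len(nrow(tm)), function(i) {
    tm$base[i] + tm$loading[i] * latents[, tm$latent[i]]
  }, numeric(nrow(latents)))
  matrix(out, nrow = nrow(latents),
         dimnames = list(NULL, tm$trait))
}

#' Generate month-level phenology windows
#'
#' Flowering duration (in months) follows a rounded linear link on the
#' duration latent. The window is centered on the biome's seasonal peak
#' month plus a species-level jitter, so the window midpoint (the mean-time
#' trait) reflects timing while the span reflects duration — the two nearly
#' orthogonal axes of phenological variation. Windows are shifted to end
#' within the year (no cross-year windows are generated); fruiting is the
#' same construction centered one to two months later, starting no earlier
#' than flowering.
#'
#' @param config A `sim_config`.
#' @param latent_duration Numeric vector of duration-latent values, one per
#'   species.
#' @param biome Single biome code (selects the seasonal peak).
#' @return Data frame: `flower_first`, `flower_last`, `fruit_first`,
#'   `fruit_last` (month indices, first <= last).
#' @export
generate_phenology <- function(config, latent_duration, biome) {
  ph <- config$phenology
  n <- length(latent_duration)
  scale <- config$noise_sd / 0.2
  m_noise <- ph$month_noise * scale
  clamp_dur <- function(d) pmax(1L, pmin(12L, as.integer(round(d))))
  d_f <- clamp_dur(ph$flower_dur["intercept"] +
                   ph$flower_dur["slope"] * latent_duration +
                   stats::rnorm(n, 0, m_noise))
  peak <- ph$flower_peak[[biome]] + stats::rnorm(n, 0, ph$peak_jitter)
  f_start <- as.integer(pmax(1L, pmin(13L - d_f,
                                      round(peak - (d_f - 1) / 2))))
  d_r <- clamp_dur(ph$fruit_dur["intercept"] +
                   ph$fruit_dur["slope"] * latent_duration +
                   stats::rnorm(n, 0, m_noise))
  lag <- ph$fruit_lag[sample.int(length(ph$fruit_lag), n, replace = TRUE)]
  # fruiting keeps its own timing jitter: maturation is not locked to anthesis
  r_peak <- ph$flower_peak[[biome]] + lag + stats::rnorm(n, 0, ph$peak_jitter)
  r_start <- as.integer(pmax(f_start, pmin(13L - d_r,
                                           round(r_peak - (d_r - 1) / 2))))
  d_r <- pmin(d_r, 13L - r_start)
  data.frame(flower_first = f_start,
             flower_last = as.integer(f_start + d_f - 1L),
             fruit_first = r_start,
             fruit_last = as.integer(r_start + d_r - 1L))
}

#' Generate a four-biome synthetic community
#'
#' Draws species-level latents (biome shift + standard normal), builds the
#' measured traits on the log10 scale and back-transforms, generates
#' phenology windows and derives the four Julian-date traits, assigns
#' abundances (all above the >20-individuals sampling rule) and random
#' genus/family labels from abstract pools — so niche-similar species are
#' frequently from distant families, the situation in which convergence is
#' detectable. Rows violating trait-table invariants (an LDMC draw above 1)
#' are resampled, never clipped. Fully deterministic under `config$seed`.
#'
#' @param config A `sim_config`.
#' @return Object of class `synthetic_community`: `records` (species, taxon
#'   and abundance table), `traits` (a `trait_table`), `windows` (month
#'   windows), `latent` (ground-truth latent values per species) and
#'   `config`.
#' @export
generate_community <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tm <- config$trait_model
  scale <- config$noise_sd / 0.2
  families <- sprintf("F%02d", seq_len(config$family_pool))
  genera <- sprintf("G%03d", seq_len(config$genus_pool))
  genus_family <- stats::setNames(
    families[sample.int(config$family_pool, config$genus_pool, replace = TRUE)],
    genera)
  total <- sum(config$n_species)
  ids <- sprintf("sp%03d", seq_len(total))
  offset <- 0L
  records <- traits <- windows <- latent <- NULL
  for (b in names(config$n_species)) {
    n <- config$n_species[[b]]
    idx <- offset + seq_len(n)
    offset <- offset + n
    lat <- cbind(
      economics = config$latent_shifts$economics[[b]] + stats::rnorm(n),
      stature   = config$latent_shifts$stature[[b]] + stats::rnorm(n),
      duration  = config$latent_shifts$duration[[b]] + stats::rnorm(n))
    noise <- matrix(stats::rnorm(n * nrow(tm)), nrow = n) *
      rep(tm$noise * scale, each = n)
    log_traits <- latent_to_log_traits(tm, lat) + noise
    # resample LDMC noise for any draw implying a dry:fresh ratio > 1
    ldmc_i <- which(tm$trait == "LDMC")
    for (iter in seq_len(100)) {
      bad <- which(log_traits[, "LDMC"] > 0)
      if (!length(bad)) break
      log_traits[bad, "LDMC"] <- tm$base[ldmc_i] +
        tm$loading[ldmc_i] * lat[bad, tm$latent[ldmc_i]] +
        stats::rnorm(length(bad), 0, tm$noise[ldmc_i] * scale)
      if (iter == 100) stop("could not resample LDMC into (0, 1]")
    }
    win <- generate_phenology(config, lat[, "duration"], b)
    flower <- phenology_stats(win$flower_first, win$flower_last)
    fruit <- phenology_stats(win$fruit_first, win$fruit_last)
    gen <- genera[sample.int(config$genus_pool, n, replace = TRUE)]
    rec <- data.frame(
      species_id = ids[idx], biome = b, family = unname(genus_family[gen]),
      genus = gen,
      abundance = config$abundance$min +
        stats::rnbinom(n, size = config$abundance$size,
                       mu = config$abundance$mu))
    tr <- cbind(rec[c("species_id", "biome", "family", "genus")],
                as.data.frame(10^log_traits),
                FLT = flower$mean_time, FRT = fruit$mean_time,
                FLD = flower$duration, FRD = fruit$duration)
    records <- rbind(records, rec)
    traits <- rbind(traits, tr)
    windows <- rbind(windows, cbind(rec[c("species_id", "biome")], win))
    latent <- rbind(latent, cbind(rec[c("species_id", "biome")],
                                  as.data.frame(lat)))
  }
  structure(list(records = records, traits = trait_table(traits),
                 windows = windows, latent = latent, config = config),
            class = "synthetic_community")
}

#' Plant a convergent cluster of known truth
#'
#' Moves `n_species` community members to (within `radius` of) a common
#' target point in latent space, regenerates their traits deterministically
#' from the perturbed latents (no residual noise, fixed phenology link) and
#' reassigns their families across `n_families` distinct labels, preferring
#' families unused elsewhere in the community. After the full pipeline the
#' planted species co-locate in niche space, so the convergence ratio of
#' their plot is known by construction (`n_families / n_species` when no
#' other species shares the plot). With `radius = 0` the planted species are
#' trait-identical and necessarily share one grid cell.
#'
#' @param community A `synthetic_community`.
#' @param n_species Number of species to plant (`n_families <= n_species`).
#' @param n_families Number of distinct families among them.
#' @param radius Uniform perturbation half-width applied to each latent
#'   coordinate; default 0 (exact co-location).
#' @param target Latent target point, named (economics, stature, duration).
#'   The default sits on the community periphery so the planted plot is
#'   unlikely to pick up bystander species.
#' @return The modified `synthetic_community`, with a `planted` element
#'   recording species ids, families, target and radius.
#' @export
plant_convergent_cluster <- function(community, n_species, n_families,
                                     radius = 0,
                                     target = c(economics = 3, stature = 3,
                                                duration = 1.5)) {
  stopifnot(inherits(community, "synthetic_community"))
  if (n_families > n_species)
    stop("n_families cannot exceed n_species")
  if (n_species > nrow(community$traits))
    stop("not enough species in the community to plant the cluster")
  if (radius < 0) stop("radius must be >= 0")
  tm <- community$config$trait_model
  pick <- sample.int(nrow(community$traits), n_species)
  lat <- matrix(rep(target[c("economics", "stature", "duration")],
                    each = n_species), nrow = n_species,
                dimnames = list(NULL, c("economics", "stature", "duration")))
  if (radius > 0)
    lat <- lat + matrix(stats::runif(n_species * 3, -radius, radius),
                        nrow = n_species)
  log_traits <- latent_to_log_traits(tm, as.data.frame(lat))
  colnames(log_traits) <- tm$trait
  ph <- community$config$phenology
  d_f <- pmax(1L, pmin(12L, as.integer(round(
    ph$flower_dur["intercept"] + ph$flower_dur["slope"] * lat[, "duration"]))))
  d_r <- pmax(1L, pmin(12L, as.integer(round(
    ph$fruit_dur["intercept"] + ph$fruit_dur["slope"] * lat[, "duration"]))))
  f_start <- pmin(4L, 13L - d_f)
  r_start <- pmin(f_start + 1L, pmax(f_start, 13L - d_r))
  d_r <- pmin(d_r, 13L - r_start)
  win <- data.frame(flower_first = f_start, flower_last = f_start + d_f - 1L,
                    fruit_first = r_start, fruit_last = r_start + d_r - 1L)
  flower <- phenology_stats(win$flower_first, win$flower_last)
  fruit <- phenology_stats(win$fruit_first, win$fruit_last)
  used <- unique(community$traits$family[-pick])
  pool <- sprintf("F%02d", seq_len(community$config$family_pool))
  avail <- c(setdiff(pool, used), setdiff(pool, character(0)))
  fam <- unique(avail)[seq_len(n_families)]
  fam_assign <- rep(fam, length.out = n_species)
  tr <- community$traits
  tr[pick, tm$trait] <- 10^log_traits
  tr$FLT[pick] <- flower$mean_time; tr$FLD[pick] <- flower$duration
  tr$FRT[pick] <- fruit$mean_time; tr$FRD[pick] <- fruit$duration
  tr$family[pick] <- fam_assign
  community$records$family[pick] <- fam_assign
  community$windows[pick, c("flower_first", "flower_last",
                            "fruit_first", "fruit_last")] <- win
  community$latent[pick, c("economics", "stature", "duration")] <- lat
  community$traits <- trait_table(as.data.frame(tr))
  community$planted <- list(
    species_id = community$traits$species_id[pick],
    biome = community$traits$biome[pick],
    families = fam_assign, target = target, radius = radius)
  community
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "Synthetic community: %d species in %d biome(s), %d families%s\n",
    nrow(x$traits), length(unique(x$traits$biome)),
    length(unique(x$traits$family)),
    if (!is.null(x$planted))
      sprintf("; planted cluster of %d", length(x$planted$species_id)) else ""))
  invisible(x)
}
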