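# Delimited-text I/O and the end-to-end pipeline driver. All artifacts are
# plain tab-separated tables plus one JSON manifest, so every run is
# reproducible from the manifest alone.

.raw_columns <- c("species_id", "family", "genus", "biome", "abundance",
                  "la_cm2", "ldmc", "sla_cm2_g", "lnc_g_kg", "std_g_cm3",
                  "mph_m", "mdbh_cm", "flower_first_month",
                  "flower_last_month", "fruit_first_month",
                  "fruit_last_month")

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a species trait table from delimited text
#'
#' Reads the canonical input schema (comma- or tab-separated, auto-detected
#' from the header): identifiers (`species_id`, `family`, `genus`, `biome`),
#' `abundance`, the seven measured traits with units in the column names
#' (`la_cm2`, `ldmc`, `sla_cm2_g`, `lnc_g_kg`, `std_g_cm3`, `mph_m`,
#' `mdbh_cm`) and the month-level phenology windows (`flower_first_month`,
#' ..., `fruit_last_month`). The four Julian-date phenology traits are
#' derived on load with [phenology_stats()], and all trait-table invariants
#' are enforced.
#'
#' @param path File path.
#' @param drop_invalid Drop rows that violate an invariant (reporting how
#'   many) instead of rejecting the file; default `FALSE`.
#' @param allow_wraparound Accept cross-year phenology windows; default
#'   `FALSE`.
#' @return List: `traits` (a `trait_table`), `records` (species, taxonomy
#'   and abundance), `n_dropped`.
#' @export
read_trait_table <- function(path, drop_invalid = FALSE,
                             allow_wraparound = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), .raw_columns)
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.raw_columns, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))

  row_ok <- rep(TRUE, nrow(df))
  note <- function(bad, why) {
    if (any(bad & row_ok))
      message(sprintf("dropping %d row(s): %s", sum(bad & row_ok), why))
    row_ok <<- row_ok & !bad
  }
  month_ok <- function(v) is.finite(v) & v >= 1 & v <= 12 & v == round(v)
  checks <- list(
    list(with(df, !is.finite(la_cm2) | la_cm2 <= 0 | !is.finite(sla_cm2_g) |
                sla_cm2_g <= 0 | !is.finite(lnc_g_kg) | lnc_g_kg <= 0 |
                !is.finite(std_g_cm3) | std_g_cm3 <= 0 | !is.finite(mph_m) |
                mph_m <= 0 | !is.finite(mdbh_cm) | mdbh_cm <= 0),
         "non-positive measured trait"),
    list(with(df, !is.finite(ldmc) | ldmc <= 0 | ldmc > 1),
         "dry-matter content outside (0, 1]"),
    list(!month_ok(df$flower_first_month) | !month_ok(df$flower_last_month) |
           !month_ok(df$fruit_first_month) | !month_ok(df$fruit_last_month),
         "invalid phenology month"),
    list(!is.element(df$biome, biome_codes()), "unknown biome code"))
  if (!allow_wraparound)
    checks <- c(checks, list(
      list(month_ok(df$flower_first_month) & month_ok(df$flower_last_month) &
             month_ok(df$fruit_first_month) & month_ok(df$fruit_last_month) &
             (df$flower_last_month < df$flower_first_month |
              df$fruit_last_month < df$fruit_first_month),
           "cross-year phenology window")))
  for (chk in checks) {
    bad <- chk[[1]] %in% TRUE
    if (any(bad) && !drop_invalid) {
      i <- which(bad)[1]
      stop(sprintf("row %d (species '%s'): %s", i, df$species_id[i],
                   chk[[2]]))
    }
    note(bad, chk[[2]])
  }
  n_dropped <- sum(!row_ok)
  df <- df[row_ok, , drop = FALSE]
  if (!nrow(df)) stop("no valid rows left after validation")

  flower <- phenology_stats(df$flower_first_month, df$flower_last_month,
                            allow_wraparound)
  fruit <- phenology_stats(df$fruit_first_month, df$fruit_last_month,
                           allow_wraparound)
  traits <- data.frame(
    species_id = df$species_id, biome = df$biome, family = df$family,
    genus = df$genus,
    LA = df$la_cm2, LDMC = df$ldmc, SLA = df$sla_cm2_g, LNC = df$lnc_g_kg,
    STD = df$std_g_cm3, MPH = df$mph_m, MDBH = df$mdbh_cm,
    FLT = flower$mean_time, FRT = fruit$mean_time,
    FLD = flower$duration, FRD = fruit$duration)
  list(traits = trait_table(traits),
       records = df[c("species_id", "family", "genus", "biome", "abundance")],
       n_dropped = n_dropped)
}

#' Write a community in the canonical input schema
#'
#' Writes the month-level delimited format that [read_trait_table()] reads,
#' so a simulated community round-trips through the same ingestion path as
#' field data.
#'
#' @param community A `synthetic_community`, or a list with `traits`,
#'   `records` and `windows` components.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(community, path) {
  tr <- community$traits
  rec <- community$records
  win <- community$windows
  df <- data.frame(
    species_id = tr$species_id, family = tr$family, genus = tr$genus,
    biome = tr$biome,
    abundance = rec$abundance[match(paste(tr$species_id, tr$biome),
                                    paste(rec$species_id, rec$biome))],
    la_cm2 = tr$LA, ldmc = tr$LDMC, sla_cm2_g = tr$SLA, lnc_g_kg = tr$LNC,
    std_g_cm3 = tr$STD, mph_m = tr$MPH, mdbh_cm = tr$MDBH,
    flower_first_month = win$flower_first, flower_last_month = win$flower_last,
    fruit_first_month = win$fruit_first, fruit_last_month = win$fruit_last)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param input Path to a trait table in the canonical schema, or `NULL` to
#'   simulate a community with `sim`.
#' @param sim A `sim_config` used when `input` is `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param width Niche-plot side in PC-score units; default 0.5.
#' @param k Number of central plots; default 8.
#' @param alpha Significance level for biome contrasts; default 0.05.
#' @param p_adjust Multiplicity adjustment for pairwise contrasts.
#' @param min_abundance Strict abundance threshold for inclusion.
#' @param seed Seed applied before any random step.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, sim = sim_config(), out_dir = tempfile(),
                       width = 0.5, k = 8, alpha = 0.05, p_adjust = "holm",
                       min_abundance = 20, seed = 1) {
  if (width <= 0) stop("width must be positive")
  if (k < 1) stop("k must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(input = input, sim = sim, out_dir = out_dir, width = width,
                 k = k, alpha = alpha, p_adjust = p_adjust,
                 min_abundance = min_abundance, seed = seed),
            class = "run_config")
}

#' Run the full niche analysis pipeline
#'
#' Simulates (or reads) a community, applies the abundance filter, builds a
#' niche space and convergence report per biome with at least three species,
#' builds the combined all-biome space, compares biome niche scores on PC1
#' and PC2, and writes every artifact plus a JSON manifest (configuration,
#' seed, input checksum, file list) to the output directory. Identical
#' configuration yields bit-identical outputs.
#'
#' @param config A `run_config`.
#' @return Invisible list: `community` or input tables, `spaces` (per biome),
#'   `combined`, `convergence` (per biome + combined), `comparison`,
#'   `manifest`, `files`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(df, path)
    files <<- c(files, path)
    path
  }
  if (is.null(config$input)) {
    sim <- config$sim
    sim$seed <- config$seed
    community <- generate_community(sim)
    input_path <- file.path(config$out_dir, "traits.tsv")
    write_trait_table(community, input_path)
    files <- c(files, input_path)
    traits <- community$traits
    records <- community$records
  } else {
    community <- NULL
    input_path <- config$input
    loaded <- read_trait_table(config$input, drop_invalid = TRUE)
    traits <- loaded$traits
    records <- loaded$records
  }
  kept <- abundance_filter(records, config$min_abundance)
  n_drop <- nrow(records) - nrow(kept)
  if (n_drop > 0)
    message(sprintf("abundance filter (> %d individuals): dropped %d species",
                    config$min_abundance, n_drop))
  keep_key <- paste(kept$species_id, kept$biome)
  traits <- traits[paste(traits$species_id, traits$biome) %in% keep_key, ,
                   drop = FALSE]
  class(traits) <- c("trait_table", "data.frame")

  spaces <- list()
  convergence <- list()
  for (b in intersect(biome_codes(), unique(traits$biome))) {
    sub <- traits[traits$biome == b, , drop = FALSE]
    if (nrow(sub) < 3) {
      message(sprintf("biome %s: only %d species, niche space skipped",
                      b, nrow(sub)))
      next
    }
    space <- suppressWarnings(build_niche_space(sub))
    spaces[[b]] <- space
    summ <- summarize_space(space)
    emit(summ$dimensions, sprintf("dimensions_%s.tsv", b))
    emit(summ$space, sprintf("space_%s.tsv", b))
    emit(space$scores, sprintf("scores_%s.tsv", b))
    conv <- convergence_report(space, config$width, config$k)
    convergence[[b]] <- conv
    emit(conv$plots, sprintf("convergence_%s.tsv", b))
  }
  combined <- NULL
  comparison <- NULL
  if (length(unique(traits$biome)) >= 2) {
    combined <- build_niche_space(traits)
    summ <- summarize_space(combined)
    emit(summ$dimensions, "dimensions_combined.tsv")
    emit(summ$space, "space_combined.tsv")
    emit(combined$scores, "scores_combined.tsv")
    conv <- convergence_report(combined, config$width, config$k)
    convergence$combined <- conv
    emit(conv$plots, "convergence_combined.tsv")
    comparison <- biome_comparison(combined, alpha = config$alpha,
                                   p_adjust = config$p_adjust)
    emit(comparison$table, "comparison.tsv")
  }
  manifest <- list(
    package = "nichetable",
    version = as.character(utils::packageVersion("nichetable")),
    seed = config$seed,
    width = config$width, k = config$k, alpha = config$alpha,
    p_adjust = config$p_adjust, min_abundance = config$min_abundance,
    simulated = is.null(config$input),
    input = basename(input_path),
    input_md5 = unname(tools::md5sum(input_path)),
    n_species = nrow(traits),
    n_dropped_abundance = n_drop,
    biomes = unique(traits$biome),
    files = basename(files))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(community = community, traits = traits, spaces = spaces,
                 combined = combined, convergence = convergence,
                 comparison = comparison, manifest = manifest,
                 files = c(files, manifest_path)))
}
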