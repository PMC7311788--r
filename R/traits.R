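# Trait data model: 11 traits in 3 niche dimensions, keyed by (species, biome).

#' Trait and biome vocabularies
#'
#' `trait_names()` returns the eleven trait codes in canonical order:
#' leaf area (LA, cm2), leaf dry-matter content (LDMC, g/g), specific leaf
#' area (SLA, cm2/g), leaf nitrogen concentration (LNC, g/kg), stem tissue
#' density (STD, g/cm3), maximum plant height (MPH, m, 95th percentile),
#' maximum diameter at breast height (MDBH, cm, 95th percentile), mean
#' flowering/fruiting time (FLT/FRT, Julian day) and flowering/fruiting
#' duration (FLD/FRD, days). `biome_codes()` returns the four biome codes:
#' TF (tropical rainforest), SF (subtropical evergreen-deciduous mixed
#' forest), WF (warm-temperate coniferous-broadleaved mixed forest), CF
#' (cold-temperate coniferous forest).
#'
#' @return Character vector of codes.
#' @export
trait_names <- function() {
  c("LA", "LDMC", "SLA", "LNC", "STD", "MPH", "MDBH",
    "FLT", "FRT", "FLD", "FRD")
}

#' @rdname trait_names
#' @export
biome_codes <- function() c("TF", "SF", "WF", "CF")

#' Default grouping of traits into niche dimensions
#'
#' Leaf economy carries the resource-acquisition traits, mechanical support
#' the stem and size traits, reproductive phenology the four Julian-date
#' traits. Each principal-component stage runs within one dimension, so every
#' dimension must keep at least two traits.
#'
#' @return Named list mapping dimension name to a character vector of traits.
#' @export
default_dimension_scheme <- function() {
  list(
    leaf_economy           = c("LA", "LDMC", "SLA", "LNC"),
    mechanical_support     = c("STD", "MPH", "MDBH"),
    reproductive_phenology = c("FLT", "FRT", "FLD", "FRD")
  )
}

#' Validate a dimension scheme
#'
#' @param scheme Named list of trait-name character vectors.
#' @param traits Trait codes that must be covered exactly once.
#' @return The scheme, invisibly, or an error.
#' @export
validate_dimension_scheme <- function(scheme, traits = trait_names()) {
  if (!is.list(scheme) || is.null(names(scheme)) || any(names(scheme) == ""))
    stop("dimension scheme must be a named list of trait vectors")
  all_traits <- unlist(scheme, use.names = FALSE)
  dup <- all_traits[duplicated(all_traits)]
  if (length(dup))
    stop("trait(s) mapped to more than one dimension: ",
         paste(unique(dup), collapse = ", "))
  missing <- setdiff(traits, all_traits)
  if (length(missing))
    stop("trait(s) not mapped to any dimension: ",
         paste(missing, collapse = ", "))
  small <- names(scheme)[vapply(scheme, length, 1L) < 2L]
  if (length(small))
    stop("dimension(s) with fewer than 2 traits (PCA needs >= 2): ",
         paste(small, collapse = ", "))
  invisible(scheme)
}

#' Leaf dry-matter content
#'
#' Ratio of leaf dry mass to fresh mass, in g per g.
#'
#' @param dry_mass Leaf dry mass (g), positive, no greater than `fresh_mass`.
#' @param fresh_mass Leaf fresh mass (g), positive.
#' @return LDMC in (0, 1]. Vectorized.
#' @export
leaf_dry_matter_content <- function(dry_mass, fresh_mass) {
  if (any(!is.finite(fresh_mass)) || any(fresh_mass <= 0))
    stop("fresh_mass must be positive")
  if (any(!is.finite(dry_mass)) || any(dry_mass <= 0))
    stop("dry_mass must be positive")
  if (any(dry_mass > fresh_mass))
    stop("dry_mass cannot exceed fresh_mass")
  dry_mass / fresh_mass
}

#' Specific leaf area
#'
#' Ratio of one-sided leaf area to leaf dry mass, in cm2 per g.
#'
#' @param leaf_area Leaf area (cm2), positive.
#' @param dry_mass Leaf dry mass (g), positive.
#' @return SLA (cm2/g). Vectorized.
#' @export
specific_leaf_area <- function(leaf_area, dry_mass) {
  if (any(!is.finite(leaf_area)) || any(leaf_area <= 0))
    stop("leaf_area must be positive")
  if (any(!is.finite(dry_mass)) || any(dry_mass <= 0))
    stop("dry_mass must be positive")
  leaf_area / dry_mass
}

#' Stem tissue density
#'
#' Branch-segment dry mass divided by fresh volume, in g per cm3.
#'
#' @param dry_mass Segment dry mass (g), positive.
#' @param fresh_volume Segment fresh volume (cm3), positive.
#' @return STD (g/cm3). Vectorized.
#' @export
stem_tissue_density <- function(dry_mass, fresh_volume) {
  if (any(!is.finite(dry_mass)) || any(dry_mass <= 0))
    stop("dry_mass must be positive")
  if (any(!is.finite(fresh_volume)) || any(fresh_volume <= 0))
    stop("fresh_volume must be positive")
  dry_mass / fresh_volume
}

#' Size percentile for maximum height / diameter traits
#'
#' Maximum plant height and maximum DBH are summarized as the 95th percentile
#' over the individuals of a species, requiring at least `min_n` individuals.
#' The quantile convention is linear interpolation between order statistics at
#' position 1 + (n - 1) p (R's default, type 7).
#'
#' @param values Positive individual measurements (m for height, cm for DBH).
#' @param percentile Percentile in (0, 100]; default 95.
#' @param min_n Minimum number of individuals required; default 20.
#' @return The percentile value. With fewer than `min_n` values an error of
#'   class `"nichetable_underivable"` is signalled so the caller can flag the
#'   species and decide on exclusion.
#' @export
size_percentile <- function(values, percentile = 95, min_n = 20) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("size measurements must be positive")
  if (length(values) < min_n) {
    cond <- structure(
      class = c("nichetable_underivable", "error", "condition"),
      list(message = sprintf(
        "trait underivable: %d individuals measured, %d required",
        length(values), min_n), call = sys.call(-1)))
    stop(cond)
  }
  unname(stats::quantile(values, probs = percentile / 100, type = 7))
}

#' Filter species records by abundance
#'
#' Keeps only records with abundance strictly greater than `min_abundance`
#' (the sampling rule: species with more than 20 individuals across the 50
#' plots of a site). Input order is preserved; an empty result is legal.
#'
#' @param records Data frame with an `abundance` column.
#' @param min_abundance Strict lower bound; default 20.
#' @return The retained subset of `records`.
#' @export
abundance_filter <- function(records, min_abundance = 20) {
  if (!is.data.frame(records) || is.null(records$abundance))
    stop("records must be a data frame with an 'abundance' column")
  records[records$abundance > min_abundance, , drop = FALSE]
}

#' Log10-transform trait values
#'
#' Trait data are log10-transformed before ordination to linearize the
#' multiplicative trait scales. All entries must be strictly positive; a zero
#' or negative entry is reported with its (species, trait) location.
#'
#' @param x A `trait_table`, or a numeric matrix / data frame.
#' @return Object of the same shape with trait values replaced by their
#'   base-10 logarithms.
#' @export
log10_transform <- function(x) {
  if (inherits(x, "trait_table")) {
    cols <- trait_names()
    m <- as.matrix(x[cols])
    bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf(
        "non-positive trait value at species '%s' (%s), trait %s",
        x$species_id[bad[1, 1]], x$biome[bad[1, 1]], cols[bad[1, 2]]))
    x[cols] <- log10(m)
    attr(x, "log10") <- TRUE
    return(x)
  }
  m <- as.matrix(x)
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive value at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  out <- log10(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Construct and validate a species-by-trait table
#'
#' A `trait_table` is a data frame keyed by (species_id, biome) with the
#' taxonomy columns `family` and `genus` and the eleven trait columns of
#' [trait_names()]. Invariants enforced: unique (species_id, biome) pairs
#' (a species measured at two sites enters once per site), known biome codes,
#' strictly positive traits, LDMC in (0, 1], Julian times in 1..365 and
#' durations in 0..364, no missing cells.
#'
#' @param df Data frame with columns `species_id`, `biome`, `family`,
#'   `genus` and all of [trait_names()].
#' @return `df` with class `trait_table` prepended.
#' @export
trait_table <- function(df) {
  required <- c("species_id", "biome", "family", "genus", trait_names())
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trait table lacks column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[
    , c(required, setdiff(names(df), required)), drop = FALSE]
  class(df) <- c("trait_table", "data.frame")
  validate_trait_table(df)
  df
}

#' @rdname trait_table
#' @param x A `trait_table`.
#' @export
validate_trait_table <- function(x) {
  stopifnot(is.data.frame(x))
  key <- paste(x$species_id, x$biome, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (species_id, biome) pair: ",
         sub("\r", " / ", key[duplicated(key)][1]))
  bad_biome <- setdiff(unique(x$biome), biome_codes())
  if (length(bad_biome))
    stop("unknown biome code(s): ", paste(bad_biome, collapse = ", "))
  check <- function(col, ok, what) {
    v <- x[[col]]
    bad <- which(!is.finite(v) | !ok(v))
    if (length(bad))
      stop(sprintf("invalid %s for species '%s' (%s): %s = %s",
                   what, x$species_id[bad[1]], x$biome[bad[1]], col,
                   format(v[bad[1]])))
  }
  for (col in trait_names()) check(col, function(v) v > 0, "trait value")
  check("LDMC", function(v) v <= 1, "dry-matter ratio (must be <= 1)")
  for (col in c("FLT", "FRT"))
    check(col, function(v) v >= 1 & v <= 365, "Julian day")
  for (col in c("FLD", "FRD"))
    check(col, function(v) v >= 0 & v <= 364, "duration")
  invisible(x)
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("Trait table: %d species-by-site rows, %d biome(s), %d families\n",
              nrow(x), length(unique(x$biome)), length(unique(x$family))))
  NextMethod()
}
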