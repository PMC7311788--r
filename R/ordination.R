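# The nested ordination: one standardized PCA per niche dimension, then a
# second PCA on the six PC1/PC2 score columns. The second-stage space is the
# "periodic table" in which species niches are compared.

#' First-stage PCA per niche dimension
#'
#' Runs one correlation-scale PCA on each dimension's log10-transformed trait
#' block and assembles the six species-score gradients (PC1 and PC2 of each
#' dimension) that feed the second-stage ordination. Each gradient is
#' annotated with its dominant trait (largest absolute loading).
#'
#' @param traits_log A `trait_table` already passed through
#'   [log10_transform()].
#' @param scheme Dimension scheme, see [default_dimension_scheme()].
#' @return Object of class `dimension_pca`: `results` (named list of
#'   `pca_result`, one per dimension), `gradients` (data frame: `species_id`,
#'   `biome`, `family`, `genus`, then `pc1.<dim>` / `pc2.<dim>` columns) and
#'   `dominant` (named character vector of dominant traits per gradient).
#' @export
dimension_pca <- function(traits_log, scheme = default_dimension_scheme()) {
  if (!isTRUE(attr(traits_log, "log10")))
    stop("traits must be log10-transformed first (see log10_transform)")
  validate_dimension_scheme(scheme)
  gradients <- traits_log[c("species_id", "biome", "family", "genus")]
  results <- list()
  dominant <- character(0)
  for (dim_name in names(scheme)) {
    block <- as.matrix(traits_log[scheme[[dim_name]]])
    res <- niche_pca(block, standardize = TRUE)
    results[[dim_name]] <- res
    for (k in 1:2) {
      col <- sprintf("pc%d.%s", k, dim_name)
      gradients[[col]] <- res$scores[, k]
      dominant[[col]] <- dominant_variable(res, k)
    }
  }
  structure(list(results = results, gradients = gradients,
                 dominant = dominant),
            class = "dimension_pca")
}

#' Second-stage PCA: the niche space
#'
#' The six dimension gradients (PC1/PC2 of leaf economy, mechanical support
#' and reproductive phenology), standardized to unit variance, enter a second
#' PCA whose first two axes define the continuous niche space. Because the
#' six inputs are standardized, each eigenvalue divided by six is the
#' fraction of niche variance on that axis.
#'
#' @param gradients A `dimension_pca` object, or its `gradients` data frame
#'   (six aligned `pc*.*` columns plus id columns).
#' @return Object of class `niche_space`: `scores` (data frame `species_id`,
#'   `biome`, `family`, `genus`, `PC1`, `PC2`, ...), `eigenvalues`,
#'   `percent_variance`, `loadings` (unit eigenvectors of the six gradients),
#'   `loadings_scaled` (eigenvectors scaled by the square root of their
#'   eigenvalue, the display convention of ordination biplots),
#'   `dominant_gradient` per axis, `gradient_names`, `dimensions` (the
#'   first-stage results when available), `biomes`, `n_species`.
#' @export
pca_of_pcas <- function(gradients) {
  dims <- NULL
  dominant_traits <- NULL
  if (inherits(gradients, "dimension_pca")) {
    dims <- gradients$results
    dominant_traits <- gradients$dominant
    gradients <- gradients$gradients
  }
  grad_cols <- grep("^pc[12]\\.", names(gradients), value = TRUE)
  if (length(grad_cols) < 2)
    stop("gradients must contain pc1./pc2. score columns")
  block <- as.matrix(gradients[grad_cols])
  if (anyNA(block)) {
    bad <- unique(gradients$species_id[!stats::complete.cases(block)])
    stop("species with incomplete gradient scores: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  res <- niche_pca(block, standardize = TRUE)
  scores <- gradients[intersect(
    c("species_id", "biome", "family", "genus"), names(gradients))]
  scores <- cbind(scores, as.data.frame(res$scores))
  dominant_gradient <- vapply(
    seq_along(res$eigenvalues),
    function(k) dominant_variable(res, k), character(1))
  structure(list(
    scores           = scores,
    eigenvalues      = res$eigenvalues,
    percent_variance = res$percent_variance,
    loadings         = res$rotation,
    loadings_scaled  = res$rotation %*% diag(sqrt(res$eigenvalues)),
    dominant_gradient = dominant_gradient,
    gradient_names   = grad_cols,
    dominant_trait   = dominant_traits,
    dimensions       = dims,
    biomes           = unique(gradients$biome),
    n_species        = nrow(gradients)
  ), class = "niche_space")
}

#' Build a niche space from a raw trait table
#'
#' Convenience pipeline: validate, log10-transform, run the per-dimension
#' PCAs, then the second-stage PCA. With fewer species than the six gradient
#' columns (the degenerate small-biome case) the trailing zero eigenvalues
#' are reported and a warning is raised.
#'
#' @param traits A `trait_table` (raw scale).
#' @param scheme Dimension scheme.
#' @return A `niche_space`.
#' @export
build_niche_space <- function(traits, scheme = default_dimension_scheme()) {
  validate_trait_table(traits)
  if (nrow(traits) < 7)
    warning(sprintf(
      "only %d species: fewer observations than second-stage variables, %s",
      nrow(traits), "trailing eigenvalues will be zero"))
  dp <- dimension_pca(log10_transform(traits), scheme)
  pca_of_pcas(dp)
}

#' Pool per-biome trait tables into the combined niche space
#'
#' Rows are concatenated across biomes (a species measured at two sites keeps
#' one row per site) and the full pipeline runs once on the pooled table, so
#' all species are ordinated in one common space with biome labels retained.
#'
#' @param tables A list of `trait_table`s (or a single pooled one).
#' @param scheme Dimension scheme.
#' @return A `niche_space` covering all biomes.
#' @export
combined_space <- function(tables, scheme = default_dimension_scheme()) {
  if (inherits(tables, "trait_table")) tables <- list(tables)
  if (length(tables) < 1) stop("no trait tables supplied")
  cols <- lapply(tables, names)
  if (length(unique(vapply(cols, paste, character(1), collapse = "\r"))) > 1)
    stop("trait tables have mismatched columns and cannot be pooled")
  pooled <- do.call(rbind, lapply(tables, as.data.frame))
  build_niche_space(trait_table(pooled), scheme)
}

#' Summary tables for a niche space
#'
#' Emits the two standard report shapes: a per-dimension table (percent
#' variance of PC1/PC2 and the dominant trait of each axis, one row pair per
#' niche dimension) and a space-level table (second-stage eigenvalues,
#' percent variance, and the loadings of the six input gradients on each
#' axis in both unit-eigenvector and sqrt-eigenvalue-scaled conventions,
#' with the dominant entries flagged).
#'
#' @param space A `niche_space` built through [build_niche_space()] (the
#'   first-stage results must be attached for the per-dimension table).
#' @param axes How many second-stage axes to report; default 2.
#' @return List with data frames `dimensions` and `space`.
#' @export
summarize_space <- function(space, axes = 2) {
  stopifnot(inherits(space, "niche_space"))
  dim_tab <- NULL
  if (!is.null(space$dimensions)) {
    dim_tab <- do.call(rbind, lapply(names(space$dimensions), function(d) {
      r <- space$dimensions[[d]]
      data.frame(dimension = d, axis = c("PC1", "PC2"),
                 percent = r$percent_variance[1:2],
                 major_eigenvector = c(dominant_variable(r, 1),
                                       dominant_variable(r, 2)))
    }))
  }
  k <- seq_len(min(axes, length(space$eigenvalues)))
  space_tab <- data.frame(quantity = c("eigenvalue", "percent",
                                       space$gradient_names))
  for (j in k) {
    unit <- space$loadings[, j]
    top <- abs(unit) >= max(abs(unit)) - 1e-6
    space_tab[[paste0("PC", j)]] <-
      c(space$eigenvalues[j], space$percent_variance[j], unit)
    space_tab[[paste0("PC", j, "_scaled")]] <-
      c(NA, NA, space$loadings_scaled[, j])
    space_tab[[paste0("PC", j, "_dominant")]] <- c(NA, NA, top)
  }
  list(dimensions = dim_tab, space = space_tab)
}

#' @export
print.niche_space <- function(x, ...) {
  cat(sprintf("Niche space: %d species, biome(s) %s\n", x$n_species,
              paste(x$biomes, collapse = ", ")))
  cat(sprintf("  PC1 %.2f%% (%s), PC2 %.2f%% (%s)\n",
              x$percent_variance[1], x$dominant_gradient[1],
              x$percent_variance[2], x$dominant_gradient[2]))
  invisible(x)
}
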