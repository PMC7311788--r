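# Niche periodicity: bin the niche space into fixed-width square plots and
# score each occupied plot by its family-to-species convergence ratio. A
# ratio of 1 means every species sharing the plot comes from a different
# family — the strongest signature of convergent (periodic) niches.

#' Assign species to grid cells of the niche space
#'
#' Every species is assigned to exactly one half-open square cell
#' `[x0, x0 + width) x [y0, y0 + width)` on a grid anchored at the origin of
#' the PC1/PC2 score plane, so assignment is total and deterministic. A score
#' sitting exactly on a cell edge belongs to the higher cell.
#'
#' @param space A `niche_space`, or a data frame with columns `PC1`, `PC2`,
#'   `species_id`, `family` (and optionally `biome`).
#' @param width Cell side in PC-score units; default 0.5.
#' @return Data frame of class `niche_bins`: the score columns plus integer
#'   cell indices `ix`, `iy` (`floor(score / width)`) and a `cell` label;
#'   the width is kept as an attribute.
#' @export
bin_species <- function(space, width = 0.5) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("width must be a positive number")
  scores <- if (inherits(space, "niche_space")) space$scores else space
  need <- c("species_id", "family", "PC1", "PC2")
  missing <- setdiff(need, names(scores))
  if (length(missing))
    stop("scores lack column(s): ", paste(missing, collapse = ", "))
  if (nrow(scores) < 1) stop("no species to bin")
  bins <- as.data.frame(scores)
  bins$ix <- as.integer(floor(bins$PC1 / width))
  bins$iy <- as.integer(floor(bins$PC2 / width))
  bins$cell <- paste(bins$ix, bins$iy, sep = ",")
  attr(bins, "width") <- width
  class(bins) <- c("niche_bins", "data.frame")
  bins
}

#' Family-to-species convergence ratio
#'
#' For the species co-occupying one niche plot, the number of distinct
#' families divided by the number of species. Always in (0, 1]; equal to 1
#' exactly when all co-occupants are from different families.
#'
#' @param families Family label of each member species (nonempty).
#' @return The ratio.
#' @export
convergence_ratio <- function(families) {
  if (length(families) < 1) stop("convergence ratio undefined for an empty plot")
  length(unique(families)) / length(families)
}

#' Select the central multi-species plots
#'
#' Summarizes every occupied cell and returns the `k` cells with at least
#' `min_species` species whose centers lie nearest the origin (edge cells
#' usually hold a single species and carry no convergence information).
#' Distance ties are broken by angle from the positive PC1 axis, then by
#' lexicographic cell index. Selected plots are labelled with Roman numerals
#' (I, II, ...). If fewer than `k` qualify, the available ones are returned
#' with a warning; with none, periodicity is not assessable.
#'
#' @param bins A `niche_bins` data frame from [bin_species()].
#' @param k Number of plots to select; default 8.
#' @param min_species Minimum occupancy for a plot to carry convergence
#'   information; default 2.
#' @return Data frame: `plot_id`, `ix`, `iy`, `x0`, `y0`, `n_species`,
#'   `n_families`, `ratio`, `dist`, `members` (semicolon-joined species ids).
#' @export
select_central_plots <- function(bins, k = 8, min_species = 2) {
  stopifnot(inherits(bins, "niche_bins"))
  width <- attr(bins, "width")
  cells <- split(seq_len(nrow(bins)), bins$cell)
  tab <- do.call(rbind, lapply(cells, function(idx) {
    data.frame(ix = bins$ix[idx[1]], iy = bins$iy[idx[1]],
               n_species = length(idx),
               n_families = length(unique(bins$family[idx])),
               ratio = convergence_ratio(bins$family[idx]),
               members = paste(bins$species_id[idx], collapse = ";"))
  }))
  tab$x0 <- tab$ix * width
  tab$y0 <- tab$iy * width
  cx <- tab$x0 + width / 2
  cy <- tab$y0 + width / 2
  tab$dist <- sqrt(cx^2 + cy^2)
  angle <- atan2(cy, cx) %% (2 * pi)
  keep <- tab$n_species >= min_species
  tab <- tab[keep, , drop = FALSE]
  angle <- angle[keep]
  if (nrow(tab) == 0) {
    warning("all occupied plots are singletons: periodicity not assessable")
    out <- tab[, c("ix", "iy", "x0", "y0", "n_species", "n_families",
                   "ratio", "dist", "members")]
    return(cbind(plot_id = character(0), out))
  }
  ord <- order(tab$dist, angle, tab$ix, tab$iy)
  tab <- tab[ord, , drop = FALSE]
  if (nrow(tab) < k)
    warning(sprintf("only %d multi-species plot(s) available (%d requested)",
                    nrow(tab), k))
  tab <- utils::head(tab, k)
  tab <- cbind(plot_id = as.character(utils::as.roman(seq_len(nrow(tab)))),
               tab[, c("ix", "iy", "x0", "y0", "n_species", "n_families",
                       "ratio", "dist", "members")])
  rownames(tab) <- NULL
  tab
}

#' Convergence (periodicity) report for a niche space
#'
#' Bins the space, selects the central multi-species plots and reports their
#' convergence ratios. The space-level flag `assessable` is `FALSE` when no
#' plot holds two or more species — the pattern of sparse high-latitude
#' communities, where wide niche separation leaves no convergence to score.
#'
#' @param space A `niche_space` (or scores data frame, see [bin_species()]).
#' @param width Plot side in PC-score units; default 0.5.
#' @param k Number of central plots; default 8.
#' @param min_species Minimum plot occupancy; default 2.
#' @return Object of class `convergence_report`: `plots` (the selected-plot
#'   table), `assessable`, `mean_ratio`, `width`, `k`, `n_species`.
#' @export
convergence_report <- function(space, width = 0.5, k = 8, min_species = 2) {
  bins <- bin_species(space, width)
  plots <- withCallingHandlers(
    select_central_plots(bins, k = k, min_species = min_species),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(
    plots = plots,
    assessable = nrow(plots) > 0,
    mean_ratio = if (nrow(plots)) mean(plots$ratio) else NA_real_,
    width = width, k = k, n_species = nrow(bins)
  ), class = "convergence_report")
}

#' Permutation null for the convergence ratio
#'
#' Optional significance layer (an extension of the descriptive ratio): the
#' observed mean central-plot ratio is compared with its distribution after
#' shuffling family labels across species, which destroys any association
#' between relatedness and niche position while keeping the spatial pattern
#' and family abundances fixed.
#'
#' @param space A `niche_space` or scores data frame.
#' @param width,k,min_species As in [convergence_report()].
#' @param n_perm Number of permutations; default 500.
#' @return List: `observed` mean ratio, `null_mean`, `null` (vector of
#'   permuted mean ratios), `p_value` (one-sided, permutation estimate of
#'   P(null >= observed)).
#' @export
convergence_null <- function(space, width = 0.5, k = 8, min_species = 2,
                             n_perm = 500) {
  scores <- if (inherits(space, "niche_space")) space$scores else space
  obs <- convergence_report(scores, width, k, min_species)$mean_ratio
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- scores
    perm$family <- sample(perm$family)
    convergence_report(perm, width, k, min_species)$mean_ratio
  }, numeric(1))
  list(observed = obs, null_mean = mean(null, na.rm = TRUE), null = null,
       p_value = (1 + sum(null >= obs, na.rm = TRUE)) / (n_perm + 1))
}

#' @export
print.convergence_report <- function(x, ...) {
  if (!x$assessable) {
    cat(sprintf(
      "Convergence report: %d species; all plots singletons %s\n",
      x$n_species, "- periodicity not assessable"))
    return(invisible(x))
  }
  cat(sprintf(
    "Convergence report: %d species, %d central plot(s) of width %.2g, %s\n",
    x$n_species, nrow(x$plots), x$width,
    sprintf("mean family/species ratio %.3f", x$mean_ratio)))
  print(x$plots[c("plot_id", "x0", "y0", "n_species", "n_families", "ratio")],
        row.names = FALSE)
  invisible(x)
}
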