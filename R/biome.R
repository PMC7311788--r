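# Cross-biome comparison of niche scores: Kruskal-Wallis rank test per axis,
# Dunn-style pairwise rank comparisons with multiplicity control, and a
# compact letter display (groups sharing a letter do not differ).

#' Kruskal-Wallis rank test
#'
#' Thin wrapper around [stats::kruskal.test()] returning the tie-corrected H
#' statistic, the degrees of freedom (number of groups minus one) and the
#' chi-square p-value. The fully tied case (all observations identical),
#' where the tie-correction divisor vanishes, is defined as H = 0, p = 1:
#' there is no rank variation to explain.
#'
#' @param scores Numeric response.
#' @param groups Group labels, at least two groups with one observation each.
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    stop("Kruskal-Wallis needs at least two groups")
  if (length(scores) != length(groups))
    stop("scores and groups differ in length")
  if (length(unique(scores)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p_value = 1))
  kt <- stats::kruskal.test(scores, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Dunn-style pairwise rank comparisons
#'
#' Pairwise z statistics on pooled mean ranks with the usual tie correction
#' of the pooled rank variance, two-sided normal p-values and multiplicity
#' adjustment via [stats::p.adjust()].
#'
#' @param scores Numeric response.
#' @param groups Group labels.
#' @param p_adjust Adjustment method; default `"holm"`.
#' @return Data frame: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(scores, groups, p_adjust = "holm") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  N <- length(scores)
  r <- rank(scores)
  mean_rank <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    (mean_rank[pr[1]] - mean_rank[pr[2]]) /
      sqrt(sigma2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
             p_value = as.numeric(p),
             p_adjusted = stats::p.adjust(p, method = p_adjust))
}

# Compact letter display by insert-and-absorb: start with one letter shared
# by all groups; for every significantly different pair split each letter
# column containing both; absorb columns that are subsets of others. Groups
# share a letter iff their pairwise comparison is non-significant.
letter_display <- function(group_order, sig_pairs) {
  cols <- list(group_order)
  if (nrow(sig_pairs)) {
    for (i in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs$group1[i]; b <- sig_pairs$group2[i]
      out <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          out <- c(out, list(setdiff(col, a), setdiff(col, b)))
        } else out <- c(out, list(col))
      }
      out <- out[vapply(out, length, 1L) > 0]
      # subset absorption (a column contained in another is redundant)
      keep <- rep(TRUE, length(out))
      for (j in seq_along(out)) {
        for (l in seq_along(out)) {
          if (j == l || !keep[j]) next
          if (all(out[[j]] %in% out[[l]]) &&
              (length(out[[j]]) < length(out[[l]]) ||
               (identical(sort(out[[j]]), sort(out[[l]])) && j > l)))
            keep[j] <- FALSE
        }
      }
      cols <- out[keep]
    }
  }
  # order columns by their best-placed member, assign letters a, b, c, ...
  first_pos <- vapply(cols, function(col) min(match(col, group_order)), 1)
  cols <- cols[order(first_pos)]
  letters_used <- letters[seq_along(cols)]
  out <- vapply(group_order, function(g) {
    paste(letters_used[vapply(cols, function(col) g %in% col, TRUE)],
          collapse = "")
  }, character(1))
  out
}

#' Kruskal-Wallis comparison with compact significance letters
#'
#' Runs the omnibus rank test, Dunn-style pairwise comparisons with
#' multiplicity adjustment, and assigns lowercase letters so that any two
#' groups sharing a letter are not significantly different at `alpha`.
#' Letters follow decreasing mean rank, so 'a' marks the highest-scoring
#' homogeneous set.
#'
#' @param scores Numeric response (e.g. niche-space PC scores).
#' @param groups Group labels (e.g. biomes).
#' @param alpha Significance level for the pairwise decisions; default 0.05.
#' @param p_adjust Multiplicity adjustment for the pairwise p-values;
#'   default `"holm"`.
#' @param axis Optional axis label carried into the result.
#' @return Object of class `comparison_result`: `axis`, `H`, `df`,
#'   `p_value`, `alpha`, `p_adjust`, `letters` (named by group), `summary`
#'   (per-group n, median, mean rank, letter) and `pairwise` (the Dunn
#'   table with a `significant` flag).
#' @export
significance_letters <- function(scores, groups, alpha = 0.05,
                                 p_adjust = "holm", axis = NA_character_) {
  groups <- factor(groups)
  kw <- kruskal_wallis(scores, groups)
  pw <- dunn_posthoc(scores, groups, p_adjust)
  pw$significant <- pw$p_adjusted < alpha
  if (length(unique(scores)) == 1L) pw$significant <- FALSE
  mean_rank <- tapply(rank(scores), groups, mean)
  ord <- names(sort(mean_rank, decreasing = TRUE))
  letts <- letter_display(ord, pw[pw$significant, , drop = FALSE])
  letts <- letts[levels(groups)]
  summary <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    median = as.numeric(tapply(scores, groups, stats::median)),
    mean_rank = as.numeric(mean_rank[levels(groups)]),
    letter = unname(letts))
  structure(list(axis = axis, H = kw$H, df = kw$df, p_value = kw$p_value,
                 alpha = alpha, p_adjust = p_adjust,
                 letters = letts, summary = summary, pairwise = pw),
            class = "comparison_result")
}

significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Compare biome niche scores axis by axis
#'
#' Applies [significance_letters()] to the biome labels of a (typically
#' combined, all-biome) niche space on each requested axis.
#'
#' @param space A `niche_space` whose scores carry a `biome` column.
#' @param axes Score columns to test; default PC1 and PC2.
#' @param alpha,p_adjust Passed to [significance_letters()].
#' @return Object of class `biome_comparison`: one `comparison_result` per
#'   axis plus a combined summary table.
#' @export
biome_comparison <- function(space, axes = c("PC1", "PC2"), alpha = 0.05,
                             p_adjust = "holm") {
  scores <- if (inherits(space, "niche_space")) space$scores else space
  if (is.null(scores$biome)) stop("scores lack a 'biome' column")
  results <- lapply(axes, function(ax) {
    significance_letters(scores[[ax]], scores$biome, alpha, p_adjust, ax)
  })
  names(results) <- axes
  tab <- do.call(rbind, lapply(results, function(r) {
    cbind(axis = r$axis, r$summary,
          H = r$H, df = r$df, p_value = r$p_value,
          stars = significance_stars(r$p_value))
  }))
  rownames(tab) <- NULL
  structure(list(results = results, table = tab),
            class = "biome_comparison")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis%s: H = %.3f, df = %d, p = %.3g %s\n",
              if (is.na(x$axis)) "" else paste0(" on ", x$axis),
              x$H, x$df, x$p_value, significance_stars(x$p_value)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
print.biome_comparison <- function(x, ...) {
  for (r in x$results) { print(r); cat("\n") }
  invisible(x)
}
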