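# Principal component analysis with deterministic axis orientation. Both
# ordination stages run on the correlation scale (columns centered and scaled
# to unit variance) so that traits on incommensurate units contribute equally
# and eigenvalues sum to the number of variables.

#' Principal component analysis with full eigen bookkeeping
#'
#' Ordinary (Euclidean-metric) PCA via singular value decomposition, returning
#' eigenvalues, percent variance, unit-length eigenvectors (loadings) and
#' species scores. Axis orientation is canonicalized with [fix_sign()] so
#' identical input always yields identical output. Eigenvalues below 1e-10
#' are clamped to zero; with fewer observations than variables the trailing
#' zero eigenvalues are reported explicitly.
#'
#' @param x Numeric matrix or data frame, observations in rows (>= 3),
#'   variables in columns (>= 2), no missing values.
#' @param standardize Scale columns to unit variance (correlation-scale PCA).
#'   A zero-variance column is then an error naming the column.
#' @return Object of class `pca_result`: `variable_names`, `eigenvalues`
#'   (descending, one per variable), `percent_variance` (summing to 100),
#'   `rotation` (variables x components, unit columns), `scores`
#'   (observations x components), `center`, `scale`, `n_obs`, `standardized`.
#' @export
niche_pca <- function(x, standardize = TRUE) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("input must be numeric")
  if (anyNA(m)) stop("input contains missing values")
  if (nrow(m) < 3) stop("PCA needs at least 3 observations")
  if (ncol(m) < 2) stop("PCA needs at least 2 variables")
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    zero <- colnames(m)[sds == 0]
    if (length(zero))
      stop("zero-variance column(s) cannot be standardized: ",
           paste(zero, collapse = ", "))
  }
  p <- ncol(m)
  fit <- stats::prcomp(m, center = TRUE, scale. = standardize)
  eig <- fit$sdev^2
  rotation <- fit$rotation
  scores <- fit$x
  if (length(eig) < p) {             # fewer observations than variables
    pad <- p - length(eig)
    eig <- c(eig, rep(0, pad))
    extra <- paste0("PC", seq.int(ncol(rotation) + 1L, p))
    rotation <- cbind(rotation,
                      matrix(0, p, pad, dimnames = list(NULL, extra)))
    scores <- cbind(scores,
                    matrix(0, nrow(m), pad, dimnames = list(NULL, extra)))
  }
  total <- sum(eig)
  eig[eig < 1e-10] <- 0
  res <- structure(list(
    variable_names   = colnames(m),
    eigenvalues      = eig,
    percent_variance = eig / total * 100,
    rotation         = rotation,
    scores           = scores,
    center           = fit$center,
    scale            = if (standardize) fit$scale else rep(1, p),
    n_obs            = nrow(m),
    standardized     = standardize
  ), class = "pca_result")
  fix_sign(res)
}

#' Canonicalize eigenvector signs
#'
#' Eigenvector sign is arbitrary; for reproducible reports each component is
#' flipped, if necessary, so that its largest-magnitude loading is positive,
#' with scores flipped consistently. Idempotent.
#'
#' @param result A `pca_result`.
#' @return The `pca_result` with canonical orientation.
#' @export
fix_sign <- function(result) {
  stopifnot(inherits(result, "pca_result"))
  for (j in seq_len(ncol(result$rotation))) {
    v <- result$rotation[, j]
    if (all(v == 0)) next
    if (v[which.max(abs(v))] < 0) {
      result$rotation[, j] <- -v
      result$scores[, j] <- -result$scores[, j]
    }
  }
  result
}

#' Dominant variable(s) of a PCA axis
#'
#' The variable with the largest absolute loading on the axis ("major
#' eigenvector"). Loadings whose magnitudes are within `tol` of the maximum
#' are reported jointly, joined by `+` (e.g. the height and diameter traits
#' that together read as plant size).
#'
#' @param result A `pca_result`.
#' @param component Axis index.
#' @param tol Tie tolerance on |loading|; default 1e-6.
#' @return Character scalar naming the dominant variable(s).
#' @export
dominant_variable <- function(result, component = 1, tol = 1e-6) {
  v <- abs(result$rotation[, component])
  paste(result$variable_names[v >= max(v) - tol], collapse = "+")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(length(x$eigenvalues), 4L)
  cat(sprintf("PCA of %d observations x %d variables (%s)\n", x$n_obs,
              length(x$variable_names),
              if (x$standardized) "correlation scale" else "covariance scale"))
  tab <- rbind(Eigenvalue = round(x$eigenvalues[1:k], 3),
               Percent = round(x$percent_variance[1:k], 2))
  colnames(tab) <- paste0("PC", 1:k)
  print(tab)
  invisible(x)
}
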