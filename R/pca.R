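#' Principal component analysis of cells in protein (or term) space
#'
#' SVD-based PCA with cells as observations and features (proteins or terms)
#' as variables: the feature-by-cell matrix is transposed, feature means are
#' removed, and components are extracted with a deterministic sign convention
#' (each loading vector's largest-magnitude element is made positive).
#'
#' @param mat Complete feature-by-cell numeric matrix.
#' @param n_components Number of components to keep, default 10; clipped with
#'   a warning when it exceeds the available rank.
#' @param center,scale Center / unit-scale features before decomposition;
#'   defaults `TRUE` / `FALSE`.
#' @return An object of class `pca_result`: list with `scores` (cell x
#'   component), `loadings` (feature x component),
#'   `explained_variance_fraction`, `n_components`, `center` (feature means).
#' @export
pca_cells <- function(mat, n_components = 10, center = TRUE, scale = FALSE) {
  if (anyNA(mat)) stop("PCA requires a complete matrix")
  x <- t(mat)                          # cells x features
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_comp) {
    warning("n_components clipped from ", n_components, " to ", max_comp)
    n_components <- max_comp
  }
  fit <- stats::prcomp(x, center = center, scale. = scale)
  ev <- fit$sdev^2
  frac <- ev / sum(ev)
  k <- n_components
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {              # deterministic sign
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    scores = scores, loadings = loadings,
    explained_variance_fraction = frac[seq_len(k)],
    explained_variance_all = frac,
    n_components = k,
    center = if (isTRUE(center)) fit$center else NULL,
    scale = if (isTRUE(scale)) fit$scale else NULL
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "cells x", nrow(x$loadings), "features,",
      x$n_components, "components\n")
  cat("explained variance (%):",
      paste(sprintf("%.1f", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Correlate principal components with cell-level phenotype variables
#'
#' Pearson correlation of each retained component's scores against each
#' numeric metadata variable, with two-sided t-test p-values (n - 2 degrees
#' of freedom) and Benjamini-Hochberg adjustment across the whole
#' component-by-variable grid.
#'
#' @param pca A `pca_result` from [pca_cells()].
#' @param metadata Data frame with a `cell_id` column matching the score row
#'   names, plus the variables to test.
#' @param variables Character vector of metadata column names (numeric).
#' @param n_components Components to test, default up to 10.
#' @param alpha Significance level on BH-adjusted p-values, default 0.05.
#' @return Data frame: `component`, `variable`, `r`, `p_value`, `p_adjusted`,
#'   `significant`. Constant variables yield `NA` with a warning.
#' @export
eigencor <- function(pca, metadata, variables, n_components = 10,
                     alpha = 0.05) {
  stopifnot(inherits(pca, "pca_result"), "cell_id" %in% names(metadata))
  k <- min(n_components, pca$n_components)
  idx <- match(rownames(pca$scores), metadata$cell_id)
  if (anyNA(idx)) {
    stop("metadata missing cell(s): ",
         paste(rownames(pca$scores)[is.na(idx)][1:3], collapse = ", "))
  }
  meta <- metadata[idx, , drop = FALSE]
  grid <- expand.grid(component = seq_len(k), variable = variables,
                      stringsAsFactors = FALSE)
  n <- nrow(pca$scores)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    v <- meta[[grid$variable[i]]]
    if (!is.numeric(v)) stop("non-numeric variable: ", grid$variable[i])
    s <- pca$scores[, grid$component[i]]
    if (stats::sd(v) == 0) {
      warning("constant variable: ", grid$variable[i])
      return(c(r = NA_real_, p = NA_real_))
    }
    r <- stats::cor(s, v)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    c(r = r, p = p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    component = paste0("PC", grid$component),
    variable = grid$variable,
    r = res[, "r"],
    p_value = res[, "p"],
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' Top loading features per principal component
#'
#' @param pca A `pca_result`.
#' @param k Number of features per component (clipped to the feature count).
#' @return Named list (one entry per component) of data frames with `feature`
#'   and signed `loading`, ordered by decreasing `|loading|`.
#' @export
top_loadings <- function(pca, k = 10) {
  stopifnot(inherits(pca, "pca_result"))
  k <- min(k, nrow(pca$loadings))
  out <- lapply(seq_len(pca$n_components), function(j) {
    l <- pca$loadings[, j]
    ord <- order(-abs(l))[seq_len(k)]
    data.frame(feature = rownames(pca$loadings)[ord], loading = l[ord],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(out) <- colnames(pca$loadings)
  out
}
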