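#' Median-center matrix rows on their observed values
#'
#' Converts each feature to a relative scale by subtracting the median of its
#' observed values; missing entries are untouched. Idempotent.
#'
#' @param mat Numeric matrix, `NA` = missing; every row needs at least one
#'   observed value.
#' @return The centered matrix (attributes preserved).
#' @export
median_center_rows <- function(mat) {
  obs_per_row <- rowSums(!is.na(mat))
  if (any(obs_per_row == 0L)) {
    stop("row with no observed values: ",
         rownames(mat)[obs_per_row == 0L][1L],
         " (apply the coverage filter first)")
  }
  med <- apply(mat, 1L, stats::median, na.rm = TRUE)
  out <- mat - med
  attributes(out) <- attributes(mat)
  out
}

#' Iterative rank-k SVD imputation
#'
#' Fills missing entries of a (row-centered) matrix by iterating a truncated
#' singular value decomposition: missing entries are initialized to 0, the
#' current matrix is approximated at rank `n_components`, and only the missing
#' entries are replaced by the low-rank reconstruction. Iteration stops when
#' the relative change of the imputed entries (root-sum-square of the change
#' over root-sum-square of the imputed values) drops below `tol`. Observed
#' entries are never modified.
#'
#' @param mat Numeric matrix with `NA` for missing entries; every row and
#'   column must have at least one observed value. Rows should already be
#'   median-centered (the 0 initialization assumes a relative scale).
#' @param n_components Rank of the truncated SVD, default 5; must be smaller
#'   than `min(dim(mat))`.
#' @param tol Relative-change convergence tolerance, default 1e-2.
#' @param max_iter Iteration cap, default 100; non-convergence produces a
#'   warning and sets the `converged` attribute to `FALSE`.
#' @return The completed matrix with attributes `converged` (logical) and
#'   `iterations` (integer). A matrix with no missing entries is returned
#'   unchanged.
#' @export
svd_impute <- function(mat, n_components = 5, tol = 1e-2, max_iter = 100) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (n_components >= min(dim(mat))) {
    stop("n_components (", n_components, ") must be < min(dim) = ",
         min(dim(mat)))
  }
  miss <- is.na(mat)
  if (!any(miss)) {
    attr(mat, "converged") <- TRUE
    attr(mat, "iterations") <- 0L
    return(mat)
  }
  if (any(rowSums(!miss) == 0L)) stop("row with no observed values")
  if (any(colSums(!miss) == 0L)) stop("column with no observed values")
  x <- mat
  x[miss] <- 0
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sv <- svd(x, nu = n_components, nv = n_components)
    d <- sv$d[seq_len(n_components)]
    recon <- sv$u %*% (d * t(sv$v))
    new_imp <- recon[miss]
    delta <- sqrt(sum((new_imp - x[miss])^2))
    denom <- sqrt(sum(new_imp^2))
    x[miss] <- new_imp
    if (denom == 0 || delta / denom < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("svd_impute did not converge in ", max_iter, " iterations")
  }
  for (a in setdiff(names(attributes(mat)), c("dim", "dimnames"))) {
    attr(x, a) <- attr(mat, a)
  }
  attr(x, "converged") <- converged
  attr(x, "iterations") <- iter
  x
}
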