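# Empirical-Bayes location/scale batch correction (ComBat-style, parametric
# priors, no covariates). Per protein the batch means are shrunk toward a
# normal prior and the batch variances toward an inverse-gamma prior, both
# estimated across proteins by the method of moments; the adjusted data are
# standardized residuals rescaled to the pooled variance and re-centered on
# the pooled mean.

# inverse-gamma hyperparameter moment estimators
.ig_aprior <- function(d2) {
  m <- mean(d2); s2 <- stats::var(d2)
  (2 * s2 + m^2) / s2
}
.ig_bprior <- function(d2) {
  m <- mean(d2); s2 <- stats::var(d2)
  (m * s2 + m^3) / s2
}

# EB iteration for one batch: shrink gamma (batch means) and delta^2 (batch
# variances) jointly until convergence.
.eb_fit <- function(z_batch, g_hat, d2_hat, g_bar, t2, a_prior, b_prior,
                    conv = 1e-4, max_iter = 500L) {
  n <- ncol(z_batch)
  g_new <- g_hat
  d2_new <- d2_hat
  for (i in seq_len(max_iter)) {
    g_old <- g_new
    d2_old <- d2_new
    g_new <- (n * t2 * g_hat + d2_new * g_bar) / (n * t2 + d2_new)
    ss <- rowSums((z_batch - g_new)^2)
    d2_new <- (0.5 * ss + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                  abs(d2_new - d2_old) / pmax(abs(d2_old), 1e-12))
    if (change < conv) break
  }
  list(gamma_star = g_new, delta2_star = d2_new)
}

#' Empirical-Bayes batch correction of a complete protein matrix
#'
#' Removes additive and multiplicative batch effects (e.g. between nanowell
#' processing chips) from a complete protein-by-cell matrix using parametric
#' empirical-Bayes shrinkage of per-protein batch means and variances. With a
#' single batch the input is returned unchanged with a warning.
#'
#' @param mat Complete (no `NA`) protein-by-cell numeric matrix, log2 scale.
#' @param batch Batch label per column; every batch needs at least 2 cells.
#' @param variance_floor Lower bound on pooled per-protein variances,
#'   default 1e-8 (guards zero-variance proteins).
#' @return A list with `corrected` (matrix, same dimensions and attributes)
#'   and `model` (per-batch shrunken means/variances and hyperparameters), of
#'   class `combat_model`.
#' @export
combat_correct <- function(mat, batch, variance_floor = 1e-8) {
  stopifnot(is.matrix(mat), length(batch) == ncol(mat))
  if (anyNA(mat)) stop("combat_correct requires a complete matrix; ",
                       "impute or summarize first")
  batch <- as.character(batch)
  batches <- unique(batch)
  sizes <- table(batch)[batches]
  if (length(batches) == 1L) {
    warning("single batch: returning input unchanged")
    return(list(corrected = mat, model = NULL))
  }
  if (any(sizes < 2L)) {
    stop("batch with fewer than 2 cells: ",
         paste(batches[sizes < 2L], collapse = ", "))
  }
  N <- ncol(mat)
  K <- length(batches)
  G <- nrow(mat)

  # per-protein batch means and pooled (size-weighted) grand mean
  gamma_hat <- vapply(batches, function(b) {
    rowMeans(mat[, batch == b, drop = FALSE])
  }, numeric(G))
  if (G == 1L) gamma_hat <- matrix(gamma_hat, nrow = 1)
  wts <- as.numeric(sizes) / N
  alpha <- as.numeric(gamma_hat %*% wts)
  resid <- mat - gamma_hat[, match(batch, batches), drop = FALSE]
  var_pooled <- pmax(rowSums(resid^2) / N, variance_floor)

  z <- (mat - alpha) / sqrt(var_pooled)

  gamma_star <- matrix(NA_real_, G, K, dimnames = list(rownames(mat), batches))
  delta2_star <- gamma_star
  hyper <- vector("list", K)
  names(hyper) <- batches
  for (k in seq_len(K)) {
    cols <- batch == batches[k]
    zb <- z[, cols, drop = FALSE]
    g_hat <- rowMeans(zb)
    d2_hat <- apply(zb, 1L, stats::var)
    d2_hat <- pmax(d2_hat, variance_floor)
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    a_prior <- .ig_aprior(d2_hat)
    b_prior <- .ig_bprior(d2_hat)
    fit <- .eb_fit(zb, g_hat, d2_hat, g_bar, t2, a_prior, b_prior)
    gamma_star[, k] <- fit$gamma_star
    delta2_star[, k] <- fit$delta2_star
    hyper[[k]] <- list(gamma_bar = g_bar, tau2 = t2,
                       a_prior = a_prior, b_prior = b_prior)
  }

  bidx <- match(batch, batches)
  adj <- (z - gamma_star[, bidx, drop = FALSE]) /
    sqrt(delta2_star[, bidx, drop = FALSE])
  corrected <- adj * sqrt(var_pooled) + alpha
  for (a in setdiff(names(attributes(mat)), c("dim", "dimnames"))) {
    attr(corrected, a) <- attr(mat, a)
  }
  model <- structure(list(
    batches = batches, alpha = alpha, var_pooled = var_pooled,
    gamma_star = gamma_star, delta2_star = delta2_star,
    hyperparameters = hyper
  ), class = "combat_model")
  list(corrected = corrected, model = model)
}
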