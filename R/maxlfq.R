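# Pairwise-median-ratio least squares (MaxLFQ) protein summarization.
#
# For every pair of cells sharing >= min_shared precursors the protein-level
# log2 ratio is estimated as the median of the per-precursor differences;
# per-cell abundances are then the least-squares solution of the resulting
# (possibly incomplete) ratio graph, solved independently on each connected
# component and anchored so that the mean estimate over a component equals the
# mean of the observed precursor values in its cells.

#' MaxLFQ summarization of one protein group
#'
#' @param mat Precursor-by-cell log2 matrix for a single protein group
#'   (`NA` = missing; a complete matrix is the post-imputation case).
#' @param min_shared Minimum number of precursors observed in both cells of a
#'   pair for the pairwise ratio to be used, default 1.
#' @return Named numeric vector of per-cell log2 abundances; `NA` for cells
#'   with no observed precursor.
#' @export
maxlfq <- function(mat, min_shared = 1) {
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1,
                                     dimnames = list(NULL, names(mat)))
  n <- ncol(mat)
  if (n == 0L || nrow(mat) == 0L) stop("empty input to maxlfq")
  obs <- !is.na(mat)
  w <- rep(NA_real_, n)
  names(w) <- colnames(mat)
  active <- which(colSums(obs) > 0L)
  if (!length(active)) return(w)

  if (nrow(mat) == 1L) {               # single precursor: identity
    w[active] <- mat[1L, active]
    return(w)
  }

  m <- length(active)
  sub <- mat[, active, drop = FALSE]
  subobs <- obs[, active, drop = FALSE]
  complete <- !anyNA(sub)

  # pairwise median log-ratios r[a,b] = median_j (x_jb - x_ja)
  r <- matrix(NA_real_, m, m)
  if (complete) {
    for (a in seq_len(m - 1L)) {
      d <- sub[, (a + 1L):m, drop = FALSE] - sub[, a]
      r[a, (a + 1L):m] <- apply(d, 2L, stats::median)
    }
  } else {
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        shared <- subobs[, a] & subobs[, b]
        if (sum(shared) >= min_shared && any(shared)) {
          r[a, b] <- stats::median(sub[shared, b] - sub[shared, a])
        }
      }
    }
  }
  has_edge <- !is.na(r)
  r[lower.tri(r)] <- -t(r)[lower.tri(r)]
  has_edge <- has_edge | t(has_edge)

  comp <- .graph_components(has_edge)
  west <- rep(NA_real_, m)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1L) {
      west[idx] <- mean(sub[subobs[, idx], idx])
      next
    }
    # Laplacian system L w = t, solved on the component with the gauge fixed
    # by adding the rank-one term (1/k) J; anchor to the component's observed
    # mean afterwards.
    k <- length(idx)
    A <- has_edge[idx, idx, drop = FALSE]
    L <- diag(rowSums(A)) - A
    tv <- vapply(seq_len(k), function(i) {
      nb <- which(A[i, ])
      -sum(r[idx[i], idx[nb]])
    }, numeric(1))
    sol <- solve(L + 1 / k, tv)
    anchor <- mean(sub[, idx, drop = FALSE][subobs[, idx, drop = FALSE]])
    west[idx] <- sol - mean(sol) + anchor
  }
  w[active] <- west
  w
}

# connected components of an adjacency matrix (undirected), simple BFS
.graph_components <- function(adj) {
  m <- nrow(adj)
  comp <- rep(NA_integer_, m)
  cid <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Summarize a precursor matrix to protein level with MaxLFQ
#'
#' Applies [maxlfq()] to each protein group of the precursor matrix. Output
#' rows are ordered by the group's lead (first) accession.
#'
#' @param mat Precursor-by-cell log2 matrix; rows grouped by `grouping`.
#' @param grouping Character vector (one per row of `mat`) of protein-group
#'   keys (semicolon-joined accessions). Defaults to the `protein_group`
#'   column of the matrix's `precursor_info` attribute.
#' @param min_shared Passed to [maxlfq()].
#' @return Protein-by-cell log2 matrix with attribute `protein_info`
#'   (data frame: `protein_group`, `lead_accession`, `gene_symbols`,
#'   `n_precursors`).
#' @export
summarize_all_proteins <- function(mat, grouping = NULL, min_shared = 1) {
  info <- attr(mat, "precursor_info")
  if (is.null(grouping)) {
    if (is.null(info)) stop("grouping not given and matrix has no ",
                            "precursor_info attribute")
    grouping <- info$protein_group
  }
  stopifnot(length(grouping) == nrow(mat))
  groups <- unique(grouping)
  lead <- vapply(split_groups(groups), `[[`, "", 1L)
  ord <- order(lead, groups)
  groups <- groups[ord]
  lead <- lead[ord]
  out <- matrix(NA_real_, length(groups), ncol(mat),
                dimnames = list(groups, colnames(mat)))
  for (i in seq_along(groups)) {
    rows <- which(grouping == groups[i])
    out[i, ] <- maxlfq(mat[rows, , drop = FALSE], min_shared = min_shared)
  }
  genes <- if (!is.null(info)) {
    vapply(groups, function(g) info$gene_symbols[match(g, info$protein_group)],
           "")
  } else rep(NA_character_, length(groups))
  attr(out, "protein_info") <- data.frame(
    protein_group = groups, lead_accession = lead, gene_symbols = genes,
    n_precursors = as.integer(table(grouping)[groups]),
    stringsAsFactors = FALSE
  )
  out
}
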