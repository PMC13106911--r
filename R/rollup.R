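#' Reference-based rollup of proteins to gene-set (GO term) level
#'
#' For each gene set, member proteins are shift-aligned to a reference member
#' and summarized by the per-cell median. The reference is the member with the
#' most observed values (ties broken by higher median abundance, then by
#' lexicographic row name); every other member is shifted by the median of
#' (reference - member) over cells where both are observed; the term value in
#' a cell is the median over shifted members observed in that cell.
#'
#' @param mat Protein-by-cell log2 matrix (`NA` allowed).
#' @param genesets Named list of gene symbol vectors, see [read_gmt()].
#' @param gene_symbols Gene symbol(s) per row of `mat` (semicolon-joined for
#'   multi-gene groups); defaults to the `protein_info` attribute.
#' @param min_members Minimum mapped member proteins per term, default 3;
#'   smaller terms are dropped (with a message).
#' @return Term-by-cell numeric matrix; attribute `n_members` gives the
#'   mapped member count per term.
#' @export
rollup_go <- function(mat, genesets, gene_symbols = NULL, min_members = 3) {
  if (is.null(gene_symbols)) {
    info <- attr(mat, "protein_info")
    if (is.null(info)) stop("gene_symbols not given and matrix has no ",
                            "protein_info attribute")
    gene_symbols <- info$gene_symbols
  }
  stopifnot(length(gene_symbols) == nrow(mat))
  row_genes <- split_groups(ifelse(is.na(gene_symbols), "", gene_symbols))
  members <- lapply(genesets, function(gs) {
    which(vapply(row_genes, function(g) any(g %in% gs), logical(1)))
  })
  sizes <- lengths(members)
  keep <- sizes >= min_members
  if (sum(!keep)) {
    message(sum(!keep), " term(s) dropped with < ", min_members,
            " mapped proteins")
  }
  if (!any(keep)) stop("no gene set has >= ", min_members, " mapped proteins")
  members <- members[keep]
  out <- matrix(NA_real_, length(members), ncol(mat),
                dimnames = list(names(members), colnames(mat)))
  for (i in seq_along(members)) {
    out[i, ] <- .rollup_one(mat[members[[i]], , drop = FALSE])
  }
  attr(out, "n_members") <- stats::setNames(lengths(members), names(members))
  out
}

.rollup_one <- function(sub) {
  if (nrow(sub) == 1L) return(sub[1L, ])
  n_obs <- rowSums(!is.na(sub))
  meds <- apply(sub, 1L, stats::median, na.rm = TRUE)
  ord <- order(-n_obs, -meds, rownames(sub))
  ref <- ord[1L]
  shifted <- sub
  for (r in seq_len(nrow(sub))) {
    if (r == ref) next
    both <- !is.na(sub[ref, ]) & !is.na(sub[r, ])
    shift <- if (any(both)) {
      stats::median(sub[ref, both] - sub[r, both])
    } else NA_real_
    shifted[r, ] <- sub[r, ] + shift
  }
  apply(shifted, 2L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else stats::median(x)
  })
}
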