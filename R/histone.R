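#' Histone-median per-cell normalization
#'
#' Histones scale with ploidy rather than cell volume, so their median
#' relative abundance serves as a per-cell reference level. For each cell the
#' median over histone-flagged proteins is computed and subtracted from every
#' protein value in that cell; afterwards the per-cell histone median is
#' exactly zero. Idempotent.
#'
#' @param mat Protein-by-cell log2 matrix (relative scale). Histone rows are
#'   located via the matrix's `protein_info` attribute, or via `annotations`.
#' @param annotations Optional protein annotation data frame with `accession`
#'   and `is_histone` (used when the matrix lacks gene information).
#' @param histone_patterns Regular expressions defining histone gene symbols.
#' @param min_histones Minimum number of histone proteins required, default 3.
#' @return A list with `normalized` (matrix) and `factors` (data frame:
#'   `cell_id`, `histone_median_log2`).
#' @export
histone_normalize <- function(mat, annotations = NULL,
                              histone_patterns = default_histone_patterns(),
                              min_histones = 3) {
  hist_rows <- .histone_rows(mat, annotations, histone_patterns)
  if (length(hist_rows) < min_histones) {
    stop("only ", length(hist_rows), " histone protein(s) detected (",
         paste(rownames(mat)[hist_rows], collapse = ", "),
         "); need >= ", min_histones)
  }
  f <- apply(mat[hist_rows, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  normalized <- sweep(mat, 2L, f, "-")
  for (a in setdiff(names(attributes(mat)), c("dim", "dimnames"))) {
    attr(normalized, a) <- attr(mat, a)
  }
  list(normalized = normalized,
       factors = data.frame(cell_id = colnames(mat),
                            histone_median_log2 = unname(f),
                            stringsAsFactors = FALSE))
}

# locate histone rows from protein_info gene symbols or an annotation table
.histone_rows <- function(mat, annotations, histone_patterns) {
  info <- attr(mat, "protein_info")
  hist_rx <- paste(histone_patterns, collapse = "|")
  if (!is.null(info) && !all(is.na(info$gene_symbols))) {
    genes <- split_groups(ifelse(is.na(info$gene_symbols), "",
                                 info$gene_symbols))
    return(which(vapply(genes, function(g) any(grepl(hist_rx, g)),
                        logical(1))))
  }
  if (!is.null(annotations)) {
    ann <- annotations
    if (!"is_histone" %in% names(ann)) {
      ann <- flag_contaminant_classes(ann, histone_patterns)
    }
    hist_acc <- ann$accession[ann$is_histone]
    leads <- vapply(split_groups(rownames(mat)), `[[`, "", 1L)
    return(which(leads %in% hist_acc |
                   vapply(split_groups(rownames(mat)),
                          function(a) any(a %in% hist_acc), logical(1))))
  }
  stop("cannot locate histone proteins: matrix has no protein_info ",
       "gene symbols and no annotations were given")
}
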