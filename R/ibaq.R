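#' Count theoretically observable tryptic peptides
#'
#' Digests a protein sequence in silico at the C-terminal side of K and R
#' (optionally skipping cleavage before proline) and counts the resulting
#' peptides whose length falls within `[min_len, max_len]`. With
#' `missed_cleavages > 0`, peptides spanning up to that many internal
#' cleavage sites are counted as well.
#'
#' @param sequence Protein sequence over the 20-letter amino-acid alphabet.
#' @param min_len,max_len Peptide length bounds, defaults 6 and 50.
#' @param missed_cleavages Maximum internal missed cleavage sites, default 0.
#' @param proline_rule If `TRUE`, K/R followed by P is not cleaved.
#' @return Integer count of observable peptides.
#' @export
#' @examples
#' theoretical_tryptic_peptides("MAAAAAKGGGGGGRTTTTTTK")  # 3
theoretical_tryptic_peptides <- function(sequence, min_len = 6, max_len = 50,
                                         missed_cleavages = 0,
                                         proline_rule = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence)) {
    stop("invalid residue in sequence: ",
         regmatches(sequence, regexpr("[^ACDEFGHIKLMNPQRSTVWY]", sequence)))
  }
  chars <- strsplit(sequence, "")[[1L]]
  nres <- length(chars)
  if (nres == 0L) return(0L)
  cut_after <- chars %in% c("K", "R")
  if (proline_rule && nres > 1L) {
    followed_by_P <- c(chars[-1L] == "P", FALSE)
    cut_after <- cut_after & !followed_by_P
  }
  cut_after[nres] <- FALSE            # C-terminus ends the last fragment anyway
  starts <- c(1L, which(cut_after) + 1L)
  ends <- c(which(cut_after), nres)
  nfrag <- length(starts)
  count <- 0L
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + missed_cleavages)) {
      len <- ends[j] - starts[i] + 1L
      if (len >= min_len && len <= max_len) count <- count + 1L
    }
  }
  count
}

#' Intensity-based absolute quantification (iBAQ)
#'
#' Per protein group and cell, iBAQ is the sum of the observed linear
#' precursor intensities divided by the number of theoretically observable
#' tryptic peptides of the group's lead accession. Intensities must be the
#' raw, pre-normalization linear values.
#'
#' @param mat Precursor-by-cell matrix of linear intensities (`NA` =
#'   unobserved), e.g. `2^build_matrix(records)`.
#' @param grouping Protein-group key per row of `mat`; defaults to the
#'   matrix's `precursor_info` attribute.
#' @param annotations Protein annotation data frame ([read_fasta()]); must
#'   cover every lead accession.
#' @param min_len,max_len,missed_cleavages,proline_rule Digestion settings,
#'   see [theoretical_tryptic_peptides()].
#' @param top_n If not `NULL`, restrict the table to the `top_n` proteins with
#'   the highest median iBAQ among proteins observed in more than
#'   `min_obs_fraction` of cells.
#' @param min_obs_fraction Observation fraction required for the `top_n`
#'   restriction, default 0.5.
#' @param reference_genes Optional character vector of gene symbols (e.g. a
#'   published aged-microglia signature); flagged in the output.
#' @return A list with `table` (data frame: `protein_group`, `accession`,
#'   `gene`, `theoretical_peptides`, `median_log10_ibaq`, `rank`,
#'   `is_in_reference_gene_set`) ranked by descending median iBAQ, and
#'   `per_cell` (protein-by-cell iBAQ matrix, linear scale).
#' @export
compute_ibaq <- function(mat, grouping = NULL, annotations,
                         min_len = 6, max_len = 50, missed_cleavages = 0,
                         proline_rule = FALSE, top_n = NULL,
                         min_obs_fraction = 0.5, reference_genes = NULL) {
  info <- attr(mat, "precursor_info")
  if (is.null(grouping)) {
    if (is.null(info)) stop("grouping not given and matrix has no ",
                            "precursor_info attribute")
    grouping <- info$protein_group
  }
  stopifnot(length(grouping) == nrow(mat), all(is.na(mat) | mat > 0))
  groups <- unique(grouping)
  lead <- vapply(split_groups(groups), `[[`, "", 1L)
  ord <- order(lead, groups)
  groups <- groups[ord]
  lead <- lead[ord]
  seq_of <- stats::setNames(annotations$sequence, annotations$accession)
  if (anyNA(seq_of[lead])) {
    stop("no sequence for lead accession: ", lead[is.na(seq_of[lead])][1L])
  }
  npep <- vapply(lead, function(acc) {
    theoretical_tryptic_peptides(seq_of[[acc]], min_len, max_len,
                                 missed_cleavages, proline_rule)
  }, integer(1))
  per_cell <- matrix(NA_real_, length(groups), ncol(mat),
                     dimnames = list(groups, colnames(mat)))
  obs_frac <- numeric(length(groups))
  for (i in seq_along(groups)) {
    rows <- mat[grouping == groups[i], , drop = FALSE]
    sums <- colSums(rows, na.rm = TRUE)
    any_obs <- colSums(!is.na(rows)) > 0L
    sums[!any_obs] <- NA_real_
    obs_frac[i] <- mean(any_obs)
    if (npep[i] > 0L) per_cell[i, ] <- sums / npep[i]
  }
  zero_pep <- npep == 0L
  if (any(zero_pep)) {
    message(sum(zero_pep), " protein(s) with no observable tryptic peptide; ",
            "iBAQ set to missing")
  }
  med <- apply(per_cell, 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else stats::median(log10(x))
  })
  gene_of <- stats::setNames(annotations$gene_symbol, annotations$accession)
  tab <- data.frame(
    protein_group = groups,
    accession = lead,
    gene = unname(gene_of[lead]),
    theoretical_peptides = npep,
    median_log10_ibaq = med,
    obs_fraction = obs_frac,
    stringsAsFactors = FALSE
  )
  tab$is_in_reference_gene_set <-
    if (is.null(reference_genes)) FALSE else tab$gene %in% reference_genes
  if (!is.null(top_n)) {
    cand <- tab[tab$obs_fraction > min_obs_fraction & !is.na(med), ,
                drop = FALSE]
    cand <- cand[order(-cand$median_log10_ibaq), , drop = FALSE]
    tab <- utils::head(cand, top_n)
    per_cell <- per_cell[tab$protein_group, , drop = FALSE]
  } else {
    tab <- tab[order(-tab$median_log10_ibaq, tab$accession,
                     na.last = TRUE), , drop = FALSE]
  }
  nonmiss <- !is.na(tab$median_log10_ibaq)
  tab$rank <- NA_integer_
  tab$rank[nonmiss] <- seq_len(sum(nonmiss))
  rownames(tab) <- NULL
  list(table = tab, per_cell = per_cell)
}
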