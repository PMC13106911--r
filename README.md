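# scpquant

Post-search quantification for single-cell, label-free DIA proteomics.

Single-cell proteomics experiments on nanowell chips produce, after the
database search, a long-format precursor report: one row per peptide ion
(modified sequence + charge) per single-cell LC-MS run, with an
identification q-value and a linear-scale intensity. Getting from that report
to protein and pathway matrices that can be compared across cells requires a
long cascade of decisions — contaminant and ambiguity filtering, per-cell
quality control, handling of intensity-dependent missingness, protein
summarization, chip-to-chip batch correction, and per-cell normalization.
`scpquant` implements that cascade as tested, reusable R functions, for
analysts working with single-cell DIA data at the scale of tens of cells and
thousands of precursors per cell.

## What it computes

- **Filtering cascade** — strict q-value cutoff (`q < 0.01`), removal of
  precursors not unambiguously assignable to the target organism (guards
  against bovine serum carry-over), keratin contaminant removal, removal of
  cells with `< 500` identified precursors, and removal of precursors
  observed in `< 50%` of cells (boundary inclusive), with every count logged
  in a filter report.
- **Median-relative scaling** — each precursor's log2 intensities are
  centered on the median of its observed values.
- **svdImpute-style imputation** — missing entries are filled by iterating a
  truncated SVD: initialize at 0, reconstruct at rank *k*, replace only the
  missing entries, repeat until the relative change of the imputed values
  falls below tolerance.
- **MaxLFQ protein summarization** — for each protein group, the log2 ratio
  between two cells is the median over shared precursors *j* of
  *x<sub>jb</sub> − x<sub>ja</sub>*; per-cell protein abundances *w* minimize
  Σ<sub>(a,b)</sub> (w<sub>b</sub> − w<sub>a</sub> − r<sub>ab</sub>)², solved
  on each connected component of the cell-pair graph and anchored to the
  component's observed mean.
- **Empirical-Bayes batch correction** — ComBat-style parametric
  location/scale adjustment across chips: per-protein batch means and
  variances are shrunk toward normal / inverse-gamma priors estimated across
  proteins, then removed.
- **Histone-median normalization** — the per-cell median relative abundance
  of histone proteins is subtracted from every protein in that cell, using
  histones as a ploidy-linked per-cell reference.
- **iBAQ** — per protein, summed raw linear precursor intensity divided by
  the number of theoretically observable tryptic peptides (length 6–50, from
  in-silico digestion of the lead accession), with abundance ranks.
- **GO-term rollup** — reference-based rollup: members of a gene set are
  shift-aligned to the best-observed member and summarized by the per-cell
  median.
- **PCA + phenotype correlation** — PCA of cells in protein (or term) space
  and Pearson correlation of each component with cell-level phenotypes such
  as diameter, with two-sided t-tests and Benjamini–Hochberg adjustment.
- **Synthetic data generator** — `simulate_dataset()` emulates the whole
  data-generating process (cell-size scaling, chip batch effects, pathway
  covariation, contaminants, logistic MNAR + MCAR missingness) with known
  ground truth, so every stage above has a recovery test.

## Worked example

```r
library(scpquant)

# simulate a 48-cell chip experiment with a cell-size effect
sim <- simulate_dataset(default_paper_scale(seed = 1))

res <- run_pipeline(sim$report, sim$annotations, sim$metadata, sim$genesets)
print(res)
#> scpquant pipeline result
#> Filter cascade:
#>   q_value                        100837 ->    98860 records (-1977)
#>   species_unambiguous             98860 ->    95948 records (-2912)
#>   keratin                         95948 ->    93603 records (-2345)
#>   cell_min_precursors                48 ->       48 cells (-0)
#>   precursor_coverage               3348 ->     2234 precursors (-1114)
#> final: 2234 precursors x 48 cells -> 834 proteins
#> PC1 explains 21.3% of variance

subset(res$eigencor, component == "PC1")
#>   component    variable         r      p_value   p_adjusted significant
#> 1       PC1 diameter_um 0.9642974 3.460856e-28 3.460856e-27        TRUE
```

The filter report shows how many records each rule removed (q-value
failures, species-ambiguous and keratin precursors), that all 48 cells
passed the 500-precursor QC, and that 2234 of 3348 precursors met the 50%
coverage rule. After imputation, MaxLFQ summarization, chip batch correction
and histone normalization, the first principal component of the 834-protein
matrix correlates with cell diameter at r = 0.96 (BH-adjusted
p ≈ 3e-27) — the generator's cell-size axis, recovered end to end.

`run_pipeline(..., outdir = "out/")` additionally writes the protein/term
matrices, iBAQ table, eigencor table, normalization factors and a JSON
manifest with all parameters and stage counts. A thin command-line wrapper
with `simulate` and `run-all` subcommands is included at
`inst/cli/scpquant.R`.

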