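---
title: "From precursor report to protein and pathway matrices: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From precursor report to protein and pathway matrices: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`scpquant` turns a long-format precursor identification/intensity report
from a single-cell DIA experiment into analysis-ready protein and pathway
matrices. This vignette describes the statistical procedure stage by stage,
the parameters that matter, the synthetic data generator used for
validation, and the design decisions taken where the procedure was
genuinely open.

## The processing model

The input is one row per precursor (modified peptide sequence + charge
state) per single-cell run, with a q-value and a linear-scale intensity,
plus a protein FASTA, a per-cell metadata table (chip assignment, diameter
in µm), and optionally a GMT gene-set file.

### Record-level filtering

Three record-level rules run in fixed order:

1. **q-value** — keep `q < 0.01`, strictly. A record at exactly the
   threshold is removed.
2. **Species ambiguity** — keep a record only if *every* accession in its
   protein group belongs to the target organism (default *Homo sapiens*).
   Single-cell preparations carry fetal bovine serum proteins; a peptide
   shared between a human and a bovine protein cannot be attributed safely,
   so the whole record is dropped rather than risking contaminated
   quantitation. This operates at protein-group granularity (the export's
   own ambiguity structure); it does not re-map peptides against the full
   proteome, which is a documented limitation.
3. **Keratins** — a record is removed if any group member's gene symbol
   matches `^KRT[0-9]+` (case-insensitive). Keratin-associated proteins
   (`KRTAP*`) are deliberately *not* matched: they are a distinct family,
   not the dust/skin contaminant class. The pattern is overridable.

### Matrix construction and matrix-level QC

Intensities are log2-transformed into a precursor × cell matrix (`NA` =
not observed). Two QC rules follow:

- **Cell QC** — cells with fewer than 500 observed precursors are dropped
  (strict; a cell at exactly 500 is kept). Counts are taken *after* the
  record-level filters, i.e. contaminants do not help a cell pass QC.
- **Coverage** — precursors observed in fewer than 50% of the *remaining*
  cells are dropped before imputation. The boundary is inclusive: exactly
  50% is kept, reading "less than 50% removed" literally. The denominator
  is the post-QC cell count, since the filter runs after cell QC; using
  all cells instead would make the filter depend on cells that are already
  excluded from every later stage.

### Median-relative scaling and imputation

Each precursor row is centered on the median of its observed values. The
relative scale serves two purposes: it makes the zero-initialization of the
imputation sensible, and it removes per-precursor ionization efficiency
before protein summarization. Centering is done at the precursor level —
at this point of the cascade precursor rows are the only rows that exist;
protein rows appear only after summarization.

Imputation is iterative truncated SVD: missing entries start at 0 (the row
median), the matrix is approximated at rank *k* (default `n_components =
5`), only the missing entries are replaced by the reconstruction, and the
loop stops when the relative change of the imputed entries (root sum of
squared change over root sum of squares) drops below `tol` (default 1e-2)
or after `max_iter = 100` iterations (warning + convergence flag). Observed
entries are never modified. Rank 5 is a deliberately conservative default
for matrices of a few thousand precursors by a few dozen cells; the
structure worth preserving (size axis, a handful of pathway modules, batch)
is low-dimensional, and a larger rank mostly fits noise back into the
imputed entries. The 1e-2 tolerance reflects that imputed values feed a
median-based summarizer: refining them below 1% changes downstream results
imperceptibly, and tests that need tighter reconstructions pass a smaller
`tol` explicitly.

### MaxLFQ summarization

For one protein group, the log2 abundance difference between cells *a* and
*b* is estimated as the median of `x[j, b] − x[j, a]` over precursors *j*
observed in both (minimum 1 shared precursor by default — the median of a
single difference). The per-cell abundances minimize the sum of squared
deviations from these pairwise ratios. The normal equations form a graph
Laplacian system; it is solved independently on each connected component of
the cell-pair graph, and the remaining additive gauge freedom is fixed by
anchoring each component so that the mean estimate equals the mean of the
observed precursor values over its cells. Cells with no observation stay
missing; no ratio is ever implied between disconnected components. After
imputation the matrix is complete, so there is a single component, but the
solver also handles pre-imputation (sparse) use.

Not implemented by design: the original method's large-ratio stabilization
and sample-normalization extras; the pairwise-median least-squares core is
the whole contract here.

### Batch correction

Chips are processing batches. The correction is the parametric
empirical-Bayes location/scale model: per protein, batch means are
estimated by least squares and residuals standardized by the pooled SD
(variance floored at 1e-8, since zero-variance proteins can arise after
imputation); per batch, the per-protein standardized means get a normal
prior and the per-protein variances an inverse-gamma prior, both estimated
across proteins by the method of moments; the shrunken parameters are
removed and the pooled scale and mean restored. One batch in, identical
matrix out (with a warning); a batch with a single cell is an error.
Parametric priors are the cited default for this adjustment; the
non-parametric variant is out of scope. A consequence worth knowing: the
adjustment re-centers each protein on the pooled estimate only
approximately — shrunken batch means do not average to exactly zero — so
grand means are preserved to ~1%, not to machine precision.

### Histone normalization

Histone content tracks ploidy rather than cell volume, which makes the
median relative abundance of histone proteins a per-cell reference level.
For each cell, that median (over histone-flagged proteins, minimum 3) is
subtracted from all proteins. The post-condition is exact: the per-cell
histone median is 0 afterwards, and the operation is idempotent. The
histone gene list ships as a plain-text pattern file (current HGNC `H1-*`,
`H2A*`, `H2B*`, `H3*`, `H4*` plus legacy `HIST*`) rather than being
hard-coded. Order contract: batch correction runs before histone
normalization.

### iBAQ

iBAQ uses the **raw, pre-normalization linear intensities** (after the
record-level filters and cell QC only): per protein and cell, the summed
observed precursor intensity divided by the count of theoretically
observable tryptic peptides of the group's lead (first) accession —
in-silico digestion after K/R, peptide length 6–50, zero missed cleavages,
proline rule off by default (all four exposed as arguments). The reported
summary is the median over cells of log10(iBAQ), ranked, optionally
restricted to the top-N proteins observed in more than half the cells
(N = 500 by default). Lead-accession digestion is a deterministic,
documented choice; longest-sequence digestion is a plausible alternative
the interface can accommodate via the annotation table.

### GO rollup, PCA, phenotype correlation

Gene sets come from a static GMT file — no live annotation service, so
analyses are hermetic and reproducible. Per term (minimum 3 mapped
proteins), the member with the most observed values is the reference (ties:
higher median abundance, then lexicographic row name); other members are
shifted by the median of (reference − member) over shared cells; the term
profile is the per-cell median of the shifted members. The construction is
invariant to per-member constant offsets.

PCA treats cells as observations of the (transposed) protein or term
matrix, centered, unscaled by default — on relative log2 data all features
share units, and unit-scaling would up-weight noise-dominated proteins; a
`scale` flag exists. Signs follow a deterministic convention (largest
loading element positive). Component–phenotype association is the Pearson
correlation of scores with each numeric metadata variable, two-sided
t-tests on n − 2 degrees of freedom, Benjamini–Hochberg adjusted across the
whole component × variable grid (the testing grid is 10 components by
however many phenotypes, so some multiplicity control is required; BH is
the field default).

## The synthetic data generator

`simulate_dataset()` draws the true log2 intensity of precursor *j* of
protein *p* in cell *c* as

> x = α_p + β_j + s · u_p · (log2 d_c − mean log2 d) + b_chip(c) +
> module effect + ν_c + ε

with α_p per-protein base abundance (Normal(14, 2)), β_j per-precursor
offset (Normal(0, 1)), d_c the cell diameter (uniform 17–36 µm), s the
size coefficient (default 1), b_k per-chip shifts (Normal(0, 0.5)), module
effects Normal(0, 0.5) shared by the proteins of a gene-set module, ν_c a
per-cell loading factor (Normal(0, 0.3)) common to all proteins, and ε
Normal noise (SD 0.5, scaled per chip). Observation is Bernoulli with
probability `plogis(mnar_slope · (x − mnar_midpoint)) · (1 − mcar_rate)` —
the standard logistic intensity-dependent missingness model for DIA — with
`mnar_slope = 0` meaning *no* intensity dependence (always observed), not a
coin flip. Observed linear intensities are `2^x`.

Two generator choices deserve emphasis:

- **Per-protein size responsiveness.** Each protein's size term is scaled
  by u_p ~ Normal(1, 0.8), truncated at zero, while histones are pinned at
  u = 1. If every protein responded to cell size identically, the size
  signal would be a pure per-cell offset and histone normalization would
  remove it entirely — no size axis could survive to PCA. Real proteomes
  scale differentially with cell volume (histones, tracking ploidy, are
  precisely the reference the normalization exploits), so differential
  responsiveness is both realistic and what makes the normalization and the
  size-axis recovery testable in the same pipeline.
- **The nuisance factor ν_c** exists so histone normalization has a known
  target to remove: recovery tests inject a large ν and check the estimated
  per-cell factors correlate with it at r > 0.99.

Contaminants are injected as whole proteins (5% of the FASTA, half bovine
serum, half human keratins); 30% of bovine precursor records also list a
human accession, creating genuinely species-ambiguous groups. Peptides are
built as explicit tryptic fragments (6–30 residues, ending in K/R, no
internal K/R, globally unique), so the theoretical peptide count is known
by construction and iBAQ ground truth is exact. Two chips of 24 cells are
the default batch layout for a 48-cell study: a single 48-well chip is one
batch, and two half-chips is the smallest configuration that exercises
batch correction while keeping per-batch sample sizes realistic.

The study-scale defaults (`default_paper_scale()`: 48 cells, 1100 proteins,
~3.2 precursors per protein, MNAR midpoint 13 and slope 0.6, MCAR 5%, 2%
q-value failures) are calibrated so a generated dataset lands, after
filtering, at roughly 2 thousand observed precursors per cell with roughly
two thirds of retained precursors at ≥ 50% coverage — the order of
magnitude of a real 48-cell chip study of primary human cells, not a
reproduction of any particular run.

**What the generator does not emulate:** retention-time structure, spectral
interference, search-engine scoring (q-values are drawn, not earned),
doublets or image-QC failures, cross-peptide intensity correlations beyond
the protein/module structure, and real histone biology beyond the u = 1
assumption. Passing recovery tests therefore demonstrates that the
implementation does what the model says — not that the model captures
everything about real single-cell DIA data.

## Numerical conventions

- Boundaries: `q < 0.01` kept (strict), cells with `>= 500` precursors
  kept (strict removal below), coverage `>= 50%` kept (inclusive), with a
  1e-12 guard against floating representation of fractions.
- Duplicate (precursor, run) pairs are an integrity error by default; a
  `"max"` resolution mode exists for deliberately merged reports.
- Zero, empty, `NA`, `NaN` and `Filtered` intensities are missing;
  strictly negative intensities are a hard error naming the row.
- Matrices round-trip TSV at 17 significant digits (lossless for doubles);
  missing entries are empty cells.
- MaxLFQ anchors per connected component (mean of estimates = mean of
  observed values); rollup ties break by observation count, then median
  abundance, then lexicographic name; PCA signs by largest-|loading|
  element positive. All three remove arbitrary degrees of freedom
  deterministically.
- The test suite and validation use problem sizes chosen for tight
  feedback: oracle comparisons at ≤ 6 cells × ≤ 8 precursors (hundreds of
  random instances), batch recovery at 500 proteins × 40 cells, end-to-end
  recovery at the 48-cell study scale.

## Known limitations

- Species filtering trusts the report's protein groups; peptides shared
  with unlisted proteomes are invisible to it.
- The EB batch model assumes exchangeable proteins within a batch; strong
  biological differences confounded with chip would be partially removed
  (no covariate support, by scope).
- svdImpute's rank must be chosen; with far fewer cells than precursors the
  practical ceiling is the cell count, and rank 5 is a heuristic, not an
  estimate.
- iBAQ from DIA precursor intensities inherits all caveats of comparing
  absolute abundances across proteins with different detectability.
- With ~48 cells, a null PC1–phenotype correlation has a sampling SD of
  ~0.15; single-seed null checks can land outside ±0.2 and should be read
  accordingly.
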