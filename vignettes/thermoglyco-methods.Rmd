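---
title: "Methods: TMT proteome and N-glycoproteome differential analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMT proteome and N-glycoproteome differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoglyco)
```

# Scope and data model

`thermoglyco` analyses isobaric-label (TMT) experiments in which the same
proteome is measured under several conditions multiplexed on one plex. The
canonical design, available as `default_design()`, is the thermophilic-fungus
setting: cultures at 30, 50 and 55 °C (T30/T50/T55), three biological
replicates each, on nine channels of a TMT-10plex, compared pairwise as
T50/T30, T55/T30 and T55/T50. Inputs are identified, quantified tables — a
peptide table with per-channel reporter intensities and a semicolon-delimited
accession list, a glycosite table (accession, 1-based Asn position,
per-channel intensities), a proteome FASTA and a per-accession annotation
table. Upstream steps (search engine, site localization, subcellular
prediction) are consumed, not re-implemented.

Two encoding rules matter throughout. A peptide is *unique* iff it maps to
exactly one accession, and only unique peptides carry quantitative weight.
And a missing intensity (`""`, `NA`, `NaN`) is distinct from a measured zero:
neither can enter a ratio, but zeros are data and survive round trips, while
missingness marks a channel that was not observed. Readers never drop rows
silently — every rejected row is reported with its row number and reason.

# Quantification

## Ratio formation and normalization

For comparison $c = N/D$ and peptide $p$, replicate pairing forms
$r_{pi} = I_{p,N_i} / I_{p,D_i}$ for replicate index $i$; a replicate ratio
exists only when both intensities are present and positive. Pairing by
replicate index (rather than averaging conditions first) preserves three
ratio observations per peptide.

Normalization applies the median-ratio rule over *unique* peptides twice:

1. each replicate-pair column is divided by its median over unique peptides,
   which makes the result exactly invariant to rescaling any single channel
   (a loading/labelling bias model);
2. all ratios are divided by the grand median, over unique peptides with a
   complete set of replicate ratios, of the replicate-averaged ratio.

Replicate averaging is the *geometric* mean — the arithmetic mean on the
log2 scale. All ratio arithmetic is done in log2 internally (symmetric
up/down, approximate normality for the t-test) and reported linear. After
stage 2 the median replicate-averaged ratio of complete unique peptides is
exactly 1; the test suite verifies this to 1e-9 over 1,000 random fixtures.

Shared peptides are carried through with normalized ratios (they remain
visible in outputs) but are excluded from every median.

## Protein roll-up

A protein's ratio per comparison is the median of the replicate-averaged
normalized ratios of its unique peptides, with the usual even-set convention
(mean of the two middle values). A peptide contributes only when it has at
least two replicate ratios, the minimum for the downstream t-test; proteins
with no unique peptide are omitted with a logged count. The even-set
convention has one subtle consequence: reversing a comparison maps every
replicate ratio to its reciprocal exactly, and all medians commute with the
reciprocal exactly at odd set sizes, but the linear interpolation between the
two middle values of an even set does not — so the up/down swap under
reversal is exact up to that interpolation. The geometric replicate mean was
chosen precisely so that the rest of the chain preserves reversal symmetry.

## Hypothesis test

The differential criterion rests on a two-tailed Student t-test, and the
package implements the equal-variance pooled two-sample form
(`student_t_two_tailed()`), with fixed conventions for degenerate input: if
both groups are constant, p = 1 when equal and p = 0 when not (flagged
`degenerate`). Its type-I error at $n = 3$ vs $3$ is verified by simulation
(10,000 null draws, rejection rate 0.05 ± 0.01 at $\alpha = 0.05$).

How to form the two groups from ratio data is a genuinely open design point;
the package tests **log2 normalized per-channel protein abundances**,
numerator-condition channels versus denominator-condition channels. A
protein's abundance in a channel is the median over its unique peptides of
the within-peptide-scaled reporter value (each peptide divided by its
geometric mean across channels, removing ionization efficiency) after
per-channel median normalization over unique peptides. This keeps three
values per group, uses the same median-ratio logic as the fold changes, and
centers true nulls at zero. The reported fold change and the tested quantity
are therefore two views of the same normalized data, not numerically
identical objects; calls combine both (ratio > 1.5 *and* p < 0.05).

## Glycosite correction

Site ratios are normalized with the unique-peptide normalizers of the same
comparison (sites share the plex, hence the channel biases). The reported
corrected ratio is exactly `raw / protein_ratio`
(`correct_site_ratio()`); when the parent protein is unquantified the
corrected value is flagged absent — never silently the raw ratio. For the
site t-test the correction happens per channel *before* testing: site channel
values are divided by the parent's channel abundances, so protein-level
variance propagates into the site test, as a per-replicate correction
should.

# Differential calling

Thresholds default to fold change 1.5 and $\alpha$ 0.05 on raw p-values, the
field's standard joint criterion for this kind of screen; down-regulation uses the reciprocal
bound ratio < 1/1.5, which makes direction reversal map up-calls to
down-calls. No multiple-testing correction is applied by default, keeping the raw-p
criterion above; `adjust = "BH"` switches on Benjamini–Hochberg
within each comparison. Rows lacking a ratio or p-value (fewer than two
replicate ratios, or an unquantified parent) are `untestable`, so the four
call classes always partition the quantified rows. Three-way overlaps of
differential sets are reported as the seven disjoint Venn cells
(`venn_partition()`), the triple intersection labelled `common`.

# Sequon and motif profiling

The N-glycosylation consensus is Asn–X–Ser/Thr with X ≠ Pro, i.e. the
pattern `N[^P][ST]`. All overlapping matches are reported (each Asn is
independently glycosylatable): `"NNTS"` yields positions 1 and 2. Observed
sites that do not sit on a sequon (deamidation artifacts and the like) are
flagged non-canonical and excluded from motif matrices by default, but never
dropped from the record. Flanking windows are 21-mers (±10 residues) padded
with `_` beyond the termini; the occupancy matrix reports per-position
residue frequencies with pad characters excluded from the denominator, so
boundary positions are not diluted and every covered position sums to 1.
Site-count distributions bin glycoproteins at 1, 2, 3, 4 and ≥5 sites; the
open-ended top bin is the conventional way to summarize heavily glycosylated
proteins.

# Amino-acid composition

Composition profiles are computed per protein first (percent of each of the
20 standard residues; B/Z/X/U excluded from numerator and denominator) and
averaged without length weighting, so `c("AA", "GGGGGGGG")` gives 50/50 —
the set-level question is "what does a typical protein in this set look
like". The dispersion is the standard error of that mean over proteins; ± conventions vary between reports, so the
choice (SEM over proteins) is stated here and in the output rather than left
implicit. Set comparisons report
the difference of means per residue with the same pooled t-test over
per-protein percentages.

# Enrichment

Category enrichment uses the two-tailed Fisher exact test with the
minimum-likelihood two-sided definition (sum of all equally-or-less-likely
tables with the same margins), as implemented by `stats::fisher.test`; the
test suite checks it against an exhaustive hypergeometric enumeration for
every margin configuration with $N \le 40$. The background defaults to the
quantified proteins, not the whole proteome, to avoid detection bias —
passing a different background is a one-argument change. Fold enrichment is
$(k/K)/(n/N)$. Heatmaps stack $-\log_{10} p$ (floored at 1e-15 to keep the
matrix finite) over comparison × direction cells, keep categories
significant in at least one cell and supported by ≥2 foreground proteins
(singleton categories make unstable rows), and cluster rows and columns with
Euclidean distance and average linkage; sorting identifiers before
clustering makes leaf order deterministic under ties. Localization summaries
count the precomputed primary compartment labels, with an explicit
`unknown` bin.

# The synthetic-data generator

`simulate_experiment()` emulates the targeted experimental conditions so that
every stage is
testable without any download: 3 × 3 design on TMT-10plex channels,
log-normal peptide intensities (`base abundance × condition effect ×
channel bias × noise`), 1,000 proteins with 1–10 unique peptides, 10%
up- and 10% down-regulated proteins per temperature contrast, log2 noise sd
0.25, a 10% shared-peptide rate, 150 glycoproteins whose site counts follow
the 59/22/10/5/3/1% distribution, threonine at the sequon +2 position with
probability 0.72, occupancy regulation independent of protein abundance, and
three planted enriched categories among the biological-process annotations.
Proteins upregulated in the first contrast carry a Glu/Asp-enriched residue
distribution, giving the composition comparison a planted signal.

Effect magnitudes are drawn from a log-normal with median 2× (sdlog 0.5)
rather than a point mass. This reflects real regulation — fold changes vary —
and it is what makes rank-correlation recovery a meaningful metric: with a
single fixed effect size the true fold changes are massively tied and a
rank correlation is bounded well below 1 for purely combinatorial reasons,
regardless of estimator quality. For the same reason the recovery check
correlates estimated and true log2 fold changes over the *regulated*
proteins (the nulls are all ties at zero). Ground-truth calls are defined by
applying the 1.5-fold threshold to the noiseless planted ratios, so a drawn
effect below 1.5× is truly `unchanged`.

What the generator does **not** emulate: missingness is uniform dropout
(default 1%), not intensity-dependent; there is no ratio compression from
co-isolation interference, no isotope-impurity cross-talk between channels,
no peptide-level modification or digestion variability, and shared peptides
simply sum their two parents' signals. Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery under the
stated generative model, not robustness to those instrument-level artifacts.

# Numerical choices and problem sizes

Degenerate t-tests follow the p = 0/1 conventions above; Fisher inputs are
validated against their margins; occupancy denominators exclude pads;
p-floors (1e-15) apply only inside heatmaps; medians use R's even-set
interpolation everywhere. One seed governs all randomness in a simulation,
and reruns of the pipeline (`run_all()`) are byte-identical, which the
manifest's MD5 checksums make easy to confirm. The default test and
acceptance workloads use 1,000 proteins for recovery checks, 1,000 random
fixtures for the normalization and roll-up oracles, 10,000 random sequences
for the sequon oracle and 10,000 null draws for the t-test calibration —
sizes at which each property is measured well inside its sampling error
while the whole suite completes in minutes.

# Known limitations

Protein grouping/parsimony is out of scope: accessions are taken as given,
and shared peptides are informative only as carried-through rows. The
t-test is unmoderated (no empirical-Bayes variance shrinkage), matching the
emulated criterion but costing power at very low replicate counts. Enrichment
treats categories independently (no GO-graph propagation) and reports raw
p-values by default. Site localization probabilities are carried but not
modelled. The pipeline's headline counts on synthetic data depend on the
generative model above; applying the package to real exports only requires
the readers' minimal schema, but the calibration statements are claims about
the model, not about any particular instrument.
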