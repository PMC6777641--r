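---
title: "Methods: quantifying and testing AM root colonization with amquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and testing AM root colonization with amquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amquant)
```

## The data and the two scoring systems

Arbuscular mycorrhiza (AM) fungi colonize plant roots through a sequence of
structures — hyphopodia on the root surface, intraradical hyphae,
arbuscules (the nutrient-exchange interface) and vesicles. Phenotyping this
symbiosis means estimating, per plant, how much of the root system carries
each structure. Two scoring systems dominate:

* **Gridline intersect**: root/gridline intersections are scored for
  presence of each structure; the data are percentages per replicate, one
  column per structure (`Total`, `Hyphopodia`, `IntrHyphae`, `Arbuscule`,
  `Vesicle`). Any subset of these columns is allowed.
* **Trouvelot**: each ~1 cm root fragment receives a mycorrhization class
  0–5 (density/coverage of colonization) and an arbuscule class A0–A3,
  written as codes like `3A2`; `0` means uncolonized.

Input tables are CSV with `Samples` and `Replicates` as the first two
columns. The first sample in file order is the control for all
control-versus-treatment annotation. Rows that repeat a
(sample, replicate) pair are *technical* replicates — repeated measurements
(grid) or additional root fragments (Trouvelot) of the same biological
replicate. Validation is atomic and exhaustive: dimensions, column names,
NA/empty cells, percentage ranges, and score grammar are all checked and
every offending cell is reported with its spreadsheet-style row number
(header = row 1). Values outside [0, 100] are hard errors because the grid
dialect is defined on percentages. Unknown columns are rejected rather than
silently dropped — misspelled headers otherwise become silently ignored
data; the one sanctioned extra column is `trt`, the second factor of
combined two-way designs.

## Trouvelot indices

For one biological replicate with $N$ fragments of which $n_c$ fall in
class $c$ ($n_0$ uncolonized):

$$F = 100\,\frac{N-n_0}{N},\qquad
  M = \frac{95 n_5 + 70 n_4 + 30 n_3 + 5 n_2 + n_1}{N},\qquad
  m = M\,\frac{N}{N-n_0},$$

with the class-intensity weights 1, 5, 30, 70, 95 % and arbuscule weights
10, 50, 100 % for A1–A3 (the conventional Mycocalc constants; the scoring
method itself does not print them). The arbuscule abundance within
colonized parts is $a = (100\,mA_3 + 50\,mA_2 + 10\,mA_1)/100$, where
$mA_j$ is the class-$j$ share of intensity among colonized fragments, and
$A = a M / 100$ is the arbuscule abundance over the whole root system.
All five indices are percentages in [0, 100]; $A = aM/100$ holds exactly
and $M = m$ whenever $F = 100$.

Numerical choices: a replicate with every fragment uncolonized gets
$m = a = A = 0$ (not NaN) so summaries stay numeric; bare nonzero classes
without an A part (e.g. `"3"`) are rejected rather than defaulted to A0,
because silent defaults are dangerous in manual data entry; codes are
matched case-insensitively (`3a2` ≡ `3A2`).

Technical replicates are *pooled* (fragments concatenated) before index
computation, not averaged — the indices are defined on a set of fragments,
and pooling weights each fragment equally. For grid data, technical
replicates are averaged per variable (unweighted mean), since each row is
already a percentage estimate of the same replicate.

## Summaries

`am_summary()` returns the per-replicate table (collapsed technical
replicates, or the indices table) and the per-sample table with mean and
standard error $s/\sqrt{n}$ per variable, $s$ the $n-1$ sample standard
deviation over biological replicates. A sample with a single biological
replicate reports `NA` for its SE rather than 0: no spread estimate exists.
Column order is fixed as sample, then variables in canonical order
(grid: Total, Hyphopodia, IntrHyphae, Arbuscule, Vesicle;
Trouvelot: F, M, m, a, A), then the SEs in the same order, since the
original tabular layout is not otherwise pinned down.

## Inference

Colonization percentages are bounded, often skewed and heteroscedastic, so
the primary analysis is rank-based. Per variable:

1. **Omnibus**: Kruskal–Wallis on the biological-replicate values with the
   usual ties correction $H' = H / (1 - \sum(t^3 - t)/(N^3 - N))$ and a
   $\chi^2_{k-1}$ upper-tail p value. An all-constant variable is defined
   as $H = 0$, $p = 1$.
2. **Pairwise**: rank-based Fisher LSD. On the pooled midranks,
   $$t_{ij} = \frac{|\bar R_i - \bar R_j|}
     {\sqrt{S^2\,\frac{N-1-H'}{N-k}\left(\frac1{n_i}+\frac1{n_j}\right)}},$$
   with $S^2$ the ties-respecting variance of the pooled ranks, referred to
   a two-sided $t_{N-k}$. This is the conventional KW-with-LSD procedure of
   agricultural statistics; the source workflow names the LSD criterion
   without formulas, so we adopt and document this standard form.
3. **Adjustment**: none, holm, hommel, hochberg, bonferroni, BH, BY, or fdr
   (alias of BH), applied *within* each variable's family of pairwise
   comparisons. Families are never pooled across variables, and the
   asterisk display adjusts over the full per-variable family (not just
   control-vs-treatment pairs) — one coherent family per variable.

All tests are two-sided and fully deterministic; no randomness enters
inference. A degenerate family (identical values everywhere) yields
pairwise $p = 1$.

**Annotations.** Letters come from the insert-and-absorb compact letter
display: starting from one group holding all samples, each significant pair
splits the groups containing it and subset groups are absorbed; letters are
assigned scanning samples in sample order. The algorithm guarantees the
defining equivalence — two samples share a letter iff their adjusted
p ≥ α — which the test suite checks exhaustively for all significance
patterns with k ≤ 4. Asterisks are single-tier: a sample is marked `*` iff
its adjusted p against the control is below α (default 0.05); p values
between 0.05 and a stricter user α are deliberately unmarked.

**Two-way ANOVA** (`anova_two_way()`) is the one parametric piece, for
combined designs with a `trt` factor: sequential (Type I) sums of squares
in the order sample, trt, sample:trt — the classic ANOVA-table convention —
plus residual-vs-fitted pairs and normal Q-Q coordinates for the two
assumption checks. When the residual SS is zero (a perfect fit) the F
ratios are undefined and flagged NA.

## Plots

Four kinds, all faceted one-variable-per-panel with samples in file order
on the x axis and a fixed y label "Colonization (%)": `dotplot` (facet
labels below), `dotplot2` (labels on top), `barplot` (per-sample mean, SE
whiskers), `boxplot` (median, quartiles, whiskers to the furthest point
within 1.5 IQR, outliers as dots). Dots are jittered horizontally
(width 0.1 of the group spacing) with a fixed seed so exports are
byte-reproducible. Annotation marks are anchored 5 % of the facet's y-range
above each sample's highest drawn element (points/box for dot and box
kinds, mean + SE for bars) — high enough to clear the data, close enough
to read. The default palette is the Okabe–Ito colorblind-safe set, cycled
when samples outnumber colors. Export formats: pdf, svg, eps, png, jpeg,
with physical width/height in cm, mm or in and a dpi setting (svg uses the
cairo device since svglite may be absent).

## Simulators

`simulate_grid()` draws replicate values from a normal distribution
truncated to [0, 100] (inverse-CDF sampling, so `sd = 0` degenerates to the
mean exactly). Its defaults emulate a three-level phosphate dose-response:
per-sample means rounded from the worked gridline table (e.g. Total
87/66/11 %), 7 biological replicates, sd = 8 — the observed
between-replicate spread in such experiments.

`simulate_trouvelot()` draws each fragment's mycorrhization class from a
per-sample probability vector over classes 0–5, then an arbuscule class
from conditional A0–A3 probabilities; defaults emulate a four-sample
strigolactone-analog experiment (class mass concentrated in classes 2–5 for
well-colonized samples, arbuscule mass on A2/A3), 30 fragments per
replicate (a typical microscopy workload) and 3 replicates.

Seeds are mandatory and the global RNG state is restored afterwards. What
the generators *do not* emulate: within-root spatial correlation of
fragments, over-dispersion between experiments, integer rounding of
manually recorded percentages, and missing-at-random cells. A green
calibration test therefore certifies the method's behavior under clean
sampling assumptions, not robustness to those artifacts.

## Known limitations

* The rank-LSD pairwise procedure is unprotected (run regardless of the
  omnibus outcome), as is conventional for this display style; users
  wanting protection should gate on `anova_one_way()`'s omnibus p.
* The chi-square approximation to the Kruskal–Wallis null is coarse below
  ~5 replicates per group; the suite logs (without tightly asserting) its
  distance from the exact permutation distribution at n = 3 + 3.
* Trouvelot dialects with vesicle-suffix codes, per-fragment length
  weighting, Excel ingestion, and locale decimal commas are out of scope.
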