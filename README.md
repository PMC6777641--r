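# amquant

Statistical analysis and display of quantitative root colonization by
arbuscular mycorrhiza (AM) fungi.

AM researchers estimate how much of a root system carries fungal
structures (hyphopodia, intraradical hyphae, arbuscules, vesicles) with one
of two scoring systems: the **gridline intersect** method (percent of
root/gridline intersections per structure) or the **Trouvelot** method
(each ~1 cm fragment gets a mycorrhization class 0–5 and an arbuscule
class A0–A3, coded `3A2`, `5A3`, `0`, …). `amquant` takes such tables from
raw CSV to publication-ready statistics and figures:

* validated ingestion of both dialects (exhaustive, atomic error
  reporting; first sample = control; repeated (sample, replicate) rows are
  technical replicates);
* the Trouvelot indices per biological replicate
  — frequency *F*, intensity *M* (root system) and *m* (colonized
  fragments), arbuscule abundance *a* (colonized parts) and
  *A* = *a·M*/100 (root system), using the conventional class weights
  1/5/30/70/95 % and arbuscule weights 10/50/100 %;
* per-replicate and per-sample (mean ± SE, SE = s/√n) summary tables;
* per-variable Kruskal–Wallis omnibus tests and rank-based Fisher-LSD
  pairwise comparisons with holm / hommel / hochberg / bonferroni / BH /
  BY / fdr adjustment, plus a parametric two-way ANOVA (sequential SS,
  residual and Q-Q diagnostics) for combined designs with a `trt` factor;
* faceted dotplots, barplots and boxplots with compact-letter or
  asterisk-vs-control annotation;
* CSV/figure export with fixed naming (`<base>_per_Replicate.csv`,
  `<base>_per_Sample.csv`, `<base>_stat.csv`; pdf/svg/eps/png/jpeg);
* seeded simulators for both dialects and a CLI for the whole workflow.

## Worked example

The package ships the worked gridline table of a *Lotus japonicus*
phosphate dose-response experiment (three phosphate levels, seven
biological replicates, five structures):

```r
library(amquant)
gr <- read_colonization_table(
  system.file("extdata", "grid_phosphate.csv", package = "amquant"), "grid")

s <- am_summary(gr)
s$per_sample[, c("Samples", "Total", "Arbuscule", "Total_se", "Arbuscule_se")]
#>            Samples    Total Arbuscule Total_se Arbuscule_se
#> 1    Low phosphate 87.42857 72.714286 3.014703     3.583788
#> 2 Medium phosphate 65.85714 51.571429 4.339347     3.584737
#> 3   High phosphate 11.00000  9.571429 2.819997     2.776235
```

Total colonization falls from 87 % at low phosphate to 11 % at high
phosphate — the dose-dependent inhibition the experiment was designed to
detect. Are the drops significant? Each structure is tested on its own
(a p value for `Total` says nothing about `Vesicle`):

```r
am_stat(gr, method = "BH")
#> Pairwise comparisons (Kruskal-Wallis rank LSD, adjustment: BH)
#>           sample_i         sample_j        Total   Hyphopodia   IntrHyphae    Arbuscule      Vesicle
#> 1    Low phosphate Medium phosphate 2.044425e-04 4.886351e-02 2.044425e-04 5.081281e-04 2.295994e-02
#> 2    Low phosphate   High phosphate 2.418924e-08 1.348917e-05 2.418924e-08 5.787778e-08 2.477463e-06
#> 3 Medium phosphate   High phosphate 5.561037e-05 5.883199e-04 5.561037e-05 7.588976e-05 1.937400e-04
```

All three levels differ from each other for `Total` even at α = 0.01, so
the compact letter display assigns three distinct groups:

```r
cmp <- am_stat(gr, method = "BH")
compact_letter_display(cmp[cmp$variable == "Total", ], alpha = 0.01,
                       samples = sample_order(gr))
#>    Low phosphate Medium phosphate   High phosphate
#>              "a"              "b"              "c"
```

Plot and export everything:

```r
p1 <- am_dotplot(gr, main = "Grid experiment", annot = "letters", method = "BH")
am_save(am_summary(gr), "Exp001")       # Exp001_per_Replicate.csv, Exp001_per_Sample.csv
am_save(am_stat(gr, method = "BH"), "Exp001")  # Exp001_stat.csv
am_save(p1, "Exp001.pdf", width = 21, height = 21, units = "cm", dpi = 300)
```

The same workflow applies to Trouvelot data
(`read_colonization_table(..., "trouvelot")`); `am_summary()` then
computes F, M, m, a, A per biological replicate, pooling technical
replicates as fragments.

## Command line

```sh
Rscript inst/cli/amquant.R summarize --type grid data.csv --out Exp001
Rscript inst/cli/amquant.R stat --type grid data.csv --method fdr --out Exp001
Rscript inst/cli/amquant.R plot --type trouvelot data.csv --kind boxplot \
    --annot letters --method BH --out fig.png --width 6 --height 4 --dpi 300
Rscript inst/cli/amquant.R simulate --type trouvelot --seed 7 --out sim
```

Diagnostics go to stderr with a nonzero exit on validation failure; data
only ever goes to files.

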