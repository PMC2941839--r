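# steroidscreen

Interpretation of quantified urinary steroid metabolite profiles for the
differential diagnosis of inborn errors of steroidogenesis and steroid
metabolism — congenital adrenal hyperplasia variants (21-, 11β- and
17α-hydroxylase and 3β-HSD2 deficiencies), P450 oxidoreductase deficiency
(ORD), apparent mineralocorticoid excess (AME), apparent cortisone
reductase deficiency (ACRD), 5α-reductase type 2 and 17β-HSD3
deficiencies.

It is written for clinical chemists and endocrine researchers who have a
table of urinary steroid metabolite excretions (µg/24 h, 30–40 analytes
per sample) and want the two standard readouts:

1. **Grouped quantitative report**: each analyte and each of five
   metabolite groups (androgens, androgen precursors, mineralocorticoids
   and precursors, glucocorticoid precursors, glucocorticoids) plotted
   against the mean and empirical 5th/95th centiles of a normal cohort.
2. **Diagnostic ratio panel**: 23 precursor/product metabolite ratios
   of the form

   sum(metabolites of the enzyme's substrate) / sum(metabolites of its product)

   e.g. 17HP/(THE + THF + 5αTHF) for 21-hydroxylase deficiency or
   THE/(THF + 5αTHF) for ACRD. A blocked enzyme elevates its ratios; a
   disorder is called **positive** when *all* of its ratios exceed the
   cohort 95th centile, and concurrent positives are ranked by the
   geometric mean of value/p95.

Because no public patient profiles exist, the package also contains a
steady-state pathway-flux **simulator**: hormone nodes, enzyme edges with
cofactor dependencies (POR-dependent microsomal CYPs, the b5-dependent
17,20-lyase step, the ADR/Adx-dependent mitochondrial CYP11 enzymes),
5α/5β and 11-oxo/11-hydroxy metabolism partitions, the back-door androgen
route, log-normal inter-individual noise, and one preset per disorder.
Every piece of the diagnostic engine is tested end-to-end against it.

## Worked example

Simulate a normal reference cohort, build centiles, and diagnose a
simulated severe ORD case:

```r
library(steroidscreen)
reg     <- load_registry()                                   # 33 analytes, 23 ratios
normals <- simulate_cohort(scenario_preset("normal"), 200, reg, seed = 11)
ref     <- build_reference(normals, reg)
case    <- simulate_cohort(scenario_preset("ORD"), 1, reg, seed = 13)[[1]]

evaluate_panel(case, reg, ref)
#> diagnostic ratio panel for sample ORD_0001
#>   POSITIVE ORD (POR): 5/5 ratios high, rank score 33.27
#>   POSITIVE 17aOHD (CYP17A1): 2/2 ratios high, rank score 15.10
#>   POSITIVE 21OHD (CYP21A2): 3/3 ratios high, rank score 11.62
```

All five ORD ratios are high — e.g. `ORD_1`, (17HP+PT)/(An+Et), sits at
21.1 against a cohort p95 of 1.21 — and ORD outranks the expected partial
overlaps with 17α- and 21-hydroxylase deficiency (ORD cripples both
CYP17A1 and CYP21A2, which share the electron donor POR). The grouped
report shows the classic ORD constellation:

```r
render_quant_report(case, ref, reg)
#> quantitative steroid report for ORD_0001
#>                         group_label   amount ref_mean ref_p5 ref_p95   flag
#> 1                         androgens    518.0    967.7  707.8  1269.7    low
#> 2               androgen_precursors 533108.6   4928.1 3474.5  6556.0   high
#> 3 mineralocorticoids_and_precursors  14472.4    963.6  748.1  1216.9   high
#> 4         glucocorticoid_precursors 366039.4   3261.9 2586.8  4087.9   high
#> 5                   glucocorticoids    291.9    289.3  240.5   347.1 normal
```

low androgens, grossly elevated pregnenolone/progesterone/17OHP and
corticosterone pathway metabolites, normal glucocorticoids under
non-stress conditions. `plot_reports()` renders either report as SVG/PNG
(dots over the shaded p5–p95 band, log axis) with a structured JSON
sidecar.

## Command line

```sh
steroidscreen simulate  --preset ORD -n 50 --seed 13 -o cohort.tsv
steroidscreen reference build -i normals.tsv -o ref.json
steroidscreen diagnose  -i patient.tsv --ref ref.json -o panel.json
steroidscreen report    panel -i patient.tsv --ref ref.json -o panel.svg
steroidscreen registry  show --ratios
```

(the `exec/steroidscreen` script, or `run_cli()` from R). Exit status 0
on success, 2 on validation errors. Profiles are plain TSV/CSV, long or
wide, auto-detected; absent analytes mean *not measured*, explicit zeros
mean *below detection*.

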