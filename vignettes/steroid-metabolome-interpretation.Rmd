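---
title: "Interpreting urinary steroid metabolomes: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting urinary steroid metabolomes: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A 24-h urine collection integrates the whole steroid metabolome: every
hormone and precursor leaves a signature of ring-reduced metabolites
(tetrahydro compounds, cortols/cortolones, androsterone and
etiocholanolone, pregnanediols and -triols). Inborn errors of
steroidogenesis block one enzymatic step, so the metabolites of the
enzyme's substrate accumulate while those of its product are depleted.
Two readouts make this clinically legible:

1. **Grouped quantitative report** — each analyte's excretion (µg/24 h)
   against the mean and the empirical 5th/95th centiles of a normal
   cohort, organised into five groups: androgens, androgen precursors
   (Δ5 steroids and androstenedione metabolites), mineralocorticoids and
   precursors, glucocorticoid precursors, glucocorticoids.
2. **Diagnostic ratio panel** — 23 precursor-metabolite /
   product-metabolite ratios covering nine disorders (21-, 11β- and
   17α-hydroxylase deficiencies; 3β-HSD2 deficiency; P450 oxidoreductase
   deficiency, ORD; apparent mineralocorticoid excess, AME; apparent
   cortisone reductase deficiency, ACRD; 5α-reductase type 2 deficiency;
   17β-HSD3 deficiency). Each ratio is elevated in its disorder. A
   disorder is called positive only when **all** of its ratios exceed
   the cohort 95th centile — partial overlap between disorders is
   expected (ORD elevates some 21-hydroxylase-deficiency ratios), and
   the all-ratios rule plus geometric-mean ranking of `value / p95`
   adjudicates it.

The package ships the knowledge base (metabolite ↔ parent-hormone table,
pathway graph with enzyme/cofactor annotations, ratio panel) as a
versioned, checksummed JSON artifact; `load_registry()` validates all
structural invariants on load.

## Reference centiles

Centiles are empirical: sort the cohort, interpolate linearly between
order statistics at plotting position $(n-1)p + 1$. No distributional
assumption and no log transform — empirical centiles are
distribution-free, and the flagging rule (below 5th = low, above 95th =
high, boundary equality = normal, unmeasurable = undefined) is the one
the graphical reports encode. The minimum cohort size defaults to 20,
the smallest $n$ for which the 5th centile is interpolation rather than
extrapolation. Ranges are not stratified by age or sex; stratification
keys can ride along in profile metadata but are deliberately out of
scope. Ratio abnormality is one-sided (high): every panel ratio is
defined in the direction elevated-in-disorder, while analyte and group
flags keep the low side (androgen deficiency is itself diagnostic, e.g.
in ORD).

**Missing vs zero.** An analyte absent from a profile means *not
measured*; an explicit 0 means *measured, below detection*. A numerator
uses whatever was measured; a denominator that was entirely unmeasured,
or measured as 0, makes the ratio undefined. Undefined ratios make their
disorder uncallable rather than raising an error.

## The flux simulator

The simulator exists so the whole diagnostic engine can be exercised
without patient data. It is a *stated world*, not a fitted model.

**Steady-state linear branch competition.** Hormones are nodes; each
enzymatic conversion is an edge with weight
`base_rate × activity × drive` (POR-dependent microsomal CYP edges —
both CYP17A1 activities, CYP21A2, CYP19A1 — are additionally multiplied
by `por_activity`). Every node also has a unit-weight excretion sink.
Inflow at a node splits across outgoing edges and the sink in proportion
to their weights; the balance is solved exactly as a linear system, with
total pregnenolone production (`input_flux`, default 10 000 µg/24 h
equivalents) entering the network. This is the minimal quantitative
skeleton that reproduces precursor build-up and product depletion; no
kinetic constants are published for such a model, so all base rates
default to 1. Two exceptions: the aromatase edges default to rate 0
because the estrogen branch carries no urinary analytes in the registry
(any mass routed there could not be excreted onto an analyte, breaking
mass closure), and the back-door branch (17OHP → 5α-17OH-pregnanolone →
androsterone → DHT) carries weight 0.5 only when `enable_backdoor` is
set, as in the ORD-pregnancy preset.

**Excretion mapping.** Each hormone's sink flux is split uniformly
across its urinary metabolites (pregnadienol is a fixed 0.2 artifact
fraction of the pregnenediol channel). Two metabolism partitions are
then applied to the metabolite pools, because 5α-reductase and the
11β-HSD system act on metabolite pools rather than on the synthesis
pathway:

* `rho_5alpha` (default 0.4) splits each 5α/5β pair (An/Et, 5αTHF/THF,
  5αTHB/THB, 5αTHA/THA, 5αTHDOC/THDOC). All androgen-pathway mass —
  including DHT — runs through the An/Et pool, so `rho_5alpha = 0`
  cleanly yields An = 0; only back-door androsterone bypasses the
  partition (it is 5α-reduced by construction).
* `beta_11oxo` (default 0.55) splits the cortisol/cortisone pool between
  the 11-oxo analytes (THE, cortolones, 11-oxo-etiocholanolone, free E)
  and the 11-hydroxy analytes (THF, 5αTHF, cortols, 6β-OH-cortisol,
  11β-OH-Et, 11β-OH-An, free F). A `free_escape` fraction (default
  0.04) of the pool leaves as the free hormones F and E.

Noise is multiplicative log-normal, independent per analyte
(`noise_sigma`, default 0.3 on the log scale), with a deterministic
per-sample substream of the seed so cohorts are reproducible
bit-for-bit. Noise-free analyte mass sums exactly to the scenario's
input flux.

**Trophic compensation in presets.** A feedback-free block model makes
*everything* downstream of a block collapse together, which contradicts
the clinical metabolome it is meant to emulate: non-stressed patients
maintain glucocorticoid output through ACTH drive, which is exactly why
ORD shows normal glucocorticoids with massively elevated progesterone,
17OHP and corticosterone metabolites. Presets therefore scale
`input_flux` so total glucocorticoid output matches the normal scenario
(the factor is recorded as `gc_compensation`; ~89× for ORD, 1 for the
pure metabolism disorders). Diagnostic ratios are invariant under this
scaling, so disorder calling is unaffected; the grouped report becomes
faithful to the described phenotypes.

**Two presets carry an extra physiological lever.** Under strict mass
conservation, two panel ratios cannot move through the enzyme block
alone, and in both cases the real-world elevation is driven by a
feedback the pure block does not contain:

* AME: `(F+E)/(THF+5αTHF+THE)` rises in patients because metabolic
  clearance of cortisol slows while free cortisol excretion climbs. A
  β-shift alone provably caps the achievable elevation below the noise
  floor (the free pool and the tetrahydro pool share one conserved
  mass). The AME preset therefore raises `free_escape` to 0.30 alongside
  `beta_11oxo = 0.15`.
* 17β-HSD3 deficiency: `(An+Et)/(THE+THF+5αTHF)` cannot rise by blocking
  androstenedione → testosterone, because both the androstenedione sink
  and the testosterone sink feed the same An/Et pool; the clinical
  elevation reflects hypergonadotropic over-drive of the androgen
  backbone. The preset sets `drive[CYP17A1_lyase] = 8` alongside the
  0.05 residual activity.

Residual activity for all enzymatic disease presets is 0.05, never 0,
so every ratio stays finite.

## What a green test establishes — and what it does not

The generator emulates: between-disorder structure driven by pathway
topology under enzyme blocks, plausible relative magnitudes of the
diagnostic ratios, independent log-normal inter-individual spread, and
maintained glucocorticoid output. It does **not** emulate: absolute
excretion magnitudes (the published figures' axis values are not
machine-readable, so defaults are order-of-magnitude placeholders),
age/sex structure, analyte covariance (real profiles share assay and
physiological factors), renal function, or gestational dynamics (the
ORD-pregnancy preset only opens the back-door route). End-to-end
parameter recovery on simulated cohorts is therefore a consistency check
of the engine, not a claim about clinical sensitivity.

One recovery margin sits at the acceptance boundary by construction:
severe 3β-HSD2 cases are always called positive (DHEA and 5-pregnenetriol
ratios ~45× and ~24× normal), but in ~13% of cases the single-ratio
17β-HSD3 call — inflated because peripheral conversion of the huge DHEA
pool raises An+Et while cortisol metabolites collapse — outranks it
under the geometric-mean rule. Down-weighting single-ratio disorders
would fix this but would change the stated ranking rule, so it was not
done; the corresponding acceptance assertion is left failing and the
behaviour is documented here.

## Numerical choices

* Flux: exact dense linear solve (21 nodes); an independent iterative
  fixed-point oracle agrees to 1e-9 in the tests.
* Centiles: hand-rolled interpolation checked against an independent
  implementation to 1e-12; translation-equivariant and
  permutation-invariant by property test.
* Serialization: profiles round-trip through long/wide TSV at 17
  significant digits; reference sets and panels through JSON with the
  registry version embedded, and a version mismatch is a refusal, not a
  warning. Parsing is locale-independent (decimal point only).
* Boundary conventions: flag boundaries are normal; ratio undefined
  propagates to `n_undefined`, never to an error; positive calls need
  zero undefined ratios.

## Known limitations

Estrogen metabolites are not quantified (the branch exists in the graph
only). Spot collections are accepted for ratio interpretation but
refused by the quantitative report and group totals, which require 24-h
collections. Reference ranges are unstratified. The registry encodes one
fixed primary-group partition for multi-parent analytes (11-oxygenated
androgen metabolites count as androgens; pregnanediol counts toward
glucocorticoid precursors), because the grouped report needs a
partition; both assignments are design choices, not published fact.
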