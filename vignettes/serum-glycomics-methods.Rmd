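---
title: "Methods: whole-serum N-glycan profiling, ratio-marker selection and prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-serum N-glycan profiling, ratio-marker selection and prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoprof)
```

## The analysis problem

Whole-serum N-glycomics measures the pool of asparagine-linked
oligosaccharides released from all serum glycoproteins at once. After
glycoblotting enrichment, sialic-acid methyl esterification and
benzyloxyamine (BOA) tagging of the reducing end, glycans are detected by
MALDI-TOF mass spectrometry as sodium adducts, and each peak is described
only by its monosaccharide *composition*: the counts of hexose (Hex),
N-acetylhexosamine (HexNAc), deoxyhexose (Fuc) and sialic acid (NeuAc),
written as a four-digit code such as `5402` (Hex5 HexNAc4 Fuc0 NeuAc2).

`glycoprof` implements the downstream analysis of such a profile in an
ulcerative-colitis (UC) versus healthy-control (HLT) setting:

1. composition-based mass annotation and structural classification of a
   61-glycan serum panel;
2. a biosynthesis network over detected compositions with group
   fold-change overlays;
3. Bonferroni-controlled differential screening and AUROC-based selection
   of an up/down abundance-ratio marker;
4. bootstrap comparisons of the marker across clinical strata;
5. Kaplan-Meier / Cox prognostic analysis of time to surgery.

Because no patient-level data are publicly available for this design, the
package ships a synthetic cohort generator with the statistical structure
the analysis assumes, so every stage is exercised and validated end to
end.

## Mass model

The theoretical m/z of a composition is the sum of residue monoisotopic
masses (Hex 162.052824, HexNAc 203.079373, Fuc 146.057909, NeuAc
291.095417), plus one methyl-ester increment (+14.015650) per NeuAc, the
BOA oxime tag (+123.068414, i.e. C7H9NO net of water) and the cation
adduct. The adduct is sodium (+22.989769) with no electron-mass
correction: this reproduces the panel's smallest member, Hex5HexNAc2, at
1362.481 to three decimals, whereas a protonated ion would not. Peaks are
conventionally *named* by the integer part of the theoretical m/z — the
label is `floor(m/z)`, not the rounded value, which is what makes
Hex5HexNAc4Fuc1 (1914.698) "glycan m/z 1914".

```{r mass}
glycan_mz(parse_glycan_code(c("5200", "5402", "5410", "7634")))
peak_label(parse_glycan_code(c("5402", "5410")))
```

Annotation of observed peak lists uses a ±0.2 Da tolerance by default
(typical for externally calibrated MALDI-TOF); assignment is greedy by
mass distance, one candidate per peak, with deterministic tie-breaks
(fewest residues, then lexicographic composition), so results do not
depend on peak order.

## Structural classification

Compositions cannot resolve isomers, so classification is a documented
heuristic over counts:

* **high-mannose**: HexNAc 2, Hex 5–9, no Fuc/NeuAc;
* **hybrid**: HexNAc 3 with Hex ≥ 5;
* **complex**: HexNAc ≥ 4, or HexNAc 3 with Hex ≤ 4 (truncated);
* antennarity of complex glycans is `min(HexNAc − 2, 4)`, with one
  override: HexNAc 5, Hex 3, NeuAc 0 is treated as a *bisected*
  bi-antennary structure, because composition alone cannot distinguish a
  bisecting GlcNAc from a third antenna and agalactosylated species of
  this composition in serum are typically bisected IgG-type glycans;
* galactose count is Hex − 3 (the trimannosyl core contributes three
  mannoses); *agalactosyl bi-antennary* means complex, two antennae,
  galactose 0;
* *highly sialylated multi-branched* means complex, ≥ 3 antennae and
  ≥ 3 NeuAc;
* *sialyl Lewis X potential* requires NeuAc ≥ 1 and Fuc ≥ 2, a single
  fucose being assumed core-linked.

On the packaged 61-glycan reference panel these rules reproduce the
published marginals exactly: 5 high-mannose, 6 hybrid, 50 complex
(25/10/15 bi/tri/tetra-antennary), 43 sialylated, 33 fucosylated, 13
highly sialylated multi-branched and 4 agalactosyl bi-antennary glycans.

```{r panel}
table(classify_glycans(reference_panel())$type)
```

**Panel provenance.** The published study never deposited its glycan
list; only the class marginals, the m/z range (1362.481–4157.522) and six
compositions (5200, 5402, 5410, 6523, 7624, 7634) are anchored by the
printed text. The packaged panel is therefore a *synthetic
reconstruction*: membership beyond the anchors was chosen once to satisfy
the full constraint set and is revalidated against the classifier — not
against hard-coded counts — every time `reference_panel()` is called, so
any classifier change that breaks the marginals fails loudly. Individual
panel members other than the anchors cannot be verified against the
study.

## Biosynthesis network

Nodes are the detected panel compositions; a directed edge runs from a to
b when b exceeds a by exactly one residue of one kind — one
glycosyltransferase step. Only detected compositions appear (no inferred
intermediates), matching how such pathway figures are drawn from measured
panels. Node fold changes are `log2(mean case / mean control)` with
*arithmetic* group means. Exports are GraphML (attributes embedded) and
SIF plus a node-attribute table, both accepted by Cytoscape; the SIF
relation is fixed to `addition`.

## Differential screen and ratio marker

Per glycan, groups are compared with the classic equal-variance Student
t-test (a Welch variant is available behind a flag, but the pooled test is
the study's stated method) at the Bonferroni threshold `alpha / G`
(0.05/61 for the full panel). The AUROC is computed in the Mann-Whitney
form — P(case value > control value), ties counted one half — which
equals the trapezoidal area under the empirical ROC. The screen is
vectorized over columns; the test suite asserts per-column equality with
`student_t_test()` and the brute-force pairwise AUROC oracle.

The ratio marker takes the significant up-regulated glycan with the
highest AUROC as numerator and the significant down-regulated glycan with
the highest direction-corrected AUROC (max of 1 − AUROC) as denominator.
AUROC orientation for down-regulated markers is genuinely ambiguous in
published reports; we store every AUROC as P(case > control) and select
"best down" by 1 − AUROC, documenting that convention. Ties are broken by
the smaller integer label, for determinism. Per-sample ratios drop
samples with non-positive denominators with a warning (abundances are
quantities and should be positive). The ratio's AUROC is then computed on
the per-sample ratios; because AUROC is rank-based, rescaling any glycan
column leaves the marker's AUROC unchanged.

Bootstrap validation resamples within groups with replacement
(B = 10000 by default); the point estimate is the mean of the B bootstrap
means and the two-sided p uses the add-one rule
`2·min(#(diff ≤ 0)+1, #(diff ≥ 0)+1)/(B+1)`, capped at 1, so a zero
p-value is never reported. Clinical strata comparisons (total vs
left-sided colitis, CAI > 10 vs ≤ 10, Mayo endoscopic score 3 vs 1–2
with score-0 patients excluded, steroid-refractory yes/no) report both
the t-test and the bootstrap.

## Survival analysis

The Kaplan-Meier estimator, the 1-df log-rank test and the Cox
proportional-hazards model are implemented in the package itself;
`survival::coxph()` and `survival::survdiff()` serve as independent
oracles in the test suite (agreement to 1e-4 on random datasets) rather
than as the implementation, so the two routes stay distinct. Design
choices:

* **Ties**: Breslow by default — simple and adequate for continuous
  synthetic times — with Efron behind a flag; the original analysis used
  JMP, which does not state its method.
* **Inference**: Newton-Raphson on the log partial likelihood with step
  halving, to gradient norm < 1e-8 or 100 iterations; Wald 95% CIs
  (`exp(b ± 1.96·se)`) and p-values, matching the HR + CI presentation
  of prognostic tables. Monotone likelihoods (perfect separation) are
  flagged, never returned silently.
* **Model building**: covariates with univariate Cox p < 0.1 enter the
  multivariate model; before the joint fit, covariate pairs with
  |Pearson r| > 0.7 are resolved by dropping the member with the larger
  univariate p. The source study states the collinearity exclusion but no
  numeric criterion; 0.7 is the conventional screening threshold. The
  correlation can be computed on supplied continuous values (e.g. the raw
  ratio underlying a dichotomized flag) because collinearity between
  binary flags understates the dependence of the underlying measures.
* **Dichotomization**: empirical quantile with linear interpolation
  (R type 7); "high" is *strictly greater* than the cutoff, matching the
  "> median" convention.
* **Sensitivity/specificity** of a dichotomized marker use the
  event-ever definition (censoring ignored), because single proportions
  without a time horizon are what such studies report; with heavy
  censoring this understates incidence, which is a documented caveat.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated; its defaults were fixed once, from the published summary
statistics, and are not tuned per analysis:

* **Design**: 75 patients, 75 controls — the published cohort size.
* **Abundances**: log-normal per glycan. Baselines are scaled by
  structural class so a control sample totals ≈ 400–450 pmol/µL with
  the fully sialylated bi-antennary glycan 5402 the most abundant
  species (105 pmol/µL) and a control 5402/5410 ratio near the reported
  10.5. Log10 SD is 0.09 for the two abundant, precisely quantified
  marker glycans and 0.13 for low-abundance species — quantification
  precision in MALDI-TOF glycomics improves with abundance, and this
  heterogeneity is also what makes the planted pair carry the dominant
  discriminative effect, as the study observed for its marker.
* **Disease effects** (log10): +0.11 on sialylated complex glycans
  (reproducing the reported complex-glycan elevation, ≈ 327 → 422
  pmol/µL), +0.19 on 5402 and −0.14 on 5410 — sized so the
  patient/control ratio medians sit near the reported 22.4 vs 10.5 —
  +0.11 on agalactosyl bi-antennary glycans (elevated but not
  severity-linked) and −0.08 on the neutral bi-antennary species, giving
  the screen both directions.
* **Severity latent**: one standard normal per patient drives CAI
  (centred at the reported median of 10), Mayo score, disease extent,
  steroid-refractory status, the marker pair (±0.08) and each highly
  sialylated multi-branched glycan (+0.12). A single shared mechanism
  reproduces the consistent stratum effects and makes the marker and the
  aggregate collinear (r ≈ 0.75 within patients), exercising the
  multivariate exclusion rule.
* **Survival**: exponential surgery times with baseline hazard
  0.011/month multiplied by exp(log 2.67) for marker-high patients — the
  reported multivariate hazard ratio — under uniform administrative
  censoring on (0, 120] months (≈ 40% censored). The study does not
  describe its follow-up or censoring; this scheme is synthetic-only.

All draws come from one seed, and the noise stream does not depend on the
effect sizes, so effects can be varied against identical noise (used by
the monotonicity property test). `null_cohort()` zeroes every effect for
type-I-error calibration.

**What passing tests do and do not show.** The generator emulates
log-normal abundance structure, a severity gradient and proportional
hazards; it does not emulate instrument noise (peak overlap, isotope
interference), non-normal heavy tails, batch effects or longitudinal
sampling. Green tests therefore demonstrate that the *procedures* are
correct and calibrated under their assumed model, not that the published
effect sizes would replicate in new patients.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to keep the full run around half a
minute: 1000 null replicates at 20+20 samples for the family-wise error
check, 200 cohorts at the default 75+75 for Wald coverage of the true log
hazard ratio, 20 random datasets for the Cox oracle comparison, and
B = 300–2000 bootstrap resamples in I/O-level tests (the analysis default
is B = 10000). Degenerate inputs are errors, not silent results: zero
pooled variance with unequal means, empty strata (named), all-equal
values at a dichotomization cutoff, Cox models without events or with
constant covariates.

## Known limitations

* Classification is composition-only; isomers, linkage (alpha-2,3 vs
  alpha-2,6 sialylation) and true epitopes are out of scope.
* The reference panel is a constrained reconstruction; member-level
  agreement with the original study cannot be checked.
* The published cohort statistics (marker AUROC 0.923, ratio medians,
  HR 2.67, log-rank p = 0.0006) are not reproducible without the patient
  data; the package validates the methods on synthetic cohorts whose
  generator encodes those summary statistics as design targets.
* Time-dependent covariates, competing risks and proportionality
  diagnostics beyond what the exports allow are not implemented.
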