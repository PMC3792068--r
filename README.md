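# glycoprof

Analysis of whole-serum N-glycan profiles measured by MALDI-TOF after
glycoblotting — for glycomics and IBD researchers who have a samples ×
glycans abundance table (pmol/µL) with clinical metadata and want to go
from composition codes to a validated diagnostic ratio marker and its
prognostic value.

Serum N-glycans are described by four-digit composition codes giving the
counts of hexose, N-acetylhexosamine, fucose and sialic acid (`5402` =
Hex5 HexNAc4 Fuc0 NeuAc2). The package covers:

* **Mass annotation** — theoretical monoisotopic m/z of BOA-tagged,
  methyl-esterified glycans detected as [M+Na]⁺:
  `m/z = Σ residue masses + 14.015650·NeuAc + 123.068414 + 22.989769`,
  with integer peak labels `⌊m/z⌋` ("glycan m/z 2378"), composition
  enumeration and peak-list annotation.
* **Structural classification** — high-mannose / hybrid / complex types,
  antennarity, and the serum aggregates (sialylated, fucosylated,
  agalactosyl bi-antennary, highly sialylated multi-branched, sialyl
  Lewis X potential), plus a packaged 61-glycan reference panel whose
  class marginals match the published serum panel.
* **Biosynthesis network** — directed single-residue-addition graph over
  detected compositions with log2(case/control) node overlays; GraphML
  and SIF exports for Cytoscape.
* **Differential screen & ratio marker** — per-glycan Student t-tests at
  the Bonferroni threshold α/G, Mann-Whitney AUROC (P(case > control),
  ties ½), and selection of the up/down abundance-ratio marker: the
  highest-AUROC significant up-regulated glycan over the best
  (1 − AUROC) down-regulated one.
* **Bootstrap & strata** — seeded within-group bootstrap of group means
  (add-one two-sided p), comparisons across disease extent, CAI, Mayo
  endoscopic score and steroid-refractory strata.
* **Survival** — own implementations of Kaplan-Meier, the log-rank test
  and Cox proportional hazards (Newton-Raphson, Breslow ties, Wald CIs),
  univariate p < 0.1 entry screening, multivariate fitting with
  |r| > 0.7 collinearity exclusion, quantile dichotomization and
  sensitivity/specificity. The `survival` package is used only as an
  independent oracle in the tests.
* **Synthetic cohort generator** — a 75 + 75 ulcerative-colitis cohort
  with log-normal abundances, a shared severity latent driving clinical
  strata and the marker, and proportional-hazards surgery times, so the
  whole pipeline is testable without patient data.

## Worked example

```r
library(glycoprof)

cohort <- simulate_cohort(cohort_config(seed = 1))
diff   <- differential_expression(cohort$abundance, cohort$metadata$group)
marker <- select_ratio_marker(diff, cohort$abundance, cohort$metadata$group)
marker
#> <ratio_marker> m/z 2378/1914 (codes 5402/5410)
#>   AUROC UC vs HLT: 0.934 over 150 samples
```

The screen flags the planted pair most strongly — `5402` (label 2378) up
with single-glycan AUROC 0.923 and `5410` (label 1914) down — and their
per-sample ratio discriminates patients from controls with AUROC 0.934:
a ratio of two abundances cancels sample-level loading variation, which
is why it beats either glycan alone.

Dichotomizing the ratio at the patient median and asking whether
marker-high patients reach surgery sooner:

```r
uc <- cohort$metadata$group == "UC"
md <- cohort$metadata[uc, ]
ratio <- tidy(marker)$ratio[match(md$sample_id, tidy(marker)$sample_id)]
md$marker_ratio_high <- as.numeric(dichotomize(ratio))

logrank_test(dplyr::mutate(md, group = ifelse(marker_ratio_high == 1, "high", "low")),
             group = "group")
#> Log-rank test: chi-square = 7.306 on 1 df, p = 0.006873

cox_fit(md, "marker_ratio_high")
#> <cox_ph_fit> n = 75, events = 44, ties = breslow
#>               term estimate std.error    hr conf.low conf.high  p.value
#>  marker_ratio_high   0.8234    0.3128 2.278    1.234     4.206 0.008476
```

Marker-high patients carry about 2.3 times the instantaneous risk of
surgery (Wald 95% CI 1.2–4.2) in this synthetic cohort, whose generator
plants a true hazard ratio of 2.67. `autoplot()` methods draw the KM
curves and marker box plots; `run_pipeline()` executes every stage and
writes the full report bundle (classification, differential, marker,
network, strata, survival tables and a run log) reproducibly for a given
seed.

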