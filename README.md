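# survregroup

Survival-curve clustering for TNM stage regrouping in non-small cell lung
cancer (NSCLC).

## The problem

The 8th-edition AJCC/UICC TNM grouping stages lung adenocarcinoma (ADC)
and squamous cell carcinoma (SCC) identically at equal anatomic extent,
yet the two histologies carry different prognoses: squamous IA survives
like adenocarcinoma IB, and several adjacent 8th-edition sub-stages
(IIA/IIB in particular) barely separate. `survregroup` is for
biostatisticians and registry analysts who want to rebuild a stage ladder
from survival data: it clusters histology-specific TNM subgroups by the
distance between their Kaplan–Meier (KM) cancer-specific survival (CSS)
curves and relabels the clusters as modified sub-stages, then compares
the modified ladder with the 8th edition.

## The method

For two survival curves $a_i, b_i$ on a common monthly grid (both start
at 1), with $\Delta a_i = a_{i-1} - a_i$, $d_i = \Delta a_i + \Delta b_i$
and $r_i = a_{i-1} + b_{i-1}$, the curve-level log-rank statistic uses

$$O_i = \Delta a_i,\qquad E_i = \frac{a_{i-1} d_i}{r_i},\qquad
V_i = \frac{a_{i-1} b_{i-1} d_i (a_i + b_i)}{r_i^{3}},$$

$$\chi^2_1 = \frac{\left(\sum_i (O_i - E_i)\right)^2}{\sum_i V_i},$$

the large-N limit of the classical hypergeometric log-rank χ² when both
groups are taken as equal-sized. The per-capita value $\chi^2_1$ is the
pairwise distance; subgroups are clustered agglomeratively (average
linkage by default), the tree is cut into 8 clusters, and clusters are
labelled IA…IV in decreasing order of pooled 5-year CSS with the 2+2+3+1
stage nesting. Staging systems are compared by adjacent-stage Cox hazard
ratios (earlier/later, Breslow ties), Harrell's C on ordinal stage ranks
with a seeded bootstrap CI, and predicted-vs-observed KM calibration at
36 and 60 months.

The package also ships the 8th-edition lookup table, the published
modified lookup (every stated histology-specific reassignment, with
unmentioned cells defaulting to the 8th edition and flagged), and a
SEER-like synthetic cohort generator calibrated to published 5-year CSS
rates, so the whole pipeline runs without registry access.

## Worked example

```r
library(survregroup)
cfg <- pipeline_config(
  input = seer_like_config(seed = 1L, n_patients = 20000),
  outdir = "regroup-out", bootstrap_B = 200, seed = 1L)
res <- run_pipeline(cfg)
res$regrouping
#> Regrouping of 64 subgroups into 8 sub-stages
#>   pooled 60 month CSS by sub-stage:
#>    IA    IB   IIA   IIB  IIIA  IIIB  IIIC    IV
#> 0.719 0.565 0.452 0.360 0.320 0.191 0.092 0.025
```

The 64 histology × TNM subgroups of the simulated cohort have been
regrouped into 8 sub-stages whose pooled 5-year CSS decreases
monotonically from 71.9% (new IA) to 2.5% (new IV). Comparing
discrimination of the derived ladder against the 8th edition on the same
cohort:

```r
harrell_c(res$cohort, stage_map_8th(), "substage", B = 200, seed = 2L)
#> C-index (substage ranks) = 0.6811 (95% CI 0.6766-0.6857), 140,943,556 pairs
harrell_c(res$cohort, res$derived_map, "substage", B = 200, seed = 2L)
#> C-index (substage ranks) = 0.6948 (95% CI 0.6905-0.7006), 140,943,556 pairs
```

The histology-aware derived grouping discriminates better than the
histology-blind 8th edition (C 0.695 vs 0.681), because the generator —
like the real registries — gives ADC and SCC different survival inside
the same TNM cells. The derived system's adjacent-stage hazard ratios
are all well below 1 (`res$reports$derived$cox$stage`: 0.49, 0.48, 0.50
for I→II, II→III, III→IV), i.e. every rung of the new ladder separates.

`run_pipeline()` writes the staged cohort, subgroup curves, distance
matrix, Newick dendrogram, derived stage map and evaluation reports as
CSV/TSV/JSON artifacts; see `?run_pipeline`.

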