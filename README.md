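# spatialtme

Compartment-resolved spatial single-cell analysis of the tumour immune
microenvironment, for multiplexed tissue imaging at micrometre resolution
(imaging mass cytometry and comparable platforms).

Tumours differ not only in *how many* immune cells they contain but in *how
those cells are organised* between the tumour parenchyma and the
intratumoural stroma — and that organisation tracks immunotherapy outcome.
`spatialtme` implements the analysis chain that turns a phenotyped
single-cell table plus compartment masks into that organisational readout:

* **Spatial graphs** — each cell's ≤ 40 nearest neighbours within 75 µm
  (neighbourhood detection), and an expansion-contact graph in which discs
  dilated by 15 µm that touch are neighbours (close interactions).
* **Immune neighbourhoods (INs)** — k-means (3 centres) over each immune
  cell's local immune composition, pooled across the cohort, with
  enrichment-based naming: CD8-hub, myeloid-hub, B/CD4-hub.
* **Interaction/avoidance testing** — the directional histocat score
  (total B neighbours of A cells ÷ A cells with ≥ 1 B neighbour) against a
  label-permutation null; scores in the highest or lowest 5% of the null
  are significant interactions or avoidances, per ROI.
* **Spatial immunotype** — per ROI, with overall CD8 T-cell density *d* and
  parenchymal:stromal density ratio *r*:

  | rule | label |
  |---|---|
  | *d* < 200 cells/mm² | depleted |
  | *d* ≥ 200, *r* < cutoff | compartmentalised |
  | *d* ≥ 200, *r* ≥ cutoff | enriched |

  with ratio cutoff 0.5 (primary classifier) or 0.6 (revised). Patient
  level: **consensus** (modal label; ties reclassify mean densities) or
  **highest** (enriched > compartmentalised > depleted).
* **Outcome association** — Kaplan–Meier curves and medians, log-rank and
  log-rank trend tests, marker dichotomisation, and ROC/AUC for reaching a
  progression-free-survival horizon (default 8 months).
* **Synthetic tissue** — masks, Poisson/Thomas cell maps, and exponential
  survival with known ground truth, so the whole pipeline is testable
  without patient data.

## Worked example

Simulate a cohort with known immunotypes, classify it, and test the
survival ordering:

```r
library(spatialtme)

co <- generate_cohort(n_patients = c(depleted = 6, compartmentalised = 6,
                                     enriched = 6),
                      rois_per_patient = 2, heterogeneity_rate = 0,
                      width = 800, height = 800, seed = 11)
co
#> synthetic_cohort: 18 patients, 36 ROIs, 31083 cells (seed 11)

roi_calls <- immunotype_rois(co$cells, co$masks, version = "primary")
head(roi_calls[, c("id", "overall_cd8", "parenchymal_cd8", "stromal_cd8",
                   "ratio", "label")], 4)
#>        id overall_cd8 parenchymal_cd8 stromal_cd8     ratio    label
#> 1 P001_R1     37.5000        20.08929    78.12500 0.2571429 depleted
#> 2 P001_R2     34.3750        15.62500    78.12500 0.2000000 depleted
#> 3 P002_R1     35.9375        20.08929    72.91667 0.2755102 depleted
#> 4 P002_R2     39.0625        26.78571    67.70833 0.3956044 depleted

pat <- classify_patient(roi_calls, mode = "consensus")
table(truth = co$clinical$truth_label[match(pat$id, co$clinical$patient_id)],
      called = pat$label)
#>                    called
#> truth               compartmentalised depleted enriched
#>   compartmentalised                 6        0        0
#>   depleted                          0        6        0
#>   enriched                          0        0        6

surv <- merge(co$clinical, pat[, c("id", "label")],
              by.x = "patient_id", by.y = "id")
surv$group <- factor(surv$label,
                     levels = c("depleted", "compartmentalised", "enriched"))
tr <- logrank_trend(surv[, c("time", "event", "group")])
sprintf("log-rank trend: chi2 = %.2f (1 df), p = %.4f", tr$statistic,
        tr$p_value)
#> [1] "log-rank trend: chi2 = 1.45 (1 df), p = 0.2282"
```

Every per-ROI density row carries full provenance (counts, areas, ratio),
and the patient confusion matrix shows the classifier recovering all 18
generating scenarios. At six patients per group the trend test is honestly
underpowered (p ≈ 0.23); the test suite runs the same check at cohort sizes
where the ordering is detectable.

`run_pipeline(config)` chains every stage (simulation → compartments →
densities → graphs → INs → interactions → immunotypes → survival) from a
YAML or list config and writes deterministic CSV/JSON artifacts plus a run
report with md5 checksums; see `?run_pipeline`.

For the models, parameter meanings, and design decisions, read the methods
vignette: `vignettes/spatial-immune-architecture.Rmd`.

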