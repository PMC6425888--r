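# dendroprov

Tree-ring analysis of forest provenance trials, with a synthetic trial
generator for method validation.

## The problem

Provenance trials grow seed-origin populations (provenances) of one tree
species in common gardens to separate genetic from environmental effects on
growth. Interpreting them runs into a confound: **site marginality**. At a
site near the climatic margin of the species' range, a single limiting
factor — typically the water balance — caps the growth of every tree
(Liebig's law of the minimum), so provenance-specific growth patterns
shrink and all provenances appear to respond alike. A trial at a marginal
site can therefore *mask* genetic differentiation that a mild site would
reveal.

`dendroprov` implements the full dendrochronological analysis chain for
such trials and quantifies that masking effect:

* **Chronology building** — ring-width indexing by a stiffness-calibrated
  smoothing curve (50 % frequency cutoff at 30 years), AR(1) prewhitening,
  Tukey biweight robust mean chronologies, and the standard descriptive
  statistics (Gleichläufigkeit, mean sensitivity, rbar).
* **Climate indices** — Hargreaves PET with FAO-56 extraterrestrial
  radiation, climatic water balance (CWB = P − PET), SPEI-3/6 via a
  log-logistic fit by unbiased probability-weighted moments, an aridity
  summary, and the 19 bioclimatic variables.
* **PCGA** — principal component gradient analysis: trees ordered by the
  polar angle of their loadings on the first two PCs of the ring-index
  matrix; a *pairwise* refinement tests every provenance pair with a
  Wilcoxon rank-sum test on the gradient ranks, yielding a provenance ×
  provenance p-value matrix and a scalar **differentiation score** per site
  (fraction of pairs with p < α).
* **Pointer years** — Cropper values in a 5-year moving window, signed
  intensity classes (|C| > 1 / 1.28 / 1.645), a 65 % series threshold per
  provenance, and common pointer years (≥ 6 provenances in agreement).
* **Clustering & ordination** — Euclidean/Ward (and three other linkages)
  clustering of chronologies with the agglomerative coefficient and the
  Mojena stopping rule; PCA of bioclim profiles.
* **I/O** — decadal Tucson/RWL reading and writing (0.01 mm and 0.001 mm
  dialects, bit-identical round trips), climate CSVs, and a long-format
  single-tree RWI export for external repeated-measures fits.
* **Synthetic trials** — a two-site weather and growth simulator whose
  `marginality` parameter in [0, 1] blends provenance-specific climate
  responses with a shared, capped water-balance signal, with full
  ground-truth records for every draw.

## Worked example

Simulate the default two-site trial (10 provenances × 15 trees × 40 years;
the mild-moist site has marginality 0.1, the drought-prone site 0.9) and
run the full pipeline:

```r
library(dendroprov)
paths <- generate_scenario("scenario", seed = 20260401, years = 40,
                           trees_per_provenance = 15, n_provenances = 10)
cfg <- pipeline_config(rwl = paths$rwl, meta_csv = paths$meta_csv,
                       climate = paths$climate, out_dir = "out")
summary <- run_pipeline(cfg)
summary$sites$MOIST$differentiation_score
#> [1] 0.8222222
summary$sites$DRY$differentiation_score
#> [1] 0.1111111
```

At the mild site 82 % of the 45 provenance pairs differ significantly in
their growth-pattern gradients; at the marginal site only 11 % do — the
between-provenance differentiation has collapsed onto the shared
water-limited signal. The same run writes, under `out/`, the provenance
chronologies and their statistics, the derived climate indices, the PCGA
p-value matrices, pointer-year and common-pointer-year tables,
climate–growth correlation grids (previous-year March through current-year
October), the chronology dendrogram (Newick; the 20 chronologies split by
site at the first bifurcation), and a machine-readable `summary.json`.

The `analysis/` scripts run this workflow end to end:

```sh
Rscript analysis/01_simulate_trials.R      # writes results/scenario/
Rscript analysis/02_run_pipeline.R         # writes results/pipeline/
Rscript analysis/03_marginality_experiment.R
Rscript analysis/04_method_calibration.R
```

`03_marginality_experiment.R` sweeps the marginality grid (20 seeds per
point) and prints, for the default effect sizes:

```
marginality 0.00: differentiation 0.851 (sd 0.057)
marginality 0.25: differentiation 0.792 (sd 0.065)
marginality 0.50: differentiation 0.714 (sd 0.072)
marginality 0.75: differentiation 0.503 (sd 0.095)
marginality 1.00: differentiation 0.046 (sd 0.048)
```

a monotone collapse from strong differentiation to the 5 % false-positive
floor as the limiting factor takes over.

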