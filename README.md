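# vascsynergy

Paired-design analysis of obesity-associated stressor synergy in vascular
cells: transcriptome effect ratios and their decomposition, plus the
formula-defined phenotype readouts of the accompanying functional assays.

## The problem

Vascular smooth muscle and endothelial cells in obesity/type-2 diabetes
face two stressor classes simultaneously — metabolic (high glucose + free
fatty acids, `MET`) and humoral (angiotensin II + noradrenaline, `HUM`).
Whether their combination (`ALL`) acts over-additively (synergistically),
and whether that depends on the EGF receptor, is a question about *paired*
contrasts: each animal contributes a strictly connected quadruple of
cultures (CTRL/MET/HUM/ALL at one passage), so stressor effects are
within-animal ratios, not group differences.

The package implements that analysis end to end:

* **Paired stressor effects** — per-set ratios `stressor/control`,
  geometric-mean point estimate, t-based confidence interval on the log2
  scale, significance = exclusion of 1 (level 0.99 for genes, 0.95 for
  functional assays).
* **Variability-derived fold-change threshold** — `3 × mean(CV)` of FPM
  across control samples, with CV = sd/mean per gene.
* **Triple DEG filter** — FDR < 0.05 in two methods *and* ≥ 3 FPM in at
  least one group *and* |log2FC| ≥ threshold, with a per-gene audit trail.
  A built-in moderated paired log-ratio test fills the FDR columns when
  external count-model results are not supplied.
* **Synergy decomposition** — additive prediction
  `log2FC(MET) + log2FC(HUM)`, synergy index `log2FC(ALL) − additive`,
  through-origin scatter slopes `Σxy/Σx²` over the ALL-DEG set, per-gene
  classification, CI-based reconciliation of DEG lists, mesh-surface
  export, and the fold-enrichment score `E = (i/q)/(t/d)`.
* **Phenotype metrics** — circularity `4πA/P²` with the ellipsoid
  contraction model, DAPI-integral cell-cycle gating, BrdU calls against
  a negative-control threshold, lipid scores (total and
  perinuclear/peripheral), mito-stress-test OCR parameters (BR, PL,
  ATP-OCR, maxOCR, NMOC, both printed coupling-efficiency variants,
  utilization), nucleus tracking and net displacement rates, metabolic
  fluxes and the glycolytic index, protein-normalized kinetic rates, and
  nuclear/perinuclear fluorescence ratios.
* **Synthetic data** — a seeded negative-binomial simulator of the paired
  four-condition design with animal effects, sparse main effects and a
  wildtype-only interaction term (plus cell-object, DAPI, OCR and
  motility generators), so every stage is testable with known truth.

## Worked example

```r
library(vascsynergy)

# Simulate a wildtype-profile study: 4 animals x 4 paired conditions,
# 15% metabolic, 10% humoral, 20% synergistic genes (1 log2 each).
cfg <- sim_config(cell_profile = "WT_VSMC", seed = 1)
sim <- simulate_counts(cfg)
res <- run_transcriptome_pipeline(sim$counts, sim$sheet)
print(res)
#> Paired stressor-synergy run: 10000 genes, 4 paired sets
#>   |log2FC| threshold 0.589 (mean control CV 0.196)
#>   DEG counts: MET 1455, HUM 978, ALL 4259
#>   slope MET~ALL over ALL-DEG: 0.344 (synergy: single stressor explains a minority of the combined effect)
```

The three numbers to read: the fold-change threshold is derived from
control variability (mean CV 0.196 → threshold 0.589); the combined
condition yields far more DEGs (4259) than the two single conditions
together (1455 + 978), the count signature of over-additivity; and the
through-origin slope of metabolic-only vs combined log2 fold changes over
the combined DEG set is 0.344 — most of the combined effect is absent
under the metabolic stressors alone. Re-running with
`cell_profile = "KO_VSMC"` or `"EC"` (no humoral effect, no interaction
in the generative truth) gives slopes of 0.97 and no synergistic calls —
the contrast that identifies EGFR-dependent synergy.

The same paired machinery serves functional endpoints:

```r
paired_effect(control = c(1, 1.1, 0.9, 1),
              stressor = c(2, 2.2, 1.9, 2.1), level = 0.95)
#>   target_id n_sets   log2fc   effect   ci_low  ci_high level excludes_one
#> 1  endpoint      4 1.037098 2.052096 1.957152 2.151646  0.95         TRUE
```

## Analysis workflow

Numbered drivers under `analysis/` reproduce the full study on synthetic
data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R          # paired counts (3 profiles) + assay fixtures
Rscript analysis/02_transcriptome_synergy.R  # thresholds, DEGs, slopes, reconciliation
Rscript analysis/03_phenotype_assays.R       # contraction, cell cycle, OCR, motility
```

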