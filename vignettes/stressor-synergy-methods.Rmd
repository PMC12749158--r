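---
title: "Methods: paired stressor-effect ratios, variability-derived thresholds and synergy decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired stressor-effect ratios, variability-derived thresholds and synergy decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascsynergy)
```

## The scientific setting

Obesity and type-2 diabetes expose vascular cells to two distinct stressor
classes at once: a metabolic milieu (high glucose plus free fatty acids,
`MET`) and a humoral milieu (angiotensin II plus noradrenaline, `HUM`).
The central question this package serves is whether the two classes act
*synergistically* — whether their combination (`ALL`) changes the
transcriptome and the cell phenotype by more than the sum of the single
exposures — and whether that synergy depends on the smooth-muscle EGF
receptor and on sex. The experimental unit is a strictly connected
quadruple of cultures: all four conditions applied to cells from the same
animal at the same passage, treated at the same time. That pairing is
what the statistics below exploit.

## Paired stressor effects and the exclusion-of-1 test

For endpoint value \(v\) (gene FPM, lipid score, BrdU fraction, median
circularity, ...) the stressor effect of set \(i\) is the ratio
\(r_i = v_{i,\mathrm{stressor}} / v_{i,\mathrm{control}}\). Ratios are
strictly positive and multiplicative, so inference happens on the
\(\log_2\) scale: the point estimate is the geometric mean
\(2^{\bar{x}}\) with \(\bar{x} = \mathrm{mean}(\log_2 r_i)\), and the
confidence interval is
\[
  2^{\,\bar{x} \pm t_{1-\alpha/2,\,n-1}\, s/\sqrt{n}},
\]
back-transformed to the ratio scale. An effect is significant when the
interval excludes 1, which is exactly a two-sided one-sample t-test of
the log-ratios at \(\alpha = 1 - \text{level}\). Gene expression uses
level 0.99, functional assays 0.95. The t construction is a package
choice: the source design reports ratio CIs without naming a scale or
distribution, and the log-t interval is the standard choice for positive
fold-type effects (a bootstrap would need more than the four sets the
design provides).

Zeros: a control FPM of 0 makes the ratio undefined. The default policy
drops that set for that gene (with an audit warning) rather than
injecting a pseudocount, because a pseudocount would bias exactly the
low-expression genes where the ratio is least trustworthy; a configurable
`pseudocount` is available for users who prefer continuity. A degenerate
zero-variance set of ratios yields a zero-width interval at the point
estimate, which excludes 1 whenever the estimate differs from 1.

The calibration of the exclusion test is checked by simulation in the
test suite: 10,000 null endpoints with 4 paired sets and lognormal noise
reject at \(\approx 1\%\) (level 0.99) and \(\approx 5\%\) (level 0.95).

## The variability-derived fold-change threshold

Rather than a conventional fixed cutoff, the |log2FC| threshold is
derived from how variable control expression actually is:
\[
  \text{threshold} = 3 \times \overline{\mathrm{CV}},\qquad
  \mathrm{CV}_g = \frac{\mathrm{sd}(\mathrm{FPM}_g)}{\mathrm{mean}(\mathrm{FPM}_g)}
\]
over control samples. Two numerical choices are made explicit because the
formula leaves them open. First, the CV uses the \(n-1\) sample standard
deviation. Second, "all RNAs" cannot literally include genes whose
control mean is 0 (0/0); genes below `min_mean_fpm` (default 1 FPM) are
excluded from the averaging. Both the all-genes and the
expression-filtered interpretation are reachable through that single
argument. The threshold is exactly homogeneous in the CVs, and the test
suite pins it to an independent brute-force loop at 1e-12 relative
tolerance.

A gene is then a DEG only if it passes the *triple* filter: FDR < 0.05 in
both of two independent methods, mean expression of at least 3 FPM in at
least one sample group of the comparison, and |log2FC| at or above the
threshold (the comparison is `>=`). External FDR columns from count-model
tools can be supplied; when they are absent, both columns are filled by
the built-in paired log-ratio test so that the pipeline is
self-contained. The built-in test applies empirical-Bayes variance
moderation (via limma) to the per-gene one-sample t statistic of the
log2 ratios: with only four paired sets, an unmoderated per-gene t test
has so little power that Benjamini–Hochberg correction at 10,000 genes
returns an essentially empty list even for twofold effects, and variance
moderation is the standard remedy. The unmoderated test remains available
(`moderate = FALSE`) and is verified against a plain `t.test()` loop.

## Synergy decomposition

On the log2 scale, additivity of the two stressor classes means
\(\mathrm{FC}_{\mathrm{ALL}} = \mathrm{FC}_{\mathrm{MET}} +
\mathrm{FC}_{\mathrm{HUM}}\). The synergy index is the departure
\[
  \mathrm{SI}_g = \mathrm{log_2FC}_{\mathrm{ALL},g} -
  (\mathrm{log_2FC}_{\mathrm{MET},g} + \mathrm{log_2FC}_{\mathrm{HUM},g}),
\]
exported together with the measured and additive surfaces for mesh
plotting. Aggregate synergy is read from the through-origin regression of
the single-condition fold changes on the combined-condition ones over the
combined-condition DEG set: slope
\(\beta = \sum x y / \sum x^2\) with \(x = \mathrm{log_2FC(ALL)}\),
\(y = \mathrm{log_2FC(MET)}\). A slope near 1 says the single stressor
already produces the combined effect on these genes; a slope well below 1
says most of the combined effect needs both stressors. Both the
regression variant and the axis assignment are package decisions (the
source analysis prints slopes without stating either); through-origin
matches the "slope 1 = identical action" reading, and regressing the
single condition on the combined one puts the conditioning set (ALL-DEGs)
on the x axis. Because both axes carry estimation noise and the DEG set
is selected on x, the slope is mildly attenuated even for identical true
effects; at the default problem size (10,000 genes, 4 sets, dispersion
0.05) a no-interaction simulation yields slopes around 0.93–0.97 rather
than exactly 1, comfortably separated from the \(\approx 0.35\) of a
wildtype-profile simulation with a 1-log2 interaction in 20% of genes.

The per-gene `classify_gene()` rule (synergistic up/down when a
combined-condition DEG has |SI| at or above the fold-change threshold;
metabolic/humoral when only that single flag is set; additive when all
three flags concur below threshold) is an explicit formalization the
package adds — the aggregate comparisons alone do not need it, but a
per-gene label is what downstream enrichment consumes.

Apparent disagreements between DEG lists are reconciled with the
confidence intervals: a gene present only in list A is "concordant" when
the other condition's CI covers A's point estimate. This operationalizes
the narrative use of CI limits in the source design; it is deliberately
asymmetric (point vs interval) to stay interpretable at n = 4.

The directed biomarker screen tests each panel gene at level 0.99 without
multiplicity correction — replicating the source procedure, where the
panel is small, fixed a priori, and each gene is reported individually.
The gene-ontology enrichment score is the plain fold-enrichment ratio of
ratios \(E = (i/q)/(t/d)\); no p-value is attached by design.

## Phenotype readouts

All imaging metrics operate on object tables (segmentation is upstream,
out of scope). The main formulas and the decisions around them:

* **Circularity** \(C = 4\pi A/P^2\), clipped to 1 with a warning when
  discretized perimeters produce impossible values. Analysis objects are
  filtered to single-nucleus cells of 400–4000 µm². Because circularity
  is heavily skewed, per-sample *medians* are compared; the contraction
  index is \((C_\text{after} - C_\text{before})/C_\text{before}\) around
  ionomycin addition.
* **Contraction model.** The cell is an ellipse whose long axis shortens
  by a fraction \(s\); the width response is the genuinely open part.
  Three modes are exposed: constant 2-D area (\(b' = b/(1-s)\)), constant
  3-D volume of a prolate ellipsoid with isotropic widening
  (\(b' = b/\sqrt{1-s}\), the default, matching the ellipsoid framing),
  and constant width. Calibrated to a baseline circularity of 0.26, a 20%
  shortening yields 0.36 (volume mode), 0.39 (area mode) and 0.32 (width
  mode); the observed value of ~0.37 lies between the first two, and the
  exact original assumption is not recoverable from its description, so
  no mode is presented as ground truth. Circularity uses Ramanujan's
  perimeter approximation (error < 1e-6 for the aspect ratios involved).
* **Cell-cycle gating.** The nuclear DAPI integral is a relative DNA
  content; G1 nuclei cluster at a mode \(m\), G2 at \(2m\). The mode is
  located by the kernel-density maximum of the lower half of the
  distribution, and the gates are \(\pm 15\%\) windows (configurable
  `window = 0.3`) around \(m\) and \(2m\) with S between and
  debris/aggregates excluded outside. The gate geometry is a package
  choice validated by simulation recovery (a 60/20/20 mixture at n = 5000,
  cluster CV 0.05, is recovered within ±3 percentage points).
* **BrdU positivity** is called against the 99th percentile of the
  negative control (mean + 3 SD available as an alternative); the exact
  original derivation "from the negative control" is not specified.
* **Lipid score** = mean red-object intensity × mean red-object area ×
  object count / nucleus count, optionally split into perinuclear
  (within 5 µm of the nucleus boundary, proxied by centroid + equivalent
  circular radius) and peripheral compartments.
* **Mito-stress OCR.** From the four phase summaries (baseline mean,
  oligomycin minimum, FCCP maximum, rotenone/antimycin-A minimum):
  NMOC, basal respiration BR, proton leak PL, maximal respiration
  (NMOC-corrected), ATP-linked OCR = BR − PL. The printed source formulas
  give the identical expression for BR and ATP-OCR — an apparent typo —
  so ATP-OCR follows the standard definition, and because the two printed
  coupling-efficiency definitions differ, both are reported:
  `coupling_methods` = (baseline − oligomycin min)/baseline and
  `coupling_results` = ATP-OCR/BR. Utilization = BR/maxOCR uses the
  corrected maximum.
* **Motility.** Nuclei are linked across frames by greedy mutual
  nearest-neighbour matching with a hard step cap — adequate for sparse
  nuclei at 2–3 h sampling, not for dense or fast fields. The readout is
  the *net* displacement rate \(\sqrt{\Delta x^2 + \Delta y^2}/\Delta t\)
  (a closed loop scores 0), which is rotation- and
  translation-invariant.
* **Fluxes.** Glucose consumption and lactate production are
  protein-normalized differences against cell-free media. The package
  defines production as (treated − cell-free)/protein so that production
  is positive when lactate accumulates; the glycolytic index
  lactate/(2 × glucose) is 1 for fully glycolytic disposal. Caspase-type
  kinetics are protein-normalized slopes between two timepoints, and the
  in-cell immunoassay compartment readout is the background-subtracted
  nuclear/perinuclear mean-fluorescence ratio (undefined, with a flag,
  when the ring signal does not exceed background).

## The synthetic-data generator

`simulate_counts()` draws negative-binomial counts with mean
\[
  \mu_{gs} = 2^{\,b_g + a_{g,\mathrm{animal}(s)} + x_\mathrm{met}\beta_{\mathrm{met},g}
  + x_\mathrm{hum}\beta_{\mathrm{hum},g} + x_\mathrm{met}x_\mathrm{hum}\gamma_g}
\]
scaled to the library size, with per-gene baselines \(b_g \sim N(4, 2^2)\)
(log2 relative abundance), a per-gene-per-animal baseline shift
\(a_{g,a} \sim N(0, 0.1^2)\) that cancels within pairs but contributes to
control variability, and disjoint truth classes (metabolic, humoral,
synergistic) with fixed-magnitude, random-sign effects. The interaction
\(\gamma\) is nonzero only under the wildtype profile; the `KO_VSMC` and
`EC` profiles force the humoral fraction and the interaction to zero,
encoding the contrasting biology as generative truth. Defaults — 10,000
genes, 4 animals, dispersion 0.03, animal SD 0.1 log2, library size
5 × 10⁶ — were chosen so that the average control CV lands near 0.21 and
the derived threshold near 0.64, the regime the analysis is designed for,
and are not adjusted per run.

What the generator does *not* emulate, and what passing tests therefore
do not show: gene-length and GC biases, correlated gene modules,
condition-dependent dispersion, compositional shifts from a few dominant
transcripts, and batch structure beyond the animal effect. Similarly,
`simulate_dapi()` places S-phase nuclei uniformly at 1.2–1.7 × the G1
mode (mid-S DNA content); real S phase spans the full 1–2× range
continuously, so on real histograms the G1/G2 gates will absorb some
true-S nuclei and the ±3-point recovery demonstrated on simulation is an
upper bound on accuracy. The OCR and track generators are phase-plateau
and random-walk idealizations whose purpose is inverse identifiability
(noiseless traces invert exactly), not physiological realism.

## Problem sizes and reproducibility

The shipped analyses and tests run at the study's own design scale —
4 paired sets per profile — with 10,000 genes for transcriptome runs,
5,000 nuclei for gating, 10,000 endpoints for calibration; these sizes
give Monte-Carlo standard errors comfortably inside the stated
tolerances. Every generator is a pure function of its configuration and
seed, and the pipeline writes deterministic TSV output: identical config
and seed reproduce result tables byte for byte.

## Known limitations

* The paired t interval assumes approximately normal log-ratios; with
  n = 4 sets, heavy-tailed technical artefacts are not absorbed.
* The moderated built-in DE test shares information across genes and is
  therefore not a drop-in replacement for count-model tools at very low
  counts; external FDR tables take precedence when supplied.
* The through-origin slope is attenuated by estimation noise and DEG
  selection (quantified above); comparisons should be made between
  profiles run at the same design size, not against the ideal value 1.
* `reconcile_sets()` treats the point estimate as fixed when testing
  coverage by the other condition's interval; it is a screening
  heuristic, not a formal equivalence test.
* Track linking is greedy; crossing trajectories closer than the typical
  step length can swap identities.
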