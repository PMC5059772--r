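---
title: "Methods: from heterogeneous omics profiles to a predictive multi-scale model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from heterogeneous omics profiles to a predictive multi-scale model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`omicforge` does two things: it normalizes heterogeneous relative-scale
omics profiles (transcripts, proteins, metabolites, fluxes, growth
phenotypes) onto absolute per-cell scales, and it trains a layered model
that maps a description of a bacterial growth condition — strain, medium,
stress set, genetic perturbation set — to genome-wide molecular state and
growth rate. This vignette records the science behind each stage, the
parameters that matter, and the design choices made where more than one
reasonable design existed.

## The condition encoding

A condition is the tuple (strain, medium, stresses, perturbations); growth
phase is metadata, never identity, so that cross-validation folds hold out
*conditions*, with all their replicates and phases together. The encoding
into the model's input vector `x` uses binary indicator blocks for strain,
stress and perturbation, and either indicators or real-valued nutrient
concentrations for the medium (when a composition table is supplied).
Encoding is strict: an attribute value never seen in training raises an
error rather than silently encoding to zeros, because a model of this kind
can only interpolate within the attribute vocabulary it was trained on.

## Normalization pipeline

The pipeline order is fixed: noise removal, platform-bias correction,
absolute quantification, missingness filtering and imputation. Each stage
preserves the matrix shape until the final filter.

**Noise removal.** Log intensities across a platform data set are modelled
as a two-component Gaussian mixture (noise floor + signal), fit by EM
(`mclust`). Initialization is semi-supervised: entries below the mean
intensity of designated noise-reference rows (the analogue of phantom
genes and negative-control probes) start in the noise component. Entries
with posterior noise probability above 0.5 are flagged and floored at the
fitted noise mean — flooring rather than deleting keeps the matrix shape
stable and the posteriors make the update reversible. A likelihood-ratio
guard (two components must beat one Gaussian by at least 0.1 per
observation) turns degenerate single-component data into an error instead
of a meaningless split.

**Platform-bias correction.** Per platform: quantile normalization of the
profiles; a per-profile loess smoothing of the implied pre-to-post map (so
the applied map is smooth and monotone, not a raw rank lookup); and a
z-score transformation of the platform data set. The default z-score is
*platform-global* (one mean and sd for the whole platform data set). This
was a genuinely open choice: a per-gene orientation is common in
meta-analysis, but per-gene centring erases the cross-gene abundance
ordering within each profile, and the next stage — mapping relative values
to an absolute reference per profile — is only identifiable if that
ordering survives. With a per-gene z-score the shared-gene reference
scatter plot degenerates and the loess back-map cannot recover absolute
levels; with the global (affine, rank-preserving) z-score it can. Per-gene
and per-profile modes remain available via `zscore=`.

**Absolute quantification.** For each profile, a loess curve of log
absolute reference levels against the profile's relative values is fitted
over the molecules shared with an absolute reference (copies per cell for
transcripts/proteins, molecules per cell for metabolites) and applied to
all molecules. Fits use span 0.75 and local quadratics, followed by a
monotone rearrangement (running maximum over a sorted grid) so that the
applied map never inverts within-profile ranks; extrapolation is clamped to
the fitted range endpoints. At least 20 shared molecules are required —
below that the fit is unsupported and the function errors, pointing at a
global affine fallback rather than silently extrapolating. Metabolite
concentrations ingested in mM are converted at 10^6 molecules per mM (1 nM
in a cell of this volume is one molecule); when directly measured absolute
molecule numbers exist for some metabolites, a loess fit on the
(concentration, absolute) pairs overrides the constant for that profile.
Fluxes are divided by the profile's glucose uptake rate, the shared
denominator of the source measurements.

**Missingness.** Molecules with *strictly more than* 70% of values
missing are removed, then profiles likewise — the strict inequality means
an exactly-70%-missing gene is retained. Remaining gaps are imputed per
gene from its k = 3 nearest genes (Euclidean distance over co-observed
profiles, scaled by the co-observation count so sparsely co-observed pairs
are comparable), with distance ties broken by row order for determinism.

## The transcriptome layer

Expression is predicted by a recurrent network on the gene state vector:
`y_(i) = sigmoid(w_x' x + w_y' y_(i-1) + b)` for `i = 1..n`, read out at
the memory depth `n` (default 2 — short feedback loops dominate bacterial
regulatory networks, so two iterations propagate most regulatory signal).
Sigmoid outputs live in (0, 1); an invertible per-gene min–max scaler on
log absolute expression maps the training range into [0.05, 0.95], leaving
headroom because a sigmoid can never reach 0 or 1. Training minimizes the
residual sum of squares in sigmoid space plus an l1 penalty on the
weights, by mini-batch stochastic gradient descent with classical momentum
(default 0.9) and a proximal soft-threshold step for the penalty.
Momentum was added after plain fixed-rate SGD plateaued an order of
magnitude above the loss the generating weights themselves achieve on the
synthetic benchmark; the proximal step keeps the l1 objective exact.
Gradients are exact backpropagation through the unrolled recurrence — a
finite-difference check is part of the test suite.

The initial state `y_(0)` is the mean unperturbed (wild-type) training
profile, at training and prediction time alike. A knockout is simulated by
clamping the gene to its scaled floor (the minimum of its training range —
literal zero has no log-space image) in the initial state and after every
iteration, so the clamp is absolute.

Training hyper-parameters (learning rate 0.2–0.5, 300–800 epochs, batch
up to the full data, l1 strength around 1e-5) were tuned on the synthetic
benchmark; there is no published reference setting for this architecture.

## Proteome, metabolome, fluxome, phenome

**Proteome.** Four LASSO modules per target protein, each restricted to a
network neighbourhood: regulators in the transcriptional regulatory
network, partners in the protein–protein interaction network, genes
sharing a pathway, and co-expressed proteins (pairwise Pearson correlation
strictly above 0.7 on the core proteome set). Lambda comes from inner
5-fold cross-validation with the one-standard-error rule. A module covers
only targets with non-empty neighbourhoods; the ensemble prediction is the
unweighted mean over covering modules and its coverage is the union. At
inference the co-expression module consumes the other modules' current
protein estimates in a single pass, not a fixed-point iteration — a
deliberate simplification that avoids stability questions at a small cost
in fidelity.

**Metabolome.** Metabolites with known enzyme–substrate relations are
regressed on their mapped enzymes only (core metabolism, protein-driven);
all others get LASSO variable selection over all genes (transcript-driven).
Predictions are floored at zero molecules per cell.

**Fluxome.** Flux balance analysis (maximize the objective flux subject to
steady state and bounds) with bounds informed by expression: each
reaction's activity is the standard gene–reaction-rule evaluation (min
over complex subunits, max over isozymes), and bounds are shrunk by
`s = min(1, l / t)` so a silent enzyme blocks its reaction and activity at
or above the threshold `t` changes nothing. This proportional-capping rule
is the package's choice for the bound update: it is monotone in activity,
controlled by the single threshold `t`, and `t` is calibrated by grid
search against measured fluxes (ties to the smallest `t`). The linear
programs are solved by the simplex method with a variable shift so
negative lower bounds (reversible reactions) are supported; an independent
LP formulation cross-checks the optima in the tests.

**Phenome.** Each layer (condition features, transcripts, proteins,
metabolites, fluxes) predicts growth by LASSO on its own values plus the
extracellular features; the final prediction is the weighted sum with
weights proportional to each layer's leave-one-condition-out Pearson
correlation clipped at zero. The informative-molecule report (nonzero
coefficients ranked by |weight|) is diagnostic only and never feeds back
into prediction — restricting a growth predictor to its top features
collapses performance, so the report is a lens, not a model reduction.

## The synthetic benchmark: what it emulates, and what it does not

`generate_system()` + `simulate_compendium()` produce the ground truth all
tests run against: transcripts are the fixed point of a true recurrent
network on the encoded condition (knocked-out genes clamped to the floor —
a deleted gene carries no transcript); proteins and metabolites are sparse
linear maps (on the log scale) whose supports are embedded in the
corresponding interaction networks; fluxes come from expression-capped FBA
on a small stoichiometric model; growth is an additive combination of
per-layer signals. Coefficients are drawn uniformly from ±[0.5, 1.5],
scaled by support size. Two calibration choices serve identifiability
rather than realism: input-weight scale 2/√k limits sigmoid saturation so
the condition-to-expression map is learnable from finitely many
conditions, and the toy metabolic model carries a fixed maintenance drain
so its optimal flux vector is not proportional to a single scalar (a
scale-invariant correlation score could otherwise not identify the
activity threshold). `distort_to_raw()` adds what the normalization
pipeline removes: strictly monotone per-platform distortions (affine in
log plus a bounded smooth warp — monotonicity is what makes loess
back-mapping identifiable), a noise floor with designated noise-reference
rows, and missing entries.

The generator deliberately gives every layer every condition; real
compendia have almost no cross-layer condition overlap, which is exactly
why the model's layered design matters in practice. Passing tests
therefore demonstrate that each estimator recovers the structure it
assumes, under that assumed structure — not that real data satisfy the
assumptions. Operons, sigma factors, condition-dependent network rewiring
and platform artefacts beyond monotone warps are all outside the
generator's vocabulary.

## Growth-curve feature extraction

Plate-reader curves are smoothed with a 3-point running median (so a
single noise spike cannot define maximum density). The maximum specific
growth rate is the largest ln(OD) slope over 1-hour windows advanced
every 15 minutes, restricted to windows whose OD lies between 10% and 90%
of maximum density; slopes are taken on ln(OD), giving 1/h units (a
`linear_slope` flag provides OD/h). The lag is the first time the
instantaneous ln(OD) slope reaches 5% of the maximum rate. Never-growing
curves report zero rate, lag equal to the horizon, and a degenerate flag
rather than NaN. The recovery sweep in the tests uses delayed-logistic
curves observed through their exponential window (the horizon ends well
below carrying capacity): once a logistic curve saturates, the density
band pins the steepest eligible window near 10% of maximum density, where
the instantaneous slope is only about 0.9 of the true rate, so recovery to
±0.01/h is only a well-posed target on curves whose measured window is
exponential.

## Evaluation protocol

Leave-one-condition-out: one fold per unique condition tuple, all
replicates of the held-out condition on the test side, and the model refit
inside each fold so no held-out information leaks into training. Scores
are per-profile Pearson correlations (on log values for absolute
expression); undefined correlations (zero variance) are excluded from
aggregates with their count reported. Three reference baselines frame
every result: the mean training profile, the mean of a seeded random
subset (10 profiles by default), and the mean wild-type (unperturbed)
profile. Method comparisons use the exact Wilcoxon rank-sum test.

## Problem sizes and numerical choices

The test and acceptance runs use a 20-gene, 10-feature system with 100
conditions for model recovery, a 120-gene, 16-profile, two-platform
fixture with 60 shared reference genes and 15% log-scale condition spread
for pipeline recovery, and 20 conditions for the flux benchmark — sizes at
which every check is exact or tightly bounded while the full suite stays
fast. The shared-gene reference is treated as a single reference-state
measurement, so condition-to-reference deviation enters the recovery error
roughly linearly; the 15% spread keeps that contribution subordinate to
the pipeline's own interpolation error. Loess uses `surface = "direct"`
(exact, no interpolation grid); EM runs to a 1e-8 log-likelihood
tolerance; LP residuals are checked to 1e-9; distance and neighbour ties
break by registry order everywhere, which is what makes reruns bit-stable.

## Known limitations

- The recurrent model interpolates within the trained attribute
  vocabulary; it cannot encode a never-seen strain, stress or nutrient.
- The co-expression proteome module consumes predicted (not measured)
  protein levels at inference, in one pass.
- The FBA layer returns a vertex solution; individual fluxes at degenerate
  optima are solver-dependent, so only objectives and measured-reaction
  fluxes should be interpreted.
- kNN imputation is O(genes² · profiles) in the worst case — fine at the
  scales here, quadratic on very large compendia.
- The noise-mixture stage assumes a unimodal signal component per
  platform; strongly bimodal biology (e.g. mixed growth phases in one
  platform set) would be mistaken for noise structure.
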