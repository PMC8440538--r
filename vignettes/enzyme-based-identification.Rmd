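---
title: "Enzyme-based identification of xenobiotic metabolites: models and methods"
author: "xenoID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme-based identification of xenobiotic metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoID)
```

## The problem

Xenobiotics — drugs, pollutants, dietary chemicals — circulate in humans at
concentrations three to five orders of magnitude below endogenous
metabolites, and authentic chemical standards exist for very few of their
phase I and II biotransformation products. Untargeted LC-HRMS therefore
detects thousands of features that cannot be identified by the classical
standard-matching route: most are too low in abundance even for MS2
acquisition. The enzyme-based identification strategy this package
implements substitutes a biochemical source of authentic material: pooled
human liver S9 fractions, which carry most phase I (cytochrome P450, FMO,
aldehyde oxidase) and phase II (UGT, SULT, GST, NAT, methyltransferase)
activities, are incubated with a xenobiotic to *generate* its metabolites.
The resulting accurate masses, retention times and (when acquirable) MS2
spectra become a reference library, and identification in study samples
rests on orthogonal criteria — accurate mass, co-elution, exposure-specific
presence, co-occurrence of related metabolites of the same precursor, and
spectral match — rather than on purified standards.

`xenoID` implements the computational core of this workflow: it consumes
aligned MS1 feature tables (it does not do peak picking or alignment) and
provides the mass arithmetic, filters, matching and network logic, plus a
synthetic-data generator so every stage can be validated end to end with
known ground truth.

## Mass arithmetic

All m/z computation rests on monoisotopic atomic masses (IUPAC/CODATA). A
formula is a map element → total atom count plus a map heavy isotope →
substitution count; substitutions *replace* light atoms, so a d3 species
written `C8H9D3N4O3` has twelve hydrogens, three of them heavy. The
monoisotopic mass is

$$ M = \sum_e n_e \, m_e + \sum_i s_i\,(m_{heavy,i} - m_{light,i}) $$

Ion m/z accounts for the electron: the proton mass is mass(1H) − mass(e−),
so \[M+H\]+ = M + 1.007276, \[M−H\]− = M − 1.007276, and an intact cation is
M − mass(e−). The electron term matters at the ppm level for fragment
cations — the expected aromatic-ring-oxidation fragment C9H11ClNO2+
computes to 200.0473 only with the electron subtracted. Only singly
charged species are supported; every ion handled by the workflow is ±1.

Biotransformations are signed element-count deltas (`+O`, `-CH2`,
`+C6H8O6`, ...) shipped as a user-extensible TSV
(`system.file("extdata", "transformations.tsv", package = "xenoID")`).
Rule mass shifts are always derived from the atomic-mass table, never
stored. Depth-limited breadth-first enumeration generates candidate
products (depth 2 by default, covering e.g. hydroxylation followed by
glucuronidation); chemically impossible branches (negative counts) are
pruned and products are deduplicated by formula, keeping the shortest
chain. Two distinct rule chains can be mass-equal — `+O` then `+H2`
equals `+H2O` at 18.01056 Da — and the enumeration reports one formula
for both, which is the chemically honest statement: MS1 cannot
distinguish them.

## S9 time-course screening

A feature is a candidate enzymatic product when its MS1 intensity rises
with incubation time and it is absent at time 0. The filter computes the
Pearson correlation of intensity against time in hours over the design's
time points (0, 2, 6, 24 h by default) and passes features with r > 0.9
not detected at t = 0.

Numerical choices, each configurable:

* Correlation is computed on raw (untransformed) intensities, replicates
  averaged per time point before correlating. Replicate-level
  correlation is a defensible alternative; averaging matches the
  duplicate-reaction design the generator emulates and makes r invariant
  to replicate count.
* Missing intensities are imputed as 0 — alignment software emits both
  blanks and zeros, and both mean "not detected" here.
* Features with zero intensity variance have undefined r and fail.
* The time-0 absence threshold defaults to 0 (any signal at t = 0
  disqualifies); it can be raised to an intensity floor for noisy blanks.

Passing features are matched against enumerated products of the
incubated parent at ±3 ppm on the ion m/z; all matches within tolerance
are reported, ranked by |ppm|. Matched features become library entries
carrying their satisfied evidence criteria (xenobiotic-specific
presence, mass match, time dependence, MS2 when available). Entries with
MS2 are recorded at identification level 2 — spectral evidence without a
purified standard; entries without spectra are tentative, level 3. A
count-based scheme would award the better level to the entry with *less*
evidence, so the spectral criterion takes precedence for library
entries.

## Stable-isotope pairing

A time-trend hit may be a nonspecific reaction product. Repeating the
incubation with an isotopically labeled precursor discriminates: a true
metabolite appears in the labeled run shifted by (retained labels) ×
(heavy − light mass), co-eluting with the unlabeled form. The pairing
searches, for each unlabeled hit, the labeled run at
`mz + k × perLabelDelta` for k from `nLabels − maxLabelLoss` to
`nLabels`, within ±3 ppm (evaluated on the labeled, larger, m/z —
instrument error is symmetric) and ±5 s. Defaults for label loss follow
the chemistry: 0 for 13C (the carbon skeleton survives metabolism), up
to all labels for deuterium, which can be displaced by the reaction
itself — the d9-bupropion hydroxylation that yields a d8 product is the
canonical case. Ties across k are all reported; the ambiguity is
chemically meaningful (label position). Features with no labeled twin
are classed nonspecific; the partition is exhaustive and disjoint.

The co-elution window for label pairing is not separately specified by
the workflow's QC scheme; the ±5 s study-sample co-elution window is
adopted by analogy.

## Library matching and confidence levels

Study features match a library entry when on the same chromatographic
method, within ±3 ppm and ±5 s. Detections are scored per sample against
five orthogonal criteria:

1. accurate-mass match (definitionally true for any match),
2. RT co-elution within ±5 s,
3. exposure-specific presence — assessable only when exposure records
   are supplied, and satisfied only when the metabolite is detected
   exclusively in samples exposed to its precursor,
4. co-occurrence — at least one *other* metabolite of the same precursor
   detected in the same sample,
5. MS2 spectral match (greedy cosine within a fragment ppm tolerance),
   when spectra were compared.

Criteria that cannot be assessed are excluded from the count rather than
counted false. Three or more satisfied criteria give confidence level 1,
exactly two level 2, one level 3. Co-occurrence is evaluated within the
same sample; detection of the pathway in a second biofluid is reported
separately ([crossBiofluidConcordance()]) as additional confidence, not
folded into the level. Relative-abundance exports are min-max scaled
within each metabolite row (a constant row scales to 1), matching how
co-occurrence heatmaps are conventionally drawn.

## Biotransformation networks

For pathway-level evidence, each parent xenobiotic feature is associated
with all features across samples and the associated set is passed
through a mass-difference filter: an edge survives only if the child −
parent m/z difference matches a transformation or adduct/isotope delta
within ±3 ppm. Association offers plain Pearson correlation (default)
and `pls1`, a one-component partial-least-squares score computed on
autoscaled data, where the weight vector is proportional to the
feature-response correlations and each feature's score is its
correlation with the latent variable. For a single parent response the
two orderings coincide up to scaling; neither is claimed to reproduce
any particular multi-block implementation numerically, which is why both
are exposed. The association threshold defaults to 0.4.

Sign policy for deltas follows chemical directionality: conjugations
only add mass, dealkylations only remove it, isotope/adduct spacings
match in both directions. Per-parent stars are united into one graph;
features reached from multiple parents are flagged ambiguous, and
connected components summarize pathway clusters.

## The synthetic-data generator

The generator is first-class, tested code; it exists so that every
pipeline stage can be checked against known ground truth without any
external download. It emulates three designs:

* **S9 time course** (`simulateS9`): parent at mild exponential decline
  (substrate consumption — the parent's true profile is rarely reported,
  a constant profile is configurable); products at
  `A (1 − exp(−k t))` first-order formation, exactly zero at t = 0;
  background features time-independent; 0/2/6/24 h, duplicate
  replicates.
* **Label pair** (`simulateLabelPair`): the labeled table mirrors the
  unlabeled one with planted features shifted by retained labels ×
  per-label delta, co-eluting within RT jitter.
* **Cohort** (`simulateCohort`): per pathway, a random exposed subset of
  samples receives correlated log-normal intensities for the parent and
  its metabolites — a shared per-sample log-scale factor with
  configurable loading induces the parent-metabolite correlation that
  the 0.4 association threshold is meant to detect; unexposed samples
  have those features missing. The exposed subset is shared across
  biofluids.

Default parameters, chosen once as realistic for this instrument class:
m/z jitter 0.5 ppm (1 σ; the ±3 ppm window sits at 6 σ), RT jitter 1 s,
retention times uniform over the 18–300 s void-volume-to-run-end span,
log-normal intensities with meanlog 13 / sdlog 1 (peak areas around
4 × 10^5), multiplicative observation noise sdlog 0.3, missing rate 5%,
formation rate k = 0.15 h⁻¹, parent decay 0.02 h⁻¹.

Two deliberate idealizations keep the ground truth exact rather than
probabilistic: background m/z values are rejection-sampled at least
10 ppm away from every planted feature (and, in label-pair mode, from
every label-shifted twin position), and missingness is applied to
background features only — a planted exposure *is defined* as the
pathway being detectable in its carriers. Consequently, passing
end-to-end tests demonstrates correct logic under the stated model; they
do not demonstrate robustness to real-data pathologies the generator
does not emulate: chromatographic drift between batches, correlated
(matrix-effect) intensity structure, isotope-envelope interference,
in-source fragmentation, or background features that genuinely share a
transformation delta with a parent. The zero-noise configurations used
in the recovery tests are the generator's limiting case, in which
sensitivity and specificity of the trend filter are provably 1.

Problem sizes used by the test suite and acceptance script — 100
background features, 120-sample cohorts, depth-2 enumeration over the
14-rule table — were chosen to match the emulated study designs while
keeping a full run in tens of seconds.

## Degenerate inputs and tie-breaking

* Empty formulas have mass 0; parsing rejects unknown symbols and
  substitution counts exceeding available atoms.
* `ppmError` requires a positive theoretical mass; ion m/z must be
  positive.
* An empty library reads as an empty table, not an error; library
  entries with a formula must agree with their stored m/z within 3 ppm
  or the read fails.
* Zero-variance features: undefined correlation → trend filter fails
  them; a zero-variance parent is an error in `associate`.
* Min-max scaling of a constant row returns 1 where detected.
* Isomer intensity ratios with a zero denominator are reported as
  infinite with a flag, not an error.
* Equal-|ppm| annotation ties keep their enumeration order after a
  stable sort; pairing ties across label counts are all reported.

## Known limitations

Only singly charged ions; no isotope fine structure or
natural-abundance correction; no structure-aware metabolism prediction
(the rule table is element-count arithmetic — it cannot know whether a
hydroxylation site exists); no FDR control across the library (the
orthogonal-criteria scheme is the control the workflow defines); RT
prediction across chromatographic methods is out of scope — entries
only match tables on the same method.
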