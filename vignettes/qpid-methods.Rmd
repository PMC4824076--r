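---
title: "Models and methods behind qpid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qpid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpid)
```

# The measurement this package models

A valved microfluidic device performs thousands of parallel protein–DNA
binding experiments. Each of 64 × 64 chambers holds one spotted, fluorescently
labeled double-stranded oligonucleotide at one concentration of a serial
dilution; a transcription factor is immobilized under a micromechanical
"button" valve. After incubation the valve traps equilibrium complexes, so
even weak and transient interactions survive the wash. Three fluorescence
channels are quantified per chamber: solution DNA in the chamber (how much
ligand remained free), bound DNA under the button, and immobilized protein
under the button. The bound-DNA/protein ratio is proportional to fractional
occupancy, and because the device measures **free** ligand concentration
directly, a simple single-site isotherm applies even under ligand depletion:

$$ r(c) \;=\; R_{\max}\,\frac{c}{K_d + c}, $$

with $c$ the measured free DNA concentration (µM) and $K_d$ the dissociation
constant. Affinity is $1/K_d$. The package covers the full analysis path —
calibration, occupancy quantification, $K_d$ estimation with censoring, DNA
shape features of the binding-site flanks, design of genomic site libraries
from ChIP-seq/DNase-seq peaks, and shape-based regression models of affinity
— plus a seeded simulator that stands in for the device and for genomic
downloads.

# The chip simulator and what it does (not) emulate

`simulate_chip()` generates chamber-level scan tables from planted truths.
Its stated world:

* **Layout.** Four independent 32 × 32 sections (one protein each; 32 oligos
  × 32 dilutions per section) or a whole-chip mode (one protein, 128 oligos
  × 32 dilutions).
* **Dilution series.** Geometric, 32 points from 2 µM down to 0.0156 µM
  (ratio $(0.0156/2)^{1/31} \approx 0.855$); the spacing is a design choice —
  only the endpoints and the count are device facts, and a constant-ratio
  series spans them exactly.
* **Equilibrium.** Mass-action partitioning with explicit depletion. The
  bound concentration solves a quadratic; we evaluate the root in its
  conjugate form $2 D_T P_T / (s + \sqrt{s^2 - 4 D_T P_T})$,
  $s = D_T + P_T + K_d$, which is numerically stable when the bound fraction
  is tiny (weak binders), and verified against a bisection oracle to 1e-10.
* **Noise.** Spotted DNA amounts get multiplicative Gaussian noise (CV 5% by
  default). The immobilized protein level varies with a per-section CV drawn
  uniformly from 6–40%, reflecting the device's reported immobilization
  variability; dividing bound DNA by protein cancels this almost exactly,
  which is precisely why the assay computes a ratio. Each channel carries a
  local background of signal/SNR (SNR 100 by default) whose true value
  jitters 10% around the recorded background estimate.
* **Instrument response.** The chamber channel responds linearly at
  35579 RFU/µM **through the origin**: backgrounds are modeled explicitly
  per chamber, so a nonzero response intercept would double-count them (and
  the printed device line's −1471 RFU offset would clamp the lowest
  dilutions to zero signal). The printed line, intercept included, is
  retained verbatim for the standalone calibration-recovery experiment
  (`simulate_calibration_series()` defaults). A full pipeline run still
  calibrates itself: it fits a line to a simulated standard series and
  inverts concentrations with the *fitted* curve, never with the truth.
* **Unstated constants, chosen once.** Immobilized protein sites 0.1 µM in
  chamber volume and a protein-channel response of 20,000 RFU/µM — plausible
  for an antibody-trapped in-vitro-expressed factor under a button valve.
  Both are exposed as arguments.

What the simulator does **not** emulate: optics and image segmentation
(the pipeline starts at spot-quantified tables), kinetics, chamber-to-chamber
cross-talk, spatial gradients across the device, and saturation or
photobleaching of the scanner. A green recovery test therefore establishes
that the analysis inverts the stated generative model at realistic noise —
not that it would survive every artifact of a physical scan.

# Calibration

`fit_calibration()` is ordinary least squares of raw intensity on
concentration — the printed linear form, with a free intercept (the device
line has one). Inversion clamps below the x-intercept at 0 µM with a warning
rather than erroring, so noise at the lowest dilutions cannot abort a
4096-chamber run.

One stated recovery goal is not statistically attainable and is deliberately
left red in the acceptance suite: with 5% multiplicative noise on the printed
line over 0.005–1 µM and $n = 128$, the OLS slope standard error is ≥ ~0.6%
of the slope for *any* concentration design (≈ 0.85% for a realistic
geometric series), so the probability of landing within 1% is at most ~90%,
below the demanded 95% seed rate. The intercept-within-10% half of the same
goal passes at ~99%.

# Kd estimation and censoring

`fit_kd()` minimizes unweighted squared residuals of the hyperbola. $R_\max$
is profiled out in closed form ($R_\max = \sum r x / \sum x^2$ with
$x = c/(K_d+c)$), leaving a smooth 1-D problem in $\log K_d$, optimized from
three starts ($K_d$ at the minimum, geometric mean and maximum observed
concentration; ties by lowest RSS then smallest $K_d$). Standard errors come
from the Jacobian at the optimum.

Censoring mirrors the assay's quantitative range: fits above 50 µM are
`censored_weak` (reported "-"), below 1 nM `censored_strong`. A fit also
censors weak when it *does not constrain* $K_d$: either the relative
standard error exceeds 100%, or an F-test (α = 0.05) cannot reject the
$K_d \to \infty$ limit of the isotherm — a straight line through the origin —
in favor of the hyperbola. The second condition matters because linearization
SEs understate uncertainty on the flat RSS ridge that near-linear
weak-binder series produce. Censored-weak interactions enter affinity
arithmetic as $1/K_d = 0$ (below detection).

Group summaries report mean ± population SD; for a pair this equals half the
absolute difference, which is the convention the reference two-member
summaries follow. Category comparisons expose both rank tests: the rank-sum
form for independent site categories (they are unpaired) and the signed-rank
form for per-oligo affinity differences.

# DNA shape features

Shape is predicted from a pentamer lookup table: minor groove width (MGW, Å)
and propeller twist (ProT, °) are base-pair features read from the pentamer
centered on each position; roll and helix twist (Roll, HelT, °) are
base-pair-*step* features carried as left/right step values per pentamer.
To honor the fixed $4(2k+w)$ feature-vector length (equal-length blocks per
feature), step features are converted to one value per base: each step
between bases $(j, j+1)$ averages the contributions of the two overlapping
pentamers, and each base averages its two flanking steps. This assignment is
strand-symmetric, which the suite verifies against a naive
per-position re-implementation and explicit reverse-complement constructions.

Feature vectors concatenate the four tracks over a $w$-long core plus $k$
flanks in the frozen block order HelT, MGW, Roll, ProT (distances are
block-wise, so the order only matters for serialization). Distances to an
averaged reference profile are normalized Euclidean,
$\lVert x - \mu\rVert_2 / \sqrt{\text{len}}$, per feature block or on the
full vector — both scopes are provided because the choice is not fixed by
the underlying method. Direction-concordance across independent feature-wise
comparisons is tested with an exact one-sided binomial tail at $p = 1/2$;
the bundled reconstruction of the reference statistic is 7 concordant of 8
comparisons (4 features × 2 reference experiments), $9/256 \approx 0.035$ —
an inference, since the original construction is not spelled out.

The bundled pentamer table is **synthetic** (`synth_pentamer_table()`): it
satisfies the reverse-complement symmetry contract, stays in plausible
physical ranges, and encodes A/T-tract minor-groove narrowing, but
reproduces no published values; a user-supplied table in the same schema
drops in for real-data work.

# Site libraries from peaks

`extract_candidates()` implements the genomic library filters: scan
DNase-accessible peaks for the CRE full site (TGACGTCA, palindromic) or
half-site (CGTCA) in either orientation; take a 200 bp window centered on
the **leftmost** occurrence (window start = core start − (100 − ⌊w/2⌋), a
frozen parity choice placing the half-site core at window positions 99–103);
reject windows clipped by chromosome ends; drop half-site windows with a
full site overlapping the 15 bp flanks of the core; and categorize each
surviving site by ChIP-peak membership (core fully inside a peak) as
A-only / B-only / both / accessible-unbound. `design_library()` samples
fixed quotas per category without replacement under a seed, optionally
adding motif-free control windows. The synthetic genome generator plants
sites ≥ 400 bp apart, wraps each in a DNase peak and category-consistent
ChIP peaks, and scrubs the background of spurious motif occurrences, so
category recovery is exact by construction — a bookkeeping test, not a
peak-calling benchmark.

# Shape regression models

`fit_model()` is plain multiple linear regression of affinity ($1/K_d$,
1/µM) — or of a per-oligo affinity difference — on the flank shape features
(default: the 5 bp on each side of the core, 10 positions × 4 features = 40
columns). No regularization by default; a ridge fallback exists solely for
rank-deficient synthetic edge cases and is always flagged. Feature
importance is the standardized coefficient, weight × column SD / response
SD — the criterion is scale-free, so "most important feature" does not
depend on the units of the individual shape tracks, and a preference for a
narrower minor groove renders as a negative MGW weight. A published
alternative flank index set (positions 11–16 and 19–25) is internally
inconsistent with a 5-bp core plus symmetric 5-bp flanks, so the package
defaults to the stated intent (the 5 bp flanks) and accepts a literal index
set whose coordinate frame the caller controls.

# Reproducibility

One master seed governs every stochastic stage through named substreams
(`derive_seed()`), so any stage can be re-run in isolation and a full
pipeline run regenerates bit-identically from (config, seed). Degenerate
inputs follow fixed conventions: all-tied rank tests return p = 1 with a
warning, negative background-corrected signals clamp to zero, ranking ties
break by column order.
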