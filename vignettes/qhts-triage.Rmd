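---
title: "Methods: normalization, Hill fitting and hit triage for organoid reporter screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, Hill fitting and hit triage for organoid reporter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhtscreen)
library(dplyr)
```

qhtscreen implements the analytics of a quantitative high-throughput
phenotypic screen (qHTS) run on dissociated retinal organoid cells in
1536-well plates. The screen looks for compounds that rescue rod
photoreceptor development in a ciliopathy disease line (here called RD16)
carrying a GFP reporter in rods: the disease line shows roughly 50% lower
viability and 60% fewer GFP-positive rods than wild type, so a rescuing
compound raises the GFP (channel 488) signal of treated disease wells
toward the wild-type level while leaving the DAPI (channel 405) nuclei
signal intact. Two counter-readouts guard against the classic false
positives of a fluorescence screen: loss of DAPI signal flags toxicity,
and GFP signal in a reporter-negative parental line flags compound
autofluorescence.

## The score model

Each plate carries its own DMSO vehicle controls, and raw intensities are
converted to percent scores against those controls:

* **Efficacy** of a disease-line compound well is its GFP position inside
  the control window, `100 * (GFP - mean_RD16_DMSO) / (mean_WT_DMSO -
  mean_RD16_DMSO)`. A vehicle-level well scores 0, a well as bright as the
  wild-type controls scores 100.
* **Toxicity** is percent loss of DAPI relative to vehicle-treated
  disease cells, `-100 * (DAPI - mean_RD16_DMSO) / mean_RD16_DMSO`; cell
  loss is positive, growth negative.
* **Fluorescence** applies the efficacy formula to the GFP-negative
  parental line: `100 * (GFP - mean_Parental_DMSO) / (mean_WT_DMSO -
  mean_Parental_DMSO)`. It measures how much of an apparent rescue a
  compound could fake by its own fluorescence.

Design choices worth knowing:

* Controls are aggregated by the plain arithmetic mean of unmasked wells
  (a trimmed mean is available via `control_stats(trim =)` but off by
  default); the formulas name single control quantities and the mean is
  the simplest faithful reading.
* Scores are **not clipped** to [0, 100]. The anchors calibrate the
  scale; noise and super-wild-type rescue legitimately exceed them, and
  clipping would bias the curve fits that consume these scores.
* Counter-screen plates carry no wild-type wells, so their WT+DMSO
  denominator is borrowed from the same replicate's disease plates
  (implemented as the replicate-level mean over all unmasked WT+DMSO
  wells).
* Replicates are normalized per plate and kept as separate observations;
  they enter the fits as individual residuals, preserving the error
  structure and the degrees of freedom behind r².

## Quality-control masking

The original screens masked aberrant wells by eye. The automated
surrogate flags a well when its robust z-score — `(x - median) /
(1.4826 * MAD)` over the 5×5 spatial neighborhood of wells with the same
treatment *and* cell line, self excluded, MAD floored at 1e-9 — exceeds 5
in either channel, and masks flagged wells only when they form a
4-connected, sign-consistent cluster of at least 3 ("localized
groupings"). Isolated outliers are left to the curve fit's residuals.
The same-line restriction matters: control columns of different cell
lines sit side by side, and only wells with the same expected baseline
form a valid reference population.

The masker presumes what real screens have: a low density of strongly
active wells per plate (the screen this package models confirmed ~2% of
compounds). In simulated campaigns that are deliberately enriched for
actives (the default test mix is ~30% non-inactive so that confusion
matrices have power), strong actives can form chance clusters and be
masked; for such data the masker should be run with a higher threshold or
skipped, which is why the funnel-fidelity checks run the analytic stages
directly on generator output, while the masker is validated on its own
fixtures (uniform plates, injected blocks, null campaigns).

## Concentration–response model

Scores are fit per compound and score type with the four-parameter Hill
(log-logistic) model

    A(c) = A0 + (Ainf - A0) / (1 + 10^( n * (log10 AC50 - log10 c) ))

with bottom asymptote `A0`, top asymptote `Ainf`, midpoint `AC50` (the
concentration giving a response half-way between the asymptotes — an
identity the suite verifies exactly) and Hill coefficient `n > 0`.
Fitting is bounded nonlinear least squares in `(A0, Ainf, log10 AC50,
n)`:

* bounds: `A0, Ainf` in [-100, 200] percent; `log10 AC50` within the
  tested range extended two decades each way; `n` in (0, 10];
* starts: a data-driven guess (asymptotes from the two lowest/highest
  concentrations, midpoint from the half-amplitude crossing of the
  interpolated response, `n = 1`), plus 4 deterministically jittered
  restarts, plus the best cells of a coarse profiled scan over a
  `(log10 AC50, n)` lattice in which the asymptotes — linear given the
  logistic shape — are solved exactly;
* each start runs bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
  ftol/ptol 1e-15) with an L-BFGS-B fallback; the lowest-SSE solution is
  polished by an exact linear re-solve of the asymptotes and a final
  local pass. Fits are deterministic for a fixed restart seed.

The test battery checks that the optimizer never loses to exhaustive grid
search over the bounded box (steps 0.01 in `log10 AC50`, 0.1 in `n`, 50
noisy 7-point curves), that noiseless 11-point curves are recovered to
1e-6 in `log10 AC50`, and that with 10% lognormal noise on a triplicate
11-point series at least 90% of 200 simulated compounds land within 0.15
of the true midpoint.

**A known identifiability limit.** On a single 7-point series with ~10%
intensity noise, the global SSE minimum for shallow-slope compounds is
sometimes a degenerate stretched curve with `A0` at the box edge and
`n < 0.5` — verifiably lower SSE than the true shape, so no optimizer
setting avoids it. The classifier correctly labels such fits
INCONCLUSIVE (their baseline is far from zero), which costs roughly a
tenth of true hits at primary-screen design density. The triplicate
11-point confirmatory design does not suffer from this; it is the reason
confirmatory screens re-test primary hits at a denser titration.

## Curve classification

A well-behaved curve (i) sits near zero at low concentration, (ii) rises
with concentration, (iii) has its inflection inside the tested range and
(iv) plateaus at the top. These qualitative criteria are operationalized
with configurable thresholds (`classify_thresholds()`): `|A0| <= 20`,
`Ainf - A0 >= 20`, `log10 AC50` within the tested range, top-response gap
to `Ainf` at most 10, `r² >= 0.7`, at least 4 distinct concentrations and
a converged fit. All pass: `ACTIVE_FULL`. Only a missing plateau and/or a
midpoint above the range: `ACTIVE_PARTIAL` (a real but unsaturated
response). Amplitude below 20 — or a clearly decreasing curve, since this
screen seeks GFP increase: `INACTIVE`. Anything else: `INCONCLUSIVE`,
with the failed criteria recorded.

## Hit triage

A desirable compound has a potent, high-amplitude efficacy curve and
counter-activities that are much less potent. With `EC50` the fitted
midpoint of each score type, triage requires

    EC50_toxicity / EC50_efficacy      >= ratio_min
    EC50_fluorescence / EC50_efficacy  >= ratio_min
    Ainf_efficacy                      >= ainf_min

with `ratio_min = 10` by default — the conventional selectivity-index
margin; a permissive preset uses 3 — and `ainf_min = 30`, about half the
anchor scale. The paper-level funnel order is preserved: toxicity is
checked before autofluorescence, so a compound failing both is labeled
TOXIC.

A counter-assay curve classed INACTIVE passes with an infinite ratio.
Whether a counter *registered* at all is decided model-free: its raw mean
response at the two highest tested concentrations must reach the 20%
margin and exceed the low-concentration mean by the same margin. This
guards both directions — a noise-chasing fit with a drifting baseline
cannot veto a clean hit, and a genuine counter signal whose fit happens
to be pathological cannot clear one (it yields an uninterpretable-verdict
instead). Weak-but-active efficacy (`Ainf < ainf_min`) is labeled
INACTIVE: a real but too-shallow rescue is not a hit.

Hits are ranked by fitted efficacy plateau (descending), then efficacy
AC50 (ascending), then compound id.

## The synthetic screen generator

`simulate_campaign()` produces ground-truth-labelled campaigns so that
every stage is testable without instrument data. It emulates:

* baselines — WT GFP mean 1000 (arbitrary units), disease GFP at a 0.4
  fraction of WT and disease DAPI at 0.5 of WT (the phenotype the screen
  is built on); parental GFP background 40, parental/WT DAPI 1000;
* compound effects through Hill terms: efficacy scales disease GFP toward
  the WT baseline; a killed fraction removes GFP and DAPI signal alike
  (dead rods lose their reporter — this coupling is what makes the
  toxicity counter-metric necessary); autofluorescence adds equally to
  disease-assay and counter-screen GFP (the artifact the parental retest
  eliminates);
* six generative classes with default mix inactive 0.70, efficacious
  0.12, toxic 0.08, autofluorescent 0.05 and the two mixtures 0.03/0.02 —
  deliberately enriched relative to a real screen so a 600-compound
  campaign yields a scoreable confusion matrix; effect parameters are
  drawn log-uniformly inside the tested range (efficacy amplitudes
  0.5–1.0 of the control window, kill fractions 0.5–1.0, added
  fluorescence 300–900 intensity units, Hill coefficients 0.8–2);
* noise and artifacts: per-well multiplicative lognormal noise with mean
  one (CV 0.10 by default, both channels), an additive separable
  row+column linear gradient and an edge-row/column offset (each 2% of
  the channel baseline by default);
* plate geometry: the standard qHTS arrangement with one concentration of
  every compound per plate (titrations span plates), 32 own-line DMSO
  wells in column 0 and, on disease plates, 32 WT+DMSO wells in column 1.
  Presets cover the primary design (seven 1:3 dilutions from 10 mM,
  single replicate — the default) and the confirmatory design (eleven 1:3
  dilutions, triplicate).

`truth_to_expected_calls()` is the simulator's analytic oracle: it
evaluates the *noiseless* percent-score curves implied by the generating
parameters (including the channel coupling, which bells the observable
efficacy curve of strongly toxic compounds) and applies the triage logic
to them without any fitting. On noiseless generator output the fitted
pipeline agrees with it for every compound.

What the generator does **not** emulate: image-level or per-cell
structure (well summaries only), instrument-specific artifact shapes
beyond the linear gradient and edge offset, plate-to-plate batch drift,
compound chemistry (no structure–activity structure), and dispensing
errors. Passing tests therefore demonstrate the analytics under the
stated statistical model, not robustness to every failure mode of a real
screening robot.

## Problem sizes and numerical conventions

The shipped verification battery uses a 600-compound seed-1 campaign for
funnel fidelity, 200 simulated compounds for noisy parameter recovery, 50
curves for the grid-search dominance check, 1000 random parameter draws
for the midpoint identity (exact to 1e-12), and an 80-compound campaign
run twice for byte-identical reproducibility. Normalization agrees with a
literal well-by-well transcription of the score formulas to 1e-12.
Degenerate cases are handled explicitly: constant neighborhoods get a
floored MAD (zero z rather than 0/0), wells exactly at the control mean
score exactly 0 (negative IEEE zero normalized), flat curves take the
midpoint of the tested log-range as their initializer, ties in the hit
ranking break lexicographically, and `r²` is undefined (NA) for
zero-variance score vectors.
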