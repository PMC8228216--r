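---
title: "Methods: sperm form–function analysis with spermform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sperm form-function analysis with spermform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermform)
```

## The scientific problem

Whether sperm morphology predicts sperm swimming performance is a
long-standing question in sperm-competition research. Hydrodynamic models
of mammalian-like sperm predict faster swimming with a larger
flagellum:head ratio (thrust vs drag) and, via ATP supply, with a longer
midpiece; total length is the classical comparative correlate. Passerine
sperm complicate all of this: the cell progresses by spinning around its
long axis like a drill rather than by whip-like flagellar bending, so the
standard predictions need not apply. Testing them requires a chain of
steps — tracking-derived kinematics, debris and motility screening,
morphometry with bias-corrected variation coefficients, cross-level
regressions that respect sampling structure, and population-genetic
context from mitochondrial haplotypes. `spermform` implements that chain
as tested, reusable code, and pairs it with a simulator that produces data
with known ground truth at the same scale and structure as a five-island
field study.

## Kinematics

A track is an ordered list of 2-D positions (µm) at strictly increasing
integer frame indices. With $n$ points at frame rate $f$ (default 50 Hz),
elapsed time is $(n-1)/f$: a cell moving at a constant 100 µm/s then
reports VCL = VSL = VAP = 100 µm/s exactly. The alternative convention
$n/f$ (which matches the phrase "25 frames = 0.5 s" for the nominal
recording duration) would bias every velocity low by $1/n$; we keep it
only in `nominal_duration()` for describing the recording configuration.

VAP needs an "average path". Commercial trackers smooth with unspecified
proprietary filters; we use a centred moving average with an odd window
(default 5 frames), truncated symmetrically at the ends. Symmetric
truncation keeps the smoothed endpoints equal to the raw endpoints, which
yields the useful invariant VSL ≤ VAP for every track (the smoothed path
still connects the raw endpoints), alongside VSL ≤ VCL from the triangle
inequality. Straightness (STR = VSL/VAP·100) and linearity
(LIN = VSL/VCL·100) are therefore bounded by 100 when defined; zero
denominators yield `NA` with the undefinedness preserved rather than a
silent 0.

## The quality-control cascade

Screening follows a fixed, auditable order, so each excluded track carries
exactly one reason:

1. **Object screen.** Elongation strictly above 50 means debris
   (`non_sperm`); these leave numerator *and* denominator of every count.
2. **Motility.** A sperm object with VAP < 30 µm/s **and** VSL < 25 µm/s
   is static or drifting, hence non-motile. We read the rule as a
   conjunction, the literal reading of the defining sentence; because much
   CASA practice uses the disjunction, `motile_rule = "or"` switches it.
3. **Speed eligibility** (motile tracks only), first failure recorded:
   fewer than 10 points (`short_track`; "frames" is read as points), STR
   below 90, LIN below 60, any frame-index gap (`discontinuous`), and the
   jump rule: maximum step exceeding the mean step by more than 4 sample
   SDs. The suspect step is included in its own mean and SD — the rule is
   a per-track summary with no leave-one-out element — and the SD uses the
   $n-1$ denominator. For 24 steps of 2 µm plus one of 10 µm this gives a
   threshold of 2.32 + 4·1.60 = 8.72 µm, so the 10 µm jump is caught.

The motile proportion is motile / all sperm objects; jump-artefact tracks
are motile (they fail only speed eligibility), so they count in the
numerator.

## Morphology and coefficients of variation

Flagellum = midpiece + tail and total = head + flagellum hold exactly, as
identities of the derived columns. Coefficients of variation use
$\mathrm{CV} = (\mathrm{SD}/\bar{x}) \cdot 100 \cdot (1 + 1/(4n))$ with
the sample SD; the correction removes the small-sample downward bias.
Within-male CV uses a male's cells ($n$ = cells); among-male CV uses male
means ($n$ = males). The convention (sample vs population SD) is our
choice; the formula's source does not state it, and sample SD is the field
norm.

## Statistical models

**Centring.** Islands are visited in brief, unevenly timed sampling events
(island–year combinations). Male-level predictors (mean total length, F:H
ratio, mean midpiece) are centred within events, so cross-level slopes are
estimated from within-event variation only, free of island- and time-level
confounds. Per-event centred means are exactly zero, and the same applies
to male mean VCL when it enters the motility models as a predictor.

**Speed model.** Cell-level VCL ~ centred morphology + island +
island:morphology interactions, with a male random intercept, fitted by
REML; tests use Satterthwaite degrees of freedom (delegated to lmerTest —
the procedure, not the approximation internals, is our contract; were the
backend to lack it, Wald z would be reported, with the method recorded in
the result). Backward elimination removes the least-significant
interaction with p > α per step (default α = 0.05); main effects are never
removed; the full path is returned as a machine-readable `selection_log`.

**Selection calibration.** Stepwise removal re-tests a surviving
interaction after a collinear companion leaves. Because midpiece length
makes up most of total length, the island:total and island:midpiece
interactions are strongly collinear, and in null simulations this
"survivor" re-testing inflates per-term retention above α (we measure
roughly 0.08 at α = 0.05). The alternative `simultaneous = TRUE` mode
drops every non-significant interaction per round, tests each term once
per round, and is calibrated (retention ≤ α, measured ≈ 0.04). A union
bound caps stepwise retention at 3α, since a term is tested at most three
times. Stepwise remains the default because removing one term at a time is
standard modelling practice; users comparing retention rates to a nominal
level should prefer the simultaneous mode.

**Motility models.** The per-male (motile, immotile) counts form a
binomial GLMM (Laplace) with a male random intercept; since each male
contributes one recording, the random intercept acts as an
observation-level overdispersion term. Island-by-predictor interactions
enter by forward selection with likelihood-ratio tests (add the best
candidate with LRT p < α, repeat); candidates that fail to converge are
skipped and logged. A simpler companion model regresses the log motile
proportion on the same terms by weighted least squares (weights = number
of sperm objects), with backward removal of interactions. A male with zero
motile cells would make the log undefined; such rows get 0.5 added to both
counts, and the correction is logged — the study conditions never produce
this case, but real data could.

**Variance comparisons.** Among-male variance in total length is compared
across islands with Levene's test on male means, using the median as
centre (the Brown–Forsythe form, robust to non-normality; the mean is a
switch). Within-male variation is compared via a model of the per-male SD
of total length with island, mean total length as covariate, and measurer
as a random intercept; with a single measurer (or a degenerate fit, e.g.
an all-zero response) the model falls back to fixed effects with a note.
The heteroscedastic-residual alternative (per-island variance functions in
a cell-level model) is out of scope; the Levene comparison on male means
is the implemented test.

**Within/between decomposition.** Cell midpiece length is regressed on the
male's mean total length (between-male allometry) and the cell's deviation
from it (within-ejaculate allometry), with island effects and tested
interactions. The decomposition is exact: per-male deviation means are
zero, and the two columns sum back to the raw predictor.

## The synthetic-data generator

The generator's defaults are the study conditions the package emulates,
chosen once:

- five islands with 23/30/11/22/19 males (morphology) and 21/13/9/22/8 in
  the motility subset; one sampling event per island with years spread
  over 2009–2011;
- segment means 16.6/85.6/11.9 µm (head/midpiece/tail; total ≈ 114.1 µm),
  among-male SDs 0.40/1.85/0.65 µm (total SD ≈ 2.0 µm), within-male SDs
  0.30/1.50/0.60 µm (within-male CV ≈ 1.45%); small per-island midpiece
  shifts place island mean totals between about 114.1 and 114.9 µm;
- island mean speeds 106.8/106.0/106.2/96.4/111.4 µm/s and motile
  fractions 0.83/0.82/0.81/0.75/0.81;
- a male-level slope of −1.88 µm/s per µm of event-centred mean total
  length, male-level residual speed SD 6 µm/s and cell-level SD 10 µm/s
  (so island VCL SDs land in the observed 8–12 µm/s range);
- 25 frames per track at 50 Hz, about 170 tracked objects per male;
- 49 haplotype sequences of 655 bp collapsing to 22 haplotypes on a fixed
  tree whose six-step branch isolates one island's cluster.

Motile tracks are a straight heading plus a sinusoidal perpendicular
wobble (amplitude 1 µm, period 5 frames) and Gaussian jitter
(SD 0.15 µm). The wobble is a 2-D stand-in for the drill-like spin of
passerine sperm — only projected kinematics are analysed, and no
quantitative description of passerine spin kinematics exists to calibrate
against, so amplitude and period are free knobs, not estimates. The
forward spacing is calibrated (by root finding on the mean step length) so
the noiseless path's VCL equals the male's target speed exactly; jitter
then inflates VCL slightly, identically across males, so slopes are
unaffected. Static tracks jitter about a fixed point and drifting tracks
translate at 5–20 µm/s, both below the motility floors by construction;
debris tracks carry elongation > 50; jump-artefact tracks get one step
inflated to 6× the mean of the others, which exceeds the 4-SD threshold
with margin. The class mixture gives the debris rate, the jump share of
motile tracks and the static:drifting split, while the per-island motile
fraction sets the motile share among sperm objects — so the QC-recovered
proportion motile estimates the configured fraction directly.

Randomness is structured as one root seed spawning fixed per-male (and
per-stream) substreams, so male *k*'s data are identical whether the
cohort has 10 males or 100, and every output is a pure function of
(config, seed). The morphology→speed linkage acts at the male level (male
mean morphology shifts male mean speed), matching the analysis granularity
of male-mean predictors with cell-level responses; cell-to-cell speed
variation is purely residual.

What the simulator does **not** emulate: image-level cell detection (it
starts from tracked coordinates, with debris represented only through the
elongation score), 3-D trajectories, within-male correlation between a
cell's own morphology and its own speed, seasonal trends, seminal-fluid or
ATP physiology, and sequencing artefacts (haplotype sequences are clean
A/C/G/T). Passing tests therefore certify the computational chain — not
that real recordings are free of tracker-specific biases these stages
never see.

## Haplotype networks

Sequences are collapsed by exact string equality after uppercasing; a
sequence containing an ambiguity code (or gap) never merges with a
resolved sequence and is flagged. Distances count sites where both
sequences have unambiguous A/C/G/T and differ (pairwise deletion) — a
conservative convention the source material leaves unstated. The minimum
spanning network is the union of all minimum spanning trees: an edge
belongs iff its weight equals the minimax path weight between its
endpoints (computed by a Floyd–Warshall-style relaxation on the maximum
edge along a path), which is equivalent to membership in at least one MST.
The tie tolerance (epsilon) is 0, matching the default behaviour of the
standard population-genetics implementation. Tests verify the edge set
against exhaustive enumeration of all spanning trees (n ≤ 5) and against
an independent forced-edge MST oracle (n ≤ 7), on 100 random integer
distance matrices.

In the simulator, each topology edge mutates sites disjoint from every
other edge, so pairwise distances are additive along the tree; with all
steps ≥ 1, any non-tree pair is strictly farther apart than the minimax
path, and the recovered network equals the configured topology exactly.

## Numerical and degenerate-input choices

- Undefined STR/LIN (zero denominators) are `NA` and flagged.
- `cv_corrected()` requires n ≥ 2 and a positive mean; constant input
  gives exactly 0.
- Zero off-diagonal distances are rejected by the network builder —
  duplicated haplotypes must be collapsed first.
- Backward/forward selection is deterministic given data and α; the
  selection log reconstructs the path.
- Non-convergence is reported (or the candidate skipped and logged),
  never silently swallowed; degenerate mixed fits fall back to fixed
  effects with a note.
- Problem sizes in the test-suite simulations are deliberately modest
  (cohorts of 18–75 males, 20–200 tracks per male, 200-replicate null
  calibrations), chosen to estimate every quantity with useful precision
  while keeping the whole suite and the acceptance script in the
  minutes range on a single core.

## Known limitations

The speed model's predictors (male mean total, midpiece, F:H) are
intrinsically collinear because the midpiece dominates total length;
coefficient SEs are inflated accordingly (variance inflation factors near
3), and interaction selection inherits the survivor-bias caveat above.
Male mean morphology is measured with error (finite cells per male),
attenuating cross-level slopes by a few percent at the default settings.
The binomial GLMM with one observation per male relies on the
observation-level intercept for overdispersion; its island main-effect
p-values are not available from the backend (no denominator df), which is
why the weighted log-proportion model is provided alongside.
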