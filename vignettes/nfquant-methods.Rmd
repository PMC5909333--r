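---
title: "Methods: infarct and no-flow quantification with a ground-truth phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infarct and no-flow quantification with a ground-truth phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfquant)
```

## Scope and rationale

`nfquant` implements the measurement chain used in serial post-contrast
studies of myocardial infarction: remote-referenced n-SD threshold
segmentation of inversion-recovery gadolinium-enhanced images, indirect
measurement of the no-flow (NF) core, pixel-wise T2 relaxometry,
volume/mass/fraction quantification, and a repeated-measures analysis of
how the NF shrinks during the post-contrast period. Because animal image
data of this kind are rarely shareable, the package ships a digital
left-ventricular phantom whose ground truth is exact at the voxel level;
every stage of the pipeline is validated by parameter recovery against it.

## Signal models and their assumptions

**T2 decay.** Multi-echo signal follows the two-parameter mono-exponential
$SI(TE) = SI_0\,e^{-TE/T2}$. Multi-component decay, stimulated echoes and
diffusion weighting are ignored.

**Inversion recovery.** Magnitude signal is modelled as
$|M| = m_0\,|1 - 2e^{-TI/T1}|$, which nulls a tissue exactly at
$TI = T1\ln 2$. The recovery-period (TR) term of a segmented acquisition
is deliberately omitted: this is the simplest model that reproduces the
two behaviours the pipeline depends on — nulling of remote myocardium and
the enhancement ordering of tissue classes. A consequence worth knowing:
under this model a tissue with *longer* T1 than remote myocardium is
*bright*, not dark, at the remote-nulling TI (real segmented readouts
saturate long-T1 species). The phantom therefore realises the defining
observation that NF signal is at or below remote signal directly through
its concentration curves (below), rather than through readout physics.
Flip angle, views per segment and TR of the emulated sequence are carried
as metadata only.

**Contrast.** Post-contrast relaxation follows the fast-exchange
relaxivity model $1/T1 = 1/T1_{pre} + r_1 C$ with $r_1 = 4.5$ L mmol⁻¹ s⁻¹
(a typical extracellular gadolinium chelate at 1.5 T).

**Noise.** Magnitude images carry Rician noise: Gaussian noise of SD
$\sigma$ in both complex channels, then the magnitude. The package defines
SNR as *tissue signal on the acquired image divided by* $\sigma$ — at the
shortest echo for the T2 series, for the brightest myocardial class for
the IR series — because no TE = 0 or magnetisation image exists to
reference. Default SNR is 20.

## The phantom

The phantom is a stack of identical short-axis slices: a circular
myocardial annulus (blood pool inside, background outside) containing a
transmural infarct sector with an NF core. Geometry defaults follow the
emulated protocol: 300 mm field of view, 256 × 256 matrix
(1.171875 mm pixels), 10 mm slices, 6 slices; echo times
12, 20, 30, 45, 60, 75, 90, 105 ms; acquisitions at 2 min (early, fixed
TI 500 ms) then 10–45 min every 5 min (TI re-tuned to null remote
myocardium at each timepoint, $TI = T1_{remote}(t)\ln 2$).

Every region is sized by direct voxel counting so stored truth matches the
requested targets to within one voxel:

- the epicardial radius is calibrated by bisection against the rasterised
  annulus so myocardial volume matches `target_lvm_g / 1.05`;
- the infarct grows inside its sector by increasing angular distance from
  the sector axis until the requested voxel count is reached;
- the NF core at every timepoint is a prefix of a single deterministic
  growth order over the infarct's internal Euclidean distance transform:
  growth starts at the deepest pixel and always extends to the 4-adjacent
  infarct pixel with the greatest distance (ties by linear pixel index).
  Prefixes of one order make the NF masks *nested over time* and
  *4-connected* by construction, and the enclosure requirement is checked
  (a target whose core would reach the infarct boundary raises a sizing
  error naming the offending timepoint).

Contrast kinetics are *not* mechanistically simulated. The spec of the
phantom dictates the true NF volume at each timepoint and the generator
realises it geometrically; the default schedules hold the early volume
flat (7.7 ml to 15 min for the reperfused configuration, 8.1 ml to 20 min
for the non-reperfused one) and then decay geometrically to the 45-min
values (1.82 and 3.05 ml). This gives exact ground truth for kinetics
recovery while staying agnostic about the diffusion physiology behind the
shrinkage.

Tissue parameters default to the group values the phantom is meant to
emulate — regional T2 of 57/94/56 ms (remote/infarct/NF, reperfused
configuration) or 63/96/60 ms (non-reperfused) — while native T1 values
are *assumptions*, not reported values: 1000 ms myocardium, 1200 ms
infarct rim, 1400 ms blood at 1.5 T. The phenomenological concentration
curves are anchored so that (a) the fixed 500-ms early TI nulls remote
myocardium at 2 min, matching the protocol's EGE setting; (b) the infarct
rim stays strongly enhanced throughout; and (c) the NF core carries 0.9 ×
the remote concentration, leaving it slightly above the nulled remote
signal but far below the enhancement threshold — the "equal to or less
than remote" appearance that defines the NF.

**What the phantom does not emulate:** cardiac/respiratory motion,
k-space and segmented-readout artefacts, coil shading, partial-volume
averaging at oblique boundaries, papillary muscles, through-plane
geometry changes, and mechanistic contrast exchange. Passing recovery
tests on the phantom therefore demonstrates the *analysis chain* is
unbiased under ideal acquisition, not that any scanner protocol is.

## Segmentation

Per slice: remote statistics come from a ≥ 100-pixel ROI (hard
requirement), the threshold is `mean + k · SD` with `k = 5` by default,
and enhancement is *strictly* above threshold (a pixel exactly at the
threshold is not enhanced). Thresholds are computed per slice rather than
pooled because inversion nulling and coil shading vary across slices.

NF detection labels sub-threshold myocardial pixels into 4-connected
components and treats diagonally touching components as one island —
standard foreground/background connectivity duality; without the merge, a
single supra-threshold noise pixel that splits an enclosed core into two
diagonally adjacent halves would make each half disqualify the other. An
island is NF iff none of its pixels touches non-myocardium (8-adjacency)
or the image border; its in-myocardium surroundings are then necessarily
all enhanced, i.e. the island is sealed by infarct rim. Two consequences
are documented limitations: a core reaching the endo/epicardial border is
not detected automatically (the manual-contour path covers it), and a rim
sealed only by a diagonal chain of enhanced pixels does not count as
closed. The manual path rasterises a traced NF polygon; where it overlaps
enhanced pixels the overlap is reassigned to NF with a warning, keeping
`total MI = enhanced ∪ NF` and the disjointness invariant intact. The NF
is always *measured indirectly*: `area(total MI) − area(enhanced)`.

## T2 fitting

The fit minimises $\sum_i (SI_i - SI_0 e^{-TE_i/T2})^2$ in the signal
domain (not log domain), initialised from the log-linear regression of
$\ln SI$ on TE over positive samples, and iterated with a damped
Gauss–Newton (Levenberg–Marquardt) step that only accepts non-increasing
SSE — so the fit is never worse than its initialiser, and noiseless data
is recovered exactly (the initialiser is already the optimum). The
implementation is matrix-vectorised across pixels: a whole myocardial
mask is fitted in one pass. T2 is floored at 1 ms and capped at 2000 ms;
fits ending on a bound or with fewer than three positive samples are
flagged and excluded from regional statistics, which report mean and
*sample* SD (n − 1).

No Rician noise-floor correction is applied (a deliberate non-goal).
Uncorrected magnitude fitting biases T2 upward where the late-echo signal
approaches the noise floor: with the default 8-echo schedule the regional
mean bias is about 1.3–1.8 % at SNR 20 and under 1 % at SNR 40 for
myocardial T2 values. The recovery tests assert exactly these envelopes.

## Kinetics statistics

The serial analysis is a one-way within-subject ANOVA
($F = MS_{time}/MS_{time\times subject}$, fitted via `aov` with an
`Error(subject/time)` stratum and cross-checked in the tests against the
definitional sum-of-squares decomposition), followed by paired t tests of
each timepoint against the early reference with Holm correction, gated by
a significant ANOVA. The reported answer is the earliest timepoint that is
significant *with all later timepoints also significant* — the "reduced
from t min onward" reading of a serial decline. Holm was chosen over
uncorrected comparisons to be conservative and over Tukey because the
structure is many-vs-one; the gate and the correction are both
configurable, and Greenhouse–Geisser adjustment is available by flag
(sphericity is not corrected by default). Group comparisons use the
pooled-variance t test by default with Welch by flag; normality checking
uses the Kolmogorov–Smirnov statistic against a normal with estimated
parameters (as period clinical software did), with a Lilliefors variant
by flag. Degenerate inputs (identical samples) return t = 0, p = 1 rather
than NaN.

The cohort simulator draws per-subject random offsets (default SD 2.4 ml,
the between-animal spread of the emulated study) plus per-measurement
noise (default 0.5 ml, a plausible test–retest error) around a step-shaped
mean curve (baseline 7.7 ml, drop 2.4 ml at 20 min by default). Under
these conditions the detection procedure finds the 20-min step in ≥ 90 %
of seeded replicates and stays silent on null cohorts in ≥ 95 %.

## Numerical conventions

- World coordinates are millimetres with origin at the image corner; the
  centre of (1-based) pixel (r, c) is at
  ((c − ½)·spacing, (r − ½)·spacing). A pixel belongs to a region iff its
  centre is inside the polygon (even-odd rule). Contours are stored in mm
  so they survive resampling.
- All tie-breaks in the generator are deterministic (linear pixel index);
  one base seed per phantom spec derives the per-series noise streams, so
  identical configs give byte-identical outputs.
- NIfTI carries the voxels; a sidecar JSON carries sequence metadata NIfTI
  cannot (series kind, echo times, TI, post-contrast minute). DICOM is out
  of scope.

## Problem sizes in the test suite

Unit tests run on a 128 × 128, 2-slice phantom; the parameter-recovery
checks use the full 256 × 256, 6-slice study configuration (two groups,
nine timepoints each) and 100-replicate cohort simulations. The complete
suite runs in well under a minute on one core.

## Known limitations

No Rician bias correction in T2 fitting; the simplified IR signal model
(no TR/readout saturation term); automatic NF detection misses cores
touching the myocardial border; no automatic remote-ROI placement (it is
an input, by design); no DICOM ingestion; single-component T2 only; no
motion or artefact simulation. TTC planimetry — the post-mortem reference
the emulated protocol was validated against — is out of scope.
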