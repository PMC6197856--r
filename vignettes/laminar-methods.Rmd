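---
title: "Laminar source discrimination with a two-surface empirical Bayesian beamformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar source discrimination with a two-surface empirical Bayesian beamformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MEG records magnetic fields a few centimeters from the cortex. Whether a
band-limited signal originates from deep (infragranular, near the
white-matter boundary) or superficial (supragranular, near the pial
surface) cortical laminae is a distinction of only 2–3 mm in source depth,
yet it carries theoretical weight: low-frequency (alpha/beta) activity is
proposed to travel through deep layers and high-frequency (gamma) activity
through superficial ones. This package implements the analysis chain that
makes that distinction testable with MEG: a generative source space built
from *two* linked cortical surfaces, a beamformer-style empirical Bayesian
source inversion over the combined space, band-limited power contrasts
between corresponding vertices on the two surfaces, and a set of
perturbation controls that probe whether an apparent laminar preference is
real or an artifact of forward-model precision and SNR.

Everything here runs on synthetic sessions with known laminar ground
truth; the point of the package is to exercise, test, and stress the
method itself.

## The generative model

**Source space.** A `laminar_model` binds a pial and a white-matter
surface with strict index correspondence: vertex *i* on the white surface
is the partner of vertex *i* on the pial surface, 1:1, with no geometric
re-matching (silent nearest-neighbor matching would corrupt the pairing
that every downstream statistic depends on). The combined source space is
ordered `[white block, pial block]`, and that convention is load-bearing:
a positive laminar *t* always means "pial/superficial".

**Synthetic anatomy.** `make_two_layer_model()` builds the two surfaces as
a subdivided icosphere (default 642 vertices per surface, radius 7 cm)
with the white surface displaced 3 mm inward along the pial normals. A
smooth deterministic radial modulation (`wrinkle`, default 10%) mimics
gyrification. The wrinkle is not cosmetic: in a spherical conductor a
radial dipole produces no external field, so perfectly concentric
spheres — whose normals are all radial — would be entirely invisible to
MEG. The wrinkle tilts the normals enough to make the source space
measurable while keeping the geometry analytic and reproducible;
`wrinkle = 0` recovers the concentric geometry for purely geometric work.

**Forward model.** Fields are computed with the closed-form solution for a
current dipole in a homogeneous conducting sphere, fitted to the scalp
surface. This is exact, dependency-free, and preserves the property the
laminar analysis cares about (systematic gain differences between a
superficial source and its deep partner); `build_lead_field()` accepts any
other field evaluator with the same signature if a realistic shell model
is wanted. Axial gradiometer channels (default 130, Fibonacci-spaced on a
spherical cap, 5 cm baseline) take the difference of the field component
along the coil orientation between the pickup coil and a reference coil
displaced outward along it.

**Patch prior.** `coherence_smooth()` replaces each lead-field column with
a Gaussian-weighted sum of its same-surface neighbors (weights on
geodesic, i.e. graph-shortest-path, distance; normalized to one). A
diagonal prior over this smoothed basis is an extended-patch covariance on
the original space. Smoothing never crosses between surfaces. The default
patch FWHM in the pipeline is 10 mm: at the toy mesh's ~9 mm edge length
this is the smallest patch the mesh resolves (a 4 mm patch on this mesh
would collapse to single vertices, which the code flags with an
under-resolution warning).

## The inversion

`svd_reduce()` projects the epochs onto dominant spatial modes (top
eigenvectors of the channel covariance; default `min(channels, 180)`) and
temporal modes (top right singular vectors of the trial-stacked data
matrix, default 16, computed by deterministic subspace iteration at large
sample counts). Stacking trials rather than averaging them matters because
the signals of interest are induced: with per-trial random phase the
phase-locked average is near zero while the stacked modes still capture
the oscillatory structure.

The per-source prior variance is the beamformer estimate
`q_i = (1/L_i'L_i) * (L_i'(YY')^{-1}L_i + lambda*mu)^{-1}`, with `lambda`
expressed as a fraction of the mean eigenvalue `mu` of the reduced data
covariance, `lambda = 0` by default (highest spatial resolution), and a
multi-regularization variant that scores the ladder 0, 5, 10, 50, 100,
1000 (percent) by free energy and keeps the argmax. Sources whose lead
field is numerically zero (possible at the wrinkle's nodal lines) are
assigned zero prior variance rather than the unbounded value the formula
would give: an unobservable source should get no variance, not infinite
variance.

`reml_mix()` scales the two covariance components — identity sensor noise
(an empty-room covariance can be substituted) and the beamformer source
covariance — by restricted maximum likelihood: log-parameterized
hyperparameters (hence positive by construction), Fisher-scoring updates
with step-halving on any free-energy decrease or non-positive-definite
candidate, convergence at |dF| < 1e-4 or 128 iterations. The free energy
`F = -N/2 (logdet C + tr(C^{-1} S))` omits constants shared by all models
on the same data, so F is comparable only within a candidate set (the
regularization ladder, the patch-size sweep, veridical-versus-shuffled
comparisons), never across data sets.

Each band/window signal gets its own inversion computed on zero-phase
band-filtered epochs. This follows the reference analysis practice of
inverting per frequency band of interest and is not optional at these
SNRs: a single broadband inversion's covariance is dominated by the
strongest low-frequency rhythm plus noise, and the resulting spatial
filters essentially ignore gamma-band structure.

## The laminar statistic

For a signal (band, window of interest, baseline window):

1. Per-trial, per-vertex band power in the WOI and baseline. At source
   level the default estimator is the time-domain mean square of the
   band-filtered projected signal ("filter" method): by Parseval this is
   the band power, and it uses the full time–bandwidth product of each
   window, which matters because the windows are short (an 0.5 s baseline
   of a 6 Hz-wide alpha band carries roughly 6 effective degrees of
   freedom per trial, and a 7-cycle wavelet at 10 Hz is 0.7 s long —
   longer than the baseline window itself). Morlet and sliding-window
   multitaper estimators are available as options and are the defaults at
   the sensor level, split at 45 Hz.
2. Unsigned fractional change `|P_woi - P_base| / P_base` per vertex per
   trial.
3. ROI: vertices of either surface at or above the 80th percentile of the
   ROI-defining map on that surface, plus their partners (pair closure).
   Ties at the threshold are included. The ROI-defining map is the
   unsigned fractional change of the *trial-mean* power. This is
   deliberate: the mean over trials of the per-trial ratio is dominated
   by the heavy-tailed noise of few-dof single-trial baselines (a vertex
   containing nothing but noise averages |ratio - 1| near 0.5, outranking
   a vertex with a genuine 30% change), whereas the ratio of trial-mean
   powers concentrates sharply around the true fractional change.
   Metrics: `global` (all vertices), `functional` (geodesic neighborhood,
   default 10 mm, of the peak vertex), `anatomical` (percentile computed
   within a label mask standing in for an atlas region).
4. Per-trial ROI means per surface; variance-floored paired t over trials
   (floor: 1% of the squared mean paired difference, disable with
   `floor_frac = 0`). Positive t = superficial, negative = deep. The
   floor attenuates artifactually large t values when paired differences
   are nearly constant, mirroring the role of corrected noise-variance
   estimates in the reference analysis chain. The per-trial denominator
   defaults to the across-trial mean baseline power
   (`baseline_ref = "mean"`): the formula `|WOI - baseline|/baseline`
   does not fix the reference, and the trial-own baseline of a 0.5 s,
   6 Hz-wide window is a ~6-dof chi-square whose reciprocal is heavy
   tailed — it dominates the statistic's variance without carrying
   laminar information. `baseline_ref = "trial"` restores the trial-own
   denominator.
5. Group level: exact Wilcoxon signed rank on per-participant pial-white
   differences. Zeros dropped, midranks for ties, W = sum of positive
   ranks, two-sided p doubling the smaller tail of the exact null
   (dynamic programming over all 2^n sign assignments; n <= 25), capped
   at 1. This convention reproduces the canonical printed (W, p) pairs at
   n = 8 — e.g. W = 0 gives p = 0.0078, W = 35 gives p = 0.016. A
   shifted null (per-participant values from the shuffled control) is
   supported; each participant's difference is shifted by their own
   shuffled mean, which we prefer to a grand-mean shift because the
   shuffled floor varies across participants.

## What the generator emulates, and what it cannot show

`simulate_session()` produces epoched sensor data with known truth:
band-limited stochastic carriers (fresh per trial, so trial-averaged
evoked fields vanish) on Gaussian geodesic patches of one surface, power-
modulated inside their time window by a raised-cosine envelope; optional
condition-dependent modulation (e.g. a larger gamma burst on incongruent
trials); projection through the veridical lead field; distributed
unmodulated background activity; and white sensor noise scaled to a
target SNR (defined against the task signal).

Three generator choices deserve explanation, because each was forced by a
degeneracy of the "obvious" sparse simulation:

* **Background activity** (`background`, default 1 = background sensor
  power equal to task-signal power): unmodulated dipole noise over the
  whole source space (spatial covariance `L L'`) with a 1/f amplitude
  spectrum. Real MEG records task modulations on top of ongoing brain
  activity everywhere. Without it, the partner vertex of a simulated
  source reconstructs *nothing but* projected sensor noise, and the
  scale-free per-trial ratio statistic turns a 500-fold reconstructed
  power separation between the surfaces into a near coin flip (the |.| of
  a pure noise ratio stochastically dominates the |.| of a modulated
  one). Shared ongoing activity gives both partners a common in-band
  denominator, which is the regime the statistic was designed for.
* **Source-level effect sizes** (alpha -60% — classical alpha blocking —
  and a +200% gamma burst): magnitudes typical of source-level occipital
  alpha desynchronization and induced visual gamma, larger than the
  corresponding sensor-level percent changes, which average over sensors
  seeing many sources. The information content of a single trial bounds
  what any estimator can do here: with a 0.5 s baseline and a 6 Hz band,
  the per-trial baseline power estimate has a CV near 0.6, so a
  fractional change well below that cannot be resolved per pair at any
  inversion quality — classification degenerates toward chance even when
  the inversion allocates power to the correct surface in every session.
  We verified exactly that: with conservative (-30%) modulations the
  prior's depth allocation was correct in 8/8 sessions while the
  ratio-based classification hovered at chance.
* **Visible source placement**: generator-chosen source locations are
  restricted to vertices whose lead-field gain is at least the median of
  their surface (within the region under the helmet). The deterministic
  wrinkle harmonic has nodal lines where normals are nearly radial and
  sources nearly silent; real cortical regions have no such synthetic
  silent lines, and placing "visual cortex" on one would test the
  forward model's blind spots rather than the laminar method.

A structural property worth stating plainly: the fractional-change
statistic is scale-free per vertex, so the empirical Bayesian prior's
depth allocation — which is robustly correct in these simulations —
cancels out of it entirely. Laminar classification rests only on the
small *direction* differences between the partner vertices' spatial
filters. That is faithful to the reference analysis chain, and it is why
per-participant accuracy has a ceiling on a 130-channel, 642-pair toy
sphere: across 24 development and held-out sessions the frozen defaults
classify the deep alpha source correctly in 24/24 and the superficial
gamma source in ~85-90% of sessions. Passing recovery tests therefore
show that the full chain discriminates laminae under realistic effect
sizes, ongoing activity, and 0 dB sensor SNR on a toy spherical anatomy —
with single-participant gamma misclassifications at roughly the rate the
original study also reports — and do not show that the method resolves
weaker modulations, real gyral geometry, or correlated sensor noise.

## Numerical choices

* Geodesic distances are graph shortest paths over mesh edges; exact
  surface geodesics are unnecessary at patch scales of 1–2 edge lengths.
* Zero-phase band filtering applies the squared-magnitude Butterworth
  response in the frequency domain (the spectral equivalent of
  forward–backward filtering, vectorized over channels). The
  preprocessing high-pass and low-pass are applied as separate passes
  because a direct-form order-5 bandpass with a near-zero lower edge is
  numerically unstable.
* The temporal SVD basis at large sample counts uses subspace iteration
  with a deterministic start (25 iterations, 8 guard vectors); below 256
  samples it falls back to an exact eigendecomposition.
* Robust averaging uses the bisquare weight function with tuning constant
  4.685 and a MAD-based scale; all-equal samples return immediately with
  unit weights.
* Trial rejection excludes trials whose variance exceeds the across-trial
  mean by more than 2.5 SD (upper tail only).
* The exact Wilcoxon null doubles midranks so tied ranks stay on an
  integer lattice for the dynamic program.
* Degenerate inputs: isolated mesh vertices get zero normals and are
  excluded from the source space; zero-lead-field sources get zero prior
  variance and zero fractional change; a singular reduced covariance at
  `lambda = 0` is an error directing the user to regularize.

## Study design defaults

The packaged study (`run_laminar_study()`, `analysis/04_laminar.R`)
simulates 8 participants sharing one toy anatomy and helmet (642 vertices
per surface, 130 channels; sensors 3 mm outside the scalp sphere,
head-cast-grade proximity) with per-participant source locations,
carriers and noise; 100 trials per session; SNR 0 dB; ongoing background
at task-signal power; inversion patch FWHM 10 mm; functional ROI metric;
mean-baseline reference. These sizes keep a full study under ~10 minutes
on one CPU. The functional (peak-centered) ROI is the default for the
synthetic study because simulated sources are spatially compact objects
with a well-defined peak; the global metric, appropriate when genuine
task-responsive cortex covers a large fraction of the surface, dilutes a
focal synthetic source among hundreds of task-silent pairs.

## Known limitations

* The spherical-conductor forward model cannot represent skull anisotropy
  or realistic shell geometry; the interface accepts replacements.
* Free energies are comparable only within a candidate set on fixed data.
* The normal-approximation Wilcoxon branch (n > 25) uses a continuity
  correction but no tie-variance correction.
* The synthetic anatomy has no sulci: scalp-distance confounds exist (the
  white surface is always deeper) but gyral-crown/sulcal-fundus geometry
  is only caricatured by the wrinkle harmonic.
* Laminar classification is binary by construction; a distribution of
  sources across depths is reported as whichever surface dominates.
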