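---
title: "Population decoding of complex texture motion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population decoding of complex texture motion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsmotion)
```

## The scientific problem

Direction-selective (DS) retinal ganglion cells are classically characterized
with drifting gratings, where only motion direction varies. Under a moving
natural-like texture, however, a DS cell is driven simultaneously by motion
*and* by luminance changes sweeping through its receptive field. Its spikes
are then ambiguous: a burst can mean "motion in my preferred direction" or
"preferred contrast entering my receptive field". This package simulates
populations of such cells and implements the full analysis chain used to
study how that ambiguity is resolved by reading out several cells together:
spike-triggered characterization, optimal linear decoding, spectral
information bounds, canonical correlation analysis, and reduced
(subtractive/additive) population codes.

Everything runs on synthetic data. The stimulus generators and model cells
are first-class, tested components; recorded spike times in the documented
CSV dialect can be substituted wherever a `spike_train_set` is accepted.

## Stimulus model

The screen model fixes the geometry and clock: 7.5 um pixels, 60 Hz refresh
with stimulus updates every second refresh (30 Hz, `dt` = 33.3 ms), and
luminance normalized to [0, 1] around a mean of 0.5. All temporal windows in
the package are `L = 24` taps = 800 ms on this clock; using one window length
for the STA, the decoder and the information segments keeps the stages
mutually consistent.

**Random-walk trajectory.** Each frame the texture moves by independent
Gaussian steps in x and y with SD 22.5 um, rounded to multiples of the 7.5 um
pixel pitch. Rounding is half-away-from-zero; it inflates the per-component
step SD to `sqrt(22.5^2 + 7.5^2/12)` (about 22.6 um), and the mean net
displacement per second is the Rayleigh mean `sigma_eff * sqrt(30 * pi / 2)`,
about 155 um — the acceptance script recomputes this number. The quantization
and SD-inflation identities are verified in the test suite against analytic
oracles.

**Textures.** The standard texture starts from binary 30 x 30 um^2 black and
white squares (p = 0.5 each) smoothed with an isotropic 60 um SD Gaussian.
Sum-normalized smoothing strongly attenuates the pattern amplitude, so the
smoothed pattern is renormalized to 100% Michelson contrast (its darkest
point black, its brightest white) before the contrast deviations are scaled
by 1.5 and clipped to the luminance range. This is a package choice where
the construction is otherwise under-determined: it keeps the nominal "100%
contrast" of the binary pattern meaningful after smoothing, and makes the
final 1.5x scale-and-clip step active (a few percent of pixels saturate)
rather than a no-op, while leaving the clipping mild enough that the
pink-noise texture's 1/f spectrum and its mean/SD matching survive. The
pink-noise texture is synthesized in the Fourier domain with a 1/f amplitude
spectrum and matched to the standard texture's mean and SD; because clipping
compresses a plain rescale, the field scale is solved numerically so that
the *clipped* texture matches the reference SD. Arbitrary grayscale images
are accepted via `texture_from_image()`.

Textures are generated larger than the viewing window plus the expected
trajectory excursion; rendering raises an error naming the offending frame
rather than wrapping around, since wrap-around would silently reuse texture
content.

## Model retina

`model_cell()` implements a linear-nonlinear Poisson cascade. The stimulus
(motion steps) is normalized to unit variance per component and filtered with
a unit-norm 800-ms filter; a static nonlinearity maps the filtered drive to a
rate in Hz; spike counts per frame are Poisson with mean `rate * dt`. The
temporal filter template is a difference of Gaussians with its main lobe at
175 ms and zero crossing near 100 ms before the spike, within the window
where measured motion STAs peak.

Two nonlinearity families matter scientifically:

* **exponential** `N(x) = A exp(Bx)` — monotonic; the cell fires more for
  motion toward its preferred direction and less for the opposite.
* **U-shaped** `N(x) = C + A x^2 exp(Bx)` — non-monotonic; strong motion of
  *either* sign raises the rate, so single-cell responses are directionally
  ambiguous. This is the regime of DS cells under texture motion.

Defaults are `A = 2, B = 1` (exponential, mean rate ~3.3 Hz for unit-variance
Gaussian drive) and `C = 1, A = 3, B = 0.25` (U-shape, ~4.3 Hz). The exact
fitted parameters behind the published curves are not available, so these
were calibrated once so that the model reproduces the qualitative regime the
analyses target: opponent pairs with the monotonic nonlinearity decode
redundantly (information ratio below 1), opponent U-shaped pairs decode
synergistically (ratio above 1) with positive count correlations, and the
U-shape costs roughly a three-fold loss of single-cell information relative
to the matched monotonic cell. A steeper exponential (e.g. `B = 1.5`) pushes
the opponent pair into a complementary half-range regime whose ratio sits at
1 instead of showing redundancy, which is why the slope matters. Rates stay
within the 1–10 Hz operating band throughout. All parameters are arguments.

For two-dimensional motion the default population cell carries *two* filter
components: the template rotated into the preferred direction, plus an
orthogonal component passed through a symmetric U-shape (`B = 0`), with
rates summing over components. Orthogonal motion modulating the rate through
a symmetric U-shape is what makes 120-degree-separated pairs and mixed
three-direction subpopulations decode synergistically; with single-component
cells that synergy largely disappears. `build_population()` assigns cells
round-robin to three preferred-direction groups 120 degrees apart.

`simulate_texture_cell()` is a deliberately synthetic scaffold — an OFF-type
contrast cell with a Barlow–Levick/Reichardt-style opponent correlator over
two spatially offset OFF subunits — used to exercise the movie-based
analyses (checkerboard receptive fields, grating tuning, conditional texture
STAs) end to end. No quantitative conclusion rests on its details, and the
acceptance checks never use it.

## Spike-triggered characterization

The motion STA is the spike-count-weighted average of the trailing 800-ms
step windows, normalized by the total spike count; the preferred direction
is the angle of the tap-summed (x, y) vector. Significance uses a shuffle
test: spike times are redrawn uniformly over the recording (1000 shuffles),
and the STA magnitude must exceed the 95th percentile of the shuffled
magnitudes. Uniform redraw was chosen as the most literal reading of
shuffling spike times over the duration; permuting inter-spike intervals is
a near-equivalent alternative that also preserves the count. The test's
type-I error is verified to sit near 5% on rate-matched null cells.

For near-symmetric U-shaped cells the STA-integral direction estimate is
intrinsically noisy (the linear component of the response is small): across
seeds the recovered direction scatters by 10–20 degrees even for 40-minute
recordings, mirroring the broad spread seen when comparing grating- and
texture-derived preferred directions in real cells. The tight 15-degree
recovery checks therefore run on STA-dominant (exponential) cells.

The LN nonlinearity is estimated by sorting (drive, count) pairs and binning
into 15 equal-count bins (remainder samples are assigned to the central
bins); rates are bin means divided by `dt`. The U-shape index
`U = (N(g_min) - N(0)) / N(g_max)` uses the leftmost, central and rightmost
bins. Parametric fits use Levenberg–Marquardt least squares.

Spike-triggered covariance is computed on the normalized stimulus scale
around the STA, and the eigenvectors of the two largest eigenvalues are
selected, with conditional nonlinearities computed per eigenvector while the
projection on the other is confined to (-0.5, 0.5). One theoretical point
deserves note: a *pure exponential* nonlinearity tilts the mean of the
Gaussian spike-triggered ensemble but leaves its covariance exactly
unchanged, so it produces no STC signature along the filter. The STC
signature exploited here comes from the U-shaped cells, whose
variance-increasing nonlinearity makes the filter direction the top
eigenvector (and, for two-component cells, makes the top two eigenvectors
span the filter plane).

Conditional texture STAs average the texture frame 200 ms before spikes
fired under strong preferred (`g > 0.5`) or anti-preferred (`g < -0.5`)
drive, subtract the all-frame mean pattern, and summarize the result by a
contrast bias `(darkest + brightest pixel) / pixel SD` and the dark-spot
location. The dark spot is localized after 30 um Gaussian smoothing to
suppress single-pixel noise; inclusion requires the absolute peak to exceed
4 pixel SDs.

## Optimal linear decoding

The decoder solves the normal equations `B = (F'F)^{-1} F'S` on a design
whose row for step `s_j` holds a leading 1 and, per cell, the `L` counts of
frames `j .. j+L-1` — the counts at and after the step, since spikes follow
the motion. The Gram matrix term corrects the reverse-correlation filters
for the pairwise correlations between cells. Tap `m` multiplies the count
`m` frames after the decoded step; the tap at lag 0 carries no signal for a
causal encoder, which matters when comparing decoder filters with
time-reversed encoding filters.

The time axis is split chronologically, first 70% train / last 30% test;
windows straddling the boundary are dropped from both blocks so no test
frame ever enters a training window. Singular designs (e.g. duplicated
cells) fall back to the minimum-norm pseudo-inverse with a warning; no ridge
regularization is applied by default. Reduced codes difference or sum the
two cells' counts into a single sequence that is then decoded and
characterized exactly like a single cell; the motion-opponent axis of a pair
is the one with the larger absolute difference between STA peaks within
300 ms before the spike (ties go to x).

## Information measures

The mutual information between held-out stimulus and reconstruction is
bounded from below in frequency space: non-overlapping 800-ms segments are
Fourier transformed, one-sided power spectra of stimulus (`Ps`) and error
(`Pe`, `e = s - u`) are averaged over segments, and the per-band density is
`log2(Ps/Pe)`, summed over the 13 bands (0–15 Hz at 1.25 Hz) and divided by
the segment duration, then summed over the independent x and y axes. Two
numerical choices: segments are rectangular (no taper), matching the plain
segment-FFT construction; and bands where finite sampling makes `Pe > Ps`
are clipped to zero density, keeping the estimate a conservative lower bound
(the clipping introduces a small positive bias at very low information,
which is why pairs with summed single-cell information below 0.1 bits/s are
flagged ineligible for ratio analysis). Both the Gaussian-channel closed
form and the duplicated-cell ratio of exactly 1/2 serve as oracles in the
tests. Reconstruction and error segments are centered by the global
test-block mean only, not per segment.

The synergy/redundancy ratio is `I_pop / sum_k I_k`. The perturbation
experiments compare same-trial decoding against trial-shuffled, flipped, or
spatially offset pairings; for the noise-shuffle comparison, ratios are
averaged over all trial combinations of each kind. Because the simulated
cells have independent Poisson noise by construction, the same-vs-shuffled
comparison is an *exact* null: its signed-rank p-value is uniform, and a
p > 0.05 check will reject for about 5% of seeds no matter the run count —
an intrinsic property of that acceptance check, not an instability of the
code.

## Canonical correlation analysis

Two-second (60-frame) sliding segments of the trajectory (x steps then y
steps) are paired with the two cells' count segments. The cross-covariance
is whitened on the stimulus side by the exact white-motion identity
`Cs = sigma^2 I` and on the response side by the symmetric inverse square
root of `Cf`, then decomposed by SVD. Spike-count covariances from finite
data are near-singular, so `Cf` receives shrinkage
`Cf + 1e-3 * tr(Cf)/dim * I`. The overall sign of each component pair is
undetermined by the decomposition; it is fixed by making the
largest-magnitude element of each stimulus component positive, which makes
results seed-stable. The per-component correlation between the two cells'
halves of the response component is the statistic that separates opponent
pairs (strongly negative) from same-direction pairs (positive).

## Problem sizes and runtime envelope

Simulated recording lengths are package choices stated here once: pair
simulations and perturbation experiments use 10-minute recordings per run
(100 and 50 seeded runs respectively), population-composition runs use
10 minutes, filter-recovery checks use 30–40 minutes, and the displacement
statistic uses a 10^4-second trajectory. These sizes give stable medians and
recovery errors comfortably inside the tested bounds while keeping the whole
suite in the minutes range; all are arguments if longer runs are wanted.

## What passing tests do and do not show

The generator emulates the study conditions — step statistics, frame clock,
rate ranges, three 120-degree direction groups, repeated/flipped/offset
trials — with independent Poisson spiking. It does not emulate spike
refractoriness, adaptation, shared noise (noise correlations), recording
artifacts, or spike-sorting errors. Consequently, green tests demonstrate
that the analysis chain is correct and that the encoding-model mechanisms
(U-shape ambiguity, opponent-pair synergy, subtractive-code resolution)
behave as described; they do not by themselves establish how large these
effects are in recorded retinas.

## Known limitations

* The spectral information bound is a lower bound with a clipping-induced
  positive bias in near-zero-information regimes; no bias-corrected
  spectral estimator is provided.
* STC significance is limited to selecting the top-2 eigenvalues; the full
  spectrum is reported but no per-eigenvalue shuffle band is computed.
* The texture-driven cell is phenomenological scaffolding; its DSI and
  contrast indices are qualitative.
* CCA is implemented for cell pairs only, as in the analyses it supports.
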