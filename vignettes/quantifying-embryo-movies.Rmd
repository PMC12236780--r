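---
title: "Quantifying nuclear-cycle hub dynamics and transcription kinetics"
author: "embryohub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear-cycle hub dynamics and transcription kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryohub)
```

# Scope and model

This package quantifies time-lapse fluorescence movies of syncytial
embryos, in which nuclei alternate between S phase and mitosis with no
gap phases, and nuclear counts double at every division. Three recurring
measurement problems are covered: (i) how bright and how clustered a
chromatin-associated factor is around S-phase entry (hub dynamics),
(ii) when each nucleus switches transcription ON and OFF (state
kinetics), and (iii) how the 5' and 3' ends of a nascent transcript
reporter behave relative to each other (initiation versus elongation).

All analysis operates on maximal-intensity z-projections. The package
assumes movies are regular in time (constant frame interval, 20 s by
default), that nuclei are roughly disc-shaped in projection, and that
sub-nuclear foci are approximately Gaussian spots of 1–4 px scale.

# Preprocessing

`maxProject()` collapses z by the per-pixel maximum.
`rollingBallSubtract()` estimates background as the grayscale
morphological opening with a flat disc structuring element (default
radius 50 px) and subtracts it, clipping at zero; the opening is
computed with EBImage and is validated in the test suite against a
brute-force erosion/dilation oracle, including border behaviour
(structuring-element positions outside the image are ignored).
`cropRegion()` uses closed, 1-based index intervals — the R convention —
rather than half-open 0-based ranges.

# Masking and segmentation

Bright histone-locus-body foci can dominate a between-class-variance
threshold and shrink nuclear masks. Both mask builders therefore first
*clip*: pixels above a threshold are replaced by a lower constant.
Where the original analyses chose this threshold manually per movie, the
package defaults to the 99.5th percentile of the frame with the median
of sub-threshold pixels as replacement — a deterministic surrogate with
the same intent — and accepts explicit values. The remaining chain is
Gaussian blur (default sigma 2 px), Otsu threshold, and for nuclear
segmentation: dilation (2 px disc, so peripheral transcription foci fall
inside their nucleus), watershed splitting seeded from maxima of the
Euclidean distance transform (neighbourhood radius 3 px, tolerance 1),
then removal of regions below 25% of the frame's median area or touching
an X-Y border. The area cutoff and the blur, dilation and watershed
parameters are configurable; their defaults were fixed once against the
synthetic fixtures and are not tuned per movie.

`otsuThreshold()` is implemented in-package as the vectorized
cumulative-moment form over 256 bins, because the package's acceptance
property is exact agreement with an exhaustive maximizer of the
between-class variance; the test oracle is an explicit loop over all
cuts. Ties break toward the lowest maximizing cut. Near-constant images
(range below a relative tolerance of 1e-10) are rejected as degenerate —
blurred constant frames carry FFT ripple of order 1e-16 that would
otherwise produce a meaningless threshold.

A deliberate limitation: the original filtering also removed nuclei
touching the top or bottom of the z-stack, a 3-D property that is
unrecoverable after projection; the area filter approximates it.

# Hub dynamics

`maskedStats()` reports the per-frame mean or variance of masked pixels.
Population variance (divide by N) is used; the choice is declared and
fixed for reproducibility since either convention is defensible at these
pixel counts. Recruitment onset — visually scored in the original
workflow — is formalized as the first frame reaching
`min + riseFraction * (max - min)` of the series (default rise fraction
0.2), with a manual override accepted everywhere an onset is consumed.
`peakInWindow()` takes the maximum over `floor(window / frameInterval)`
frames from onset (120 s default, i.e. 6 frames at 20 s). Per-nucleus
maxima (`perNucleusIntensities()`) serve as a clustering proxy for
pooled box-plot comparisons across treatments.

# Transcription state kinetics

Nuclei are linked frame-to-frame by greedy nearest-centroid assignment
capped at a maximum displacement (default: the median-area-equivalent
radius). Only tracks present in every frame are retained, so every state
series covers the full movie; this retention contract is the tested
behaviour, the linker itself being secondary. Foci are detected with a
scale-normalized Laplacian of Gaussian over sigmas 1.5–4 px; the
response threshold (default 0.5 intensity units, roughly one sixth of
the default simulated focus amplitude) was calibrated once on blank
synthetic frames, where the largest nuisance response (nuclear-body
edges) stays below 0.4 and true foci respond above 1.4. A nucleus is ON
at a frame when at least one focus falls inside its (pre-dilated) label;
nuclei with several simultaneous foci are treated identically to
single-focus nuclei. The first OFF transition is the start of the first
run of at least `debounce` consecutive dark frames after activation
(default 1: no smoothing). Cumulative ON/OFF curves divide by all
retained nuclei, so they are nondecreasing, bounded by 100%, and the OFF
curve never crosses the ON curve; multi-embryo runs aggregate pointwise
mean ± SEM.

# Dual-reporter quantification

Spots are detected on the *sum* of the two reporter channels (so a
5'-only spot is still found) after a 1 px blur, using a Difference of
Gaussians with sigmas (1.5, 3) px. Detections link into tracks with gap
closing: a track survives up to 5 consecutive undetected frames — a gap
of exactly 5 is bridged, 6 splits — and positions are never
interpolated across gaps. Each detection is quantified in both channels
as the mean of a 17×17 px square; local background is the mean of the
surrounding 31×31 px square *excluding* the inner square (annulus
policy). The literal reading — the full 31×31 mean — is available as
`policy = "full"`; the annulus is the default because the spot's own
signal would otherwise contaminate its background estimate. Corrected
intensity may be negative. Tracks of a single frame or with any
quantification window crossing the border are discarded. Sorting is by
first appearance, ties broken by *descending* total (summed) corrected
3' intensity — "total" is read as sum rather than mean, and brightest
first matches the intended display order. Montages tile 17×17 crops with
rows = tracks and columns = time, anchored at the earliest first
appearance over the displayed tracks, using the last known position
during gaps and blank tiles before first appearance.

# The synthetic movie generator

`simulateEmbryoMovie()` renders what the pipelines assume, with a full
ground truth. Its defaults are the study conditions and are not
adjusted per experiment:

* geometry: 256×256 px field, nuclei on a jittered hexagonal lattice
  with an 11 px radius (decaying 0.8× per cycle), kept
  `radius + 8` px clear of the borders — emulating the cropped central
  field that excludes peripheral nuclei — with a 0.2 px/frame random
  walk; mitosis condenses chromatin (0.55× radius, 1.6× intensity) and
  splits each nucleus into two daughters displaced along a random axis;
* schedule: S and M blocks from per-cycle durations (defaults 8.5 and
  15.5 min S phases — the characteristic shorter-then-longer succession —
  with 3 min mitoses) at a 20 s frame interval;
* bookmark foci persist through mitosis and disperse within 1 min of
  S-phase onset, reappearing 2 min into S phase; kinase foci appear in
  the last minute of mitosis and disperse 1 min into S; polymerase foci
  appear 2 min into S;
* transcription follows a telegraph model: per-nucleus ON onset is
  S-start + 1.5 min + an exponential of mean 1.5 min (mean onset 3 min
  into S phase), switching OFF with per-frame probability 0.01; the 3'
  (pcp) focus lags the 5' (mcp) focus by exactly
  `elongationDelayFrames` (default 10 frames = 200 s, within the
  observed 3–4 min range; the parameter is in frames so recovery tests
  are exact);
* noise: a constant baseline of 0.2 intensity units (camera offset, so
  zero-clipping never biases the background), Poisson shot noise at 100
  photons per intensity unit, Gaussian read noise of sd 0.02, applied in
  that order after rendering;
* the `cdc7i` preset (kinase inhibition) delays kinase recruitment into
  S phase, prolongs bookmark persistence to 3 min, shifts the onset
  distribution to 3 + Exp(3) min, raises the OFF probability to 0.06 per
  frame, and makes half the spots fail to ever acquire a 3' signal —
  the delayed/transient/elongation-defective phenotypes in one knob.

All stochastic draws consume a single stream seeded from `rngSeed` in a
documented order (placement; per-cycle division, offsets and kinetics;
drift; noise), so identical configurations are bit-identical. Focus and
body amplitudes are free parameters — the real amplitude ratios between
histone-locus and minor foci are not known quantitatively — chosen so
spot responses sit well above segmentation-edge responses at the default
noise level.

What the generator does *not* emulate: photobleaching, chromatin
mechanics, 3-D point-spread-function optics, channel bleed-through, or
inhomogeneous illumination. Passing recovery tests therefore
demonstrates correctness of the measurement chain under the stated
statistical structure, not robustness to every real-data artifact; on
real movies the clipping threshold and detector thresholds may need
per-dataset values, which every function accepts.

# Statistics

`mannWhitneyU()` enumerates all assignments of the pooled sample for
exact two-sided p values (`min(1, 2 * min(P(U<=u), P(U>=u)))`), with
midranks for ties; the automatic mode switches to the normal
approximation with tie-corrected variance and a 0.5 continuity
correction above 16 total observations or whenever ties are present (the
exact mode still accepts ties explicitly). The test suite cross-checks
the exact path against `wilcox.test` on tie-free samples and against a
direct pair-counting enumeration with ties. Bonferroni correction takes
an explicit family size so panels with more comparisons than supplied p
values adjust correctly. Box summaries use the linear-interpolation
(type 7) quantile rule with 1.5·IQR whiskers at actual data points.

# Problem sizes and determinism

The shipped validation runs use 64×64 px images for primitive oracles,
160–256 px fields with 8–30 nuclei and 18–60 frames for recovery and
contrast studies — sizes at which every property of interest (identity
recovery, detection F1, onset error, DKW band membership, preset
contrasts) is already stable across seeds. Pipelines write CSVs and
resolved configs with no timestamps; reruns with the same config and
seed are byte-identical, which the acceptance checks assert at the file
level.

# Known limitations

* Greedy nearest-neighbour linking can swap identities when nuclei or
  spots approach within the displacement cap in a single frame; the
  complete-track filter drops such casualties rather than repairing
  them.
* Sub-pixel localisation is out of scope: spot positions are integer
  pixels, and recovered focus peaks are validated to 1 px.
* OFF calling with `debounce = 1` treats any single dark frame after
  activation as a transition; on noisy real data a debounce of 2–3
  frames may be preferable, at the cost of delaying genuine OFF calls.
* Absolute transcript counts are not calibrated from intensities.
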