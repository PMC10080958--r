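---
title: "Quantifying retinal visual stimulation from head-mounted recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal visual stimulation from head-mounted recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retstim)
```

## The scientific problem

Near work such as reading is epidemiologically associated with myopia
progression, while time outdoors protects against it. One candidate
mechanism runs through the retina's parallel ON and OFF pathways: ON
pathways are driven by luminance increments, bright large fields,
luminance transients (including blinks), and the large-field motion that
drives image-stabilization reflexes. A task that floods central vision
with dark-on-bright text, holds the scene still, suppresses blinks and
head movement, and lowers retinal illuminance will under-stimulate ON
pathways relative to OFF pathways.

`retstim` quantifies exactly this, starting from what a head-mounted
eye tracker records: a scene video, eye videos, a gaze/pupil stream, and
inertial (gyroscope/accelerometer) data. The pipeline reconstructs the
*retinal* input by sampling the scene video contingent on gaze, and then
summarizes it with a small set of statistics whose signs and orderings
carry the scientific content.

## The core statistics

Let `L(s, t)` be the 8-bit scene luminance (scaled to `[0, 1]`) at
retinal sample point `s` and retained frame `t`, where retained frames
are those recorded during fixation or smooth pursuit (stable retinal
projection) and the `s` are `N_S = 1000` points drawn uniformly by area
over a gaze-centred retinal region — a 5-degree foveal disc, the 8–60
degree peripheral ring, its upper/lower halves, or a sequence of
apertures.

* **Spatial RMS contrast** per frame:
  `C_S(t) = sqrt( sum_s (L(s,t) − mu_S(t))^2 / (N_S − 1) )`
* **Temporal RMS contrast** per retinal point:
  `C_T(s) = sqrt( sum_t (L(s,t) − mu_T(s))^2 / (N_T − 1) )`
* **Spatial skewness** per frame:
  `SK_S(t) = (1/N_S) sum_s ((L(s,t) − mu_S(t)) / C_S(t))^3`
* **Temporal skewness** per point, analogously with divisor `N_T`.

The divisors intentionally differ between the contrast (`N − 1`) and the
skewness (`N`); both follow the source formulations and the test suite
pins them against independent two-pass loop oracles. Negative skewness
means the luminance variation is carried by dark pixels (OFF-weighted
stimulation), positive by light pixels (ON-weighted). Retinal
illuminance in trolands is `L_v * pi * (d/2)^2` for pupil diameter `d`.

Supporting machinery: a piecewise-linear gaze segmentation plus a
four-state hidden-Markov-style classifier (fixation, saccade, smooth
pursuit, postsaccadic oscillation); a small convolutional
eyes-open/eyes-closed classifier for blink detection; head-velocity
event detection (threshold 2.5 x the directional median, 50 ms
refractory) with event-triggered eye averages; dense optical flow by
polynomial expansion for turn-induced optokinetic nystagmus (OKN)
analysis; Gaussian and Alpha (`y = max(0, b + d·((x−a)/r)·e^{1−(x−a)/r})`)
distribution fits; and a Wilcoxon comparison utility.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| fovea / periphery | 5 deg disc; 8–60 deg ring | anatomical definitions of fovea and (para)foveal boundary |
| `N_S` | 1000 offsets/region | equalizes sampling across regions of very different area |
| offsets | drawn once per region per analysis | a column of `L` must mean one retinal location over time |
| eq. divisors | `N−1` (contrast), `N` (skewness) | printed definitions; not "fixed" |
| classifier velocity priors | fixation 2, pursuit 12, saccade 150, PSO 30 deg/s (log-Gaussian) | head-free fixation includes 2–4 deg/s vestibulo-ocular drift; pursuit/OKN slow phases run 5–60 deg/s |
| transition table | `default_em_transitions()` | saccades are brief and return to fixation; PSO only after saccade |
| segmentation penalty | 25 x robust noise variance | exact DP segmentation; penalty plays the role of a duration prior |
| saccade seed speed | 30 deg/s central-difference, both-sided | at 50 Hz a 40 ms saccade is 1–2 samples; seeding prevents absorption |
| head-event threshold | 2.5 x directional median, 50 ms refractory | matches the event definition used for triggered averages |
| flow | 5 scales, 10 iterations, 5x5 windows (sigma 1.1), 25x25 averaging | the polynomial-expansion algorithm's published operating point |
| OKN band | 2–6 Hz, 100 samples at 50 Hz, >= 60 valid | turn-induced nystagmus band; windows centred on flow peaks |
| blink CNN | 3x3 convs of 16/32/64, BN+ReLU, 2x2 pools (36→18→9), SGD lr 0.01, batch 128 | the reference architecture; 50 desk-scale epochs (500 in the reference recipe) saturate on the synthetic set |

## What the synthetic sessions emulate — and what they do not

The study's raw recordings are not publicly deposited, so the package
ships deterministic generators whose *defaults are the stated world* of
the two tasks, and every test that "recovers" something recovers it
from these generators' exported ground truth.

**Reading** renders a 25.5 x 26 cm page of dark (2 cd/m^2) glyph-like
stroke runs (~13% ink within text lines) on a 90 cd/m^2 page over a dim
(12 cd/m^2) office surround, viewed at 0.5 m. Text is rendered at the
device's native 1920 x 1080 geometry, blurred by a Gaussian camera
point-spread (sd 2 native px) and area-downsampled to the working
480 x 270 frame — this is what makes foveal "ink" arrive as partial-
pixel grays, as it does through a real scene camera imaging 0.4 cm
letters, and it is why foveal spatial contrast is ~0.1 rather than the
~0.4 a binary ink model would give. Gaze scans lines left-to-right in
~2 degree saccades (fixations 0.22 +/- 0.15 s) with return sweeps;
blinks are Poisson at 10/min; the head is nearly still.

**Walking** builds a wrapping corridor panorama with the luminance
bands of indoor corridors (lights 1600–5000, walls 90–145, floors
70–90, ceilings 40–65 cd/m^2), 1/f texture, ceiling lights, and —
following the description of the recording environment — wall posters
and doors that both raise local contrast and attract about half of the
fixations. Ego-motion pans the panorama with gait sway, a 2 Hz
footstep pitch oscillation, and scheduled body turns (raised-cosine
velocity, 90 degrees over 2.5 s) that inject sustained horizontal flow;
during turns the eye performs a symmetric triangular 3 Hz oscillation
of 1.5 degree amplitude (the turn-induced OKN), and otherwise fixates
world targets with an 80 ms lagged counter-rotation of head motion.
Blinks run at 30/min; fixation distances follow a Gamma(2) (Alpha-
function-shaped) distribution with mode near 1 m.

Deliberate simplifications, hence limits on what a green test
establishes: the scene is a 2-D panorama (no parallax, no depth
structure, no stairwells); luminance-to-pixel mapping is a fixed-
exposure linear clip (the real camera auto-exposes, uncontrollably);
eye images are schematic pupil/iris/lid renderings, so the blink
network's 95%+ accuracy here does not certify performance on real
infrared eye video; head oscillation amplitudes are kept small
(0.3 degrees) so that compensatory eye-in-head velocity stays inside
the fixation regime and ground-truth labels remain well defined; and
saccade kinematics are linear ramps sampled with a midpoint-phase
convention, with samples that already show the landed position labelled
as fixation (observable-state convention). Sign structure and ordering
relations across tasks are meaningful under these simplifications;
absolute values of real recordings are not reproduced and are not
claimed.

## Numerical and design choices

* **Clock and alignment.** All streams are re-expressed with t = 0 at
  the first scene frame; 50 Hz gaze is matched to 25 Hz frames by
  nearest-neighbour lookup, never by interpolating invalid samples.
  Invalid samples are flagged and honoured downstream, not dropped.
* **Grayscale.** ITU-R BT.601 weights with round-half-up; pixel
  intensity is treated as proportional to luminance (the scene camera's
  measured relation is close to linear); an optional linearization hook
  can be applied upstream if a calibration exists.
* **Out-of-frame retinal samples.** The 60-degree ring necessarily
  exceeds the 52-degree vertical field of view; invalid cells are
  excluded and the effective `N` per statistic is the valid count, with
  a low-confidence flag below 30 valid cells. Frames whose gaze point
  leaves the frame are dropped entirely.
* **Segmentation.** The penalized least-squares segmentation is solved
  exactly by dynamic programming per between-gap chunk (gaps > 40 ms or
  invalid samples split the trace). Velocity emissions widen with the
  slope standard error of short segments, so the classifier does not
  over-read noise slopes. Decoding is full Viterbi by default (a greedy
  left-to-right pass is available via `classifier_config(viterbi =
  FALSE)`); saccade onset/offset boundaries are refined at sample
  resolution by a maximum-likelihood plateau test.
* **Spectra.** Periodic Hann window per frame, radial averaging in
  0.05 cycles/degree bins with per-axis pixels-per-degree, frequencies
  up to the smaller Nyquist limit.
* **Fits.** Bounded L-BFGS-B on the residual sum of squares with
  moment-based initialization and an iteration cap; goodness of fit is
  the coefficient of determination. `nls` is deliberately avoided
  because zero-residual (noiseless) data must be recoverable.
* **Flow.** Coarse-to-fine over a 5-level pyramid (0.5 scale steps with
  binomial anti-aliasing). The displacement solve averages the normal
  equations over a 25 x 25 box; frames wider than 480 px are downscaled
  first. The 20% peak threshold is taken against the session's own
  maximum in single-session mode (a cohort reference maximum can be
  supplied); peaks in the final 10 s are excluded; the peak search uses
  the absolute trace since turns occur in both directions.
* **Blink events.** Runs of closed frames separated by a single open
  frame are not merged; rates are reported both per 15 s window and per
  minute because the field reports both conventions.
* **Comparisons.** The unpaired rank-sum test is the default for
  frame/offset-level comparisons (a paired signed-rank mode exists);
  no multiple-testing correction is applied by default.

## Known limitations

Binocular analysis (vergence, per-eye blink fusion) is out of scope, as
are live device capture, vendor binary formats, calibration, cohort
management beyond two-way comparison, and any claim about real-subject
distribution values. The classifier is a functional equivalent of the
published segmented-regression + HMM approach, not a bit-level
replication of any external library.
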