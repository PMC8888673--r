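---
title: "Reconstructing apparent stimulus position from retinotopic maps: methods and conventions"
author: "prfRecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing apparent stimulus position from retinotopic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prfRecon)
```

## The question and the method

Early visual cortex contains an orderly map of the visual field: each
cortical vertex responds to stimuli in a restricted region, its population
receptive field (pRF), well summarised by a 2-D isotropic Gaussian with
centre $(x, y)$ and size $\sigma$ (degrees of visual angle). If the map is
a reference for *apparent* position, then an illusion that shifts where a
stimulus appears should shift where cortical responses fall in the map,
even when the physical stimulus is fixed.

`prfRecon` implements the analysis chain that operationalises this test:

1. **pRF mapping.** Each vertex's response time course to a wedge-and-ring
   mapping protocol is modelled as
   $r(t) = \beta \cdot \big[\mathrm{overlap}(G_{x,y,\sigma}, S_t)\big]
   \circledast h + \alpha$,
   where $S_t$ is the binary stimulus aperture at time $t$ and $h$ a
   canonical double-gamma haemodynamic response function (HRF).
2. **Evoked responses.** A block-design GLM turns the main-experiment
   series into one response value per vertex per condition.
3. **Reconstruction.** Responses of vertices whose fitted pRF centres fall
   inside a sliding spatial window are averaged into a response-versus-
   position profile, summarised by a 1-D Gaussian
   $\alpha + \beta\,e^{-(c-\mu)^2/2\sigma^2}$; the peak $\mu$ is the
   neural estimate of stimulus position.
4. **Encoding-model matching.** Profiles predicted for banks of simulated
   physical stimuli are correlated with the observed profile; the argmax
   of the correlation identifies the physical stimulus that best matches
   the apparent one.

Because real cortical data carry no ground truth, the package ships a
synthetic-observer module: ensembles of vertices with known pRFs, and BOLD
runs generated from exactly the forward model above, with an injectable
apparent-position shift $\delta$. Every downstream claim is then testable
as parameter recovery.

## The two experiments

**Two-dot (geometric) illusion.** Two target dots at 4° eccentricity on
the horizontal meridian, flanked by contextual fin dots at 45° polar angle
(centre-to-centre spacing 1.36°, dot diameter 0.64°). Outward fins make
the dots appear further apart, inward fins closer. Blocks: 10 s context
only, 16 s flashing targets plus context, 6 s fixation; eight blocks per
256-volume run, ten runs. The GLM contrast *target-period minus
background-period* isolates the target-evoked response (the static context
is present in both periods and cancels). Profiles are sampled on the
horizontal meridian (1° × 1° window, centres 1.5–6.5°, step 0.1°,
hemifield collapse).

**Drifting-Gabor (motion) illusion.** Four Gabor patches (wavelength 0.4°,
envelope SD 0.192°) at ±4° horizontal offset travel vertically toward the
horizontal meridian at 2.88°/s for 2.5 s (7.2° path). Internal carrier
drift orthogonal-outward produces a striking apparent outward tilt of the
path; drift anti-parallel to the path is the control. Runs are 291
volumes (15 s lead-in plus six repeats of 15 + 1 + 15 + 15 s). Profiles
are sampled with tall windows in two locations (peripheral 1° × 4.5°,
central 1° × 2°; centres 1–7°, quadrant collapse).

The generator injects $\delta$ as a *stimulus* displacement in the
illusory-designated condition: dot eccentricity $4 + \delta$, or a path
tilted about its start so the end point is displaced outward by $\delta$.
This tests the readout exactly as the analysis interprets it — by where
responses fall in the retinotopic map.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Analysis grid | 100 × 100 px over ±8.925° | — | the coarse-search extent must be representable on the mask; 0.1785°/px |
| Coarse grid | 15 × 15 × 34 (x, y, log σ) | deg | σ log-spaced 0.18–17°; exhaustive, deterministic x-major order |
| Coarse gate | R² > 0.05 | — | vertices failing it are not fine-fitted |
| Fine-fit bounds | x, y ∈ [−10, 10], σ ∈ [0.05, 17] | deg | quadratic penalty outside; σ optimised on the log scale |
| HRF | double gamma, peak 6 s, undershoot 16 s, ratio 6, 32 s support | s | any fixed kernel used consistently for simulation and fitting preserves recovery |
| Vertices | 2000 per V1 hemisphere | — | dense enough for 0.1° windows at desk scale |
| pRF size law | σ = 0.1 + 0.1·ecc (V1) | deg | linear eccentricity scaling with 20% multiplicative jitter, floor 0.05° |
| Amplitude, noise | β ~ N(3, 0.5), white noise SD 1 | z-units | puts the signal peak near β so noise SD 1 is a realistic SNR |
| Meridian gap | 20° polar angle (V2/V3) | deg | quarter-field maps under-represent the horizontal meridian |
| Context weight | 0.5 | — | static black context dots vs 2.5 Hz flashing targets; unknowable from data, exposed as a parameter |
| Window specs | see above | deg | half-open on the upper edge to avoid double counting at 0.1° steps |
| Searchlight | radius 1°, spacing 0.1°, weight 1/(d + 0.05°) | deg | the ε guard bounds the degenerate d → 0 case |

## Conventions the results depend on

**Profile normalisation.** The fitting path (`prfProfile`,
`predictTimeseries`) uses *unit-sum* (density) profiles, so the overlap
with a full-field mask is 1; per-vertex scale is absorbed by β, so the fit
is unaffected by the convention. The *generative* overlaps and the
encoding-model predictions (`predictProfile`) use *unit-amplitude*
Gaussians, normalised by the stimulus-mask mass: a stimulus centred on a
pRF then drives ~1 unit regardless of pRF size. This is the convention
under which the sliding-window peak sits at the stimulus position — with
density profiles the $1/\sigma^2$ prefactor combined with the
size–eccentricity law drags peaks foveally, and an injected 0.5° shift is
read out as ~0.34°.

**Series normalisation.** Mapping runs are linearly detrended and
z-scored per vertex (the pRF fit is invariant to per-vertex scale).
Main-experiment runs are detrended per vertex and run, then scaled by a
single session-wide RMS SD: per-vertex z-scoring of noiseless series would
divide each vertex by its own signal-dependent SD, destroying the
amplitude ratios the reconstruction reads out (the two conventions
coincide when homoscedastic noise dominates, which is the regime of real
recordings).

**Profile-fit weighting.** Window means are weighted by vertex count in
the 1-D Gaussian fit (variance of a window mean scales as 1/n). At desk
scale the outer windows hold only a few vertices; unweighted fits let
their seed-dependent means drag $\mu$ by up to ~0.2°. With thousands of
vertices per window, as in real cortex, the weighting is immaterial.

**Other numerical choices.** Dots are rasterised as filled discs (a pixel
belongs if its centre is inside; no anti-aliasing) so masks are
deterministic and binary. The C++ fine-fit objective evaluates the
Gaussian inside ±6σ and normalises by the in-window sum (tail mass
< 1e−7 relative). Coarse-fit ties resolve to the first candidate in scan
order. Gaussian profile fits initialise at the argmax window with σ = 1°
and run Levenberg–Marquardt with bounds σ ∈ (0.05, 10], μ ∈ sweep ± 1°;
fewer than 5 non-missing windows is a fit failure, and missing windows
are omitted, never interpolated. The poor-fit exclusion rule (R² more
than 2.5 SD below the group mean) uses leave-one-out moments, since an
outlier inflates a small group's SD enough to mask itself. Behavioural
effects use the binary logarithm throughout; the adjustment-jitter is
multiplicative $2^{N(0,\sigma)}$ (geometric mean 1), so per-context
effects are unbiased on the log2 scale. Gaze local medians are mapped
back to samples by nearest window centre; the MAD is reported raw (no
1.4826 consistency factor).

## Design choices where the protocol was open

- Mapping protocol for synthetic runs: one clockwise wedge cycle (60
  frames), one expanding ring cycle (36), one counter-clockwise wedge
  cycle, one contracting ring cycle — 192 s at 1 s/frame. Any protocol
  covering the field works; this one balances polar and eccentric
  information.
- Analysis apertures use a 17° diameter (2 × 8.5°).
- Two-dot simulated bank: per-side dot eccentricities 0.064°–8.32° (130
  steps of 0.128° inter-dot distance). Motion-path bank: straight paths
  pivoting at the path start, tilts −40°…+40° in 1° steps, positive =
  outward, each mask the rectified (`|v − 0.5|·2`) average of 150 frames.
- Motion start/end: |y| from 8.55° (half the 17.1° screen height) to
  1.35°. The tall windows cover |y| ∈ [4.05, 8.55] (peripheral) and
  [1.35, 3.35] (central).
- The stringent sampling criterion is implemented as |y| + σ < 0.5°
  (pRF centre ± 1σ inside the window height); windows extend symmetrically
  below the meridian, so the absolute value reflects the geometric intent.
- Coordinates: x positive rightward, y positive upward, degrees of visual
  angle, fixation at the origin; left cortex represents the right
  hemifield.

## What the synthetic observers do and do not emulate

They emulate: hemifield (V1) and gap-depleted quarter-field (V2/V3) pRF
ensembles with eccentricity-scaled sizes and log-eccentricity density
(cortical magnification); BOLD generated by pRF–stimulus overlap convolved
with the HRF; white Gaussian noise in z-units; detrending/normalisation;
block protocols with seeded condition orders; adjustment responses with
log-normal jitter; gaze traces with slow drift.

They do not emulate: cortical mesh geometry (surface smoothing is a no-op
hook — `fitPRF(smoother = )` accepts any vertex-neighbourhood smoother),
physiological/vascular noise or motion artefacts (the GLM accepts motion
regressors but none are generated), temporally correlated noise (AR
structure), attention or adaptation effects, or receptive-field
nonlinearities (centre–surround, compressive exponents — explicitly out of
scope). Passing recovery tests therefore shows the *readout logic* is
correct under the stated forward model, not that the model captures every
property of real data.

A known desk-scale artefact: vertices with sub-pixel ground-truth pRFs
near fixation (σ below the 0.18° grid resolution) can be mislocalised by
the fit, some to eccentricities just inside the 8.5° analysis gate. They
survive the R² > 0.05 gate with mediocre R² and add vertex-sampling noise
to the profiles; the count-weighted profile fit and (for headline numbers)
averaging over a small observer cohort keep the recovered shift stable.

## Problem sizes and runtimes

The test suite and the acceptance script use desk-scale sizes chosen so a
full run stays in the minutes range on one CPU: parameter-recovery checks
use 200-vertex observers; end-to-end shift recovery uses 4000-vertex V1
observers (2000 per hemisphere, the generator default) with 10 simulated
two-dot runs or 8 motion runs; the acceptance script averages the
recovered shift over a 3-observer cohort, mirroring the group-level nature
of the statistic. The coarse prediction matrix (7650 × 192) is built once
per session and cached.

## Statistics

Paired two-sided t-tests compare conditions within observer; Pearson
correlations come with a seeded percentile bootstrap CI (default 10,000
resamples of observer pairs); multiple comparisons across the four
profile-fit parameters use Bonferroni thresholds (0.05/4 = 0.0125). The
bootstrap is percentile (not BCa) — adequate for the CI-visualisation role
it plays here.
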