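# prfRecon

Does early retinotopic cortex encode where a stimulus *appears* to be, or
where it physically is? A family of fMRI studies answers this by reading
stimulus position back out of the cortical retinotopic map: estimate each
vertex's population receptive field (pRF), evoke responses with stimuli
whose apparent position is shifted by an illusion, and ask where in visual
space the response profile peaks. `prfRecon` implements that entire
analysis chain in R — together with a synthetic-observer generator with
known ground truth, so every stage can be validated by parameter recovery
rather than by eyeballing.

The package is aimed at visual/computational neuroscientists who want a
tested, scriptable reference implementation of:

- **Stimulus generation** — rotating-wedge and expanding/contracting-ring
  mapping apertures (60 × 6° wedge steps with 50% overlap, 36 logarithmic
  ring steps with a proportional 57% annulus, 8.5° maximal eccentricity),
  two-dot displays with inward/outward fin contexts, drifting-Gabor movies,
  and banks of simulated-stimulus masks.
- **pRF estimation** — the 2-D isotropic Gaussian model
  `r(t) = β · Σ_pixels G_{x,y,σ} · S(t) ⊛ HRF`, fitted in two stages: an
  exhaustive coarse grid search (15 x × 15 y × 34 σ = 7650 candidates,
  maximal Pearson correlation, R² > 0.05 gate) followed by Nelder–Mead
  refinement of (x, y, σ) with β and an intercept solved by least squares.
  The hot inner objective is implemented in C++ (Rcpp).
- **Block-design GLM** — HRF-convolved boxcars per condition × period,
  per-run intercept/trend columns, OLS contrasts per vertex.
- **Sliding-window reconstruction** — pooling responses of vertices whose
  pRF centres fall in a 1°-wide window stepping at 0.1° along the
  collapsed retinotopic map, summarised by a 4-parameter Gaussian
  `α + β·exp(−(c−μ)²/2σ²)`; the peak location μ is the neural estimate of
  apparent position. Lenient (σ ≤ 1°) and stringent (|y| + σ < 0.5°)
  pRF-size sampling criteria and participant exclusion rules are included.
- **Encoding-model matching** — predicted window profiles for banks of
  hypothetical stimuli (130 dot distances at 0.128° spacing; 81 motion-path
  tilts over ±40°) correlated with observed profiles to find the physical
  stimulus that best matches the apparent one.
- **Searchlight backprojection**, **psychophysical adjustment scoring**
  (binary-log size ratios; illusion magnitude in %), and **eye-tracking
  preprocessing** (10 s / 1 s local-median detrending, 0.05°-bin 2-D
  histograms, median absolute deviation).

## Worked example

Simulate an observer whose illusory condition carries a 0.5° apparent
outward shift, run the full pipeline, and read the recovered shift:

```r
library(prfRecon)

report <- runPipeline(list(
  experiment    = "mueller_lyer",
  nObservers    = 1L,
  deltaShiftDeg = 0.5,          # injected apparent shift (ground truth)
  noiseSd       = 0,
  nRuns         = 2L,
  observer      = list(nVertices = c(V1 = 500L)),
  match         = FALSE,
  seed          = 501L))

report$summary$muDiffMean
#> [1] 0.4607619
```

The number is the difference in fitted peak location μ (outward − inward
condition) of the sliding-window response profiles, in degrees of visual
angle: the pipeline reads the injected 0.5° apparent shift back out of the
synthetic cortex (up to window-sampling noise at this desk-scale vertex
count). With `deltaShiftDeg = 0` the same pipeline returns a difference of
~0 — no spurious shift.

Individual stages are exported and composable; for instance:

```r
spec <- ObserverSpec(nVertices = c(V1 = 2000L), noiseSd = 0, seed = 1L)
ens  <- makeObserver(spec)                       # ground-truth pRFs
ap   <- mappingApertures()                       # wedge + ring protocol
bold <- simulateMappingRun(ens, ap)              # z-scored BOLD
ens  <- fitPRF(ens, bold, ap)                    # two-stage estimation
head(fittedPRF(ens))
```

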