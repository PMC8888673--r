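# Synthetic observers: ground-truth pRF ensembles and noisy BOLD runs for
# the mapping session and both main experiments, with an injectable
# apparent-position shift so downstream recovery can be scored against
# truth. Also generators for adjustment-task trials and gaze traces.

#' Draw a ground-truth pRF ensemble
#'
#' Samples vertices per region and hemisphere. V1 tiles each hemifield
#' uniformly in polar angle and log eccentricity (the log-eccentricity
#' density emulates cortical magnification). V2/V3 vertices are drawn the
#' same way but avoid a polar-angle band of total width `meridianGapDeg`
#' around the horizontal meridian, emulating the sparser coverage of
#' quarter-field maps there. pRF size follows the per-region linear
#' eccentricity law plus multiplicative Gaussian jitter, truncated below at
#' 0.05 deg. All draws are fixed by the spec's seed.
#'
#' @param spec an [ObserverSpec-class].
#' @return An [ObserverEnsemble-class] with ground truth filled and no
#'   fitted pRFs.
#' @export
makeObserver <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, {
    rows <- list()
    for (region in c("V1", "V2", "V3")) {
      nPerHemi <- spec@nVertices[[region]]
      if (nPerHemi < 1L) next
      for (hemi in c("L", "R")) {
        side <- if (hemi == "L") 1 else -1   # left cortex: right hemifield
        gap <- if (region == "V1") 0 else spec@meridianGapDeg / 2
        # polar angle from the horizontal meridian, uniform outside the gap
        u <- stats::runif(nPerHemi, gap, 90)
        sgn <- sample(c(-1, 1), nPerHemi, replace = TRUE)
        phi <- sgn * u * pi / 180
        ecc <- exp(stats::runif(nPerHemi, log(spec@eccRange[1]),
                                log(spec@eccRange[2])))
        law <- spec@sigmaIntercept[[region]] +
          spec@sigmaSlope[[region]] * ecc
        sigma <- pmax(0.05, law * (1 + stats::rnorm(nPerHemi, 0, 0.2)))
        beta <- stats::rnorm(nPerHemi, spec@betaMean, spec@betaSd)
        rows[[length(rows) + 1L]] <- data.frame(
          region = region, hemisphere = hemi,
          x = side * ecc * cos(phi), y = ecc * sin(phi),
          sigma = sigma, beta = beta)
      }
    }
    truth <- do.call(rbind, rows)
    truth <- cbind(vertex = seq_len(nrow(truth)), truth)
    new("ObserverEnsemble", truth = truth, fitted = NULL, spec = spec)
  })
}

# Per-vertex overlap of ground-truth pRF profiles with mask columns
# (masks: npix x k matrix on `grid`); chunked for memory. Profiles are
# unit-amplitude Gaussians (the standard encoding-model convention: a
# stimulus at the pRF centre drives the same response whatever the pRF
# size; per-vertex scale is carried by beta). `profile = "density"` divides
# each profile by its total mass instead (unit-sum convention), which is
# used for mapping-run simulation where the per-vertex scale is irrelevant
# to fitting and the overlap should peak near 1 so that `beta` sets the
# signal-to-noise scale.
.truthOverlaps <- function(truth, masks, grid, chunk = 256L,
                           profile = c("amplitude", "density")) {
  profile <- match.arg(profile)
  pc <- pixelCoords(grid)
  n <- nrow(truth)
  out <- matrix(0, n, ncol(masks))
  for (i0 in seq(1L, n, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, n)
    W <- matrix(0, length(ii), nrow(masks))
    for (j in seq_along(ii)) {
      v <- truth[ii[j], ]
      gx <- exp(-(pc$x - v$x)^2 / (2 * v$sigma^2))
      gy <- exp(-(pc$y - v$y)^2 / (2 * v$sigma^2))
      w <- as.numeric(outer(gy, gx))
      if (profile == "density") w <- w / sum(w)
      W[j, ] <- w
    }
    out[ii, ] <- W %*% masks
  }
  out
}

#' Simulate a retinotopic mapping run
#'
#' Per vertex: overlap of the ground-truth pRF profile with each aperture
#' frame scaled by the vertex amplitude, resampled to the TR, convolved with
#' the HRF, plus white Gaussian noise, then linearly detrended and z-scored.
#'
#' @param ensemble an [ObserverEnsemble-class].
#' @param apertures mapping stack; defaults to [mappingApertures()] on the
#'   standard grid.
#' @param hrf HRF kernel at `trS`.
#' @param trS repetition time (s).
#' @param noiseSd white-noise SD (z-units); defaults to the observer spec.
#' @param seed seed for the noise draw; defaults to the spec seed + 1.
#' @return A [BoldSeries-class], vertices in ensemble order.
#' @export
simulateMappingRun <- function(ensemble, apertures = NULL,
                               hrf = canonicalHRF(trS), trS = 1,
                               noiseSd = NULL, seed = NULL) {
  spec <- observerSpec(ensemble)
  if (is.null(apertures)) apertures <- mappingApertures()
  if (is.null(noiseSd)) noiseSd <- spec@noiseSd
  if (is.null(seed)) seed <- spec@seed + 1L
  truth <- truthPRF(ensemble)
  fr <- frames(apertures)
  npix <- prod(dim(fr)[1:2])
  M <- matrix(fr, npix, dim(fr)[3])
  ov <- .truthOverlaps(truth, M, fieldGrid(apertures), profile = "density")
  ov <- resampleToTR(ov, frameDuration(apertures), trS)
  sig <- convolveHRF(ov * truth$beta, hrf)
  .withSeed(seed, {
    if (noiseSd > 0)
      sig <- sig + matrix(stats::rnorm(length(sig), 0, noiseSd),
                          nrow(sig), ncol(sig))
    BoldSeries(detrendZScore(sig), trS = trS)
  })
}

# block/event tables ----------------------------------------------------------

# one two-dot-experiment run: 8 blocks of 10 s background + 16 s target +
# 6 s fixation, four blocks per fin condition in seeded order
.mlEvents <- function(run, seed) {
  conds <- .withSeed(seed, sample(rep(c("outward", "inward"), each = 4L)))
  onsets <- (seq_len(8L) - 1L) * 32
  rbind(
    data.frame(run = run, onset_s = onsets, duration_s = 10,
               condition = conds, period = "background"),
    data.frame(run = run, onset_s = onsets + 10, duration_s = 16,
               condition = conds, period = "target"))
}

# one moving-stimulus run: 15 s lead-in, then six repeats of
# (15 s stimulus, 1 s fixation, 15 s stimulus, 15 s fixation); the two
# stimulus periods of a repeat carry the two conditions in seeded order
.cbEvents <- function(run, seed) {
  first <- .withSeed(seed, sample(c("illusory", "control"), 6L,
                                  replace = TRUE))
  ev <- list()
  t0 <- 15
  for (rep in 1:6) {
    c1 <- first[rep]
    c2 <- setdiff(c("illusory", "control"), c1)
    ev[[rep]] <- data.frame(
      run = run, onset_s = c(t0, t0 + 16), duration_s = 15,
      condition = c(c1, c2), period = "stimulus")
    t0 <- t0 + 46
  }
  do.call(rbind, ev)
}

#' Run durations (retained volumes) per experiment
#' @param experiment `"mueller_lyer"` or `"curveball"`.
#' @return Volumes per run at TR = 1 s (256 and 291 respectively).
#' @export
runVolumes <- function(experiment = c("mueller_lyer", "curveball")) {
  switch(match.arg(experiment), mueller_lyer = 8L * 32L,
         curveball = 15L + 6L * 46L)
}

#' Simulate main-experiment runs
#'
#' Generates z-scored BOLD runs plus the event table for either experiment.
#' Both conditions alternate within each run, as in the protocols. The
#' injected apparent shift `deltaShiftDeg` displaces the stimulus mask of
#' the illusory-designated condition outward before the overlap is taken
#' (the readout is then tested exactly as interpreted downstream — by where
#' responses fall in the retinotopic map):
#' * two-dot experiment (`"mueller_lyer"`): the outward-fins condition's
#'   target dots sit at eccentricity `4 + delta`; the inward-fins condition
#'   keeps the physical 4 deg. Contextual fin dots contribute in both
#'   periods of both conditions at `contextWeight` times the target's
#'   effective amplitude (static black context vs flashing targets).
#' * moving-stimulus experiment (`"curveball"`): the illusory condition's
#'   trajectory is tilted about the path start so the path end is displaced
#'   outward by `delta`; the control path is veridical.
#'
#' @param ensemble an [ObserverEnsemble-class].
#' @param experiment `"mueller_lyer"` or `"curveball"`.
#' @param deltaShiftDeg apparent outward shift (deg); defaults to the spec.
#' @param noiseSd noise SD; defaults to the spec.
#' @param nRuns number of runs (defaults: 10 two-dot, 8 moving-stimulus).
#' @param grid analysis [FieldGrid-class].
#' @param hrf HRF kernel at `trS`.
#' @param trS repetition time (s).
#' @param contextWeight effective response weight of the static contextual
#'   dots relative to the flashing targets.
#' @param seed base seed; defaults to the spec seed + 2.
#' @return List with `bold` (a [BoldSeries-class], runs concatenated after
#'   per-run detrend/z-score), `events` (data.frame: run, onset_s,
#'   duration_s, condition, period) and `runLengths`.
#' @export
simulateExperimentRun <- function(ensemble,
                                  experiment = c("mueller_lyer", "curveball"),
                                  deltaShiftDeg = NULL, noiseSd = NULL,
                                  nRuns = NULL, grid = FieldGrid(),
                                  hrf = canonicalHRF(trS), trS = 1,
                                  contextWeight = 0.5, seed = NULL) {
  experiment <- match.arg(experiment)
  spec <- observerSpec(ensemble)
  if (is.null(deltaShiftDeg)) deltaShiftDeg <- spec@deltaShiftDeg
  if (is.null(noiseSd)) noiseSd <- spec@noiseSd
  if (is.null(nRuns)) nRuns <- if (experiment == "mueller_lyer") 10L else 8L
  if (is.null(seed)) seed <- spec@seed + 2L
  truth <- truthPRF(ensemble)
  nV <- nrow(truth)
  nVol <- runVolumes(experiment)

  if (experiment == "mueller_lyer") {
    ctxOut <- muellerLyerMasks("outward", grid)$context
    ctxIn <- muellerLyerMasks("inward", grid)$context
    tgtOut <- muellerLyerMasks("none", grid,
                               targetEccDeg = 4 + deltaShiftDeg)$target
    tgtIn <- muellerLyerMasks("none", grid, targetEccDeg = 4)$target
    masks <- cbind(as.numeric(ctxOut), as.numeric(ctxIn),
                   as.numeric(tgtOut), as.numeric(tgtIn))
    colnames(masks) <- c("ctx_outward", "ctx_inward", "tgt_outward",
                         "tgt_inward")
  } else {
    tiltIll <- asin(min(1, deltaShiftDeg / 7.2)) * 180 / pi
    mIll <- rectifyAverage(curveballFrames("illusory", grid = grid,
                                           pathAngleDeg = tiltIll))
    mCtl <- rectifyAverage(curveballFrames("control", grid = grid,
                                           pathAngleDeg = 0))
    masks <- cbind(illusory = as.numeric(mIll), control = as.numeric(mCtl))
  }
  ov <- .truthOverlaps(truth, masks, grid)      # vertices x masks
  # normalise by mask mass (a per-mask constant): a stimulus centred on a
  # pRF then drives ~1 unit, so beta sets the signal scale for the noise
  ov <- sweep(ov, 2, pmax(colSums(masks), 1e-12), "/")
  colnames(ov) <- colnames(masks)

  events <- list(); boldRuns <- list()
  for (run in seq_len(nRuns)) {
    ev <- if (experiment == "mueller_lyer")
      .mlEvents(run, seed + 100L * run) else .cbEvents(run, seed + 100L * run)
    events[[run]] <- ev
    drive <- matrix(0, nV, nVol)                 # neural drive at TR grid
    tt <- seq_len(nVol) - 1L                     # volume start times
    for (k in seq_len(nrow(ev))) {
      on <- ev$onset_s[k]; off <- on + ev$duration_s[k]
      cols <- which(tt >= on & tt < off)
      amp <- if (experiment == "mueller_lyer") {
        w <- contextWeight *
          ov[, paste0("ctx_", ev$condition[k])]
        if (ev$period[k] == "target")
          w <- w + ov[, paste0("tgt_", ev$condition[k])]
        w
      } else ov[, ev$condition[k]]
      drive[, cols] <- drive[, cols] + amp * truth$beta
    }
    sig <- convolveHRF(drive, hrf)
    sig <- .withSeed(seed + run, {
      if (noiseSd > 0)
        sig + matrix(stats::rnorm(length(sig), 0, noiseSd), nV, nVol)
      else sig
    })
    boldRuns[[run]] <- detrendZScore(sig, scale = "none")
  }
  # one common scale for the whole session (the RMS per-vertex SD over all
  # runs): SD is ~1 as with z-scoring, but relative response amplitudes
  # across vertices and runs are preserved, keeping the noiseless signal
  # exactly within the GLM design span
  all <- do.call(cbind, boldRuns)
  s <- sqrt(mean(rowSums(all^2) / (ncol(all) - 1)))
  if (s > 1e-12) all <- all / s
  list(bold = BoldSeries(all, trS = trS),
       events = do.call(rbind, events),
       runLengths = rep(nVol, nRuns))
}

#' Simulate adjustment-task trials
#'
#' Generates trial tables for the psychophysical adjustment tasks with
#' multiplicative log-normal response jitter (`adjusted = truth * 2^e`,
#' `e ~ N(0, jitterSdLog2)`; geometric mean 1, so per-context effects are
#' unbiased on the log2 scale).
#'
#' For `"mueller_lyer"`, `gain` is a named vector of perceptual gains per
#' context (`outward`, `inward`, `none`): the adjusted distance is
#' `referenceDeg * gain * jitter`. For `"curveball"`, `perceptShiftDeg` is
#' the apparent outward displacement of the last-seen position in the
#' illusory condition: positions are `(referenceDeg + shift) * jitter`
#' (illusory) and `referenceDeg * jitter` (control).
#'
#' @param experiment `"mueller_lyer"` or `"curveball"`.
#' @param nPerCondition trials per context/condition.
#' @param gain named gains (two-dot experiment).
#' @param perceptShiftDeg apparent shift (moving-stimulus experiment, deg).
#' @param referenceDeg reference distance (two-dot: shaft length; moving
#'   stimulus: physical end position).
#' @param jitterSdLog2 SD of the log2 jitter (defaults: 0.25 and 0.1).
#' @param seed integer seed.
#' @return data.frame with columns `experiment`, `condition`, `reference`,
#'   `adjusted`.
#' @export
simulateAdjustmentTrials <- function(experiment = c("mueller_lyer",
                                                    "curveball"),
                                     nPerCondition = 16L,
                                     gain = c(outward = 1.05, inward = 0.945,
                                              none = 1),
                                     perceptShiftDeg = 0.6,
                                     referenceDeg = NULL,
                                     jitterSdLog2 = NULL, seed = 1L) {
  experiment <- match.arg(experiment)
  .withSeed(seed, {
    if (experiment == "mueller_lyer") {
      if (is.null(referenceDeg)) referenceDeg <- 8
      if (is.null(jitterSdLog2)) jitterSdLog2 <- 0.25
      conds <- rep(names(gain), each = nPerCondition)
      adj <- referenceDeg * gain[conds] *
        2^stats::rnorm(length(conds), 0, jitterSdLog2)
      data.frame(experiment = experiment, condition = conds,
                 reference = referenceDeg, adjusted = as.numeric(adj),
                 row.names = NULL)
    } else {
      if (is.null(referenceDeg)) referenceDeg <- 4
      if (is.null(jitterSdLog2)) jitterSdLog2 <- 0.1
      conds <- rep(c("illusory", "control"), each = nPerCondition)
      truthPos <- ifelse(conds == "illusory",
                         referenceDeg + perceptShiftDeg, referenceDeg)
      adj <- truthPos * 2^stats::rnorm(length(conds), 0, jitterSdLog2)
      data.frame(experiment = experiment, condition = conds,
                 reference = referenceDeg, adjusted = as.numeric(adj),
                 row.names = NULL)
    }
  })
}

#' Simulate a gaze trace with slow drift
#'
#' A fixational gaze record at `rateHz` with linear drift plus white
#' position noise, suitable for exercising the detrending and dispersion
#' pipeline.
#'
#' @param durationS record duration (s).
#' @param rateHz sampling rate (Hz).
#' @param driftDegPerS length-2 drift rate (x, y) in deg/s.
#' @param noiseSd white position noise SD (deg).
#' @param seed integer seed.
#' @return data.frame with `time`, `x`, `y`, `valid`.
#' @export
simulateGaze <- function(durationS = 60, rateHz = 60,
                         driftDegPerS = c(0.01, 0), noiseSd = 0.05,
                         seed = 1L) {
  .withSeed(seed, {
    t <- seq(0, durationS, by = 1 / rateHz)
    data.frame(time = t,
               x = driftDegPerS[1] * t + stats::rnorm(length(t), 0, noiseSd),
               y = driftDegPerS[2] * t + stats::rnorm(length(t), 0, noiseSd),
               valid = TRUE)
  })
}
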