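# Shared fixtures, memoised per test run. The fitted ensemble is the
# expensive object (mapping simulation + two-stage pRF fit on 4000 V1
# vertices); it is built once and reused across test files.

.fixtures <- new.env()

fixGrid <- function() FieldGrid()

fixHRF <- function() canonicalHRF(1)

fixMapApertures <- function() {
  if (is.null(.fixtures$map))
    .fixtures$map <- mappingApertures(fixGrid())
  .fixtures$map
}

# noiseless observer with fitted pRFs (V1 only, default density)
fixFittedEnsemble <- function() {
  if (is.null(.fixtures$fitEns)) {
    spec <- ObserverSpec(nVertices = c(V1 = 2000L), noiseSd = 0,
                         seed = 101L)
    ens <- makeObserver(spec)
    bold <- simulateMappingRun(ens, fixMapApertures(), fixHRF())
    .fixtures$fitEns <- fitPRF(ens, bold, fixMapApertures(), fixHRF())
  }
  .fixtures$fitEns
}

# ground-truth vertex table usable directly as a fitted-pRF table
fixTruthVertices <- function() {
  if (is.null(.fixtures$truthVert)) {
    spec <- ObserverSpec(nVertices = c(V1 = 2000L), noiseSd = 0,
                         seed = 31L)
    tr <- truthPRF(makeObserver(spec))
    tr$r2 <- 1
    .fixtures$truthVert <- tr
  }
  .fixtures$truthVert
}

# Muller-Lyer end-to-end: simulate runs at a given apparent shift on a
# fitted ensemble and return the per-condition profile-peak locations
mlPeakLocations <- function(ens, delta, nRuns = 10L,
                            sizeCriterion = "none") {
  g <- fixGrid(); hrf <- fixHRF()
  sim <- simulateExperimentRun(ens, "mueller_lyer", deltaShiftDeg = delta,
                               noiseSd = 0, nRuns = nRuns, grid = g,
                               hrf = hrf)
  design <- buildDesign(sim$events, runVolumes("mueller_lyer"), 1, hrf)
  ft <- fittedPRF(ens)
  ws <- WindowSpec(sizeCriterion = sizeCriterion)
  vapply(list(outward = c(outward_target = 1, outward_background = -1),
              inward = c(inward_target = 1, inward_background = -1)),
         function(cv) {
           glm <- fitAndContrast(sim$bold, design, cv)
           fitProfile(slidingSample(cbind(ft, response = glm$contrast),
                                    ws))$mu
         }, numeric(1))
}

# centroid (degrees) of a mask, the rasterisation oracle used across tests
maskCentroid <- function(mask, grid = fixGrid()) {
  pc <- pixelCoords(grid)
  tot <- sum(mask)
  list(x = sum(colSums(mask) * pc$x) / tot,
       y = sum(rowSums(mask) * pc$y) / tot)
}
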