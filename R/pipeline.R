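# End-to-end orchestration: simulate -> fit pRFs -> GLM -> sliding-window
# reconstruction -> encoding-model matching -> summary statistics.

.defaultConfig <- function() {
  list(experiment = "mueller_lyer", nObservers = 1L, deltaShiftDeg = 0,
       noiseSd = 0, nRuns = NULL, sizeCriterion = "none", seed = 1L,
       observer = list(), match = TRUE, backproject = FALSE,
       contextWeight = 0.5, outDir = NULL)
}

# polynomial rolling hash of the serialised config, for the report
.configHash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        null = "null")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 536870909
  sprintf("%08x", h)
}

# condition labels and GLM contrasts per experiment
.experimentConditions <- function(experiment) {
  if (experiment == "mueller_lyer")
    list(conditions = c("outward", "inward"),
         contrasts = list(
           outward = c(outward_target = 1, outward_background = -1),
           inward = c(inward_target = 1, inward_background = -1)))
  else
    list(conditions = c("illusory", "control"),
         contrasts = list(illusory = c(illusory_stimulus = 1),
                          control = c(control_stimulus = 1)))
}

#' Run the full reconstruction pipeline on synthetic observers
#'
#' Executes, per observer: ensemble generation, a noiseless-or-noisy
#' mapping run, two-stage pRF fitting, main-experiment simulation with the
#' configured apparent shift, block-GLM contrasts per condition,
#' sliding-window profiles with 1-D Gaussian summaries, and (optionally)
#' encoding-model matching against the simulated-stimulus bank and a
#' searchlight backprojection. Across observers it reports the per-observer
#' peak locations and, with two or more observers, a paired t-test on the
#' condition difference. Fully deterministic under `config$seed`.
#'
#' @param config list merged over the defaults: `experiment`
#'   (`"mueller_lyer"` or `"curveball"`), `nObservers`, `deltaShiftDeg`,
#'   `noiseSd`, `nRuns`, `sizeCriterion`, `seed`, `observer` (argument
#'   overrides for [ObserverSpec()]), `match`, `backproject`,
#'   `contextWeight`, `outDir` (when set, the report is written there as
#'   JSON).
#' @return The report: `config`, `configHash`, `perObserver` (data.frame),
#'   `profiles`, `summary`.
#' @export
runPipeline <- function(config = list()) {
  config <- utils::modifyList(.defaultConfig(), config)
  experiment <- match.arg(config$experiment, c("mueller_lyer", "curveball"))
  grid <- FieldGrid()
  trS <- 1
  hrf <- canonicalHRF(trS)
  apertures <- mappingApertures(grid)
  cset <- .experimentConditions(experiment)
  specs <- if (experiment == "mueller_lyer")
    list(meridian = WindowSpec(sizeCriterion = config$sizeCriterion))
  else
    list(central = curveballWindowSpec("central", config$sizeCriterion),
         peripheral = curveballWindowSpec("peripheral",
                                          config$sizeCriterion))
  bank <- if (isTRUE(config$match)) simulatedMaskBank(experiment, grid)

  perObs <- list(); profilesOut <- list(); maps <- list()
  for (o in seq_len(config$nObservers)) {
    obsSeed <- config$seed + 1000L * (o - 1L)
    spec <- do.call(ObserverSpec, utils::modifyList(
      list(noiseSd = config$noiseSd, deltaShiftDeg = config$deltaShiftDeg,
           seed = obsSeed), config$observer))
    ens <- makeObserver(spec)
    bold <- simulateMappingRun(ens, apertures, hrf, trS)
    ens <- fitPRF(ens, bold, apertures, hrf)
    sim <- simulateExperimentRun(ens, experiment, nRuns = config$nRuns,
                                 grid = grid, hrf = hrf, trS = trS,
                                 contextWeight = config$contextWeight)
    design <- buildDesign(sim$events, runVolumes(experiment), trS, hrf)
    fitted <- fittedPRF(ens)
    bankProfiles <- if (isTRUE(config$match))
      predictProfileBank(bank$masks, fitted, specs, grid)
    row <- list(observer = o, delta = config$deltaShiftDeg)
    for (cond in cset$conditions) {
      glm <- fitAndContrast(sim$bold, design, cset$contrasts[[cond]])
      vert <- cbind(fitted, response = glm$contrast)
      for (loc in names(specs)) {
        prof <- slidingSample(vert, specs[[loc]])
        gf <- fitProfile(prof)
        key <- paste(cond, loc, sep = ".")
        profilesOut[[paste(o, key)]] <- prof
        row[[paste0("mu.", key)]] <- gf$mu
        row[[paste0("r2.", key)]] <- gf$r2
        row[[paste0("anyEmpty.", key)]] <- any(prof$missing)
      }
      if (isTRUE(config$match)) {
        obsProf <- do.call(rbind, lapply(specs, function(sp)
          slidingSample(vert, sp)))
        mr <- bestMatch(obsProf, bankProfiles, bank$axis)
        row[[paste0("bestParam.", cond)]] <- mr$bestParameter
        row[[paste0("bestR.", cond)]] <- mr$bestR
      }
      if (isTRUE(config$backproject))
        maps[[paste(o, cond)]] <-
          searchlightMap(cbind(fitted, response = glm$contrast))
    }
    perObs[[o]] <- as.data.frame(row)
  }
  perObserver <- do.call(rbind, perObs)

  loc1 <- names(specs)[1]
  muA <- perObserver[[paste0("mu.", cset$conditions[1], ".", loc1)]]
  muB <- perObserver[[paste0("mu.", cset$conditions[2], ".", loc1)]]
  summary <- list(experiment = experiment,
                  muDiffMean = mean(muA - muB),
                  muDiffPerObserver = muA - muB)
  if (config$nObservers >= 2L)
    summary$pairedT <- pairedT(muA, muB)

  report <- list(config = config, configHash = .configHash(config),
                 perObserver = perObserver, profiles = profilesOut,
                 summary = summary)
  if (isTRUE(config$backproject)) report$maps <- maps
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- report
    out$maps <- NULL
    jsonlite::write_json(out, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' Validate a pipeline report against the shipped schema
#'
#' Light structural validation of a [runPipeline()] report against the JSON
#' schema in `inst/extdata/report-schema.json`: required top-level fields
#' and types.
#'
#' @param report a report list (or path to a report JSON file).
#' @return TRUE invisibly; stops with a message on violation.
#' @export
checkReportSchema <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata",
                                            "report-schema.json",
                                            package = "prfRecon"))
  for (field in names(schema$properties))
    if (field %in% schema$required && is.null(report[[field]]))
      stop("report is missing required field '", field, "'")
  if (!is.null(report$summary) &&
      is.null(report$summary$muDiffMean))
    stop("report summary must contain muDiffMean")
  invisible(TRUE)
}
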