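# Block-design GLM: HRF-convolved boxcar regressors per condition x period,
# nuisance columns, ordinary least squares per vertex, and contrasts.

#' Build a block-design matrix
#'
#' One boxcar per `condition x period` cell of the event table (fractional
#' TR coverage at block edges), convolved with the HRF per run. A constant
#' column is always included; with several runs, per-run intercept and
#' linear-trend columns are appended (matching the per-run detrending of
#' the series), followed by any supplied nuisance regressors (e.g. six
#' motion parameters and a global covariate). Overlapping blocks of the
#' same condition are merged with a warning.
#'
#' @param events data.frame with `run`, `onset_s`, `duration_s`,
#'   `condition` and optionally `period` (onsets are within-run).
#' @param nVolumes volumes per run (scalar, or vector per run).
#' @param trS repetition time (s).
#' @param hrf HRF kernel at `trS`.
#' @param nuisance optional numeric matrix (total volumes x k).
#' @param runTrends include per-run linear trend columns?
#' @return List with `X` (design matrix), `conditionCols` (named logical
#'   flag per column: condition vs nuisance) and `runLengths`.
#' @export
buildDesign <- function(events, nVolumes, trS = 1, hrf = canonicalHRF(trS),
                        nuisance = NULL, runTrends = TRUE) {
  if (!"run" %in% names(events)) events$run <- 1L
  if (!"period" %in% names(events)) events$period <- ""
  runs <- sort(unique(events$run))
  runLengths <- rep(nVolumes, length.out = length(runs))
  cellNames <- sort(unique(ifelse(events$period == "", events$condition,
                                  paste(events$condition, events$period,
                                        sep = "_"))))
  ends <- cumsum(runLengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  X <- matrix(0, sum(runLengths), length(cellNames),
              dimnames = list(NULL, cellNames))
  for (ri in seq_along(runs)) {
    ev <- events[events$run == runs[ri], , drop = FALSE]
    nVol <- runLengths[ri]
    volStart <- (seq_len(nVol) - 1) * trS
    box <- matrix(0, nVol, length(cellNames),
                  dimnames = list(NULL, cellNames))
    for (k in seq_len(nrow(ev))) {
      cell <- if (ev$period[k] == "") ev$condition[k] else
        paste(ev$condition[k], ev$period[k], sep = "_")
      if (ev$onset_s[k] + ev$duration_s[k] > nVol * trS + 1e-9)
        stop("event extends beyond the run duration")
      # fractional TR coverage of [onset, onset + duration)
      cov <- pmax(0, pmin(volStart + trS, ev$onset_s[k] + ev$duration_s[k]) -
                    pmax(volStart, ev$onset_s[k])) / trS
      if (any(box[, cell] > 0 & cov > 0)) {
        warning("overlapping blocks of the same condition merged")
        cov <- pmax(cov, box[, cell]) - box[, cell]
      }
      box[, cell] <- box[, cell] + cov
    }
    conv <- convolveHRF(t(box), hrf)   # rows = cells
    X[starts[ri]:ends[ri], ] <- t(conv)
  }
  extra <- matrix(1, sum(runLengths), 1, dimnames = list(NULL, "const"))
  if (length(runs) > 1L) {
    for (ri in seq_along(runs)[-1L]) {
      col <- numeric(sum(runLengths)); col[starts[ri]:ends[ri]] <- 1
      extra <- cbind(extra, col)
      colnames(extra)[ncol(extra)] <- paste0("run", runs[ri])
    }
  }
  if (runTrends) {
    for (ri in seq_along(runs)) {
      tt <- numeric(sum(runLengths))
      n <- runLengths[ri]
      tt[starts[ri]:ends[ri]] <- seq_len(n) - (n + 1) / 2
      extra <- cbind(extra, tt)
      colnames(extra)[ncol(extra)] <- paste0("trend", runs[ri])
    }
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    extra <- cbind(extra, nuisance)
  }
  X <- cbind(X, extra)
  conditionCols <- stats::setNames(colnames(X) %in% cellNames, colnames(X))
  list(X = X, conditionCols = conditionCols, runLengths = runLengths)
}

#' Fit the GLM and evaluate a contrast per vertex
#'
#' Ordinary least squares of every vertex's series on the design, returning
#' the contrast value `c' betahat` and the full-model R-squared per vertex.
#'
#' @param bold a [BoldSeries-class] (or vertices-by-volumes matrix).
#' @param design from [buildDesign()].
#' @param contrast named numeric vector over condition columns (unnamed
#'   design columns get weight 0), or a full-length vector.
#' @return data.frame with `contrast` and `r2` per vertex.
#' @export
fitAndContrast <- function(bold, design, contrast) {
  Y <- if (is(bold, "BoldSeries")) boldData(bold) else as.matrix(bold)
  X <- design$X
  if (ncol(Y) != nrow(X))
    stop("design rows (", nrow(X), ") must match series length (",
         ncol(Y), ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  cvec <- numeric(ncol(X))
  if (!is.null(names(contrast))) {
    unknown <- setdiff(names(contrast), colnames(X))
    if (length(unknown))
      stop("contrast names not in design: ", paste(unknown, collapse = ", "))
    cvec[match(names(contrast), colnames(X))] <- contrast
  } else {
    if (length(contrast) != ncol(X))
      stop("unnamed contrast must have one weight per design column")
    cvec <- contrast
  }
  B <- qr.coef(qrX, t(Y))                    # coefficients x vertices
  fitted <- X %*% B
  res <- t(Y) - fitted
  sse <- colSums(res^2)
  sst <- colSums((t(Y) - matrix(colMeans(t(Y)), nrow(X), nrow(Y),
                                byrow = TRUE))^2)
  r2 <- ifelse(sst > 0, 1 - sse / sst, NA_real_)
  data.frame(contrast = as.numeric(crossprod(B, cvec)), r2 = r2)
}
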