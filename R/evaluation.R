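#' @include AllClasses.R AllGenerics.R inference.R
NULL

## ---------------------------------------------------------------------------
## Time-series cross-validation (rolling origin, expanding window)
## ---------------------------------------------------------------------------

#' Rolling-origin split of a patient record
#'
#' The first training window contains the first 8 weeks (56 days) of the
#' patient's data, extended forward if needed until it contains at least
#' two leukocyte observations.  Each round's prediction window is the next
#' `horizon` days; after a round the training window absorbs the prediction
#' window, and rounds repeat until the data are exhausted.  A final window
#' shorter than the horizon is still evaluated by default.
#'
#' @param record a [PatientRecord-class].
#' @param horizon horizon length in days (14 or 28 in the protocol).
#' @param firstTrainDays length of the first training window (days).
#' @param minTrainObs minimum number of leukocyte observations the first
#'   window must contain (the window is extended to reach it).
#' @param evaluatePartialFinal evaluate a final window shorter than
#'   `horizon`?
#' @return data.frame with one row per round: `round`, `trainEnd`,
#'   `predStart`, `predEnd`, `nTargets` (held-out leukocyte observations in
#'   `(trainEnd, predEnd]`).  Zero rows (with a warning) if the record is
#'   too short.
#' @export
#' @examples
#' rec <- simulatePatient(simulationScenario(seed = 1))$record
#' tscSplit(rec, horizon = 14)
tscSplit <- function(record, horizon, firstTrainDays = 56, minTrainObs = 2,
                     evaluatePartialFinal = TRUE) {
  stopifnot(horizon > 0)
  ot <- obsTimes(record); lk <- leukocyte(record)
  lt <- ot[!is.na(lk)]
  tEnd <- max(ot)
  empty <- data.frame(round = integer(), trainEnd = numeric(),
                      predStart = numeric(), predEnd = numeric(),
                      nTargets = integer())
  if (!length(lt)) { warning("record has no leukocyte observations"); return(empty) }
  tStart <- min(c(ot, doseTimes(record)))
  t0 <- tStart + firstTrainDays
  if (sum(lt <= t0) < minTrainObs) {
    if (length(lt) < minTrainObs) {
      warning("record too short for the first training window")
      return(empty)
    }
    t0 <- lt[minTrainObs]
  }
  if (t0 >= tEnd) { warning("record spans less than the first training window"); return(empty) }
  rounds <- list(); i <- 0L; tr <- t0
  while (tr < tEnd) {
    pe <- tr + horizon
    if (pe > tEnd) {
      if (!evaluatePartialFinal) break
      pe <- tEnd
    }
    i <- i + 1L
    rounds[[i]] <- data.frame(
      round = i, trainEnd = tr, predStart = tr, predEnd = pe,
      nTargets = sum(lt > tr & lt <= pe))
    tr <- tr + horizon
  }
  do.call(rbind, rounds)
}

#' Empirical coverage probability
#'
#' Fraction of observations falling inside their central probability
#' intervals, `CP_alpha = (1/n) sum 1{y_i in I_i}`.  Intervals are treated
#' as closed, so a degenerate zero-width interval at the observation counts
#' as covered.
#'
#' @param observations numeric vector.
#' @param intervals two-column matrix (`lo`, `hi`) of the same length.
#' @return proportion in `[0, 1]`.
#' @export
coverageProbability <- function(observations, intervals) {
  intervals <- as.matrix(intervals)
  if (!length(observations)) stop("coverage of an empty set is undefined")
  if (nrow(intervals) != length(observations) || ncol(intervals) != 2L)
    stop("intervals must be a 2-column matrix matching observations")
  mean(observations >= intervals[, 1] & observations <= intervals[, 2])
}

#' Point-prediction error metrics on the linear scale
#'
#' RMSE and MAE between observed leukocyte counts and point predictions,
#' both on the 1e9 cells/L scale (log-scale predictions are exponentiated
#' by [pointPrediction()]).
#'
#' @param observations observed counts (1e9 cells/L).
#' @param predictions a [PredictionSet-class] or a numeric vector of point
#'   predictions on the linear scale.
#' @return named numeric `c(rmse, mae)`.
#' @export
pointMetrics <- function(observations, predictions) {
  pt <- if (is(predictions, "PredictionSet")) pointPrediction(predictions)
        else as.numeric(predictions)
  if (length(pt) != length(observations))
    stop("observations and predictions differ in length")
  err <- observations - pt
  c(rmse = sqrt(mean(err^2)), mae = mean(abs(err)))
}

## ---------------------------------------------------------------------------
## Cross-validation driver
## ---------------------------------------------------------------------------

.tscMetricsFromPred <- function(pred) {
  ok <- !pred$failed
  n <- sum(ok)
  if (!n) return(c(rmse = NA_real_, mae = NA_real_, cp50 = NA_real_,
                   cp90 = NA_real_, n = 0))
  pm <- pointMetrics(pred$observed[ok], pred$predicted[ok])
  c(pm,
    cp50 = coverageProbability(pred$observed[ok],
                               cbind(pred$lo50[ok], pred$hi50[ok])),
    cp90 = coverageProbability(pred$observed[ok],
                               cbind(pred$lo90[ok], pred$hi90[ok])),
    n = n)
}

#' Run time-series cross-validation of one model on one patient
#'
#' For each round of [tscSplit()], fits the model on the training data with
#' [mapFit()] and forecasts the held-out leukocyte observations of the
#' prediction window with [predictHorizon()] using the actually
#' administered doses.  Rounds where fitting or prediction fails are
#' flagged and excluded from the per-patient metrics (computed on the
#' linear scale).
#'
#' @param record a [PatientRecord-class].
#' @param init a [ModelParameters-class] selecting the model and providing
#'   fixed values and optimiser starting point.
#' @param horizon horizon in days (14 or 28 in the protocol).
#' @param useCrp condition on CRP observations inside the horizon
#'   (TCM-CRP only; default `FALSE`).
#' @param mapControl named list of extra arguments passed to [mapFit()]
#'   (e.g. `list(maxit = 500)`).
#' @param firstTrainDays,minTrainObs,evaluatePartialFinal passed to
#'   [tscSplit()].
#' @return a [TscReport-class].
#' @export
#' @examples
#' rec <- simulatePatient(simulationScenario(seed = 1))$record
#' runTsc(rec, nmParameters(3, 1), horizon = 14)
runTsc <- function(record, init, horizon = 14, useCrp = FALSE,
                   mapControl = list(), firstTrainDays = 56, minTrainObs = 2,
                   evaluatePartialFinal = TRUE) {
  split <- tscSplit(record, horizon, firstTrainDays, minTrainObs,
                    evaluatePartialFinal)
  modelId <- switch(class(init),
                    TcmCrpParameters = "tcmcrp", TcmParameters = "tcm",
                    JmParameters = "jm", NmParameters = "nm",
                    class(init))
  rows <- list()
  nFailed <- 0L
  for (i in seq_len(nrow(split))) {
    tr <- split$trainEnd[i]
    if (split$nTargets[i] == 0L) next
    res <- tryCatch({
      train <- truncateRecord(record, tr)
      fit <- do.call(mapFit, c(list(record = train, init = init), mapControl))
      if (!converged(fit)) stop("fit did not converge")
      args <- list(record = record, params = fittedParameters(fit),
                   tFrom = tr, horizon = split$predEnd[i] - tr)
      if (is(init, "TcmCrpParameters")) args$useCrp <- useCrp
      pred <- do.call(predictHorizon, args)
      if (!length(pred@times)) stop("no predictions produced")
      i50 <- predictionIntervals(pred, 50)
      i90 <- predictionIntervals(pred, 90)
      obs <- leukocyte(record)[match(pred@times, obsTimes(record))]
      data.frame(round = i, trainEnd = tr, time = pred@times,
                 observed = obs, predicted = pointPrediction(pred),
                 lo50 = i50[, 1], hi50 = i50[, 2],
                 lo90 = i90[, 1], hi90 = i90[, 2], failed = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      nFailed <- nFailed + 1L
      ot <- obsTimes(record); lk <- leukocyte(record)
      sel <- which(ot > tr & ot <= split$predEnd[i] & !is.na(lk))
      rows[[length(rows) + 1L]] <- data.frame(
        round = i, trainEnd = tr, time = ot[sel], observed = lk[sel],
        predicted = NA_real_, lo50 = NA_real_, hi50 = NA_real_,
        lo90 = NA_real_, hi90 = NA_real_, failed = TRUE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  pred <- if (length(rows)) do.call(rbind, rows)
          else data.frame(round = integer(), trainEnd = numeric(),
                          time = numeric(), observed = numeric(),
                          predicted = numeric(), lo50 = numeric(),
                          hi50 = numeric(), lo90 = numeric(),
                          hi90 = numeric(), failed = logical())
  new("TscReport", patientId = patientId(record), model = modelId,
      horizon = horizon, predictions = pred,
      nRounds = nrow(split), nFailed = nFailed,
      metrics = .tscMetricsFromPred(pred))
}

#' In-sample metrics of one model on one patient
#'
#' Fits the model to the full record, computes the fitted mean with
#' [inSampleFit()], and returns RMSE/MAE/CP50/CP90 between the fitted mean
#' (plus its intervals) and the observed leukocyte counts on the linear
#' scale.
#'
#' @inheritParams runTsc
#' @return named numeric `c(rmse, mae, cp50, cp90, n)`.
#' @export
inSampleMetrics <- function(record, init, mapControl = list()) {
  fit <- do.call(mapFit, c(list(record = record, init = init), mapControl))
  if (!converged(fit)) stop("fit did not converge")
  fm <- inSampleFit(record, fittedParameters(fit))
  obs <- leukocyte(record)[match(fm@times, obsTimes(record))]
  i50 <- predictionIntervals(fm, 50)
  i90 <- predictionIntervals(fm, 90)
  pm <- pointMetrics(obs, fm)
  c(pm, cp50 = coverageProbability(obs, i50),
    cp90 = coverageProbability(obs, i90), n = length(obs))
}

## TscReport accessors
setMethod("tscPredictions", "TscReport", function(x) x@predictions)
setMethod("tscMetrics", "TscReport", function(x) x@metrics)

#' @rdname TscReport-accessors
#' @name TscReport-accessors
#' @title Accessors for cross-validation reports
#' @param x a [TscReport-class].
#' @aliases tscPredictions tscMetrics
NULL

#' Summarise cross-validation reports across patients
#'
#' Means and standard deviations of the per-patient metrics (CP50, CP90,
#' MAE, RMSE), the tabulation convention of the evaluation protocol.
#' Patients whose metrics are undefined (all rounds failed) are excluded;
#' with a single patient the SDs are `NA` by convention.
#'
#' @param reports list of [TscReport-class] objects (one model/horizon).
#' @return data.frame with columns `metric`, `mean`, `sd`, `nPatients`.
#' @export
summarizeReports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  mt <- do.call(rbind, lapply(reports, tscMetrics))
  mt <- mt[!is.na(mt[, "mae"]), , drop = FALSE]
  metrics <- c("cp50", "cp90", "mae", "rmse")
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(mt[, m]), numeric(1)),
    sd = vapply(metrics, function(m)
      if (nrow(mt) > 1L) stats::sd(mt[, m]) else NA_real_, numeric(1)),
    nPatients = nrow(mt), row.names = NULL)
}

#' Cross-validate a whole cohort under one model
#'
#' Convenience wrapper running [runTsc()] per patient and summarising with
#' [summarizeReports()].
#'
#' @param records list of [PatientRecord-class].
#' @inheritParams runTsc
#' @return list with `reports` (per patient) and `summary` (data.frame).
#' @export
crossValidateCohort <- function(records, init, horizon = 14, useCrp = FALSE,
                                mapControl = list()) {
  reports <- lapply(records, runTsc, init = init, horizon = horizon,
                    useCrp = useCrp, mapControl = mapControl)
  list(reports = reports, summary = summarizeReports(reports))
}
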