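#' @include AllClasses.R AllGenerics.R parameters.R ssm-kernels.R jm-model.R
NULL

## ---------------------------------------------------------------------------
## Internal filtering machinery
##
## The filter series of a record starts at the first observation carrying a
## leukocyte value (the initial law L_1 ~ N(l_1, 0.5) needs l_1); the
## geometry of the sub-steps and the BSA-normalised dose inputs depend only
## on the fixed discretisation, so they are precomputed once per record and
## reused across all likelihood evaluations of an optimisation run.
## ---------------------------------------------------------------------------

.ssmSeries <- function(record) {
  ot <- obsTimes(record); lk <- leukocyte(record); cr <- crp(record)
  i0 <- which(!is.na(lk))[1]
  if (is.na(i0)) stop("record has no leukocyte observations")
  sel <- seq.int(i0, length(ot))
  list(times = ot[sel], l = log(lk[sel]), v = log1p(cr[sel]))
}

.ssmGeometry <- function(record, params, times) {
  K <- length(times)
  if (K < 1L) stop("empty observation series")
  nsub <- integer(max(K - 1L, 0L))
  dts <- vector("list", max(K - 1L, 0L))
  starts <- vector("list", max(K - 1L, 0L))
  for (k in seq_len(K - 1L)) {
    delta <- times[k + 1L] - times[k]
    if (delta <= 1e-12) { nsub[k] <- 0L; next }
    st <- .substeps(times[k], times[k + 1L], params@dt)
    nsub[k] <- length(st$dt)
    dts[[k]] <- st$dt
    starts[[k]] <- st$start
  }
  subdt <- unlist(dts, use.names = FALSE)
  substart <- unlist(starts, use.names = FALSE)
  if (is.null(subdt)) { subdt <- numeric(0); substart <- numeric(0) }
  list(nsub = nsub,
       subdt = subdt,
       subdose = doseInput(record, substart, params@tDur))
}

# 13-element natural-scale parameter vector for the C++ filter; OU slots are
# benign placeholders for plain TCM (crp = FALSE ignores them).
.thetaVec <- function(params) {
  crpModel <- is(params, "TcmCrpParameters")
  c(params@eTgn, params@h, params@kPlMax, params@kL, params@sigmaL,
    params@gamma, params@kMe, params@rho, params@sigmaLeuk,
    if (crpModel) c(params@thetaOu, params@sigmaOu, params@betaCrp,
                    params@sigmaCrp) else c(1, 1, 1, 1))
}

# Run the compiled filter on explicit series; geometry may be precomputed.
.ekfRun <- function(record, params, times, l, v, l1, geom = NULL) {
  if (is.null(geom)) geom <- .ssmGeometry(record, params, times)
  crpModel <- is(params, "TcmCrpParameters")
  ekf_filter_cpp(.thetaVec(params), crpModel,
                 geom$subdt, geom$subdose, geom$nsub,
                 l, if (crpModel) v else rep(NA_real_, length(l)),
                 l1, 0.5)
}

## ---------------------------------------------------------------------------
## EKF marginal likelihood
## ---------------------------------------------------------------------------

#' Extended Kalman filter log-likelihood of a state-space model
#'
#' Prediction-error decomposition: the sum over observation times of the
#' Gaussian log-density of each innovation under the predicted observation
#' distribution, with missing components skipped.  For TCM-CRP the
#' likelihood covers both the log leukocyte counts and the log(CRP + 1)
#' series.  Numerically repaired covariance steps (round-off negative
#' variances floored at zero) are reported via a message.
#'
#' @param record a [PatientRecord-class].
#' @param params a [TcmParameters-class] or [TcmCrpParameters-class].
#' @return scalar log-likelihood (may be `-Inf` for degenerate parameters).
#' @export
#' @examples
#' rec <- simulatePatient(simulationScenario(seed = 1))$record
#' ekfLoglik(rec, tcmCrpParameters())
ekfLoglik <- function(record, params) {
  ser <- .ssmSeries(record)
  res <- .ekfRun(record, params, ser$times, ser$l, ser$v, ser$l[1])
  if (res$repairs > 0)
    message("ekfLoglik: ", res$repairs,
            " covariance diagonal value(s) floored at zero (round-off repair)")
  res$loglik
}

#' @describeIn modelLoglik EKF likelihood of the state-space models.
setMethod("modelLoglik", signature("PatientRecord", "TcmParameters"),
  function(record, params, ...) ekfLoglik(record, params))

#' @describeIn modelLoglik i.i.d. Gaussian likelihood of the naive baseline
#'   on the linear scale.
setMethod("modelLoglik", signature("PatientRecord", "NmParameters"),
  function(record, params, ...) {
    y <- leukocyte(record); y <- y[!is.na(y)]
    if (!length(y)) stop("record has no leukocyte observations")
    if (params@sigmaNm <= 0) return(if (all(y == params@muNm)) Inf else -Inf)
    sum(stats::dnorm(y, params@muNm, params@sigmaNm, log = TRUE))
  })

## ---------------------------------------------------------------------------
## MAP estimation
## ---------------------------------------------------------------------------

.nmOptControl <- function(maxit, reltol) list(maxit = maxit, reltol = reltol)

# Shared Nelder-Mead driver over log free parameters.  `negObj` maps a log
# parameter vector to the negative log posterior (non-finite values are
# replaced by a large penalty so the simplex can recover).
.mapOptimise <- function(init, negObj, nStarts, jitterSd, seed, maxit,
                         reltol) {
  theta0 <- freeParamsLog(init)
  safe <- function(lt) {
    val <- negObj(lt)
    if (!is.finite(val)) 1e10 else val
  }
  starts <- list(theta0)
  if (nStarts > 1L) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    for (i in seq_len(nStarts - 1L))
      starts[[i + 1L]] <- theta0 + stats::rnorm(length(theta0), 0, jitterSd)
  }
  runOne <- function(s) {
    # Nelder-Mead with up to two simplex restarts from the incumbent: a
    # collapsed simplex on a flat ridge otherwise reports non-convergence.
    fit <- stats::optim(s, safe, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    tries <- 0L
    while (fit$convergence != 0 && tries < 2L) {
      tries <- tries + 1L
      nxt <- stats::optim(fit$par, safe, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = reltol))
      nxt$counts <- fit$counts + nxt$counts
      fit <- nxt
    }
    fit
  }
  fits <- lapply(starts, runOne)
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  trace <- cbind(do.call(rbind, lapply(fits, `[[`, "par")),
                 logPosterior = -vals)
  list(par = best$par, value = best$value,
       converged = best$convergence == 0 && best$value < 1e10,
       counts = sum(vapply(fits, function(f) f$counts[["function"]],
                           numeric(1))),
       trace = trace)
}

#' @describeIn mapFit MAP fit of TCM or TCM-CRP by Nelder-Mead over the log
#'   free parameters (`eTgn`, `h`, `kPlMax`, `kL`, `sigmaL`), using the EKF
#'   marginal likelihood.  Deterministic given `init` and the tolerances;
#'   `nStarts > 1` adds seeded jittered restarts and keeps the best.
#' @param priorMean,priorVar Gaussian prior moments on each log free
#'   parameter (default `N(0, 10)`).
#' @param nStarts number of Nelder-Mead starts (1 = the supplied init).
#' @param jitterSd SD of the log-scale jitter of additional starts.
#' @param seed RNG seed for the jittered starts.
#' @param maxit,reltol Nelder-Mead iteration cap and relative function
#'   tolerance.
setMethod("mapFit", signature("PatientRecord", "TcmParameters"),
  function(record, init, priorMean = 0, priorVar = 10, nStarts = 1,
           jitterSd = 0.5, seed = NULL, maxit = 2000, reltol = 1e-8) {
    ser <- .ssmSeries(record)
    geom <- .ssmGeometry(record, init, ser$times)
    crpModel <- is(init, "TcmCrpParameters")
    vv <- if (crpModel) ser$v else rep(NA_real_, length(ser$l))
    nmFree <- freeParamNames(init)
    fixedTheta <- .thetaVec(init)
    freeIdx <- match(nmFree, c("eTgn", "h", "kPlMax", "kL", "sigmaL"))
    negObj <- function(lt) {
      th <- fixedTheta
      th[freeIdx] <- exp(lt)
      res <- ekf_filter_cpp(th, crpModel, geom$subdt, geom$subdose,
                            geom$nsub, ser$l, vv, ser$l[1], 0.5)
      -(res$loglik + logPrior(lt, priorMean, priorVar))
    }
    opt <- .mapOptimise(init, negObj, nStarts, jitterSd, seed, maxit, reltol)
    new("MapFit", parameters = setFreeParams(init, opt$par),
        logPosterior = -opt$value, converged = opt$converged,
        nEvaluations = opt$counts,
        model = if (crpModel) "tcmcrp" else "tcm", trace = opt$trace)
  })

#' @describeIn mapFit MAP fit of the comparator ODE model over its log free
#'   parameters (`kCm`, `kTr`, `kPlMax`, `kL`, `gamma`, `eMax`,
#'   `sigmaLeuk`).  Solver failures enter the objective as `-Inf`
#'   likelihood; a fit whose optimum is non-finite is returned with
#'   `converged = FALSE`.
setMethod("mapFit", signature("PatientRecord", "JmParameters"),
  function(record, init, priorMean = 0, priorVar = 10, nStarts = 1,
           jitterSd = 0.5, seed = NULL, maxit = 2000, reltol = 1e-8) {
    negObj <- function(lt) {
      p <- tryCatch(setFreeParams(init, lt), error = function(e) NULL)
      if (is.null(p)) return(Inf)
      -(jmLoglik(record, p) + logPrior(lt, priorMean, priorVar))
    }
    opt <- .mapOptimise(init, negObj, nStarts, jitterSd, seed, maxit, reltol)
    new("MapFit", parameters = setFreeParams(init, opt$par),
        logPosterior = -opt$value, converged = opt$converged,
        nEvaluations = opt$counts, model = "jm", trace = opt$trace)
  })

#' Closed-form fit of the naive mean baseline
#'
#' The baseline's estimate is the sample mean and (n-1) sample variance of
#' the observed leukocyte counts on the linear scale; no optimisation is
#' involved.
#'
#' @param record a [PatientRecord-class].
#' @return a [MapFit-class] holding [NmParameters-class].
#' @export
nmFit <- function(record) {
  y <- leukocyte(record); y <- y[!is.na(y)]
  if (!length(y)) stop("record has no leukocyte observations")
  mu <- mean(y)
  sdv <- if (length(y) >= 2L) stats::sd(y) else 0
  p <- nmParameters(mu, sdv)
  ll <- if (sdv > 0) sum(stats::dnorm(y, mu, sdv, log = TRUE)) else Inf
  new("MapFit", parameters = p, logPosterior = ll,
      converged = TRUE, nEvaluations = 0, model = "nm",
      trace = matrix(numeric(0), 0, 0))
}

#' @describeIn mapFit closed-form naive baseline fit (ignores the optimiser
#'   settings and the slot values of `init`).
setMethod("mapFit", signature("PatientRecord", "NmParameters"),
  function(record, init, ...) nmFit(record))

## MapFit accessors
setMethod("fittedParameters", "MapFit", function(x) x@parameters)
setMethod("logPosterior", "MapFit", function(x) x@logPosterior)
setMethod("converged", "MapFit", function(x) x@converged)

#' @rdname MapFit-accessors
#' @name MapFit-accessors
#' @title Accessors for MAP fit results
#' @param x a [MapFit-class].
#' @aliases fittedParameters logPosterior converged
NULL

## ---------------------------------------------------------------------------
## Joint estimation of the infection hyperparameters
## ---------------------------------------------------------------------------

#' Jointly estimate the infection hyperparameters across a cohort
#'
#' Maximises the product over patients of `p(y_i | theta_i, thetaV)
#' p(theta_i, thetaV)` with respect to every patient's free TCM parameters
#' and the shared infection hyperparameters
#' `thetaV = (sigmaOu, thetaOu, betaCrp)`, all on the log scale with
#' `N(0, 10)` priors.  The default optimises the stacked vector in one
#' Nelder-Mead run; `method = "block"` alternates per-patient fits with a
#' 3-dimensional `thetaV` step, which is more robust in high dimension.
#' The returned `thetaV` is meant to be fixed in subsequent per-patient
#' TCM-CRP fits.
#'
#' @param records list of [PatientRecord-class] (>= 2 with CRP data).
#' @param init a [TcmCrpParameters-class]: starting values for the
#'   per-patient free parameters and for `thetaV`.
#' @param method `"stacked"` (single Nelder-Mead, as defined) or `"block"`
#'   (coordinate alternation).
#' @param maxit,reltol optimiser controls for the stacked run.
#' @param nCycles block-coordinate cycles when `method = "block"`.
#' @return list with `thetaV` (named numeric: `thetaOu`, `sigmaOu`,
#'   `betaCrp`), `logPosterior`, `converged`, and `patientParameters` (list
#'   of fitted [TcmCrpParameters-class] per patient).
#' @export
jointFitThetaV <- function(records, init = tcmCrpParameters(),
                           method = c("stacked", "block"),
                           maxit = 20000, reltol = 1e-8, nCycles = 3) {
  method <- match.arg(method)
  stopifnot(is(init, "TcmCrpParameters"))
  hasCrp <- vapply(records, function(r) any(!is.na(crp(r))), logical(1))
  if (sum(hasCrp) < 2L && length(records) > 1L)
    stop("need at least 2 patient records with CRP data")
  n <- length(records)
  sers <- lapply(records, .ssmSeries)
  geoms <- lapply(seq_len(n), function(i)
    .ssmGeometry(records[[i]], init, sers[[i]]$times))
  nmFree <- c("eTgn", "h", "kPlMax", "kL", "sigmaL")
  baseTheta <- .thetaVec(init)
  patientLL <- function(i, freeNat, thetaVNat) {
    th <- baseTheta
    th[1:5] <- freeNat
    th[10:12] <- thetaVNat[c("thetaOu", "sigmaOu", "betaCrp")]
    ekf_filter_cpp(th, TRUE, geoms[[i]]$subdt, geoms[[i]]$subdose,
                   geoms[[i]]$nsub, sers[[i]]$l, sers[[i]]$v,
                   sers[[i]]$l[1], 0.5)$loglik
  }
  objective <- function(stacked) {
    lv <- stacked[(5 * n + 1):(5 * n + 3)]
    thetaV <- stats::setNames(exp(lv), c("thetaOu", "sigmaOu", "betaCrp"))
    tot <- logPrior(lv)
    for (i in seq_len(n)) {
      lf <- stacked[(5 * (i - 1) + 1):(5 * i)]
      tot <- tot + patientLL(i, exp(lf), thetaV) + logPrior(lf)
    }
    tot
  }
  lf0 <- freeParamsLog(init)[nmFree]
  lv0 <- log(c(thetaOu = init@thetaOu, sigmaOu = init@sigmaOu,
               betaCrp = init@betaCrp))
  stacked0 <- c(rep(lf0, n), lv0)

  if (method == "stacked") {
    safe <- function(s) { v <- -objective(s); if (!is.finite(v)) 1e10 else v }
    opt <- stats::optim(stacked0, safe, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    best <- opt$par
    conv <- opt$convergence == 0 && opt$value < 1e10
    lp <- -opt$value
  } else {
    best <- stacked0
    for (cycle in seq_len(nCycles)) {
      thetaV <- stats::setNames(exp(best[(5 * n + 1):(5 * n + 3)]),
                                c("thetaOu", "sigmaOu", "betaCrp"))
      for (i in seq_len(n)) {
        idx <- (5 * (i - 1) + 1):(5 * i)
        negI <- function(lf) {
          v <- -(patientLL(i, exp(lf), thetaV) + logPrior(lf))
          if (!is.finite(v)) 1e10 else v
        }
        best[idx] <- stats::optim(best[idx], negI, method = "Nelder-Mead",
                                  control = list(maxit = 1000,
                                                 reltol = reltol))$par
      }
      negV <- function(lv) {
        tv <- stats::setNames(exp(lv), c("thetaOu", "sigmaOu", "betaCrp"))
        tot <- logPrior(lv)
        for (i in seq_len(n))
          tot <- tot + patientLL(i, exp(best[(5 * (i - 1) + 1):(5 * i)]), tv)
        if (!is.finite(tot)) 1e10 else -tot
      }
      best[(5 * n + 1):(5 * n + 3)] <-
        stats::optim(best[(5 * n + 1):(5 * n + 3)], negV,
                     method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = reltol))$par
    }
    lp <- objective(best)
    conv <- is.finite(lp)
  }
  if (!is.finite(lp))
    stop("joint thetaV optimisation failed; best objective ", lp)
  thetaV <- stats::setNames(exp(best[(5 * n + 1):(5 * n + 3)]),
                            c("thetaOu", "sigmaOu", "betaCrp"))
  patientParameters <- lapply(seq_len(n), function(i) {
    p <- init
    lf <- best[(5 * (i - 1) + 1):(5 * i)]
    for (j in seq_along(nmFree)) slot(p, nmFree[j]) <- exp(lf[[j]])
    p@thetaOu <- thetaV[["thetaOu"]]
    p@sigmaOu <- thetaV[["sigmaOu"]]
    p@betaCrp <- thetaV[["betaCrp"]]
    validObject(p)
    p
  })
  list(thetaV = thetaV, logPosterior = lp, converged = conv,
       patientParameters = patientParameters)
}

## ---------------------------------------------------------------------------
## Prediction
## ---------------------------------------------------------------------------

.emptyPrediction <- function(scale)
  new("PredictionSet", times = numeric(0), mean = numeric(0),
      var = numeric(0), scale = scale)

# Replace the doses strictly after tFrom with a supplied schedule.
.withFutureDoses <- function(record, tFrom, futureDoses) {
  if (is.null(futureDoses)) return(record)
  stopifnot(is.data.frame(futureDoses),
            all(c("time", "dose") %in% names(futureDoses)))
  keep <- doseTimes(record) <= tFrom
  PatientRecord(patientId(record),
    doseTimes = c(doseTimes(record)[keep], futureDoses$time),
    doses = c(doses(record)[keep], futureDoses$dose),
    obsTimes = obsTimes(record), leukocyte = leukocyte(record),
    crp = crp(record), bsaTimes = bsaTimes(record), bsa = bsa(record))
}

#' @describeIn predictHorizon EKF forecast for TCM / TCM-CRP: filter up to
#'   `tFrom`, then propagate without observation updates, emitting the
#'   predictive mean/variance of the log leukocyte count (measurement noise
#'   included) at each held-out leukocyte observation time.
#' @param useCrp logical; keep conditioning on CRP observations inside the
#'   horizon (TCM-CRP only; default `FALSE`, a fully unobserved horizon).
#' @param futureDoses optional `data.frame(time, dose)` replacing the doses
#'   after `tFrom` (defaults to the record's administered doses).
setMethod("predictHorizon", signature("PatientRecord", "TcmParameters"),
  function(record, params, tFrom, horizon, useCrp = FALSE,
           futureDoses = NULL) {
    stopifnot(horizon >= 0)
    if (horizon == 0) return(.emptyPrediction("log"))
    record <- .withFutureDoses(record, tFrom, futureDoses)
    ser <- .ssmSeries(record)
    inWin <- ser$times > tFrom & ser$times <= tFrom + horizon
    targets <- which(inWin & !is.na(ser$l))
    if (!length(targets)) return(.emptyPrediction("log"))
    keep <- which(ser$times <= tFrom | inWin)
    times <- ser$times[keep]
    l <- ser$l[keep]; v <- ser$v[keep]
    mask <- times > tFrom
    l[mask] <- NA_real_
    if (!useCrp) v[mask] <- NA_real_
    res <- .ekfRun(record, params, times, l, v, ser$l[1])
    if (!res$ok) stop("EKF prediction failed (non-finite filter state)")
    rows <- match(targets, keep)
    new("PredictionSet", times = ser$times[targets],
        mean = res$predMean[rows, 1],
        var = res$predVar[rows, 1] + params@sigmaLeuk^2,
        scale = "log")
  })

#' @describeIn predictHorizon forecast of the comparator ODE model: refit is
#'   the caller's responsibility; the fitted trajectory is solved forward
#'   over the administered doses and the observation variance
#'   `sigmaLeuk^2` is attached.
setMethod("predictHorizon", signature("PatientRecord", "JmParameters"),
  function(record, params, tFrom, horizon, futureDoses = NULL) {
    stopifnot(horizon >= 0)
    if (horizon == 0) return(.emptyPrediction("log"))
    record <- .withFutureDoses(record, tFrom, futureDoses)
    ot <- obsTimes(record); lk <- leukocyte(record)
    sel <- which(ot > tFrom & ot <= tFrom + horizon & !is.na(lk))
    if (!length(sel)) return(.emptyPrediction("log"))
    keepD <- doseTimes(record) <= tFrom + horizon
    sol <- jmSolve(params, doseTimes(record)[keepD], doses(record)[keepD],
                   ot[sel])
    if (!sol$ok)
      stop("ODE prediction failed: ", sol$message)
    new("PredictionSet", times = ot[sel], mean = sol$L,
        var = rep(params@sigmaLeuk^2, length(sel)), scale = "log")
  })

#' @describeIn predictHorizon the naive baseline predicts
#'   `N(muNm, sigmaNm^2)` on the linear scale at every target time.
setMethod("predictHorizon", signature("PatientRecord", "NmParameters"),
  function(record, params, tFrom, horizon, ...) {
    stopifnot(horizon >= 0)
    if (horizon == 0) return(.emptyPrediction("linear"))
    ot <- obsTimes(record); lk <- leukocyte(record)
    sel <- which(ot > tFrom & ot <= tFrom + horizon & !is.na(lk))
    if (!length(sel)) return(.emptyPrediction("linear"))
    new("PredictionSet", times = ot[sel],
        mean = rep(params@muNm, length(sel)),
        var = rep(params@sigmaNm^2, length(sel)), scale = "linear")
  })

## PredictionSet methods ------------------------------------------------------

#' @rdname PredictionSet-accessors
#' @name PredictionSet-accessors
#' @title Point predictions and central intervals on the linear scale
#' @param x a [PredictionSet-class].
#' @param alpha central interval level in percent (50 or 90 in the
#'   evaluation protocol; any value in (0, 100) is accepted).
#' @details The point prediction is the exponentiated predictive mean of
#'   the log count for log-scale predictions and the mean itself for
#'   linear-scale predictions.  Intervals are central (equal-tailed)
#'   Gaussian intervals on the prediction's native scale, exponentiated to
#'   the linear scale where needed; they are treated as closed.
#' @aliases pointPrediction predictionIntervals
NULL

setMethod("pointPrediction", "PredictionSet", function(x) {
  if (x@scale == "log") exp(x@mean) else x@mean
})

setMethod("predictionIntervals", "PredictionSet", function(x, alpha = 90) {
  stopifnot(alpha > 0, alpha < 100)
  z <- stats::qnorm(1 - (1 - alpha / 100) / 2)
  s <- sqrt(x@var)
  lo <- x@mean - z * s; hi <- x@mean + z * s
  if (x@scale == "log") { lo <- exp(lo); hi <- exp(hi) }
  cbind(lo = lo, hi = hi)
})

## ---------------------------------------------------------------------------
## In-sample fitted means
## ---------------------------------------------------------------------------

#' @describeIn inSampleFit state-space fitted mean: one EKF pass with every
#'   leukocyte count masked (CRP still observed for TCM-CRP), conditional on
#'   the supplied parameters.
setMethod("inSampleFit", signature("PatientRecord", "TcmParameters"),
  function(record, params, ...) {
    ser <- .ssmSeries(record)
    l <- rep(NA_real_, length(ser$l))
    res <- .ekfRun(record, params, ser$times, l, ser$v, ser$l[1])
    if (!res$ok) stop("EKF pass failed (non-finite filter state)")
    sel <- which(!is.na(ser$l))
    new("PredictionSet", times = ser$times[sel],
        mean = res$predMean[sel, 1],
        var = res$predVar[sel, 1] + params@sigmaLeuk^2, scale = "log")
  })

#' @describeIn inSampleFit comparator fitted mean: the exponentiated solved
#'   trajectory conditional on the parameters.
setMethod("inSampleFit", signature("PatientRecord", "JmParameters"),
  function(record, params, ...) {
    lk <- leukocyte(record); sel <- !is.na(lk)
    tObs <- obsTimes(record)[sel]
    sol <- jmSolve(params, doseTimes(record), doses(record), tObs)
    if (!sol$ok) stop("ODE fitted-mean solve failed: ", sol$message)
    new("PredictionSet", times = tObs, mean = sol$L,
        var = rep(params@sigmaLeuk^2, length(tObs)), scale = "log")
  })

#' @describeIn inSampleFit the baseline's fitted mean is the constant
#'   `muNm`.
setMethod("inSampleFit", signature("PatientRecord", "NmParameters"),
  function(record, params, ...) {
    lk <- leukocyte(record); sel <- !is.na(lk)
    tObs <- obsTimes(record)[sel]
    new("PredictionSet", times = tObs,
        mean = rep(params@muNm, length(tObs)),
        var = rep(params@sigmaNm^2, length(tObs)), scale = "linear")
  })
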