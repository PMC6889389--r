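#' @include AllClasses.R AllGenerics.R ssm-kernels.R patient-data.R
NULL

## Generative simulator of maintenance-therapy patients with the statistical
## structure the state-space models assume: the exact forward recursion of
## the discretised model at dt = 0.25 day, daily dosing with stepwise
## intensification (and an optional pause, as seen in real dosing
## histories), weekly/biweekly clinic visits with jitter, and infection
## episodes emerging from the latent Ornstein-Uhlenbeck path.

#' Describe a simulation scenario
#'
#' Bundles the true generating parameters, treatment length, observation
#' cadence, dosing policy and seed of one synthetic patient.  Defaults
#' emulate the clinical setting the models target: treatment lengths of
#' 227-524 days, weekly visits, daily oral dosing intensified incrementally
#' to 50 mg with a ~20-day pause, and a paediatric BSA slowly increasing by
#' growth.
#'
#' @param params true generating parameters ([TcmCrpParameters-class] by
#'   default; a plain [TcmParameters-class] simulates without the CRP
#'   channel).
#' @param lengthDays treatment length in days.
#' @param cadenceDays mean visit spacing (7 = weekly, 14 = biweekly).
#' @param visitJitterDays visits are jittered uniformly by up to this many
#'   days.
#' @param dosing dosing policy list, see [simulateDosing()].
#' @param bsaStart starting BSA (m^2).
#' @param bsaGrowthPerYear BSA gain per year of treatment (m^2).
#' @param pMissLeuk,pMissCrp probability that a visit lacks the leukocyte
#'   or CRP measurement (rows missing both are dropped).
#' @param seed integer seed; the generated record is reproducible given the
#'   seed.
#' @return a list of class `"SimulationScenario"`.
#' @export
simulationScenario <- function(params = tcmCrpParameters(),
                               lengthDays = NULL,
                               cadenceDays = 7, visitJitterDays = 2,
                               dosing = list(), bsaStart = NULL,
                               bsaGrowthPerYear = 0.06,
                               pMissLeuk = 0.05, pMissCrp = 0.1,
                               seed = NULL) {
  structure(list(params = params, lengthDays = lengthDays,
                 cadenceDays = cadenceDays,
                 visitJitterDays = visitJitterDays, dosing = dosing,
                 bsaStart = bsaStart, bsaGrowthPerYear = bsaGrowthPerYear,
                 pMissLeuk = pMissLeuk, pMissCrp = pMissCrp, seed = seed),
            class = "SimulationScenario")
}

#' Simulate a daily dosing schedule
#'
#' Stepwise-intensification policy: the daily dose starts at `startDose`
#' and is raised by `stepSize` every `stepEvery` days up to `maxDose`;
#' optionally a pause of `pauseLength` zero-dose days begins at
#' `pauseStart` (emulating a treatment break), after which the dose is
#' re-intensified from `restartDose` back to `maxDose`.
#'
#' @param lengthDays schedule length in days (doses on days
#'   `0 .. lengthDays - 1`).
#' @param policy named list overriding any of `startDose` (25), `maxDose`
#'   (50), `stepSize` (12.5), `stepEvery` (56), `pause` (TRUE),
#'   `pauseStart` (200), `pauseLength` (20), `restartDose` (25),
#'   `restartStepEvery` (28), all doses in mg, times in days.
#' @return data.frame with columns `time`, `dose`.
#' @export
#' @examples
#' sched <- simulateDosing(300)
#' table(sched$dose)
simulateDosing <- function(lengthDays, policy = list()) {
  p <- utils::modifyList(list(startDose = 25, maxDose = 50, stepSize = 12.5,
                              stepEvery = 56, pause = TRUE, pauseStart = 200,
                              pauseLength = 20, restartDose = 25,
                              restartStepEvery = 28), policy)
  days <- seq(0, lengthDays - 1)
  level <- pmin(p$startDose + p$stepSize * (days %/% p$stepEvery), p$maxDose)
  if (isTRUE(p$pause) && lengthDays > p$pauseStart) {
    inPause <- days >= p$pauseStart & days < p$pauseStart + p$pauseLength
    level[inPause] <- 0
    after <- days >= p$pauseStart + p$pauseLength
    if (any(after)) {
      d2 <- days[after] - (p$pauseStart + p$pauseLength)
      level[after] <- pmin(p$restartDose +
                             p$stepSize * (d2 %/% p$restartStepEvery),
                           p$maxDose)
    }
  }
  data.frame(time = days, dose = level)
}

#' Simulate one synthetic patient
#'
#' Runs the exact forward recursion of the discretised state-space model at
#' the model's step (`dt = 0.25` day by default) with Gaussian state
#' noises: the piecewise-analytic drug-effect update, the Euler-Maruyama
#' leukopoiesis step (volatility modulated by the Ornstein-Uhlenbeck
#' infection path for the CRP model), and measurement noise at the
#' subsampled visit times.  The latent paths are returned for oracle
#' testing.  CRP observations are `expm1(V + noise)` truncated at zero.
#'
#' @param scenario a [simulationScenario()].
#' @return list with `record` (a [PatientRecord-class]), `latent`
#'   (data.frame `time`, `M`, `L`, `V`), `params` (the true generating
#'   parameters) and `dosing`.
#' @export
#' @examples
#' sim <- simulatePatient(simulationScenario(seed = 42))
#' sim$record
simulatePatient <- function(scenario) {
  stopifnot(inherits(scenario, "SimulationScenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  p <- scenario$params
  crpModel <- is(p, "TcmCrpParameters")
  lengthDays <- if (is.null(scenario$lengthDays))
    round(stats::runif(1, 227, 524)) else scenario$lengthDays
  bsaStart <- if (is.null(scenario$bsaStart))
    stats::runif(1, 0.85, 1.15) else scenario$bsaStart
  dosing <- simulateDosing(lengthDays, scenario$dosing)

  bsaT <- seq(0, lengthDays, by = 30)
  bsaV <- bsaStart + scenario$bsaGrowthPerYear * bsaT / 365

  # latent recursion on the dt grid
  dt <- p@dt
  grid <- seq(0, lengthDays, by = dt)
  n <- length(grid)
  M <- L <- V <- numeric(n)
  M[1] <- 0
  L[1] <- steadyStateLogLeukocyte(p)
  V[1] <- if (crpModel) stats::rnorm(1, 0, p@sigmaOu / sqrt(2 * p@thetaOu))
          else 0
  doseLevel <- function(t) {
    # last dose in (t - tDur, t] (daily schedule, dose day floor(t))
    i <- findInterval(t, dosing$time)
    ifelse(i >= 1 & dosing$time[pmax(i, 1)] > t - p@tDur,
           dosing$dose[pmax(i, 1)], 0)
  }
  dBsaGrid <- doseLevel(grid) /
    stats::approx(bsaT, bsaV, xout = grid, rule = 2)$y
  zeta <- stats::rnorm(n - 1)
  eta <- if (crpModel) stats::rnorm(n - 1) else numeric(n - 1)
  for (k in 2:n) {
    sigL <- if (crpModel) sigmaLOfV(V[k - 1], p) else p@sigmaL
    L[k] <- L[k - 1] +
      dt * lDrift(L[k - 1], M[k - 1], p) + sigL * sqrt(dt) * zeta[k - 1]
    M[k] <- mUpdate(M[k - 1], dBsaGrid[k - 1], p, dt)
    if (crpModel) {
      ou <- ouUpdate(V[k - 1], p, dt)
      V[k] <- ou$mean + sqrt(ou$var) * eta[k - 1]
    }
  }

  # visit times: cadence with jitter, snapped to the dt grid
  visits <- seq(0, lengthDays, by = scenario$cadenceDays)
  if (length(visits) > 1 && scenario$visitJitterDays > 0) {
    jit <- stats::runif(length(visits), -scenario$visitJitterDays,
                        scenario$visitJitterDays)
    jit[1] <- 0
    visits <- pmin(pmax(visits + jit, 0), lengthDays)
  }
  vi <- sort(unique(as.integer(round(visits / dt)))) + 1L
  visits <- grid[vi]
  lObs <- exp(L[vi] + stats::rnorm(length(vi), 0, p@sigmaLeuk))
  crpObs <- if (crpModel)
    pmax(expm1(V[vi] + stats::rnorm(length(vi), 0, p@sigmaCrp)), 0)
  else rep(NA_real_, length(vi))
  missL <- stats::runif(length(vi)) < scenario$pMissLeuk
  missL[1] <- FALSE  # the filter needs a first leukocyte count
  missC <- if (crpModel) stats::runif(length(vi)) < scenario$pMissCrp
           else rep(TRUE, length(vi))
  lObs[missL] <- NA_real_
  crpObs[missC] <- NA_real_
  keep <- !(is.na(lObs) & is.na(crpObs))

  record <- PatientRecord(
    patientId = paste0("sim", if (is.null(scenario$seed)) "" else scenario$seed),
    doseTimes = dosing$time, doses = dosing$dose,
    obsTimes = visits[keep], leukocyte = lObs[keep], crp = crpObs[keep],
    bsaTimes = bsaT, bsa = bsaV)
  list(record = record,
       latent = data.frame(time = grid, M = M, L = L,
                           V = if (crpModel) V else NA_real_),
       params = p, dosing = dosing)
}

#' Simulate a cohort of heterogeneous patients
#'
#' Independent patients whose free parameters are drawn around the base
#' values with mild log-normal population spreads, with treatment lengths
#' in the configured range.  The cohort is byte-identical given the seed.
#'
#' @param nPatients number of patients (>= 1).
#' @param params base generating parameters.
#' @param seed integer seed.
#' @param sdlog log-normal population SD applied to the free parameters.
#' @param lengthRange treatment length range in days.
#' @param cadenceDays mean visit spacing per patient (recycled).
#' @param scenarioArgs extra arguments passed to [simulationScenario()].
#' @return list with `records` (named list of [PatientRecord-class]),
#'   `truth` (list of per-patient generating parameters) and `latent`
#'   (list of latent paths).
#' @export
#' @examples
#' coh <- makeCohort(3, seed = 7)
#' names(coh$records)
makeCohort <- function(nPatients, params = tcmCrpParameters(), seed = 1,
                       sdlog = 0.1, lengthRange = c(227, 524),
                       cadenceDays = 7, scenarioArgs = list()) {
  stopifnot(nPatients >= 1)
  set.seed(seed)
  cadenceDays <- rep_len(cadenceDays, nPatients)
  free <- freeParamNames(params)
  out <- vector("list", nPatients)
  truth <- vector("list", nPatients)
  latent <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    pi <- params
    repeat {
      for (s in free)
        slot(pi, s) <- slot(params, s) * stats::rlnorm(1, 0, sdlog)
      if (pi@kL < pi@kPlMax) break
    }
    lengthDays <- round(stats::runif(1, lengthRange[1], lengthRange[2]))
    sc <- do.call(simulationScenario,
                  c(list(params = pi, lengthDays = lengthDays,
                         cadenceDays = cadenceDays[i], seed = NULL),
                    scenarioArgs))
    sim <- simulatePatient(sc)
    rec <- sim$record
    rec@patientId <- sprintf("sim%02d", i)
    out[[i]] <- rec
    truth[[i]] <- pi
    latent[[i]] <- sim$latent
  }
  names(out) <- names(truth) <- names(latent) <-
    vapply(out, patientId, character(1))
  list(records = out, truth = truth, latent = latent)
}
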