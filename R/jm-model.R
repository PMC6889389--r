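#' @include AllClasses.R AllGenerics.R parameters.R
NULL

## The comparator model: 3-compartment 6-MP pharmacokinetics (gut, plasma,
## red-blood-cell thioguanine nucleotides) feeding a 5-compartment
## leukopoiesis maturation chain written in log state variables, with
## steady-state initialisation and an i.i.d. Gaussian likelihood on the log
## leukocyte counts.  Oral doses enter as impulses: each dose adds its
## amount to the gut compartment at the dose time (realised as a solver
## event, equivalent to a Dirac input).

.jmStateNames <- c("Xgut", "Xplasma", "Xtgn", "S", "C1", "C2", "C3", "L")

#' Right-hand side of the comparator ODE system
#'
#' The eight time-derivatives of the drug and (log) cell compartments.
#' Dose impulses are not part of the vector field: they are applied as
#' instantaneous additions to the gut compartment at the dose times by
#' [jmSolve()]; the optional `dose` argument adds a continuous infusion
#' rate to the gut compartment for testing purposes.
#'
#' @param t time in days (unused; the system is autonomous between doses).
#' @param state named numeric of length 8
#'   (`Xgut`, `Xplasma`, `Xtgn`, `S`, `C1`, `C2`, `C3`, `L`).
#' @param params a [JmParameters-class].
#' @param dose continuous dose-input rate added to `dXgut/dt` (default 0).
#' @return named numeric of the 8 derivatives.
#' @export
jmRhs <- function(t, state, params, dose = 0) {
  state <- state[.jmStateNames]
  p <- params
  mm <- p@kCm * state[["Xplasma"]] / (p@k + state[["Xplasma"]])
  prg <- p@rho^p@gamma
  drugEff <- p@eMax * state[["Xtgn"]] / (p@eC50 + state[["Xtgn"]])
  d <- c(
    Xgut = -p@kAb * state[["Xgut"]] + dose,
    Xplasma = p@kAb * state[["Xgut"]] - p@kEl * state[["Xplasma"]] - mm,
    Xtgn = p@vCm * mm - p@kMe * state[["Xtgn"]],
    S = p@kPlMax * prg / (prg + exp(state[["L"]])^p@gamma) - drugEff - p@kTr,
    C1 = p@kTr * exp(state[["S"]] - state[["C1"]]) - p@kTr,
    C2 = p@kTr * exp(state[["C1"]] - state[["C2"]]) - p@kTr,
    C3 = p@kTr * exp(state[["C2"]] - state[["C3"]]) - p@kTr,
    L = p@kTr * exp(state[["C3"]] - state[["L"]]) - p@kL)
  d
}

#' Steady-state initial condition of the comparator model
#'
#' Sets the drug compartments to zero and the cell compartments to the
#' drug-free steady state:
#' `L(0) = log(rho) + log(kPlMax/kTr - 1)/gamma`,
#' `C3(0) = log(kL) - log(kTr) + L(0)`, `S(0) = C1(0) = C2(0) = C3(0)`.
#' Feasible whenever `kTr < kPlMax`; at the returned state the drug-free
#' vector field vanishes.
#'
#' @param params a [JmParameters-class].
#' @return named numeric state of length 8.
#' @export
jmSteadyStateInit <- function(params) {
  if (params@kTr >= params@kPlMax)
    stop("infeasible steady state: requires kTr < kPlMax")
  L0 <- log(params@rho) + log(params@kPlMax / params@kTr - 1) / params@gamma
  C3 <- log(params@kL) - log(params@kTr) + L0
  c(Xgut = 0, Xplasma = 0, Xtgn = 0, S = C3, C1 = C3, C2 = C3, C3 = C3,
    L = L0)
}

#' Solve the comparator model over a dose schedule
#'
#' Stiff-capable solve (lsoda) from the steady-state initial condition with
#' dose impulses applied as additive events on the gut compartment.  Solver
#' failure is reported explicitly (`ok = FALSE` plus the condition message),
#' never as silent `NaN`s.
#'
#' @param params a [JmParameters-class].
#' @param doseTimes,doseAmounts dose schedule (days, mg).
#' @param tEval ascending evaluation days for the log leukocyte trajectory.
#' @return list with `ok` (logical), `times`, `L` (log leukocyte count at
#'   `tEval`), `state` (full trajectory matrix at `tEval`) and `message`.
#' @export
jmSolve <- function(params, doseTimes = numeric(), doseAmounts = numeric(),
                    tEval) {
  stopifnot(!is.unsorted(tEval))
  init <- jmSteadyStateInit(params)
  keep <- doseAmounts > 0
  doseTimes <- doseTimes[keep]; doseAmounts <- doseAmounts[keep]
  if (anyDuplicated(doseTimes)) {
    doseAmounts <- as.numeric(tapply(doseAmounts, doseTimes, sum))
    doseTimes <- sort(unique(doseTimes))
  }
  tStart <- min(c(0, doseTimes, tEval)) - 1e-8
  times <- sort(unique(c(tStart, doseTimes, tEval)))
  rhs <- function(t, y, parms) list(unname(jmRhs(t, stats::setNames(y, .jmStateNames), params)))
  events <- if (length(doseTimes))
    list(data = data.frame(var = "Xgut", time = doseTimes,
                           value = doseAmounts, method = "add"))
  else NULL
  out <- tryCatch(
    suppressWarnings(deSolve::ode(
      y = init, times = times, func = rhs, parms = NULL,
      method = "lsoda", rtol = params@rtol, atol = 1e-8,
      events = events, maxsteps = 10000)),
    error = function(e) e)
  fail <- function(msg) list(ok = FALSE, times = tEval,
                             L = rep(NA_real_, length(tEval)),
                             state = NULL, message = msg)
  if (inherits(out, "error")) return(fail(conditionMessage(out)))
  if (nrow(out) < length(times) || any(!is.finite(out[, "L"])))
    return(fail("solver did not reach all evaluation times"))
  sel <- match(tEval, out[, "time"])
  if (any(is.na(sel))) return(fail("evaluation times missing from solution"))
  list(ok = TRUE, times = tEval, L = unname(out[sel, "L"]),
       state = out[sel, .jmStateNames, drop = FALSE], message = "")
}

#' Log-likelihood of the comparator model
#'
#' Sum of i.i.d. Gaussian log-densities of the observed log leukocyte
#' counts about the solved trajectory, `l_k ~ N(Lhat(t_k), sigmaLeuk^2)`.
#' Returns `-Inf` if the solver fails (the failure propagates to the fit
#' as a non-converged result).
#'
#' @param record a [PatientRecord-class] with at least one leukocyte
#'   observation.
#' @param params a [JmParameters-class].
#' @return scalar log-likelihood.
#' @export
jmLoglik <- function(record, params) {
  lk <- leukocyte(record)
  sel <- !is.na(lk)
  if (!any(sel)) stop("record has no leukocyte observations")
  tObs <- obsTimes(record)[sel]
  sol <- jmSolve(params, doseTimes(record), doses(record), tObs)
  if (!sol$ok) return(-Inf)
  sum(stats::dnorm(log(lk[sel]), sol$L, params@sigmaLeuk, log = TRUE))
}

#' @describeIn modelLoglik comparator ODE model likelihood.
setMethod("modelLoglik", signature("PatientRecord", "JmParameters"),
  function(record, params, ...) jmLoglik(record, params))
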