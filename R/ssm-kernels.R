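#' @include AllClasses.R AllGenerics.R
NULL

## Transition and observation kernels of the TCM / TCM-CRP state-space
## models, exactly as discretised: M follows the piecewise-analytic solution
## of its linear ODE, L an Euler-Maruyama step of the leukopoiesis SDE, and
## V the exact conditional Gaussian of the Ornstein-Uhlenbeck process.
## These R kernels are the reference implementation; the filter hot path in
## src/ekf.cpp is cross-checked against them in the tests.

#' Drug-effect (cytotoxicity) update
#'
#' One deterministic step of the drug-effect state:
#' `M' = (M - a) exp(-kMe dt) + a` with `a = eTgn d / (d + h)`, the exact
#' solution of the linear cytotoxicity ODE over a step with constant dose
#' input `d` (mg/m^2, BSA-normalised).
#'
#' @param mPrev previous cytotoxicity (1/day).
#' @param dBsa BSA-normalised dose input (mg/m^2, >= 0).
#' @param params a [TcmParameters-class].
#' @param dt step length in days (> 0).
#' @return updated cytotoxicity (1/day).
#' @export
#' @examples
#' mUpdate(0, 0, tcmParameters(), 0.25)  # no drug, no effect
mUpdate <- function(mPrev, dBsa, params, dt) {
  stopifnot(dt > 0, dBsa >= 0)
  a <- if (dBsa > 0) params@eTgn * dBsa / (dBsa + params@h) else 0
  (mPrev - a) * exp(-params@kMe * dt) + a
}

#' Drift part of the log-leukocyte update
#'
#' The Euler-Maruyama mean step of the leukopoiesis SDE:
#' `L' = L + dt (kPlMax rho^gamma / (rho^gamma + exp(L)^gamma) - M - kL)`.
#' The associated process variance of the step is `sigmaL^2 * dt`.
#'
#' @param lPrev previous log leukocyte count.
#' @param mPrev previous cytotoxicity (1/day).
#' @param params a [TcmParameters-class].
#' @param dt step length in days (> 0).
#' @return updated log leukocyte count (drift only).
#' @export
lUpdateMean <- function(lPrev, mPrev, params, dt) {
  stopifnot(dt > 0)
  lPrev + dt * (lDrift(lPrev, mPrev, params))
}

#' @rdname lUpdateMean
#' @details `lDrift` returns the instantaneous drift
#'   `kPlMax rho^gamma / (rho^gamma + exp(L)^gamma) - M - kL`, and
#'   `lDriftJacobian` its closed-form derivative with respect to `L`,
#'   used as the EKF linearisation.
#' @export
lDrift <- function(lPrev, mPrev, params) {
  prg <- params@rho^params@gamma
  eL <- exp(params@gamma * lPrev)
  params@kPlMax * prg / (prg + eL) - mPrev - params@kL
}

#' @rdname lUpdateMean
#' @export
lDriftJacobian <- function(lPrev, params) {
  prg <- params@rho^params@gamma
  eL <- exp(params@gamma * lPrev)
  -params@kPlMax * prg * params@gamma * eL / (prg + eL)^2
}

#' Exact one-step law of the latent infection level
#'
#' The Ornstein-Uhlenbeck infection state conditional on its previous
#' value is Gaussian with mean `v exp(-thetaOu dt)` and variance
#' `sigmaOu^2 / (2 thetaOu) * (1 - exp(-2 thetaOu dt))`.
#'
#' @param vPrev previous log-infection level.
#' @param params a [TcmCrpParameters-class].
#' @param dt step length in days (> 0).
#' @return list with elements `mean` and `var`.
#' @export
ouUpdate <- function(vPrev, params, dt) {
  stopifnot(dt > 0)
  list(mean = vPrev * exp(-params@thetaOu * dt),
       var = params@sigmaOu^2 / (2 * params@thetaOu) *
             (1 - exp(-2 * params@thetaOu * dt)))
}

#' Infection-modulated leukopoiesis volatility
#'
#' `sigmaL(V) = sigmaL0 * exp(betaCrp * V)`: the stochastic-volatility
#' coupling through which an elevated latent infection level inflates the
#' leukopoiesis noise.
#'
#' @param v log-infection level.
#' @param params a [TcmCrpParameters-class] (`sigmaL` slot is the baseline).
#' @return volatility in 1/sqrt(day).
#' @export
sigmaLOfV <- function(v, params) {
  params@sigmaL * exp(params@betaCrp * v)
}

#' Untreated steady state of the log leukocyte count
#'
#' Solves `kPlMax rho^gamma / (rho^gamma + exp(L)^gamma) = kL` (drug-free,
#' zero drift): `L* = log(rho) + log(kPlMax/kL - 1) / gamma`.  Requires
#' `kL < kPlMax`.
#'
#' @param params a [TcmParameters-class].
#' @return steady-state log leukocyte count.
#' @export
steadyStateLogLeukocyte <- function(params) {
  if (params@kL >= params@kPlMax)
    stop("no finite steady state: requires kL < kPlMax")
  log(params@rho) + log(params@kPlMax / params@kL - 1) / params@gamma
}

## ---------------------------------------------------------------------------
## Beliefs
## ---------------------------------------------------------------------------

#' Construct a state belief
#'
#' @param time day.
#' @param mean named numeric state mean (`M`, `L`, optionally `V`).
#' @param cov covariance matrix of matching dimension.
#' @return a [StateBelief-class].
#' @export
stateBelief <- function(time, mean, cov) {
  if (is.null(names(mean)))
    names(mean) <- c("M", "L", "V")[seq_along(mean)]
  cov <- as.matrix(cov)
  dimnames(cov) <- list(names(mean), names(mean))
  new("StateBelief", time = time, mean = mean, cov = cov)
}

#' Initial state belief of a state-space model
#'
#' The model's initial law: `M ~ N(0, 0)` (point mass), `L ~ N(l1, 0.5)`
#' where `l1` is the first observed log leukocyte count, and for TCM-CRP
#' `V ~ N(0, sigmaOu^2 / (2 thetaOu))`, the stationary law of the OU
#' infection process.
#'
#' @param params a [TcmParameters-class] or [TcmCrpParameters-class].
#' @param firstLogLeuk first observed log leukocyte count.
#' @param time day of the first observation (default 0).
#' @return a [StateBelief-class].
#' @export
#' @examples
#' initialBelief(tcmParameters(), log(3))
initialBelief <- function(params, firstLogLeuk, time = 0) {
  if (length(firstLogLeuk) != 1L || !is.finite(firstLogLeuk))
    stop("a first observed leukocyte count is required")
  if (is(params, "TcmCrpParameters")) {
    stateBelief(time, c(M = 0, L = firstLogLeuk, V = 0),
                diag(c(0, 0.5, params@sigmaOu^2 / (2 * params@thetaOu))))
  } else {
    stateBelief(time, c(M = 0, L = firstLogLeuk),
                diag(c(0, 0.5)))
  }
}

#' EKF prediction: propagate a belief forward in time
#'
#' Propagates mean and covariance over `[belief@time, tNext]` by
#' sub-stepping at the model's discretisation step (`params@dt`, final
#' partial step if the interval is not a multiple), linearising the
#' leukopoiesis drift at the current mean.  Process noise enters L (with
#' the volatility evaluated at the current mean of V for TCM-CRP) and V.
#' The dose input is evaluated at each sub-step's start time.
#'
#' @param belief a [StateBelief-class].
#' @param params a [TcmParameters-class] or [TcmCrpParameters-class].
#' @param doseFun function of time returning the BSA-normalised dose input
#'   (e.g. `function(t) doseInput(record, t)`).
#' @param tNext target time (> `belief@time`).
#' @return the propagated [StateBelief-class].
#' @export
transitionBelief <- function(belief, params, doseFun, tNext) {
  if (tNext <= belief@time) stop("tNext must exceed the belief time")
  crpModel <- is(params, "TcmCrpParameters")
  d <- length(belief@mean)
  stopifnot(d == (if (crpModel) 3L else 2L))
  m <- belief@mean; P <- belief@cov
  steps <- .substeps(belief@time, tNext, params@dt)
  for (i in seq_along(steps$dt)) {
    dt <- steps$dt[i]
    dBsa <- doseFun(steps$start[i])
    phiM <- exp(-params@kMe * dt)
    jLL <- 1 + dt * lDriftJacobian(m[["L"]], params)
    sigL <- if (crpModel) sigmaLOfV(m[["V"]], params) else params@sigmaL
    mNew <- m
    mNew[["M"]] <- mUpdate(m[["M"]], dBsa, params, dt)
    mNew[["L"]] <- lUpdateMean(m[["L"]], m[["M"]], params, dt)
    F <- diag(d)
    F[1, 1] <- phiM
    F[2, 1] <- -dt
    F[2, 2] <- jLL
    Q <- matrix(0, d, d)
    Q[2, 2] <- sigL^2 * dt
    if (crpModel) {
      ou <- ouUpdate(m[["V"]], params, dt)
      mNew[["V"]] <- ou$mean
      F[3, 3] <- exp(-params@thetaOu * dt)
      Q[3, 3] <- ou$var
    }
    P <- F %*% P %*% t(F) + Q
    P <- (P + t(P)) / 2
    m <- mNew
  }
  stateBelief(tNext, m, P)
}

# Sub-step geometry of one observation interval: n = ceiling(delta/dt) steps
# of length dt with a shorter final step; returns step lengths and start
# times.
.substeps <- function(t0, t1, dt) {
  delta <- t1 - t0
  n <- max(1L, as.integer(ceiling(delta / dt - 1e-9)))
  len <- rep(dt, n)
  len[n] <- delta - (n - 1L) * dt
  list(dt = len, start = t0 + c(0, cumsum(len))[seq_len(n)])
}

#' EKF update: condition a belief on an observation
#'
#' Kalman update with the linear observation map selecting L (log leukocyte
#' count, measurement SD `sigmaLeuk`) and, for TCM-CRP, V (log(CRP + 1),
#' measurement SD `sigmaCrp`).  Missing components are skipped; at least
#' one must be present.  The Joseph-form update keeps the posterior
#' covariance positive semi-definite.
#'
#' @param belief a [StateBelief-class].
#' @param l observed log leukocyte count, or `NA`.
#' @param v observed log(CRP + 1), or `NA` (ignored for plain TCM).
#' @param params a [TcmParameters-class] or [TcmCrpParameters-class].
#' @return list with the posterior [StateBelief-class] (`belief`) and the
#'   log predictive density of the used components (`loglik`).
#' @export
observeBelief <- function(belief, l = NA, v = NA, params) {
  crpModel <- is(params, "TcmCrpParameters")
  if (!crpModel) v <- NA
  if (is.na(l) && is.na(v))
    stop("at least one observation component must be present")
  m <- belief@mean; P <- belief@cov
  d <- length(m)
  ll <- 0
  upd <- function(j, y, r) {
    S <- P[j, j] + r^2
    innov <- unname(y - m[j])
    ll <<- ll + stats::dnorm(innov, 0, sqrt(S), log = TRUE)
    K <- P[, j] / S
    m <<- m + K * innov
    IKH <- diag(d); IKH[, j] <- IKH[, j] - K
    P <<- IKH %*% P %*% t(IKH) + r^2 * (K %o% K)
    P <<- (P + t(P)) / 2
  }
  if (!is.na(l)) upd(2L, l, params@sigmaLeuk)
  if (!is.na(v)) upd(3L, v, params@sigmaCrp)
  list(belief = stateBelief(belief@time, m, P), loglik = ll)
}
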