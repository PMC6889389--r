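# Independent oracles and fixture builders used across the suite.  These
# deliberately re-derive the quantities they check (substep geometry, filter
# recursions) rather than calling the package's internals.

# A minimal record: constant BSA, optional dosing, explicit observations.
makeRecord <- function(obsTimes, leuk, crpVals = rep(NA_real_, length(obsTimes)),
                       doseTimes = numeric(), doseVals = numeric(),
                       bsaVal = 1, id = "toy") {
  PatientRecord(id, doseTimes = doseTimes, doses = doseVals,
                obsTimes = obsTimes, leukocyte = leuk, crp = crpVals,
                bsaTimes = 0, bsa = bsaVal)
}

# Substep lengths for one interval: steps of `dt` with a shorter final step.
oracleSubsteps <- function(t0, t1, dt = 0.25) {
  delta <- t1 - t0
  n <- max(1L, ceiling(delta / dt - 1e-9))
  len <- rep(dt, n)
  len[n] <- delta - (n - 1) * dt
  list(len = len, start = t0 + cumsum(c(0, len))[seq_len(n)])
}

# Reference EKF log-likelihood composed from the exported R kernels
# (transitionBelief / observeBelief); used to cross-check the compiled
# filter.
referenceEkfLoglik <- function(record, params) {
  ot <- obsTimes(record); lk <- leukocyte(record); cr <- crp(record)
  i0 <- which(!is.na(lk))[1]
  sel <- seq(i0, length(ot))
  times <- ot[sel]; l <- log(lk[sel])
  v <- if (is(params, "TcmCrpParameters")) log1p(cr[sel])
       else rep(NA_real_, length(sel))
  doseFun <- function(t) doseInput(record, t, params@tDur)
  bel <- initialBelief(params, l[1], time = times[1])
  ll <- 0
  for (k in seq_along(times)) {
    if (k > 1) bel <- transitionBelief(bel, params, doseFun, times[k])
    if (!is.na(l[k]) || !is.na(v[k])) {
      up <- observeBelief(bel, l = l[k], v = v[k], params = params)
      bel <- up$belief
      ll <- ll + up$loglik
    }
  }
  ll
}

# Exact Kalman filter for the TCM filter in its linear-Gaussian special
# case (negligible kPlMax: the L-drift is -M - kL, linear).  Explicit
# matrix recursion, independent of the package kernels.
exactLinearKfLoglik <- function(record, params) {
  stopifnot(params@kPlMax < 1e-10)
  ot <- obsTimes(record); lk <- leukocyte(record)
  i0 <- which(!is.na(lk))[1]
  sel <- seq(i0, length(ot))
  times <- ot[sel]; l <- log(lk[sel])
  m <- c(0, l[1]); P <- diag(c(0, 0.5))
  H <- matrix(c(0, 1), 1, 2); R <- params@sigmaLeuk^2
  ll <- 0
  for (k in seq_along(times)) {
    if (k > 1) {
      st <- oracleSubsteps(times[k - 1], times[k], params@dt)
      for (s in seq_along(st$len)) {
        dt <- st$len[s]
        dBsa <- doseInput(record, st$start[s], params@tDur)
        a <- if (dBsa > 0) params@eTgn * dBsa / (dBsa + params@h) else 0
        phi <- exp(-params@kMe * dt)
        Fm <- matrix(c(phi, -dt, 0, 1), 2, 2)  # column-major
        cvec <- c(a * (1 - phi),
                  dt * (params@kPlMax * params@rho^params@gamma /
                          (params@rho^params@gamma + exp(params@gamma * m[2])) -
                          params@kL))
        m <- as.numeric(Fm %*% m) + cvec
        P <- Fm %*% P %*% t(Fm) + diag(c(0, params@sigmaL^2 * dt))
      }
    }
    if (!is.na(l[k])) {
      S <- as.numeric(H %*% P %*% t(H)) + R
      innov <- l[k] - m[2]
      ll <- ll + dnorm(innov, 0, sqrt(S), log = TRUE)
      K <- as.numeric(P %*% t(H)) / S
      m <- m + K * innov
      P <- (diag(2) - K %*% H) %*% P
    }
  }
  ll
}

# Bootstrap particle filter log-likelihood for plain TCM (leukocyte channel
# only): propagates the exact discretised state recursion and weights by the
# Gaussian observation density.  Multinomial resampling each observation.
particleFilterLoglik <- function(record, params, nParticles = 1e4) {
  ot <- obsTimes(record); lk <- leukocyte(record)
  i0 <- which(!is.na(lk))[1]
  sel <- seq(i0, length(ot))
  times <- ot[sel]; l <- log(lk[sel])
  M <- rep(0, nParticles)
  L <- rnorm(nParticles, l[1], sqrt(0.5))
  ll <- 0
  prg <- params@rho^params@gamma
  for (k in seq_along(times)) {
    if (k > 1) {
      st <- oracleSubsteps(times[k - 1], times[k], params@dt)
      for (s in seq_along(st$len)) {
        dt <- st$len[s]
        dBsa <- doseInput(record, st$start[s], params@tDur)
        a <- if (dBsa > 0) params@eTgn * dBsa / (dBsa + params@h) else 0
        drift <- params@kPlMax * prg / (prg + exp(params@gamma * L)) - M -
          params@kL
        L <- L + dt * drift +
          params@sigmaL * sqrt(dt) * rnorm(nParticles)
        M <- (M - a) * exp(-params@kMe * dt) + a
      }
    }
    if (!is.na(l[k])) {
      w <- dnorm(l[k], L, params@sigmaLeuk)
      mw <- mean(w)
      if (mw <= 0) return(-Inf)
      ll <- ll + log(mw)
      idx <- sample.int(nParticles, nParticles, replace = TRUE, prob = w)
      L <- L[idx]; M <- M[idx]
    }
  }
  ll
}

# Median absolute relative error between fitted and true free parameters.
relErr <- function(fit, truth) {
  nm <- freeParamNames(truth)
  vapply(nm, function(s)
    abs(slot(fittedParameters(fit), s) - slot(truth, s)) / slot(truth, s),
    numeric(1))
}

# Random draw of valid comparator-model parameters (steady state feasible).
randomValidJm <- function() {
  repeat {
    p <- try(jmParameters(
      kCm = runif(1, 0.2, 3), kTr = runif(1, 0.2, 1.5),
      kPlMax = runif(1, 0.5, 3), kL = runif(1, 0.1, 1.5),
      gamma = runif(1, 0.4, 2), eMax = runif(1, 0, 0.5),
      sigmaLeuk = runif(1, 0.05, 0.5)), silent = TRUE)
    if (!inherits(p, "try-error") && p@kTr < p@kPlMax) return(p)
  }
}

# Location of the converted clinical cohort (the real patient dataset in the
# package CSV schema), when a user has placed it under inst/extdata.
clinicalCohortDir <- function() {
  d <- system.file("extdata", "real-cohort", package = "leukopred")
  if (nzchar(d) && length(list.files(d, "\\.csv$"))) d else NA_character_
}
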