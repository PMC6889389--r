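# Transition and observation kernels of the state-space models, checked
# against closed forms, numerical ODE solutions and Monte-Carlo simulation.

test_that("mUpdate matches the analytic solution of the cytotoxicity ODE", {
  p <- tcmParameters(eTgn = 0.2, h = 20, kMe = 0.5)
  expect_equal(mUpdate(0, 0, p, 0.25), 0)  # no drug, no effect
  # large dt: relaxes to the asymptote for any start
  a <- 0.2 * 50 / (50 + 20)
  expect_equal(mUpdate(0.9, 50, p, 500), a, tolerance = 1e-12)
  expect_equal(mUpdate(0.0, 50, p, 500), a, tolerance = 1e-12)
  # numerical solution of dM/dt = kMe (eTgn d/(d+h) - M) over [0, 0.25]
  sol <- deSolve::ode(c(M = 0.1), times = c(0, 0.25),
                      func = function(t, y, parms)
                        list(0.5 * (a - y[1])),
                      parms = NULL, rtol = 1e-12, atol = 1e-14)
  expect_equal(mUpdate(0.1, 50, p, 0.25), unname(sol[2, "M"]),
               tolerance = 1e-10)
})

test_that("mUpdate agrees with the per-step closed form to 1e-12 relative", {
  p <- tcmParameters()
  set.seed(4)
  for (i in 1:20) {
    m0 <- runif(1, 0, 0.5); d <- runif(1, 0, 60); dt <- runif(1, 0.01, 2)
    a <- if (d > 0) p@eTgn * d / (d + p@h) else 0
    closed <- a + (m0 - a) * exp(-p@kMe * dt)
    expect_equal(mUpdate(m0, d, p, dt), closed, tolerance = 1e-12)
  }
})

test_that("lUpdateMean leaves the steady state fixed and matches arithmetic", {
  p <- tcmParameters(kPlMax = 1, kL = 0.5, rho = 5, gamma = 1)
  lStar <- steadyStateLogLeukocyte(p)
  expect_equal(lStar, log(5))  # kPlMax = 2 kL puts the steady state at rho
  expect_equal(lUpdateMean(lStar, 0, p, 0.25), lStar)
  # repeated drift-free application is constant
  l <- lStar
  for (i in 1:40) l <- lUpdateMean(l, 0, p, 0.25)
  expect_equal(l, lStar)
  # hand-evaluated drift step: kPlMax=2, kL=1, rho=3, gamma=1, L=log 3, M=0.05
  p2 <- tcmParameters(kPlMax = 2, kL = 1, rho = 3, gamma = 1)
  expect_equal(lUpdateMean(log(3), 0.05, p2, 0.25),
               log(3) + 0.25 * (2 * 3 / (3 + 3) - 0.05 - 1))
})

test_that("the drift Jacobian matches a finite-difference derivative", {
  p <- tcmParameters(gamma = 1.3, rho = 4.2, kPlMax = 1.7)
  for (l in c(-0.5, 0.8, 1.6, 2.5)) {
    h <- 1e-6
    fd <- (lDrift(l + h, 0.1, p) - lDrift(l - h, 0.1, p)) / (2 * h)
    expect_equal(lDriftJacobian(l, p), fd, tolerance = 1e-6)
  }
})

test_that("ouUpdate is the exact conditional law of the OU process", {
  p <- tcmCrpParameters(thetaOu = 1, sigmaOu = 0.5)
  expect_equal(ouUpdate(0, p, 0.25)$mean, 0)
  expect_equal(ouUpdate(0, p, 5)$mean, 0)
  # long-step variance approaches the stationary variance sigma^2/(2 theta)
  expect_equal(ouUpdate(0.3, p, 1e3)$var, 0.5^2 / 2, tolerance = 1e-12)
  # Euler Monte-Carlo oracle at dt = 0.25
  set.seed(99)
  nPaths <- 2e4; step <- 1e-3; nStep <- 250
  v <- rep(0.7, nPaths)
  for (i in seq_len(nStep))
    v <- v - p@thetaOu * v * step + p@sigmaOu * sqrt(step) * rnorm(nPaths)
  ou <- ouUpdate(0.7, p, 0.25)
  seMean <- sd(v) / sqrt(nPaths)
  expect_lt(abs(mean(v) - ou$mean), 3 * seMean + 2e-3)  # + O(step) Euler bias
  seVar <- var(v) * sqrt(2 / (nPaths - 1))
  expect_lt(abs(var(v) - ou$var), 3 * seVar + 2e-3)
})

test_that("sigmaLOfV couples volatility to the infection level", {
  p <- tcmCrpParameters(sigmaL = 0.1, betaCrp = 0.5)
  expect_equal(sigmaLOfV(0, p), 0.1)
  expect_equal(sigmaLOfV(2, p), 0.1 * exp(1))
  p0 <- tcmCrpParameters(sigmaL = 0.1, betaCrp = 1e-300)
  expect_equal(sigmaLOfV(3, p0), 0.1)  # decoupled limit
})

test_that("initialBelief encodes the model's initial law", {
  p <- tcmParameters()
  b <- initialBelief(p, log(3))
  expect_equal(unname(b@mean), c(0, log(3)))
  expect_equal(b@cov, diag(c(0, 0.5)), ignore_attr = TRUE)
  pc <- tcmCrpParameters(thetaOu = 0.5, sigmaOu = 1)
  bc <- initialBelief(pc, log(3))
  expect_equal(unname(bc@mean), c(0, log(3), 0))
  expect_equal(unname(diag(bc@cov)), c(0, 0.5, 1.0))  # stationary V variance 1/(2*0.5)
  expect_error(initialBelief(p, NA_real_), "first observed")
})

test_that("transitionBelief keeps a noise-free steady state fixed", {
  p <- tcmParameters(sigmaL = 1e-12)
  lStar <- steadyStateLogLeukocyte(p)
  b0 <- stateBelief(0, c(M = 0, L = lStar), diag(c(0, 0)))
  b1 <- transitionBelief(b0, p, function(t) 0, 7)
  expect_equal(unname(b1@mean), c(0, lStar), tolerance = 1e-10)
  expect_equal(max(abs(b1@cov)), 0, tolerance = 1e-12)
})

test_that("transitionBelief equals the exact Kalman prediction when the drift is linear", {
  # negligible kPlMax disables the feedback: drift = -M - kL, exactly linear
  p <- tcmParameters(kPlMax = 1e-12, kL = 0.3, eTgn = 0.4, h = 10)
  rec <- makeRecord(c(0, 10), c(3, 3), doseTimes = 0:9,
                    doseVals = rep(50, 10))
  doseFun <- function(t) doseInput(rec, t, p@tDur)
  b0 <- stateBelief(0, c(M = 0.05, L = log(3)),
                    matrix(c(0.01, 0.002, 0.002, 0.3), 2, 2))
  b1 <- transitionBelief(b0, p, doseFun, 10)
  # independent affine-Gaussian propagation over the same substep rule
  m <- b0@mean; P <- b0@cov
  st <- oracleSubsteps(0, 10, p@dt)
  for (s in seq_along(st$len)) {
    dt <- st$len[s]
    d <- doseFun(st$start[s])
    a <- if (d > 0) p@eTgn * d / (d + p@h) else 0
    phi <- exp(-p@kMe * dt)
    Fm <- matrix(c(phi, -dt, 0, 1), 2, 2)
    m <- as.numeric(Fm %*% m) + c(a * (1 - phi), -dt * p@kL)
    P <- Fm %*% P %*% t(Fm) + diag(c(0, p@sigmaL^2 * dt))
  }
  expect_equal(unname(b1@mean), m, tolerance = 1e-10)
  expect_equal(b1@cov, P, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("one-week EKF propagation tracks Monte-Carlo simulation of the recursion", {
  p <- tcmParameters()
  lStar <- steadyStateLogLeukocyte(p)
  b0 <- stateBelief(0, c(M = 0.02, L = lStar), diag(c(0, 0)))
  b1 <- transitionBelief(b0, p, function(t) 0, 7)
  set.seed(5)
  n <- 1e5
  M <- rep(0.02, n); L <- rep(lStar, n)
  st <- oracleSubsteps(0, 7, p@dt)
  prg <- p@rho^p@gamma
  for (s in seq_along(st$len)) {
    dt <- st$len[s]
    drift <- p@kPlMax * prg / (prg + exp(p@gamma * L)) - M - p@kL
    L <- L + dt * drift + p@sigmaL * sqrt(dt) * rnorm(n)
    M <- M * exp(-p@kMe * dt)
  }
  se <- sd(L) / sqrt(n)
  expect_lt(abs(b1@mean[["L"]] - mean(L)), 3 * se)
  expect_equal(b1@cov["L", "L"], var(L), tolerance = 0.05)
})

test_that("observeBelief reproduces conjugate-Gaussian conditioning", {
  p <- tcmParameters(sigmaLeuk = 0.2)
  b <- stateBelief(0, c(M = 0, L = 1.0), diag(c(0, 0.5)))
  up <- observeBelief(b, l = 1.4, params = p)
  # scalar posterior: precision-weighted mean, product variance
  postVar <- 1 / (1 / 0.5 + 1 / 0.04)
  postMean <- postVar * (1.0 / 0.5 + 1.4 / 0.04)
  expect_equal(up$belief@mean[["L"]], postMean, tolerance = 1e-12)
  expect_equal(up$belief@cov["L", "L"], postVar, tolerance = 1e-12)
  expect_equal(up$loglik, dnorm(1.4, 1.0, sqrt(0.5 + 0.04), log = TRUE))
  # observation at the prior mean with tiny prior variance: no movement
  b2 <- stateBelief(0, c(M = 0, L = 1.0), diag(c(0, 1e-12)))
  up2 <- observeBelief(b2, l = 1.0, params = p)
  expect_equal(up2$belief@mean[["L"]], 1.0, tolerance = 1e-9)
  # an (effectively) uninformative observation is a no-op
  p3 <- tcmParameters(sigmaLeuk = 1e8)
  up3 <- observeBelief(b, l = 5, params = p3)
  expect_equal(up3$belief@mean[["L"]], 1.0, tolerance = 1e-6)
  expect_equal(up3$belief@cov["L", "L"], 0.5, tolerance = 1e-6)
  expect_error(observeBelief(b, params = p), "at least one")
})

test_that("transition and observe preserve covariance symmetry and PSD", {
  set.seed(21)
  p <- tcmCrpParameters()
  rec <- simulatePatient(simulationScenario(seed = 21, lengthDays = 120))$record
  doseFun <- function(t) doseInput(rec, t, p@tDur)
  ser <- log(leukocyte(rec)); ot <- obsTimes(rec)
  i0 <- which(!is.na(ser))[1]
  bel <- initialBelief(p, ser[i0], time = ot[i0])
  for (k in seq(i0 + 1, length(ot))) {
    bel <- transitionBelief(bel, p, doseFun, ot[k])
    l <- ser[k]; v <- log1p(crp(rec)[k])
    if (!is.na(l) || !is.na(v))
      bel <- observeBelief(bel, l = l, v = v, params = p)$belief
    expect_equal(bel@cov, t(bel@cov))
    ev <- eigen(bel@cov, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("with betaCrp ~ 0 and CRP ignored the CRP model nests plain TCM", {
  sim <- simulatePatient(simulationScenario(seed = 8, lengthDays = 150))
  rec <- sim$record
  # strip the CRP channel so both filters see the same data
  lk <- leukocyte(rec)
  keep <- !is.na(lk)
  recL <- PatientRecord(patientId(rec), doseTimes = doseTimes(rec),
                        doses = doses(rec), obsTimes = obsTimes(rec)[keep],
                        leukocyte = lk[keep], bsaTimes = bsaTimes(rec),
                        bsa = bsa(rec))
  pT <- tcmParameters()
  pC <- tcmCrpParameters(betaCrp = 1e-300)
  expect_equal(ekfLoglik(recL, pC), ekfLoglik(recL, pT), tolerance = 1e-12)
  fT <- inSampleFit(recL, pT)
  fC <- inSampleFit(recL, pC)
  expect_equal(fC@mean, fT@mean, tolerance = 1e-12)
  expect_equal(fC@var, fT@var, tolerance = 1e-12)
})
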