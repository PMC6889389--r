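# EKF marginal likelihood, MAP estimation, joint hyperparameter estimation
# and horizon prediction.

test_that("the compiled filter agrees with the R kernel composition", {
  for (seed in c(3, 14)) {
    sim <- simulatePatient(simulationScenario(seed = seed, lengthDays = 120))
    for (p in list(tcmParameters(), tcmCrpParameters())) {
      expect_equal(ekfLoglik(sim$record, p),
                   referenceEkfLoglik(sim$record, p), tolerance = 1e-10)
    }
  }
})

test_that("EKF equals the exact Kalman filter when the drift is linear", {
  p <- tcmParameters(kPlMax = 1e-12, kL = 0.2, sigmaL = 0.15)
  sim <- simulatePatient(simulationScenario(
    params = tcmCrpParameters(), seed = 31, lengthDays = 150))
  rec <- sim$record
  expect_equal(ekfLoglik(rec, p), exactLinearKfLoglik(rec, p),
               tolerance = 1e-8)
})

test_that("a single observation gives the hand-computable scalar density", {
  rec <- makeRecord(0, 3.5)
  p <- tcmParameters()
  # L1 ~ N(l1, 0.5); the observation sits at the prior mean
  expect_equal(ekfLoglik(rec, p),
               dnorm(0, 0, sqrt(0.5 + p@sigmaLeuk^2), log = TRUE))
})

test_that("EKF log-likelihood matches a bootstrap particle filter within 3 SE", {
  set.seed(77)
  p <- tcmParameters()
  for (i in 1:3) {
    sim <- simulatePatient(simulationScenario(
      params = p, seed = 100 + i, lengthDays = 100))
    recL <- sim$record
    pf <- replicate(4, particleFilterLoglik(recL, p, nParticles = 1e4))
    ekf <- ekfLoglik(recL, p)
    expect_lt(abs(ekf - mean(pf)), 3 * max(sd(pf), 0.05))
  }
})

test_that("the naive baseline MAP/ML is the sample mean and SD", {
  rec <- makeRecord(c(0, 7, 14, 28), c(2.5, 3.5, 4.0, 3.0))
  fit <- nmFit(rec)
  p <- fittedParameters(fit)
  expect_equal(p@muNm, mean(c(2.5, 3.5, 4.0, 3.0)))
  expect_equal(p@sigmaNm, sd(c(2.5, 3.5, 4.0, 3.0)))
  expect_true(converged(fit))
  # dispatch through mapFit gives the identical closed form
  fit2 <- mapFit(rec, nmParameters(1, 1))
  expect_equal(fittedParameters(fit2)@muNm, p@muNm)
})

test_that("MAP initialised at the generating values stays near them", {
  truth <- tcmCrpParameters()
  sim <- simulatePatient(simulationScenario(seed = 55, lengthDays = 400))
  fit <- mapFit(sim$record, truth)
  expect_true(converged(fit))
  # the optimum cannot be worse than the starting point
  startLp <- ekfLoglik(sim$record, truth) + logPrior(freeParamsLog(truth))
  expect_gte(logPosterior(fit), startLp - 1e-6)
  err <- relErr(fit, truth)
  # the well-identified parameters come back close; the dose-effect pair
  # (eTgn, h) is only weakly identified from a single series
  expect_lt(median(err), 0.5)
  expect_true(all(err[c("kPlMax", "kL", "sigmaL")] < 0.5))
  expect_true(all(err < 3))
})

test_that("the reported log posterior decomposes as likelihood plus prior", {
  sim <- simulatePatient(simulationScenario(seed = 56, lengthDays = 200))
  fit <- mapFit(sim$record, tcmParameters(), maxit = 600)
  p <- fittedParameters(fit)
  expect_equal(logPosterior(fit),
               ekfLoglik(sim$record, p) + logPrior(freeParamsLog(p)),
               tolerance = 1e-8)
  # halving the prior variance changes the posterior by the prior difference
  fitN <- mapFit(sim$record, p, priorVar = 5, maxit = 5)
  lt <- freeParamsLog(fittedParameters(fitN))
  expect_equal(logPosterior(fitN),
               ekfLoglik(sim$record, fittedParameters(fitN)) +
                 logPrior(lt, var = 5), tolerance = 1e-8)
})

test_that("jittered multi-start fits agree on the log posterior", {
  sim <- simulatePatient(simulationScenario(seed = 58, lengthDays = 250))
  fit <- mapFit(sim$record, tcmParameters(), nStarts = 5, jitterSd = 0.5,
                seed = 9)
  lps <- fit@trace[, "logPosterior"]
  expect_equal(length(lps), 5L)
  expect_lt(max(lps) - sort(lps, decreasing = TRUE)[2], 0.5)
})

test_that("likelihood is a function of the parameter values, not their representation", {
  sim <- simulatePatient(simulationScenario(seed = 59, lengthDays = 120))
  p <- tcmParameters(eTgn = 0.27, h = 12, kPlMax = 1.1, kL = 0.55,
                     sigmaL = 0.12)
  p2 <- setFreeParams(tcmParameters(), freeParamsLog(p))
  expect_equal(ekfLoglik(sim$record, p), ekfLoglik(sim$record, p2),
               tolerance = 1e-12)
})

test_that("joint thetaV estimation recovers shared infection hyperparameters", {
  truth <- tcmCrpParameters()
  coh <- makeCohort(4, params = truth, seed = 23, sdlog = 0.08,
                    lengthRange = c(227, 300))
  jf <- jointFitThetaV(coh$records, init = tcmCrpParameters(),
                       method = "block", nCycles = 2)
  expect_true(jf$converged)
  # the optimum cannot fall below the objective at the generating values
  atTruth <- sum(vapply(seq_along(coh$records), function(i) {
    pi <- coh$truth[[i]]
    ekfLoglik(coh$records[[i]], pi) + logPrior(freeParamsLog(pi))
  }, numeric(1))) + logPrior(log(c(truth@thetaOu, truth@sigmaOu,
                                   truth@betaCrp)))
  expect_gte(jf$logPosterior, atTruth - 1e-6)
  # hyperparameters recovered to the right order of magnitude
  expect_lt(abs(log(jf$thetaV[["sigmaOu"]] / truth@sigmaOu)), log(2.5))
  expect_lt(abs(log(jf$thetaV[["thetaOu"]] / truth@thetaOu)), log(4))
  expect_equal(length(jf$patientParameters), 4L)
})

test_that("a single-patient joint fit degenerates to one concatenated MAP problem", {
  coh <- makeCohort(1, seed = 29, lengthRange = c(227, 260))
  jf <- jointFitThetaV(coh$records, init = tcmCrpParameters(),
                       method = "stacked", maxit = 4000)
  p1 <- jf$patientParameters[[1]]
  manual <- ekfLoglik(coh$records[[1]], p1) +
    logPrior(freeParamsLog(p1)) +
    logPrior(log(c(jf$thetaV[["thetaOu"]], jf$thetaV[["sigmaOu"]],
                   jf$thetaV[["betaCrp"]])))
  expect_equal(jf$logPosterior, manual, tolerance = 1e-8)
})

test_that("predictHorizon emits growing uncertainty and honours edge cases", {
  sim <- simulatePatient(simulationScenario(seed = 61, lengthDays = 250))
  p <- tcmCrpParameters()
  # zero horizon: empty prediction set
  empty <- predictHorizon(sim$record, p, tFrom = 100, horizon = 0)
  expect_length(empty@times, 0)
  pred <- predictHorizon(sim$record, p, tFrom = 100, horizon = 60)
  expect_gt(length(pred@times), 2)
  expect_equal(pred@scale, "log")
  # predictive variance non-decreasing in lead time without updates
  expect_true(all(diff(pred@var) >= -1e-10))
  # the naive baseline predicts its fitted Gaussian everywhere
  nm <- fittedParameters(nmFit(truncateRecord(sim$record, 100)))
  predNm <- predictHorizon(sim$record, nm, tFrom = 100, horizon = 28)
  expect_true(all(predNm@mean == nm@muNm))
  expect_true(all(predNm@var == nm@sigmaNm^2))
  expect_equal(predNm@scale, "linear")
})

test_that("conditioning on CRP inside the horizon is off by default, switchable", {
  sim <- simulatePatient(simulationScenario(seed = 62, lengthDays = 250))
  p <- tcmCrpParameters()
  off <- predictHorizon(sim$record, p, tFrom = 100, horizon = 28)
  on <- predictHorizon(sim$record, p, tFrom = 100, horizon = 28,
                       useCrp = TRUE)
  expect_equal(off@times, on@times)
  # CRP updates shrink (or keep) the volatility-driven variance path
  expect_false(isTRUE(all.equal(off@var, on@var)))
})
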