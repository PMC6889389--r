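# Rolling-origin cross-validation harness, metrics and summaries.

test_that("tscSplit enumerates expanding windows by the documented rule", {
  # weekly observations over 100 days, horizon 14
  rec <- makeRecord(seq(0, 100, by = 7), rep(4, 15),
                    doseTimes = 0:99, doseVals = rep(25, 100))
  sp <- tscSplit(rec, horizon = 14)
  # independent enumeration: first window 56 days, advance by the horizon
  # until the observations are exhausted, evaluating a final partial window
  lt <- seq(0, 100, by = 7)   # observations end on day 98
  ends <- c(); tr <- 56
  while (tr < max(lt)) { ends <- c(ends, tr); tr <- tr + 14 }
  expect_equal(sp$trainEnd, ends)
  expect_equal(sp$predEnd, pmin(ends + 14, max(lt)))
  # held-out counts per round match a direct scan
  expect_equal(sp$nTargets,
               vapply(seq_along(ends), function(i)
                 sum(lt > ends[i] & lt <= min(ends[i] + 14, max(lt))),
                 integer(1)))
  # every observation after the first training window is held out once
  expect_equal(sum(sp$nTargets), sum(lt > 56))
})

test_that("a sparse first window is extended to contain two leukocyte counts", {
  rec <- makeRecord(c(0, 70, 84, 98, 130), c(5, 4, 3, 3, 4))
  sp <- tscSplit(rec, horizon = 14)
  expect_equal(sp$trainEnd[1], 70)  # extended to the 2nd observation
  # horizon at least as long as the rest: a single round
  sp2 <- tscSplit(rec, horizon = 200)
  expect_equal(nrow(sp2), 1L)
  expect_equal(sp2$predEnd, 130)
  # too-short record: empty split with a warning
  shortRec <- makeRecord(c(0, 7), c(5, 4))
  expect_warning(sp3 <- tscSplit(shortRec, horizon = 14), "spans less")
  expect_equal(nrow(sp3), 0L)
})

test_that("coverageProbability counts closed-interval membership", {
  expect_equal(coverageProbability(c(1, 2, 3),
                                   cbind(c(0, 1, 2), c(2, 3, 4))), 1.0)
  expect_equal(coverageProbability(c(1, 2, 3, 10),
                                   cbind(c(0, 1, 2, 0), c(2, 3, 4, 5))), 0.75)
  # degenerate zero-width interval at the observation counts as inside
  expect_equal(coverageProbability(2, cbind(2, 2)), 1.0)
  # boundary values are inside (closed intervals)
  expect_equal(coverageProbability(c(1, 5), cbind(c(1, 0), c(3, 5))), 1.0)
  expect_error(coverageProbability(numeric(0), cbind(numeric(0), numeric(0))),
               "undefined")
})

test_that("coverage is invariant under a consistent monotone transform", {
  set.seed(33)
  y <- rlnorm(50, 1, 0.4)
  lo <- y * runif(50, 0.5, 1.05); hi <- lo * runif(50, 1, 2)
  cpLinear <- coverageProbability(y, cbind(lo, hi))
  cpLog <- coverageProbability(log(y), cbind(log(lo), log(hi)))
  expect_identical(cpLinear, cpLog)
})

test_that("point metrics agree with direct arithmetic and a loop oracle", {
  expect_equal(pointMetrics(c(2, 4), c(3, 3)),
               c(rmse = 1, mae = 1))
  expect_equal(pointMetrics(c(1, 1), c(1, 1)), c(rmse = 0, mae = 0))
  set.seed(12)
  obs <- rlnorm(30, 1, 0.3); prd <- rlnorm(30, 1, 0.3)
  m <- pointMetrics(obs, prd)
  sse <- 0; sae <- 0
  for (i in 1:30) { sse <- sse + (obs[i] - prd[i])^2
                    sae <- sae + abs(obs[i] - prd[i]) }
  expect_equal(m[["rmse"]], sqrt(sse / 30))
  expect_equal(m[["mae"]], sae / 30)
  expect_error(pointMetrics(1:3, 1:2), "length")
})

test_that("in-sample fitted means follow each model's definition", {
  sim <- simulatePatient(simulationScenario(seed = 71, lengthDays = 200))
  rec <- sim$record
  # NM: constant at the sample mean
  nm <- fittedParameters(nmFit(rec))
  fmNm <- inSampleFit(rec, nm)
  expect_true(all(pointPrediction(fmNm) == nm@muNm))
  # TCM with no doses at steady-state parameters: flat fitted mean
  recND <- makeRecord(seq(0, 140, by = 7), rep(5, 21))
  p <- tcmParameters()
  fm <- inSampleFit(recND, p)
  lStar <- steadyStateLogLeukocyte(p)
  expect_equal(fm@mean, rep(fm@mean[1], length(fm@mean)), tolerance = 1e-9)
  expect_equal(fm@mean[1], log(5), tolerance = 1e-12)  # init at l1 = log 5 = L*
  expect_equal(lStar, log(5))
  # TCM-CRP with negligible coupling reproduces TCM's fitted mean
  pC <- tcmCrpParameters(betaCrp = 1e-300)
  fmT <- inSampleFit(rec, tcmParameters())
  fmC <- inSampleFit(rec, pC)
  expect_equal(fmC@mean, fmT@mean, tolerance = 1e-12)
})

test_that("summarizeReports tabulates patientwise means and SDs", {
  mkReport <- function(id, rmse, mae, cp50, cp90) {
    new("TscReport", patientId = id, model = "tcm", horizon = 14,
        predictions = data.frame(), nRounds = 5, nFailed = 0,
        metrics = c(rmse = rmse, mae = mae, cp50 = cp50, cp90 = cp90, n = 10))
  }
  reports <- list(mkReport("a", 1.2, 1.0, 0.5, 0.9),
                  mkReport("b", 1.6, 2.0, 0.4, 0.8),
                  mkReport("c", 1.0, 0.6, 0.6, 1.0))
  sm <- summarizeReports(reports)
  # spreadsheet-style recomputation
  expect_equal(sm$mean[sm$metric == "mae"], mean(c(1.0, 2.0, 0.6)))
  expect_equal(sm$sd[sm$metric == "mae"], sd(c(1.0, 2.0, 0.6)))
  expect_equal(sm$mean[sm$metric == "rmse"], mean(c(1.2, 1.6, 1.0)))
  expect_equal(sm$mean[sm$metric == "cp90"], mean(c(0.9, 0.8, 1.0)))
  expect_equal(unique(sm$nPatients), 3L)
  # two patients with MAE 1 and 2 average to 1.5
  sm2 <- summarizeReports(list(mkReport("a", 1, 1, .5, .9),
                               mkReport("b", 2, 2, .5, .9)))
  expect_equal(sm2$mean[sm2$metric == "mae"], 1.5)
  # single patient: SD is NA by convention
  sm1 <- summarizeReports(reports[1])
  expect_true(all(is.na(sm1$sd)))
  expect_equal(sm1$mean[sm1$metric == "rmse"], 1.2)
})

test_that("NM cross-validation is exactly reproducible and fully covered", {
  sim <- simulatePatient(simulationScenario(seed = 81, lengthDays = 300))
  r1 <- runTsc(sim$record, nmParameters(1, 1), horizon = 14)
  r2 <- runTsc(sim$record, nmParameters(9, 9), horizon = 14)
  expect_identical(tscMetrics(r1), tscMetrics(r2))  # closed form, no optimiser
  expect_equal(r1@nFailed, 0)
  # every held-out observation belongs to exactly one round
  pred <- tscPredictions(r1)
  expect_false(any(duplicated(pred$time)))
  lt <- obsTimes(sim$record)[!is.na(leukocyte(sim$record))]
  sp <- tscSplit(sim$record, 14)
  expect_equal(nrow(pred), sum(lt > sp$trainEnd[1]))
})

test_that("failed rounds are flagged and excluded from the metrics", {
  sim <- simulatePatient(simulationScenario(seed = 82, lengthDays = 250))
  # an absurd iteration cap forces non-convergence in every round
  rep <- runTsc(sim$record, tcmParameters(), horizon = 28,
                mapControl = list(maxit = 1))
  expect_gt(rep@nFailed, 0)
  pred <- tscPredictions(rep)
  expect_true(all(pred$failed))
  expect_true(is.na(tscMetrics(rep)[["mae"]]))
})
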