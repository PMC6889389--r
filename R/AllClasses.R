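#' @import methods
NULL

## ---------------------------------------------------------------------------
## PatientRecord
## ---------------------------------------------------------------------------

#' Longitudinal record of one maintenance-therapy patient
#'
#' A `PatientRecord` holds the irregular multivariate time series of one
#' patient on 6-mercaptopurine (6-MP) maintenance therapy: the daily
#' prescribed doses, leukocyte counts and C-reactive protein (CRP)
#' measurements made at clinic visits, and the body surface area (BSA)
#' series used to normalise doses.  All times are in days from the start of
#' maintenance therapy.
#'
#' @slot patientId character scalar identifier.
#' @slot doseTimes numeric, ascending; days on which 6-MP doses were given.
#' @slot doses numeric, same length; dose in mg (non-negative; 0 = pause).
#' @slot obsTimes numeric, ascending; visit days.
#' @slot leukocyte numeric, same length as `obsTimes`; leukocyte count in
#'   1e9 cells/L, `NA` where not measured.
#' @slot crp numeric, same length as `obsTimes`; CRP in mg/L, `NA` where not
#'   measured.
#' @slot bsaTimes numeric, ascending; days at which BSA is recorded.
#' @slot bsa numeric, same length as `bsaTimes`; BSA in m^2 (positive).
#'
#' @seealso [PatientRecord()], [readPatientCsv()], [doseInput()]
#' @export
setClass("PatientRecord",
  representation(
    patientId = "character",
    doseTimes = "numeric",
    doses     = "numeric",
    obsTimes  = "numeric",
    leukocyte = "numeric",
    crp       = "numeric",
    bsaTimes  = "numeric",
    bsa       = "numeric"
  )
)

setValidity("PatientRecord", function(object) {
  msg <- character()
  chkLen <- function(a, b, na, nb) {
    if (length(a) != length(b))
      sprintf("length(%s) != length(%s)", na, nb) else character()
  }
  msg <- c(msg,
    if (length(object@patientId) != 1L || is.na(object@patientId))
      "patientId must be a single non-NA string",
    chkLen(object@doseTimes, object@doses, "doseTimes", "doses"),
    chkLen(object@obsTimes, object@leukocyte, "obsTimes", "leukocyte"),
    chkLen(object@obsTimes, object@crp, "obsTimes", "crp"),
    chkLen(object@bsaTimes, object@bsa, "bsaTimes", "bsa"))
  if (length(msg)) return(msg)
  if (is.unsorted(object@doseTimes)) msg <- c(msg, "doseTimes must be non-decreasing")
  if (is.unsorted(object@obsTimes))  msg <- c(msg, "obsTimes must be non-decreasing")
  if (is.unsorted(object@bsaTimes))  msg <- c(msg, "bsaTimes must be non-decreasing")
  if (any(is.na(object@doses)) || any(object@doses < 0))
    msg <- c(msg, "doses must be non-negative and non-missing")
  if (any(!is.na(object@leukocyte) & object@leukocyte <= 0))
    msg <- c(msg, "leukocyte counts must be positive where present")
  if (any(!is.na(object@crp) & object@crp < 0))
    msg <- c(msg, "crp must be non-negative where present")
  if (length(object@bsa) == 0L || any(is.na(object@bsa)) || any(object@bsa <= 0))
    msg <- c(msg, "bsa must be positive and non-empty")
  if (length(object@obsTimes) &&
      any(is.na(object@leukocyte) & is.na(object@crp)))
    msg <- c(msg, "every observation row needs at least one of leukocyte, crp")
  allT <- c(object@doseTimes, object@obsTimes, object@bsaTimes)
  if (length(unique(allT)) >= 2L && diff(range(allT)) <= 0)
    msg <- c(msg, "treatment span must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Model parameters
## ---------------------------------------------------------------------------

#' Virtual parent of all model parameter classes
#' @export
setClass("ModelParameters", representation("VIRTUAL"))

#' Parameters of the two-compartment state-space model (TCM)
#'
#' TCM couples a one-compartment kinetic-pharmacodynamic drug-effect state M
#' (cytotoxicity, 1/day) to an Euler-Maruyama discretised stochastic
#' differential equation for the log leukocyte count L.  Free parameters
#' (estimated per patient) are `eTgn`, `h`, `kPlMax`, `kL` and `sigmaL`;
#' the rest are fixed and come from the configuration file.
#'
#' @slot eTgn maximal drug-effect rate (1/day), free.
#' @slot h half-saturation dose (mg/m^2), free.
#' @slot kPlMax maximal leukocyte proliferation rate (1/day), free.
#' @slot kL leukocyte elimination rate (1/day), free.
#' @slot sigmaL leukopoiesis standard deviation (1/sqrt(day)), free.  In the
#'   CRP extension this slot plays the baseline volatility.
#' @slot gamma feedback exponent (dimensionless), fixed.
#' @slot kMe drug-effect elimination rate (1/day), fixed.
#' @slot rho feedback scale (1e9 cells/L), fixed.
#' @slot sigmaLeuk measurement SD of log leukocyte counts, fixed (0.057).
#' @slot tDur dose-input window (days; 1 = the last 24 h), fixed.
#' @slot dt discretisation step of the state recursion (days; 0.25), fixed.
#'
#' @seealso [tcmParameters()], [tcmCrpParameters()]
#' @export
setClass("TcmParameters", contains = "ModelParameters",
  representation(
    eTgn = "numeric", h = "numeric", kPlMax = "numeric", kL = "numeric",
    sigmaL = "numeric", gamma = "numeric", kMe = "numeric", rho = "numeric",
    sigmaLeuk = "numeric", tDur = "numeric", dt = "numeric"
  )
)

setValidity("TcmParameters", function(object) {
  v <- c(eTgn = object@eTgn, h = object@h, kPlMax = object@kPlMax,
         kL = object@kL, sigmaL = object@sigmaL, gamma = object@gamma,
         kMe = object@kMe, rho = object@rho, sigmaLeuk = object@sigmaLeuk,
         tDur = object@tDur, dt = object@dt)
  if (any(lengths(list(object@eTgn, object@h, object@kPlMax, object@kL,
                       object@sigmaL, object@gamma, object@kMe, object@rho,
                       object@sigmaLeuk, object@tDur, object@dt)) != 1L))
    return("all parameter slots must be scalars")
  if (any(!is.finite(v)) || any(v <= 0))
    return(paste("parameters must be positive and finite; offending:",
                 paste(names(v)[!is.finite(v) | v <= 0], collapse = ", ")))
  TRUE
})

#' Parameters of the CRP-extended state-space model (TCM-CRP)
#'
#' Extends [TcmParameters-class] with a latent Ornstein-Uhlenbeck infection
#' level V whose value inflates the leukopoiesis volatility
#' `sigmaL * exp(betaCrp * V)` and is observed through log(CRP + 1).  The
#' `sigmaL` slot of the parent class acts as the baseline volatility
#' (sigma_L^0).  The infection hyperparameters `thetaOu`, `sigmaOu` and
#' `betaCrp` are fixed per patient; they are estimated jointly across a
#' cohort with [jointFitThetaV()].
#'
#' @slot thetaOu OU mean-reversion rate (1/day).
#' @slot sigmaOu OU diffusion SD.
#' @slot betaCrp volatility coupling (dimensionless).
#' @slot sigmaCrp measurement SD of log(CRP + 1), fixed (0.1).
#' @export
setClass("TcmCrpParameters", contains = "TcmParameters",
  representation(
    thetaOu = "numeric", sigmaOu = "numeric", betaCrp = "numeric",
    sigmaCrp = "numeric"
  )
)

setValidity("TcmCrpParameters", function(object) {
  v <- c(thetaOu = object@thetaOu, sigmaOu = object@sigmaOu,
         betaCrp = object@betaCrp, sigmaCrp = object@sigmaCrp)
  if (any(lengths(list(object@thetaOu, object@sigmaOu, object@betaCrp,
                       object@sigmaCrp)) != 1L))
    return("all parameter slots must be scalars")
  if (any(!is.finite(v)) || any(v <= 0))
    return(paste("parameters must be positive and finite; offending:",
                 paste(names(v)[!is.finite(v) | v <= 0], collapse = ", ")))
  TRUE
})

#' Parameters of the eight-compartment ODE comparator model (JM)
#'
#' Three-compartment 6-MP pharmacokinetics (gut, plasma, red-blood-cell
#' thioguanine nucleotides) coupled to a five-compartment leukopoiesis
#' maturation chain in log state variables, observed through i.i.d. Gaussian
#' errors on the log leukocyte count.  Free parameters are `kCm`, `kTr`,
#' `kPlMax`, `kL`, `gamma`, `eMax` and `sigmaLeuk`.
#'
#' @slot kAb gut absorption rate (1/day), fixed.
#' @slot kEl plasma elimination rate (1/day), fixed.
#' @slot kCm maximal plasma-to-TGN metabolism rate, free.
#' @slot k Michaelis constant of the metabolism term, fixed.
#' @slot vCm TGN production scaling, fixed.
#' @slot kMe TGN elimination rate (1/day), fixed.
#' @slot kPlMax maximal stem-cell proliferation rate (1/day), free.
#' @slot gamma feedback exponent, free.
#' @slot rho feedback scale (1e9 cells/L), fixed.
#' @slot eMax maximal drug effect on stem-cell production (1/day), free.
#' @slot eC50 TGN level of half-maximal effect, fixed.
#' @slot kTr maturation-chain transit rate (1/day), free.
#' @slot kL leukocyte elimination rate (1/day), free.
#' @slot sigmaLeuk observation SD on the log scale, free.
#' @slot rtol relative tolerance of the stiff ODE solver.
#' @export
setClass("JmParameters", contains = "ModelParameters",
  representation(
    kAb = "numeric", kEl = "numeric", kCm = "numeric", k = "numeric",
    vCm = "numeric", kMe = "numeric", kPlMax = "numeric", gamma = "numeric",
    rho = "numeric", eMax = "numeric", eC50 = "numeric", kTr = "numeric",
    kL = "numeric", sigmaLeuk = "numeric", rtol = "numeric"
  )
)

setValidity("JmParameters", function(object) {
  v <- c(kAb = object@kAb, kEl = object@kEl, kCm = object@kCm, k = object@k,
         vCm = object@vCm, kMe = object@kMe, kPlMax = object@kPlMax,
         gamma = object@gamma, rho = object@rho, eC50 = object@eC50,
         kTr = object@kTr, kL = object@kL, sigmaLeuk = object@sigmaLeuk,
         rtol = object@rtol)
  if (any(!is.finite(v)) || any(v <= 0))
    return(paste("parameters must be positive and finite; offending:",
                 paste(names(v)[!is.finite(v) | v <= 0], collapse = ", ")))
  if (!is.finite(object@eMax) || object@eMax < 0)
    return("eMax must be finite and non-negative")
  TRUE
})

#' Parameters of the naive mean baseline (NM)
#'
#' NM assumes the leukocyte counts are i.i.d. Gaussian on the linear scale,
#' `N(muNm, sigmaNm^2)`; it ignores dosing entirely and serves as a
#' baseline.
#'
#' @slot muNm mean leukocyte count (1e9 cells/L).
#' @slot sigmaNm SD of the leukocyte count (1e9 cells/L).
#' @export
setClass("NmParameters", contains = "ModelParameters",
  representation(muNm = "numeric", sigmaNm = "numeric")
)

setValidity("NmParameters", function(object) {
  if (!is.finite(object@muNm)) return("muNm must be finite")
  if (is.na(object@sigmaNm) || object@sigmaNm < 0)
    return("sigmaNm must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Filtering / prediction containers
## ---------------------------------------------------------------------------

#' Gaussian belief over the latent state at one time point
#'
#' The extended Kalman filter represents its knowledge of the latent state
#' (M = cytotoxicity, L = log leukocyte count, optionally V = log infection
#' level) as a Gaussian with mean vector and covariance matrix.  Exactly
#' zero variances are allowed (the model's initial law puts a point mass on
#' M = 0).
#'
#' @slot time days since start of maintenance therapy.
#' @slot mean named numeric state mean; names in `c("M","L")` or
#'   `c("M","L","V")`.
#' @slot cov symmetric positive semi-definite matrix of matching dimension.
#' @seealso [stateBelief()], [transitionBelief()], [observeBelief()]
#' @export
setClass("StateBelief",
  representation(time = "numeric", mean = "numeric", cov = "matrix")
)

setValidity("StateBelief", function(object) {
  d <- length(object@mean)
  if (length(object@time) != 1L || !is.finite(object@time))
    return("time must be a finite scalar")
  if (!d %in% c(2L, 3L)) return("state dimension must be 2 (TCM) or 3 (TCM-CRP)")
  if (!all(dim(object@cov) == c(d, d))) return("cov dimension mismatch")
  if (any(!is.finite(object@mean)) || any(!is.finite(object@cov)))
    return("mean and cov must be finite")
  if (max(abs(object@cov - t(object@cov))) > 1e-8 * (1 + max(abs(object@cov))))
    return("cov must be symmetric")
  ev <- eigen((object@cov + t(object@cov)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8 * (1 + max(abs(ev))))
    return("cov must be positive semi-definite")
  TRUE
})

#' Predictive distribution of leukocyte observations at target times
#'
#' Per-time predictive mean and variance, either on the natural-log scale
#' (state-space and ODE models: the predictive law of the log count,
#' measurement noise included) or on the linear scale (the naive mean
#' baseline).  Point predictions and central intervals on the linear
#' 1e9 cells/L scale are derived with [pointPrediction()] and
#' [predictionIntervals()].
#'
#' @slot times target days.
#' @slot mean predictive mean per target time (scale per `scale`).
#' @slot var predictive variance per target time (measurement noise
#'   included).
#' @slot scale `"log"` or `"linear"`.
#' @export
setClass("PredictionSet",
  representation(times = "numeric", mean = "numeric", var = "numeric",
                 scale = "character")
)

setValidity("PredictionSet", function(object) {
  n <- length(object@times)
  if (length(object@mean) != n || length(object@var) != n)
    return("times, mean and var must have equal length")
  if (any(object@var < 0, na.rm = TRUE)) return("var must be non-negative")
  if (!object@scale %in% c("log", "linear"))
    return('scale must be "log" or "linear"')
  TRUE
})

#' Result of a maximum a posteriori fit
#'
#' @slot parameters the fitted [ModelParameters-class] object.
#' @slot logPosterior unnormalised log posterior at the optimum.
#' @slot converged logical convergence flag of the optimiser.
#' @slot nEvaluations number of objective evaluations.
#' @slot model character model id ("tcm", "tcmcrp", "jm" or "nm").
#' @slot trace optional matrix of multi-start results.
#' @export
setClass("MapFit",
  representation(parameters = "ModelParameters", logPosterior = "numeric",
                 converged = "logical", nEvaluations = "numeric",
                 model = "character", trace = "matrix")
)

setValidity("MapFit", function(object) {
  if (isTRUE(object@converged) && !is.finite(object@logPosterior))
    return("logPosterior must be finite when converged")
  TRUE
})

#' Per-patient time-series cross-validation report
#'
#' One rolling-origin cross-validation run of one model on one patient:
#' the per-round predictions paired with the held-out observations, failure
#' flags, and the per-patient metrics (RMSE, MAE, CP50, CP90) computed on
#' the linear scale with failed rounds removed.
#'
#' @slot patientId character.
#' @slot model character model id.
#' @slot horizon prediction horizon in days.
#' @slot predictions data.frame with columns `round`, `trainEnd`, `time`,
#'   `observed`, `predicted`, `lo50`, `hi50`, `lo90`, `hi90`, `failed`.
#' @slot nRounds number of cross-validation rounds attempted.
#' @slot nFailed number of rounds where fitting or prediction failed.
#' @slot metrics named numeric: `rmse`, `mae`, `cp50`, `cp90`, `n`.
#' @export
setClass("TscReport",
  representation(patientId = "character", model = "character",
                 horizon = "numeric", predictions = "data.frame",
                 nRounds = "numeric", nFailed = "numeric",
                 metrics = "numeric")
)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "PatientRecord", function(object) {
  nl <- sum(!is.na(object@leukocyte)); nc <- sum(!is.na(object@crp))
  cat("PatientRecord '", object@patientId, "'\n", sep = "")
  cat(sprintf("  span: %.0f days | %d dose days | %d visits (%d leukocyte, %d CRP) | %d BSA points\n",
              treatmentSpan(object), length(object@doseTimes),
              length(object@obsTimes), nl, nc, length(object@bsaTimes)))
})

setMethod("show", "TcmParameters", function(object) {
  cat(class(object), "\n")
  cat(sprintf("  free : eTgn=%.4g h=%.4g kPlMax=%.4g kL=%.4g sigmaL=%.4g\n",
              object@eTgn, object@h, object@kPlMax, object@kL, object@sigmaL))
  cat(sprintf("  fixed: gamma=%.3g kMe=%.3g rho=%.3g sigmaLeuk=%.3g tDur=%.3g dt=%.3g\n",
              object@gamma, object@kMe, object@rho, object@sigmaLeuk,
              object@tDur, object@dt))
  if (is(object, "TcmCrpParameters"))
    cat(sprintf("  infection: thetaOu=%.4g sigmaOu=%.4g betaCrp=%.4g sigmaCrp=%.3g\n",
                object@thetaOu, object@sigmaOu, object@betaCrp, object@sigmaCrp))
})

setMethod("show", "NmParameters", function(object) {
  cat(sprintf("NmParameters: muNm=%.4g sigmaNm=%.4g (1e9 cells/L)\n",
              object@muNm, object@sigmaNm))
})

setMethod("show", "JmParameters", function(object) {
  cat("JmParameters\n")
  cat(sprintf("  free : kCm=%.4g kTr=%.4g kPlMax=%.4g kL=%.4g gamma=%.4g eMax=%.4g sigmaLeuk=%.4g\n",
              object@kCm, object@kTr, object@kPlMax, object@kL, object@gamma,
              object@eMax, object@sigmaLeuk))
  cat(sprintf("  fixed: kAb=%.3g kEl=%.3g k=%.3g vCm=%.3g kMe=%.3g rho=%.3g eC50=%.3g rtol=%.1e\n",
              object@kAb, object@kEl, object@k, object@vCm, object@kMe,
              object@rho, object@eC50, object@rtol))
})

setMethod("show", "StateBelief", function(object) {
  cat(sprintf("StateBelief at day %.2f\n", object@time))
  cat("  mean:", paste(sprintf("%s=%.4g", names(object@mean), object@mean),
                       collapse = " "), "\n")
  cat("  sd  :", paste(sprintf("%.4g", sqrt(pmax(diag(object@cov), 0))),
                       collapse = " "), "\n")
})

setMethod("show", "MapFit", function(object) {
  cat(sprintf("MapFit [%s]: logPosterior=%.4f converged=%s (%d evaluations)\n",
              object@model, object@logPosterior, object@converged,
              as.integer(object@nEvaluations)))
  show(object@parameters)
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: %d target times on the %s scale\n",
              length(object@times), object@scale))
})

setMethod("show", "TscReport", function(object) {
  cat(sprintf("TscReport: patient '%s', model %s, horizon %d days\n",
              object@patientId, object@model, as.integer(object@horizon)))
  cat(sprintf("  %d rounds (%d failed), %d held-out observations\n",
              as.integer(object@nRounds), as.integer(object@nFailed),
              sum(!object@predictions$failed)))
  m <- object@metrics
  cat(sprintf("  RMSE=%.3f MAE=%.3f CP50=%.3f CP90=%.3f\n",
              m[["rmse"]], m[["mae"]], m[["cp50"]], m[["cp90"]]))
})
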