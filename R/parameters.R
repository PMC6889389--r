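#' @include AllClasses.R AllGenerics.R
NULL

#' Default parameter configuration
#'
#' Reads the model parameter configuration shipped with the package (or a
#' user-supplied YAML file of the same layout).  The file separates, per
#' model, the `fixed` parameters from the `free_init` starting values of the
#' estimated parameters, so that fixed constants are never hard-coded and
#' can be overridden for sensitivity analyses.
#'
#' @param path YAML file; defaults to the packaged
#'   `extdata/default-parameters.yaml`.
#' @return nested list as stored in the YAML file.
#' @export
#' @examples
#' cfg <- defaultParameterConfig()
#' names(cfg)
defaultParameterConfig <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default-parameters.yaml",
                        package = "leukopred", mustWork = TRUE)
  yaml::read_yaml(path)
}

.override <- function(vals, dots) {
  if (length(dots)) {
    bad <- setdiff(names(dots), names(vals))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    vals[names(dots)] <- dots
  }
  vals
}

#' Construct TCM parameters
#'
#' Values default to the packaged configuration; any parameter can be
#' overridden by name (natural scale).
#'
#' @param ... named overrides, e.g. `eTgn = 0.3, h = 20`.
#' @param config configuration list from [defaultParameterConfig()].
#' @return a [TcmParameters-class].
#' @export
#' @examples
#' p <- tcmParameters(eTgn = 0.25)
#' p
tcmParameters <- function(..., config = defaultParameterConfig()) {
  vals <- .override(c(config$tcm$free_init, config$tcm$fixed), list(...))
  new("TcmParameters",
      eTgn = vals$eTgn, h = vals$h, kPlMax = vals$kPlMax, kL = vals$kL,
      sigmaL = vals$sigmaL, gamma = vals$gamma, kMe = vals$kMe,
      rho = vals$rho, sigmaLeuk = vals$sigmaLeuk, tDur = vals$tDur,
      dt = vals$dt)
}

#' Construct TCM-CRP parameters
#'
#' As [tcmParameters()], adding the infection hyperparameters (`thetaOu`,
#' `sigmaOu`, `betaCrp`) and the CRP measurement SD `sigmaCrp`.  The
#' `sigmaL` slot is the baseline volatility of the stochastic-volatility
#' extension.
#'
#' @inheritParams tcmParameters
#' @return a [TcmCrpParameters-class].
#' @export
tcmCrpParameters <- function(..., config = defaultParameterConfig()) {
  vals <- .override(c(config$tcm$free_init, config$tcm$fixed,
                      config$tcmcrp$fixed), list(...))
  new("TcmCrpParameters",
      eTgn = vals$eTgn, h = vals$h, kPlMax = vals$kPlMax, kL = vals$kL,
      sigmaL = vals$sigmaL, gamma = vals$gamma, kMe = vals$kMe,
      rho = vals$rho, sigmaLeuk = vals$sigmaLeuk, tDur = vals$tDur,
      dt = vals$dt, thetaOu = vals$thetaOu, sigmaOu = vals$sigmaOu,
      betaCrp = vals$betaCrp, sigmaCrp = vals$sigmaCrp)
}

#' Construct JM (ODE comparator) parameters
#'
#' @inheritParams tcmParameters
#' @return a [JmParameters-class].
#' @export
jmParameters <- function(..., config = defaultParameterConfig()) {
  vals <- .override(c(config$jm$free_init, config$jm$fixed), list(...))
  new("JmParameters",
      kAb = vals$kAb, kEl = vals$kEl, kCm = vals$kCm, k = vals$k,
      vCm = vals$vCm, kMe = vals$kMe, kPlMax = vals$kPlMax,
      gamma = vals$gamma, rho = vals$rho, eMax = vals$eMax,
      eC50 = vals$eC50, kTr = vals$kTr, kL = vals$kL,
      sigmaLeuk = vals$sigmaLeuk, rtol = vals$rtol)
}

#' Construct naive-mean baseline parameters
#'
#' @param muNm mean leukocyte count (1e9 cells/L).
#' @param sigmaNm SD of the leukocyte count (1e9 cells/L).
#' @return an [NmParameters-class].
#' @export
nmParameters <- function(muNm, sigmaNm) {
  new("NmParameters", muNm = muNm, sigmaNm = sigmaNm)
}

## Free-parameter bookkeeping ------------------------------------------------

#' @rdname freeParamNames
setMethod("freeParamNames", "TcmParameters", function(params)
  c("eTgn", "h", "kPlMax", "kL", "sigmaL"))

#' @rdname freeParamNames
setMethod("freeParamNames", "JmParameters", function(params)
  c("kCm", "kTr", "kPlMax", "kL", "gamma", "eMax", "sigmaLeuk"))

#' @rdname freeParamNames
setMethod("freeParamNames", "NmParameters", function(params)
  c("muNm", "sigmaNm"))

#' Log-scale vector of the free parameters
#'
#' MAP estimation works on the natural logarithm of the free parameters;
#' these helpers map a parameter object to/from that vector.
#'
#' @param params a [ModelParameters-class].
#' @return named numeric of log free parameters.
#' @seealso [setFreeParams()]
#' @export
freeParamsLog <- function(params) {
  nm <- freeParamNames(params)
  vapply(nm, function(s) log(slot(params, s)), numeric(1))
}

#' Replace the free parameters from a log-scale vector
#'
#' @param params a [ModelParameters-class] supplying the fixed values.
#' @param logTheta named (or positionally ordered as [freeParamNames()])
#'   numeric of log free parameters.
#' @return a parameter object of the same class.
#' @export
setFreeParams <- function(params, logTheta) {
  nm <- freeParamNames(params)
  stopifnot(length(logTheta) == length(nm))
  for (i in seq_along(nm)) slot(params, nm[i]) <- exp(logTheta[[i]])
  validObject(params)
  params
}

## Gaussian prior on log free parameters -------------------------------------

#' Log prior density of the free parameters
#'
#' Independent Gaussian priors on the log free parameters, by default vague
#' `N(0, 10)` (variance 10) on each, as used in all MAP fits.
#'
#' @param logTheta numeric vector of log free parameters.
#' @param mean prior mean (scalar, recycled).
#' @param var prior variance (scalar, recycled).
#' @return scalar log prior density.
#' @export
logPrior <- function(logTheta, mean = 0, var = 10) {
  sum(stats::dnorm(logTheta, mean = mean, sd = sqrt(var), log = TRUE))
}
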