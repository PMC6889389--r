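#' @include AllClasses.R
NULL

#' Model log-likelihood of a patient record
#'
#' Dispatches on the parameter class: state-space models (TCM, TCM-CRP) use
#' the extended Kalman filter prediction-error decomposition, the ODE
#' comparator uses the i.i.d. Gaussian likelihood about the solved log
#' leukocyte trajectory, and the naive baseline uses the i.i.d. Gaussian
#' likelihood on the linear scale.
#'
#' @param record a [PatientRecord-class].
#' @param params a [ModelParameters-class] object.
#' @param ... method-specific arguments.
#' @return scalar log-likelihood (may be `-Inf`).
#' @export
setGeneric("modelLoglik", function(record, params, ...)
  standardGeneric("modelLoglik"))

#' Maximum a posteriori fit of a model to one patient
#'
#' Maximises `log p(y | theta) + log p(theta)` over the logarithms of the
#' free parameters with the Nelder-Mead method, with independent Gaussian
#' `N(0, 10)` priors on each log free parameter.  Dispatches on the class of
#' `init`, whose slot values provide both the fixed parameters and the
#' optimiser's starting point.  The naive baseline has a closed form (sample
#' mean and variance of the leukocyte counts) and ignores the optimiser
#' settings.
#'
#' @param record a [PatientRecord-class].
#' @param init a [ModelParameters-class] giving fixed values and the starting
#'   point for the free parameters.
#' @param ... method-specific arguments, see e.g.
#'   [mapFit,PatientRecord,TcmParameters-method].
#' @return a [MapFit-class].
#' @export
setGeneric("mapFit", function(record, init, ...) standardGeneric("mapFit"))

#' Forecast held-out leukocyte observations over a horizon
#'
#' Conditions the model on all data up to `tFrom`, then predicts the
#' leukocyte observations falling in `(tFrom, tFrom + horizon]` without any
#' further observation updates, using the supplied (actually administered)
#' dose schedule.  State-space models filter to `tFrom` and propagate; the
#' ODE comparator solves forward; the naive baseline predicts its fitted
#' Gaussian at every time.
#'
#' @param record a [PatientRecord-class].
#' @param params fitted [ModelParameters-class].
#' @param tFrom forecast origin (days).
#' @param horizon horizon length (days); targets are the record's leukocyte
#'   observation times in `(tFrom, tFrom + horizon]`.
#' @param ... method-specific arguments (e.g. `useCrp` to keep conditioning
#'   on CRP observations inside the horizon for TCM-CRP; default off).
#' @return a [PredictionSet-class] (empty if no targets fall in the window).
#' @export
setGeneric("predictHorizon", function(record, params, tFrom, horizon, ...)
  standardGeneric("predictHorizon"))

#' In-sample fitted mean of a model
#'
#' Computes the "fitted mean" series at the record's leukocyte observation
#' times given parameters estimated from the full record: for the
#' state-space models, one filter pass with every leukocyte count masked
#' (CRP still observed for TCM-CRP), exponentiated; for the ODE comparator,
#' the exponentiated solved trajectory; for the naive baseline, the constant
#' fitted mean.
#'
#' @param record a [PatientRecord-class].
#' @param params fitted [ModelParameters-class].
#' @param ... unused.
#' @return a [PredictionSet-class] over the leukocyte observation times.
#' @export
setGeneric("inSampleFit", function(record, params, ...)
  standardGeneric("inSampleFit"))

#' Names of the free (estimated) parameters of a model
#'
#' @param params a [ModelParameters-class].
#' @return character vector of slot names optimised on the log scale.
#' @export
setGeneric("freeParamNames", function(params) standardGeneric("freeParamNames"))

## Accessors -----------------------------------------------------------------

#' @rdname PatientRecord-accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname PatientRecord-accessors
#' @export
setGeneric("doseTimes", function(x) standardGeneric("doseTimes"))
#' @rdname PatientRecord-accessors
#' @export
setGeneric("doses", function(x) standardGeneric("doses"))
#' @rdname PatientRecord-accessors
#' @export
setGeneric("obsTimes", function(x) standardGeneric("obsTimes"))
#' @rdname PatientRecord-accessors
#' @export
setGeneric("leukocyte", function(x) standardGeneric("leukocyte"))
#' @rdname PatientRecord-accessors
#' @export
setGeneric("crp", function(x) standardGeneric("crp"))
#' @rdname PatientRecord-accessors
#' @export
setGeneric("bsaTimes", function(x) standardGeneric("bsaTimes"))
#' @rdname PatientRecord-accessors
#' @export
setGeneric("bsa", function(x) standardGeneric("bsa"))
#' @rdname PatientRecord-accessors
#' @export
setGeneric("treatmentSpan", function(x) standardGeneric("treatmentSpan"))

#' @rdname MapFit-accessors
#' @export
setGeneric("fittedParameters", function(x) standardGeneric("fittedParameters"))
#' @rdname MapFit-accessors
#' @export
setGeneric("logPosterior", function(x) standardGeneric("logPosterior"))
#' @rdname MapFit-accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname TscReport-accessors
#' @export
setGeneric("tscPredictions", function(x) standardGeneric("tscPredictions"))
#' @rdname TscReport-accessors
#' @export
setGeneric("tscMetrics", function(x) standardGeneric("tscMetrics"))

#' @rdname PredictionSet-accessors
#' @export
setGeneric("pointPrediction", function(x) standardGeneric("pointPrediction"))
#' @rdname PredictionSet-accessors
#' @export
setGeneric("predictionIntervals", function(x, alpha = 90)
  standardGeneric("predictionIntervals"))
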