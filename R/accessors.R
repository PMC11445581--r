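# Accessor generics and methods; slot access stays internal to the package.

#' @rdname accessors
#' @param object an fccstools S4 object.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("channel", function(object) standardGeneric("channel"))
#' @rdname accessors
#' @export
setGeneric("lags", function(object) standardGeneric("lags"))
#' @rdname accessors
#' @export
setGeneric("gValues", function(object) standardGeneric("gValues"))
#' @rdname accessors
#' @export
setGeneric("gSD", function(object) standardGeneric("gSD"))
#' @rdname accessors
#' @export
setGeneric("curveKind", function(object) standardGeneric("curveKind"))
#' @rdname accessors
#' @export
setGeneric("waistXY", function(object) standardGeneric("waistXY"))
#' @rdname accessors
#' @export
setGeneric("waistZ", function(object) standardGeneric("waistZ"))
#' @rdname accessors
#' @export
setGeneric("structureParameter", function(object) standardGeneric("structureParameter"))
#' @rdname accessors
#' @export
setGeneric("nMolecules", function(object) standardGeneric("nMolecules"))
#' @rdname accessors
#' @export
setGeneric("tauD", function(object) standardGeneric("tauD"))
#' @rdname accessors
#' @export
setGeneric("dCoef", function(object) standardGeneric("dCoef"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("compartment", function(object) standardGeneric("compartment"))
#' @rdname accessors
#' @export
setGeneric("onsetFrame", function(object) standardGeneric("onsetFrame"))
#' @rdname accessors
#' @export
setGeneric("initialSpeed", function(object) standardGeneric("initialSpeed"))
#' @rdname accessors
#' @export
setGeneric("maxSpeed", function(object) standardGeneric("maxSpeed"))
#' @rdname accessors
#' @export
setGeneric("kdValue", function(object) standardGeneric("kdValue"))
#' @rdname accessors
#' @export
setGeneric("truthParams", function(object) standardGeneric("truthParams"))

#' Accessors for fccstools classes
#'
#' Small read-only accessors for the package's S4 objects.
#'
#' @name accessors
#' @aliases counts binWidth channel lags gValues gSD curveKind waistXY
#'   waistZ structureParameter nMolecules tauD dCoef isConverged frames
#'   intensities compartment onsetFrame initialSpeed maxSpeed kdValue
#'   truthParams
NULL

#' @rdname accessors
#' @export
setMethod("counts", "PhotonCountTrace", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("binWidth", "PhotonCountTrace", function(object) object@binWidth)
#' @rdname accessors
#' @export
setMethod("channel", "PhotonCountTrace", function(object) object@channel)

#' @rdname accessors
#' @export
setMethod("lags", "CorrelationCurve", function(object) object@lags)
#' @rdname accessors
#' @export
setMethod("gValues", "CorrelationCurve", function(object) object@g)
#' @rdname accessors
#' @export
setMethod("gSD", "CorrelationCurve", function(object)
  if (length(object@sd)) object@sd else NULL)
#' @rdname accessors
#' @export
setMethod("curveKind", "CorrelationCurve", function(object) object@kind)

#' @rdname accessors
#' @export
setMethod("waistXY", "ObservationVolume", function(object) object@wXY)
#' @rdname accessors
#' @export
setMethod("waistZ", "ObservationVolume", function(object) object@kappa * object@wXY)
#' @rdname accessors
#' @export
setMethod("structureParameter", "ObservationVolume", function(object) object@kappa)

#' @rdname accessors
#' @export
setMethod("nMolecules", "DiffusionFit", function(object) object@nMolecules)
#' @rdname accessors
#' @export
setMethod("tauD", "DiffusionFit", function(object) object@tauD)
#' @rdname accessors
#' @export
setMethod("dCoef", "DiffusionFit", function(object) object@dCoef)
#' @rdname accessors
#' @export
setMethod("isConverged", "DiffusionFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("frames", "DegradationTrace", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("intensities", "DegradationTrace", function(object) object@intensities)
#' @rdname accessors
#' @export
setMethod("compartment", "DegradationTrace", function(object) object@compartment)

#' @rdname accessors
#' @export
setMethod("onsetFrame", "KineticsResult", function(object)
  if (is.na(object@onsetFrame)) NA_integer_ else object@onsetFrame)
#' @rdname accessors
#' @export
setMethod("initialSpeed", "KineticsResult", function(object) object@initialSpeed)
#' @rdname accessors
#' @export
setMethod("maxSpeed", "KineticsResult", function(object) object@maxSpeed)

#' @rdname accessors
#' @export
setMethod("kdValue", "InteractionResult", function(object) object@kd)

#' @rdname accessors
#' @export
setMethod("truthParams", "SyntheticTruth", function(object) object@params)

setMethod("show", "ObservationVolume", function(object) {
  cat(sprintf(
    "ObservationVolume: w_xy = %.4g um, kappa = %.4g, V_eff = %.4g fL\n",
    object@wXY, object@kappa, effectiveVolume(object) * 1e15))
})

setMethod("show", "PhotonCountTrace", function(object) {
  cat(sprintf(
    "PhotonCountTrace '%s': %d bins of %.3g s (%.3g s), mean rate %.4g kHz\n",
    object@channel, length(object@counts), object@binWidth,
    length(object@counts) * object@binWidth,
    mean(object@counts) / object@binWidth / 1000))
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf(
    "CorrelationCurve [%s]: %d lags in [%.3g, %.3g] s, G(first lag) = %.4g%s\n",
    object@kind, length(object@lags), min(object@lags), max(object@lags),
    object@g[1L], if (length(object@sd)) ", with per-lag sd" else ""))
})

setMethod("show", "DiffusionFit", function(object) {
  if (!object@converged) {
    cat(sprintf("DiffusionFit [%s]: no fit (%s)\n", object@modelId, object@note))
  } else {
    cat(sprintf(
      "DiffusionFit [%s]: N = %.4g, tauD = %s s, D = %s um^2/s, red. chi^2 = %.3g\n",
      object@modelId, object@nMolecules,
      paste(signif(object@tauD, 4), collapse = "/"),
      paste(signif(object@dCoef, 4), collapse = "/"), object@chiSqReduced))
  }
})

setMethod("show", "EquilibriumState", function(object) {
  cat(sprintf(
    "EquilibriumState: totals %.4g / %.4g nM, Kd = %.4g nM -> complex %.4g nM, free %.4g / %.4g nM\n",
    object@aTotal * 1e9, object@bTotal * 1e9, object@kd * 1e9,
    object@complex * 1e9, object@aFree * 1e9, object@bFree * 1e9))
})

setMethod("show", "InteractionResult", function(object) {
  cat(sprintf(
    "InteractionResult: Kd = %s nM, q = %.3g, complex = %.4g nM (free %.4g / %.4g nM)%s\n",
    if (is.na(object@kd)) "withheld" else format(object@kd * 1e9, digits = 4),
    object@q, object@cComplex * 1e9, object@cGreenFree * 1e9,
    object@cRedFree * 1e9,
    if (object@valid) "" else sprintf(" [flagged: %s]", object@note)))
})

setMethod("show", "DegradationTrace", function(object) {
  cat(sprintf(
    "DegradationTrace '%s' [%s]: frames %d..%d, interval %.3g s\n",
    object@cellId, object@compartment, min(object@frames), max(object@frames),
    object@frameInterval))
})

setMethod("show", "KineticsResult", function(object) {
  cat(sprintf(
    "KineticsResult: onset %s, initial speed %s, max speed %.4g /frame at frame %d\n",
    if (is.na(object@onsetFrame)) "not detected" else object@onsetFrame,
    if (is.na(object@initialSpeed)) "-" else signif(object@initialSpeed, 4),
    object@maxSpeed, object@maxSpeedFrame))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth [%s]: %d recorded parameters (seed %s)\n",
              object@kind, length(object@params),
              as.character(object@params$seed)))
})
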