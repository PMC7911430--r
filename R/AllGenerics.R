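#' Accessors for bovocal objects
#'
#' Small accessor generics following the usual container conventions:
#' `samples()` and `sampleRate()` pull the waveform and rate out of an
#' [AudioSegment-class], `peakDb()` its calibrated peak level, `duration()`
#' its length in seconds; `values()` extracts the numeric payload of an
#' [STFTMatrix-class], [TimeFrequencyMask-class] or [MFCCMatrix-class].
#'
#' @param x the object.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("peakDb", function(x) standardGeneric("peakDb"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setMethod("samples", "AudioSegment", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("sampleRate", "AudioSegment", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setMethod("peakDb", "AudioSegment", function(x) x@peakDb)

#' @rdname accessors
#' @export
setMethod("duration", "AudioSegment",
          function(x) length(x@samples) / x@sampleRate)

#' @rdname accessors
#' @export
setMethod("sampleRate", "STFTMatrix", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setMethod("values", "STFTMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("values", "TimeFrequencyMask", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("values", "MFCCMatrix", function(x) x@coefficients)

#' @describeIn accessors dimensions (bins x frames) of an STFT.
#' @export
setMethod("dim", "STFTMatrix", function(x) dim(x@values))

#' @describeIn accessors dimensions (coefficients x frames) of a feature
#'   matrix.
#' @export
setMethod("dim", "MFCCMatrix", function(x) dim(x@coefficients))

setMethod("show", "AudioSegment", function(object) {
  cat(sprintf(
    "AudioSegment: %.3f s @ %g Hz | peak %.2f dB | sensor %s zone %s | t0 %.2f s\n",
    length(object@samples) / object@sampleRate, object@sampleRate,
    object@peakDb, object@sensorId, object@zoneId, object@startTime))
})

setMethod("show", "SensorEvent", function(object) {
  cat(sprintf("SensorEvent: trigger %.2f s | threshold %.1f dB | peak %.2f dB (%s/%s)\n",
              object@triggerTime, object@thresholdDb, object@segment@peakDb,
              object@segment@zoneId, object@segment@sensorId))
})

setMethod("show", "STFTMatrix", function(object) {
  cat(sprintf("STFTMatrix: %d bins x %d frames | nFft %d, win %d, hop %d (%s) | %g Hz\n",
              nrow(object@values), ncol(object@values), object@config@nFft,
              object@config@winLength, object@config@hop,
              object@config@windowFn, object@sampleRate))
})

setMethod("show", "NoiseProfile", function(object) {
  cat(sprintf("NoiseProfile: %d bins | nStd %.2f | threshold range [%.1f, %.1f] dB\n",
              length(object@thresholdDb), object@nStd,
              min(object@thresholdDb), max(object@thresholdDb)))
})

setMethod("show", "MFCCMatrix", function(object) {
  cat(sprintf("MFCCMatrix (%s): %d coefficients x %d frames\n",
              object@representation, nrow(object@coefficients),
              object@tFixed))
})

setMethod("show", "MelFilterBank", function(object) {
  cat(sprintf("MelFilterBank: %d triangular filters over %d bins (%g Hz, nFft %d)\n",
              object@M, ncol(object@weights), object@sampleRate, object@nFft))
})

setMethod("show", "AdadeltaState", function(object) {
  cat(sprintf("AdadeltaState: %d parameters | step %d | gamma %.2f, epsilon %g\n",
              length(object@theta), object@t, object@gamma, object@epsilon))
})

setMethod("show", "ConfusionMatrix2", function(object) {
  cat("ConfusionMatrix2 (rows: predicted, cols: actual)\n")
  m <- matrix(c(object@tp, object@fp, object@fn, object@tn), 2, 2,
              byrow = TRUE,
              dimnames = list(c("pred TRUE", "pred FALSE"),
                              c("actual TRUE", "actual FALSE")))
  print(m)
})

setMethod("show", "CNNModel", function(object) {
  convs <- vapply(object@layers, function(l) identical(l$type, "conv"), logical(1))
  cat(sprintf("CNNModel: input %dx%d | %d conv blocks | %d classes | %s (%s parameters)\n",
              object@inputShape[1], object@inputShape[2], sum(convs),
              object@nClasses, if (object@fitted) "fitted" else "not fitted",
              format(parameterCount(object), big.mark = ",")))
})
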