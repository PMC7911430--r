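#' @import methods
#' @importFrom stats fft mvfft rnorm runif sd
#' @importFrom utils head read.csv write.csv
#' @useDynLib bovocal, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' AudioSegment: a timestamped mono PCM clip
#'
#' Container for a mono audio clip as captured by a barn sound sensor:
#' the waveform, its sample rate, when it started relative to the stream
#' origin, which sensor/zone recorded it, and its peak level in decibels
#' under the package's calibration convention (see [measureDb]).
#'
#' @slot samples numeric waveform, amplitudes nominally in \[-1, 1\].
#' @slot sampleRate sampling rate in Hz.
#' @slot startTime clip start in seconds since the stream origin.
#' @slot sensorId,zoneId identifiers of the recording sensor and its zone.
#' @slot peakDb peak level in dB; always recomputable as
#'   `measureDb(samples, calibrationOffset)` (`-Inf` for an all-zero clip).
#' @slot calibrationOffset dB offset mapping full-scale amplitude to an
#'   absolute level (default 60, so full scale corresponds to 60 dB).
#'
#' @seealso [AudioSegment()], [readWav()], [detectEvents()]
#' @export
setClass("AudioSegment",
  slots = c(
    samples = "numeric",
    sampleRate = "numeric",
    startTime = "numeric",
    sensorId = "character",
    zoneId = "character",
    peakDb = "numeric",
    calibrationOffset = "numeric"
  )
)

setValidity("AudioSegment", function(object) {
  msg <- character()
  if (length(object@samples) == 0L)
    msg <- c(msg, "samples must be non-empty")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@samples) > 0L && any(object@samples != 0)) {
    expected <- 20 * log10(max(abs(object@samples))) + object@calibrationOffset
    if (!isTRUE(all.equal(expected, object@peakDb, tolerance = 1e-8)))
      msg <- c(msg, "peakDb inconsistent with samples and calibrationOffset")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AudioSegment
#'
#' @param samples numeric waveform (mono).
#' @param sampleRate sampling rate in Hz (default 16000).
#' @param startTime seconds since stream origin.
#' @param sensorId,zoneId sensor and zone identifiers.
#' @param calibrationOffset dB added to `20*log10(peak)`; default 60 so that
#'   a full-scale clip measures 60 dB.
#' @return An [AudioSegment-class] object with `peakDb` filled in.
#' @examples
#' seg <- AudioSegment(sin(2 * pi * 440 * seq(0, 1, length.out = 16000)))
#' peakDb(seg)
#' @export
AudioSegment <- function(samples, sampleRate = 16000, startTime = 0,
                         sensorId = "sensor-1", zoneId = "zone-1",
                         calibrationOffset = 60) {
  samples <- as.numeric(samples)
  peak <- if (length(samples) && any(samples != 0)) {
    20 * log10(max(abs(samples))) + calibrationOffset
  } else {
    -Inf
  }
  new("AudioSegment",
    samples = samples, sampleRate = as.numeric(sampleRate),
    startTime = as.numeric(startTime), sensorId = sensorId, zoneId = zoneId,
    peakDb = peak, calibrationOffset = calibrationOffset
  )
}

#' SensorEvent: a dB-triggered capture
#'
#' A clip saved because the stream level crossed the recording threshold,
#' together with the trigger time and the threshold in force.
#'
#' @slot segment the captured [AudioSegment-class].
#' @slot triggerTime trigger instant in seconds since stream origin.
#' @slot thresholdDb the dB threshold that fired (peak of the clip is
#'   always at or above it).
#' @seealso [detectEvents()], [deduplicateZone()]
#' @export
setClass("SensorEvent",
  slots = c(segment = "AudioSegment", triggerTime = "numeric",
            thresholdDb = "numeric")
)

setValidity("SensorEvent", function(object) {
  if (object@segment@peakDb < object@thresholdDb - 1e-9)
    "segment peakDb below thresholdDb" else TRUE
})

#' SensorEvent constructor
#' @param segment an [AudioSegment-class].
#' @param triggerTime seconds since stream origin.
#' @param thresholdDb threshold in dB that triggered the capture.
#' @return A [SensorEvent-class].
#' @export
SensorEvent <- function(segment, triggerTime, thresholdDb = -Inf) {
  new("SensorEvent", segment = segment, triggerTime = as.numeric(triggerTime),
      thresholdDb = as.numeric(thresholdDb))
}

#' STFTConfig: analysis parameters of the short-time Fourier transform
#'
#' Frame length (`nFft`), window length, hop between successive columns and
#' the taper. Defaults follow the monitoring pipeline's analysis settings:
#' 2048-point frames, 2048-sample window, hop 256, Hann taper.
#'
#' @slot nFft DFT length per frame.
#' @slot winLength taper length in samples (`<= nFft`).
#' @slot hop samples between the starts of consecutive frames.
#' @slot windowFn taper name: `"hann"`, `"hamming"` or `"rect"`.
#' @export
setClass("STFTConfig",
  slots = c(nFft = "integer", winLength = "integer", hop = "integer",
            windowFn = "character")
)

setValidity("STFTConfig", function(object) {
  msg <- character()
  if (object@hop <= 0L || object@winLength <= 0L || object@nFft <= 0L)
    msg <- c(msg, "nFft, winLength and hop must be positive")
  if (!(object@hop <= object@winLength && object@winLength <= object@nFft))
    msg <- c(msg, "must satisfy hop <= winLength <= nFft")
  if (!object@windowFn %in% c("hann", "hamming", "rect"))
    msg <- c(msg, "windowFn must be one of 'hann', 'hamming', 'rect'")
  if (length(msg)) msg else TRUE
})

#' @param nFft,winLength,hop,windowFn see [STFTConfig-class].
#' @return An [STFTConfig-class].
#' @rdname STFTConfig-class
#' @examples
#' STFTConfig()                     # pipeline defaults: 2048/2048/256, Hann
#' STFTConfig(nFft = 1024, hop = 512)
#' @export
STFTConfig <- function(nFft = 2048L, winLength = nFft, hop = 256L,
                       windowFn = "hann") {
  new("STFTConfig", nFft = as.integer(nFft), winLength = as.integer(winLength),
      hop = as.integer(hop), windowFn = windowFn)
}

#' STFTMatrix: one-sided complex time-frequency matrix
#'
#' Result of [stft()]: rows are frequency bins (`nFft/2 + 1` of them,
#' bin k centred at `k * sampleRate / nFft` Hz), columns are analysis
#' frames spaced `hop` samples apart.
#'
#' @slot values complex matrix (bins x frames).
#' @slot config the [STFTConfig-class] used.
#' @slot sampleRate sampling rate of the analysed clip (Hz).
#' @slot nSamples original clip length in samples (used by [istft()]).
#' @export
setClass("STFTMatrix",
  slots = c(values = "matrix", config = "STFTConfig", sampleRate = "numeric",
            nSamples = "integer")
)

setValidity("STFTMatrix", function(object) {
  msg <- character()
  expected <- object@config@nFft %/% 2L + 1L
  if (nrow(object@values) != expected)
    msg <- c(msg, sprintf("expected %d frequency bins, found %d", expected,
                          nrow(object@values)))
  if (!all(is.finite(Re(object@values))) || !all(is.finite(Im(object@values))))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' NoiseProfile: per-bin spectral-gate thresholds
#'
#' Per-frequency-bin statistics of a noise recording's dB magnitudes: the
#' mean, the (population) standard deviation, and the resulting gate
#' threshold `mean + nStd * sd`.
#'
#' @slot meanPowerDb,stdPowerDb,thresholdDb numeric vectors, one entry per
#'   frequency bin.
#' @slot nStd the threshold multiplier used.
#' @seealso [estimateNoiseProfile()], [computeMask()]
#' @export
setClass("NoiseProfile",
  slots = c(meanPowerDb = "numeric", stdPowerDb = "numeric",
            thresholdDb = "numeric", nStd = "numeric")
)

setValidity("NoiseProfile", function(object) {
  n <- length(object@meanPowerDb)
  if (length(object@stdPowerDb) != n || length(object@thresholdDb) != n)
    return("meanPowerDb, stdPowerDb and thresholdDb must have equal length")
  if (object@nStd >= 0 &&
      any(object@thresholdDb < object@meanPowerDb - 1e-9))
    return("thresholdDb below meanPowerDb despite nStd >= 0")
  TRUE
})

#' TimeFrequencyMask: soft spectral gate
#'
#' A matrix of gains in \[0, 1\] with the same shape as the STFT it gates,
#' plus the smoothing kernel used by [smoothMask()] (default: 2 frequency
#' rows x 4 time columns of equal weight).
#'
#' @slot values real matrix with entries in \[0, 1\].
#' @slot smoothingKernel non-negative kernel whose weights sum to 1.
#' @export
setClass("TimeFrequencyMask",
  slots = c(values = "matrix", smoothingKernel = "matrix")
)

setValidity("TimeFrequencyMask", function(object) {
  msg <- character()
  if (any(object@values < -1e-12) || any(object@values > 1 + 1e-12))
    msg <- c(msg, "mask values must lie in [0, 1]")
  if (any(object@smoothingKernel < 0))
    msg <- c(msg, "smoothing kernel weights must be non-negative")
  if (abs(sum(object@smoothingKernel) - 1) > 1e-9)
    msg <- c(msg, "smoothing kernel weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Default mask-smoothing kernel: 2 frequency channels x 4 time channels,
#' equal weights.
#' @return A 2 x 4 matrix of weights summing to 1.
#' @export
defaultSmoothingKernel <- function() {
  matrix(1 / 8, nrow = 2, ncol = 4)
}

#' MelFilterBank: triangular filters on the Mel scale
#'
#' @slot weights M x (nFft/2 + 1) matrix; row m is a triangular filter that
#'   is zero outside bins `(f(m-1), f(m+1))`, rises linearly to 1 at the
#'   centre bin `f(m)` and falls linearly back to zero.
#' @slot boundaries the M + 2 filter boundary positions, in frequency-bin
#'   units, equally spaced on the Mel scale.
#' @slot M number of filters.
#' @slot sampleRate,nFft analysis parameters the bank was built for.
#' @seealso [buildFilterBank()]
#' @export
setClass("MelFilterBank",
  slots = c(weights = "matrix", boundaries = "numeric", M = "integer",
            sampleRate = "numeric", nFft = "integer")
)

setValidity("MelFilterBank", function(object) {
  msg <- character()
  if (nrow(object@weights) != object@M)
    msg <- c(msg, "weights must have M rows")
  if (length(object@boundaries) != object@M + 2L)
    msg <- c(msg, "boundaries must have M + 2 entries")
  if (any(object@weights < 0))
    msg <- c(msg, "filter weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' MFCCMatrix: fixed-width cepstral feature matrix
#'
#' The classifier input: M coefficient rows by a fixed number of time
#' frames (default 128 x 2000 in the full-scale pipeline). Clips shorter
#' than `tFixed` frames are zero-padded on the right; longer clips are
#' truncated on the right.
#'
#' @slot coefficients M x tFixed real matrix.
#' @slot logEnergies optional retained log filter-bank energies (matrix or
#'   NULL).
#' @slot tFixed the fixed frame target.
#' @slot representation `"mfcc"` (post-DCT) or `"logmel"`.
#' @seealso [mfccFeatures()]
#' @export
setClass("MFCCMatrix",
  slots = c(coefficients = "matrix", logEnergies = "ANY", tFixed = "integer",
            representation = "character")
)

setValidity("MFCCMatrix", function(object) {
  if (ncol(object@coefficients) != object@tFixed)
    return(sprintf("coefficients must have exactly tFixed = %d columns",
                   object@tFixed))
  if (!object@representation %in% c("mfcc", "logmel"))
    return("representation must be 'mfcc' or 'logmel'")
  TRUE
})

#' AdadeltaState: accumulators of the Adadelta optimizer
#'
#' Holds the parameter vector and the two exponentially decaying
#' accumulators of squared gradients and squared updates, with the decay
#' gamma = 0.95 and smoothing epsilon = 1e-7 used throughout the package.
#'
#' @slot theta parameter vector.
#' @slot accumGradSq running average of squared gradients, E\[g^2\].
#' @slot accumUpdateSq running average of squared updates, E\[dtheta^2\].
#' @slot gamma decay / momentum term in (0, 1).
#' @slot epsilon smoothing term guarding the division.
#' @slot t step counter.
#' @seealso [adadeltaStep()]
#' @export
setClass("AdadeltaState",
  slots = c(theta = "numeric", accumGradSq = "numeric",
            accumUpdateSq = "numeric", gamma = "numeric", epsilon = "numeric",
            t = "integer")
)

setValidity("AdadeltaState", function(object) {
  msg <- character()
  if (any(object@accumGradSq < 0) || any(object@accumUpdateSq < 0))
    msg <- c(msg, "accumulators must be non-negative")
  if (object@gamma <= 0 || object@gamma >= 1)
    msg <- c(msg, "gamma must lie in (0, 1)")
  if (object@epsilon <= 0)
    msg <- c(msg, "epsilon must be positive")
  if (length(msg)) msg else TRUE
})

#' Initialize an Adadelta optimizer state
#'
#' @param theta initial parameter vector.
#' @param gamma decay term (default 0.95).
#' @param epsilon smoothing term (default 1e-7).
#' @return An [AdadeltaState-class] with zeroed accumulators.
#' @examples
#' st <- adadeltaInit(c(1, -2))
#' st <- adadeltaStep(st, gradient = c(0.5, 0.1))
#' @export
adadeltaInit <- function(theta, gamma = 0.95, epsilon = 1e-7) {
  new("AdadeltaState", theta = as.numeric(theta),
      accumGradSq = numeric(length(theta)),
      accumUpdateSq = numeric(length(theta)),
      gamma = gamma, epsilon = epsilon, t = 0L)
}

#' ConfusionMatrix2: binary confusion counts
#'
#' The 2x2 layout used to evaluate the cattle-voice/noise gate: true/false
#' positives and negatives.
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @seealso [accuracy()], [trueRecognitionRate()], [falseRecognitionRate()]
#' @export
setClass("ConfusionMatrix2",
  slots = c(tp = "numeric", fp = "numeric", fn = "numeric", tn = "numeric")
)

setValidity("ConfusionMatrix2", function(object) {
  counts <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(counts < 0) || any(counts != round(counts)))
    return("counts must be non-negative integers")
  TRUE
})

#' ConfusionMatrix2 constructor
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return A [ConfusionMatrix2-class].
#' @examples
#' cm <- ConfusionMatrix2(tp = 140, fp = 12, fn = 19, tn = 189)
#' accuracy(cm)
#' @export
ConfusionMatrix2 <- function(tp, fp, fn, tn) {
  new("ConfusionMatrix2", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn))
}

#' CNNModel: a small 2D convolutional classifier
#'
#' Sequential stack of same-padded 3x3 convolutions with ReLU and max
#' pooling, a flatten, one hidden dense ReLU layer and a Softmax output.
#' Built by [buildBinaryCnn()] / [buildBehaviorCnn()], fitted by [train()].
#'
#' @slot layers ordered list of layer descriptors (weights live here).
#' @slot inputShape integer(2): (mel bands, time frames).
#' @slot nClasses number of Softmax output units (2 or 4).
#' @slot fitted TRUE once [train()] has run.
#' @slot inputScale divisor applied to features on the way in (set from the
#'   training set for numerical conditioning; 1 before fitting).
#' @slot history per-epoch training/validation loss and accuracy, or NULL.
#' @slot classLabels optional character labels for the output classes.
#' @export
setClass("CNNModel",
  slots = c(layers = "list", inputShape = "integer", nClasses = "integer",
            fitted = "logical", inputScale = "numeric", history = "ANY",
            classLabels = "character")
)

setValidity("CNNModel", function(object) {
  msg <- character()
  if (!object@nClasses %in% c(2L, 4L))
    msg <- c(msg, "nClasses must be 2 or 4")
  if (length(object@inputShape) != 2L || any(object@inputShape < 1L))
    msg <- c(msg, "inputShape must be two positive integers")
  if (length(msg)) msg else TRUE
})

#' CallSpec: recipe for one synthetic cattle call
#'
#' Parameters of the harmonic-stack call generator. The four behavioral
#' classes map to distinct acoustic signatures: 0 = estrus (long rising
#' fundamental-frequency sweep), 1 = food anticipation (repeated short
#' pulses), 2 = cough (short broadband noisy burst), 3 = normal (flat-f0
#' moderate call). These are synthetic conventions chosen for learnability,
#' not bioacoustic measurements of real cattle.
#'
#' @slot classIndex behavioral class 0..3.
#' @slot f0Range fundamental frequency range in Hz (within 50-1000).
#' @slot nHarmonics number of harmonics in the stack.
#' @slot durationRange call duration range in seconds.
#' @slot amplitudeEnvelope envelope identifier ("rise-fall" or "pulsed").
#' @slot repetition calls per clip.
#' @slot seed RNG seed (NA = use the current RNG stream).
#' @seealso [generateCall()]
#' @export
setClass("CallSpec",
  slots = c(classIndex = "integer", f0Range = "numeric",
            nHarmonics = "integer", durationRange = "numeric",
            amplitudeEnvelope = "character", repetition = "integer",
            seed = "integer")
)

setValidity("CallSpec", function(object) {
  msg <- character()
  if (!object@classIndex %in% 0:3)
    msg <- c(msg, "classIndex must be 0, 1, 2 or 3")
  if (object@f0Range[1] <= 50 || object@f0Range[2] >= 1000)
    msg <- c(msg, "f0Range must lie within (50, 1000) Hz")
  if (any(object@durationRange <= 0))
    msg <- c(msg, "durationRange must be positive")
  if (length(msg)) msg else TRUE
})

#' CallSpec constructor with class-specific defaults
#'
#' @param classIndex behavioral class 0..3.
#' @param f0Range,nHarmonics,durationRange,amplitudeEnvelope,repetition,seed
#'   override the class defaults; see [CallSpec-class].
#' @return A [CallSpec-class].
#' @export
CallSpec <- function(classIndex, f0Range = NULL, nHarmonics = NULL,
                     durationRange = NULL, amplitudeEnvelope = NULL,
                     repetition = NULL, seed = NA_integer_) {
  classIndex <- as.integer(classIndex)
  defaults <- switch(as.character(classIndex),
    "0" = list(f0 = c(120, 300), nh = 10L, dur = c(1.2, 2.0),
               env = "rise-fall", rep = 1L),
    "1" = list(f0 = c(100, 220), nh = 8L, dur = c(0.15, 0.30),
               env = "pulsed", rep = 4L),
    "2" = list(f0 = c(150, 300), nh = 4L, dur = c(0.20, 0.40),
               env = "rise-fall", rep = 1L),
    "3" = list(f0 = c(80, 180), nh = 8L, dur = c(0.6, 1.0),
               env = "rise-fall", rep = 1L),
    stop("classIndex must be 0..3")
  )
  new("CallSpec",
    classIndex = classIndex,
    f0Range = if (is.null(f0Range)) defaults$f0 else as.numeric(f0Range),
    nHarmonics = if (is.null(nHarmonics)) defaults$nh else as.integer(nHarmonics),
    durationRange = if (is.null(durationRange)) defaults$dur
                    else as.numeric(durationRange),
    amplitudeEnvelope = if (is.null(amplitudeEnvelope)) defaults$env
                        else amplitudeEnvelope,
    repetition = if (is.null(repetition)) defaults$rep else as.integer(repetition),
    seed = as.integer(seed)
  )
}

#' NoiseSpec: recipe for one synthetic noise component
#'
#' @slot kind `"white"` (broadband microphone noise), `"low_band_hum"`
#'   (continuous background energy concentrated below `bandLimit`),
#'   `"transient_clang"` (decaying inharmonic metallic strike) or
#'   `"speech_like"` (syllabically modulated band noise).
#' @slot snrDb target clip signal-to-noise ratio in dB.
#' @slot bandLimit upper edge of the hum band in Hz (default 400).
#' @slot seed RNG seed (NA = current stream).
#' @seealso [addNoise()]
#' @export
setClass("NoiseSpec",
  slots = c(kind = "character", snrDb = "numeric", bandLimit = "numeric",
            seed = "integer")
)

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("white", "low_band_hum", "transient_clang",
                          "speech_like"))
    msg <- c(msg, "unknown noise kind")
  if (is.na(object@snrDb) || identical(object@snrDb, -Inf))
    msg <- c(msg, "snrDb must be finite (or +Inf for the noiseless limit)")
  if (length(msg)) msg else TRUE
})

#' NoiseSpec constructor
#' @param kind,snrDb,bandLimit,seed see [NoiseSpec-class].
#' @return A [NoiseSpec-class].
#' @export
NoiseSpec <- function(kind = "white", snrDb = 10, bandLimit = 400,
                      seed = NA_integer_) {
  new("NoiseSpec", kind = kind, snrDb = as.numeric(snrDb),
      bandLimit = as.numeric(bandLimit), seed = as.integer(seed))
}

#' Training configuration for the CNN classifiers
#'
#' @param epochs training epochs (default 60; validation accuracy on the
#'   bundled synthetic corpora typically converges well before 40).
#' @param batchSize minibatch size (default 32).
#' @param validationFraction held-out stratified fraction (default 0.2).
#' @param seed RNG seed controlling the split, the shuffling and the
#'   weight initialization; fixed seed gives bit-reproducible training.
#' @param gamma,epsilon Adadelta hyperparameters (defaults 0.95 and 1e-7).
#' @param classWeights optional per-class loss weights (default: none).
#' @return A `TrainConfig` list.
#' @export
trainConfig <- function(epochs = 60L, batchSize = 32L,
                        validationFraction = 0.2, seed = 1L,
                        gamma = 0.95, epsilon = 1e-7, classWeights = NULL) {
  stopifnot(epochs >= 1L, batchSize >= 1L,
            validationFraction > 0, validationFraction < 1)
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 validationFraction = validationFraction,
                 seed = as.integer(seed), gamma = gamma, epsilon = epsilon,
                 classWeights = classWeights),
            class = "TrainConfig")
}

#' Behavioral class labels (index 0..3)
#' @return Character vector of the four behavior class names, in index order.
#' @export
behaviorClassLabels <- function() {
  c("estrus", "food_anticipating", "cough", "normal")
}
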