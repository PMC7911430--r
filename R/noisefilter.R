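magnitudeDb <- function(values) 20 * log10(Mod(values) + 1e-12)

#' Estimate per-frequency noise statistics and gate thresholds
#'
#' For each frequency bin, computes the mean and (population) standard
#' deviation of the dB magnitudes over time, and sets the spectral-gate
#' threshold to `mean + nStd * sd`. Statistics are taken in the dB domain,
#' matching how noise floors are usually summarized per frequency band.
#'
#' @param noiseStft [STFTMatrix-class] of a noise-only recording (at least
#'   2 time columns).
#' @param nStd threshold multiplier (default 1.5).
#' @return A [NoiseProfile-class].
#' @export
estimateNoiseProfile <- function(noiseStft, nStd = 1.5) {
  stopifnot(is(noiseStft, "STFTMatrix"))
  db <- magnitudeDb(noiseStft@values)
  if (ncol(db) < 2L)
    stop("estimateNoiseProfile: need at least 2 time columns for statistics")
  mu <- rowMeans(db)
  sigma <- sqrt(rowMeans((db - mu)^2))  # population sd over time
  new("NoiseProfile", meanPowerDb = mu, stdPowerDb = sigma,
      thresholdDb = mu + nStd * sigma, nStd = nStd)
}

#' Compute the raw (binary) spectral-gating mask
#'
#' A time-frequency bin passes (mask 1) when its dB magnitude exceeds the
#' noise threshold of its frequency bin, otherwise it is gated (mask 0).
#'
#' @param signalStft [STFTMatrix-class] of the clip to clean.
#' @param profile [NoiseProfile-class] with one threshold per bin.
#' @param smoothingKernel kernel stored on the mask for later
#'   [smoothMask()] (default 2 x 4 equal weights).
#' @return A binary [TimeFrequencyMask-class], same shape as the STFT.
#' @export
computeMask <- function(signalStft, profile,
                        smoothingKernel = defaultSmoothingKernel()) {
  stopifnot(is(signalStft, "STFTMatrix"), is(profile, "NoiseProfile"))
  if (nrow(signalStft@values) != length(profile@thresholdDb))
    stop("computeMask: frequency bin count mismatch between STFT and profile")
  db <- magnitudeDb(signalStft@values)
  raw <- (db > profile@thresholdDb) * 1
  new("TimeFrequencyMask", values = raw, smoothingKernel = smoothingKernel)
}

#' Smooth a time-frequency mask
#'
#' 2D convolution of the mask with its normalized smoothing kernel
#' (default 2 frequency channels x 4 time channels, equal weights),
#' zero-padded at the borders, yielding a soft mask in \[0, 1\] of the same
#' shape. Smoothing spreads isolated pass/stop decisions over their
#' neighbourhood and suppresses musical-noise artifacts.
#'
#' @param mask a [TimeFrequencyMask-class].
#' @return The smoothed [TimeFrequencyMask-class].
#' @export
smoothMask <- function(mask) {
  stopifnot(is(mask, "TimeFrequencyMask"))
  m <- mask@values
  k <- mask@smoothingKernel
  kr <- nrow(k); kc <- ncol(k)
  if (kr > nrow(m) || kc > ncol(m))
    stop("smoothMask: kernel larger than mask")
  # roughly centred anchor for even kernel dimensions
  r0 <- kr %/% 2L
  c0 <- kc %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      dr <- a - 1L - r0
      dc <- b - 1L - c0
      srcR <- seq_len(nr) + dr
      srcC <- seq_len(nc) + dc
      okR <- srcR >= 1L & srcR <= nr
      okC <- srcC >= 1L & srcC <= nc
      out[okR, okC] <- out[okR, okC] +
        k[a, b] * m[srcR[okR], srcC[okC], drop = FALSE]
    }
  }
  out <- pmin(pmax(out, 0), 1)
  new("TimeFrequencyMask", values = out, smoothingKernel = k)
}

#' Apply a mask to an STFT
#'
#' Element-wise product of complex STFT values and mask gains; a
#' contraction (per-bin output magnitude never exceeds the input).
#'
#' @param signalStft [STFTMatrix-class].
#' @param mask [TimeFrequencyMask-class] of the same shape.
#' @return The masked [STFTMatrix-class].
#' @export
applyMask <- function(signalStft, mask) {
  stopifnot(is(signalStft, "STFTMatrix"), is(mask, "TimeFrequencyMask"))
  if (!all(dim(signalStft@values) == dim(mask@values)))
    stop("applyMask: shape mismatch")
  out <- signalStft
  out@values <- signalStft@values * mask@values
  out
}

# Lowest-energy window of a clip, used as the noise reference when no
# dedicated noise recording is available.
quietestWindow <- function(x, sampleRate, windowSeconds = 0.5) {
  win <- min(length(x), max(1L, round(windowSeconds * sampleRate)))
  hop <- max(1L, win %/% 2L)
  starts <- seq.int(1L, max(1L, length(x) - win + 1L), by = hop)
  energies <- vapply(starts, function(s) sum(x[s:(s + win - 1L)]^2), numeric(1))
  s <- starts[which.min(energies)]
  x[s:(s + win - 1L)]
}

#' Spectral-gating noise removal
#'
#' End-to-end denoising of a clip: STFT, per-frequency noise thresholds
#' from a noise reference (an explicit noise recording, or by default the
#' lowest-energy 0.5 s window of the clip itself), binary gate, 2x4 mask
#' smoothing, masking, and inverse STFT. Output has the input's length and
#' metadata.
#'
#' @param segment the [AudioSegment-class] to clean.
#' @param noiseReference optional [AudioSegment-class] (or numeric vector)
#'   of noise only; `NULL` selects the quietest 0.5 s of `segment`.
#' @param config [STFTConfig-class] (default 2048/2048/256, Hann).
#' @param nStd gate threshold multiplier (default 1.5).
#' @param smoothingKernel mask smoothing kernel (default 2 x 4, equal).
#' @return The denoised [AudioSegment-class].
#' @examples
#' sr <- 8000
#' t <- seq(0, 1 - 1/sr, by = 1/sr)
#' noisy <- sin(2 * pi * 800 * t) * 0.5 + rnorm(sr, sd = 0.05)
#' seg <- AudioSegment(noisy, sr)
#' clean <- denoise(seg, config = STFTConfig(nFft = 1024, hop = 128))
#' @export
denoise <- function(segment, noiseReference = NULL, config = STFTConfig(),
                    nStd = 1.5, smoothingKernel = defaultSmoothingKernel()) {
  stopifnot(is(segment, "AudioSegment"))
  x <- segment@samples
  sr <- segment@sampleRate
  L <- length(x)
  win <- config@winLength
  hop <- config@hop
  if (L < win) stop("denoise: clip shorter than one analysis window")
  # pad so frames tile the clip completely, then trim after reconstruction
  rem <- (L - win) %% hop
  xp <- if (rem == 0L) x else c(x, numeric(hop - rem))

  sig <- stft(xp, config = config, sampleRate = sr)

  noise <- if (is.null(noiseReference)) {
    quietestWindow(x, sr)
  } else if (is(noiseReference, "AudioSegment")) {
    noiseReference@samples
  } else {
    as.numeric(noiseReference)
  }
  if (length(noise) < win) {
    # analyze a short noise reference with a correspondingly shorter window
    nf <- max(4L, 2L^floor(log2(length(noise))))
    ncfg <- STFTConfig(nFft = config@nFft,
                       winLength = min(nf, config@nFft),
                       hop = max(1L, min(nf, config@nFft) %/% 8L),
                       windowFn = config@windowFn)
    profile <- estimateNoiseProfile(stft(noise, ncfg, sampleRate = sr), nStd)
  } else {
    ncfg <- STFTConfig(nFft = config@nFft, winLength = win,
                       hop = max(1L, win %/% 8L), windowFn = config@windowFn)
    profile <- estimateNoiseProfile(stft(noise, ncfg, sampleRate = sr), nStd)
  }

  mask <- smoothMask(computeMask(sig, profile,
                                 smoothingKernel = smoothingKernel))
  cleaned <- istft(applyMask(sig, mask))
  y <- cleaned@samples[seq_len(L)]
  AudioSegment(y, sampleRate = sr, startTime = segment@startTime,
               sensorId = segment@sensorId, zoneId = segment@zoneId,
               calibrationOffset = segment@calibrationOffset)
}
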