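#' Mel scale conversions
#'
#' The standard Mel mapping `m = 2595 * log10(1 + f/700)` and its inverse;
#' a strictly increasing bijection with `melScale(0) == 0`.
#'
#' @param hz frequency in Hz (non-negative).
#' @param mel value on the Mel scale (non-negative).
#' @return The converted value(s).
#' @examples
#' melScale(1000)          # ~ 1000 by construction of the scale
#' invMelScale(melScale(440))
#' @export
melScale <- function(hz) {
  if (any(hz < 0)) stop("melScale: frequency must be non-negative")
  2595 * log10(1 + hz / 700)
}

#' @rdname melScale
#' @export
invMelScale <- function(mel) {
  if (any(mel < 0)) stop("invMelScale: mel value must be non-negative")
  700 * (10^(mel / 2595) - 1)
}

#' Build a triangular Mel filter bank
#'
#' The M + 2 boundary frequencies are equally spaced on the Mel scale
#' between `fMin` and `fMax`, mapped to (integer) FFT bin positions. Row m
#' of the weight matrix is zero outside `(f(m-1), f(m+1))`, rises linearly
#' to 1 at the centre bin `f(m)` and falls linearly back to zero, so
#' adjacent filters overlap and their weights sum to 1 between centres.
#'
#' @param M number of filters (default 128).
#' @param nFft FFT length the bank applies to (bins `0..nFft/2`).
#' @param sampleRate sampling rate in Hz.
#' @param fMin,fMax frequency range covered (defaults 0 to Nyquist).
#' @return A [MelFilterBank-class].
#' @export
buildFilterBank <- function(M = 128L, nFft = 2048L, sampleRate = 16000,
                            fMin = 0, fMax = sampleRate / 2) {
  M <- as.integer(M)
  nFft <- as.integer(nFft)
  if (M < 1L) stop("buildFilterBank: M must be >= 1")
  if (!(fMin < fMax && fMax <= sampleRate / 2))
    stop("buildFilterBank: need fMin < fMax <= Nyquist")
  nBins <- nFft %/% 2L + 1L
  mels <- seq(melScale(fMin), melScale(fMax), length.out = M + 2L)
  hz <- invMelScale(mels)
  bounds <- round(hz * nFft / sampleRate)
  bounds <- pmin(pmax(bounds, 0), nBins - 1L)
  if (any(diff(bounds) < 1))
    stop("buildFilterBank: M too large for the available frequency ",
         "resolution (adjacent filter boundaries collide)")
  k <- 0:(nBins - 1L)
  W <- matrix(0, nrow = M, ncol = nBins)
  for (m in seq_len(M)) {
    lo <- bounds[m]; mid <- bounds[m + 1L]; hi <- bounds[m + 2L]
    rise <- k >= lo & k <= mid
    fall <- k > mid & k <= hi
    W[m, rise] <- (k[rise] - lo) / (mid - lo)
    W[m, fall] <- (hi - k[fall]) / (hi - mid)
  }
  new("MelFilterBank", weights = W, boundaries = as.numeric(bounds), M = M,
      sampleRate = as.numeric(sampleRate), nFft = nFft)
}

#' Filter-bank energies and their logarithm
#'
#' Multiplies each power-spectrum frame by the triangular filters
#' (`E = weights %*% P`) and takes the floored logarithm
#' `Elog = log(E + floorEpsilon)`.
#'
#' @param powerSpectrum non-negative matrix, frequency bins x frames.
#' @param bank a [MelFilterBank-class] with matching bin count.
#' @param floorEpsilon additive guard against `log(0)` (default 1e-10).
#' @return List with components `E` and `Elog` (both M x frames).
#' @export
filterBankEnergies <- function(powerSpectrum, bank, floorEpsilon = 1e-10) {
  stopifnot(is(bank, "MelFilterBank"))
  P <- as.matrix(powerSpectrum)
  if (any(P < 0)) stop("filterBankEnergies: power spectrum must be non-negative")
  if (nrow(P) != ncol(bank@weights))
    stop("filterBankEnergies: bin count mismatch")
  E <- bank@weights %*% P
  list(E = E, Elog = log(E + floorEpsilon))
}

#' Discrete cosine transform of log filter-bank energies
#'
#' Per frame, `MFCC(n) = sum_m Elog(m) * cos(n * (m - 1/2) * pi / M)` for
#' `n = 1..M` (unnormalized DCT-II family). A constant row pattern maps to
#' zero in every coefficient, making the cepstrum invariant to uniform
#' gain changes.
#'
#' @param Elog M x frames matrix of log energies.
#' @return M x frames matrix of cepstral coefficients.
#' @export
dctCoefficients <- function(Elog) {
  Elog <- as.matrix(Elog)
  M <- nrow(Elog)
  n <- seq_len(M)
  m <- seq_len(M)
  D <- cos(outer(n, m - 0.5) * pi / M)
  D %*% Elog
}

#' Fixed-width MFCC (or log-Mel) features of a clip
#'
#' Full feature pipeline: one-sided STFT power spectrum, triangular Mel
#' filter-bank energies, floored log, DCT (skipped for
#' `representation = "logmel"`), then right-side zero-padding or truncation
#' to exactly `tFixed` time frames. Defaults produce the 128 x 2000
#' classifier input of the full-scale pipeline.
#'
#' @param segment an [AudioSegment-class] or numeric vector.
#' @param M number of Mel bands / retained coefficients (default 128).
#' @param tFixed fixed frame target (default 2000).
#' @param config [STFTConfig-class] (default 2048/2048/256, Hann).
#' @param sampleRate required for bare numeric input.
#' @param representation `"mfcc"` (post-DCT, default) or `"logmel"`.
#' @param keepLogEnergies retain the intermediate `Elog` matrix.
#' @param floorEpsilon see [filterBankEnergies()].
#' @return An [MFCCMatrix-class] of dimension M x tFixed.
#' @export
mfccFeatures <- function(segment, M = 128L, tFixed = 2000L,
                         config = STFTConfig(), sampleRate = NULL,
                         representation = c("mfcc", "logmel"),
                         keepLogEnergies = FALSE, floorEpsilon = 1e-10) {
  representation <- match.arg(representation)
  S <- stft(segment, config = config, sampleRate = sampleRate)
  P <- Mod(S@values)^2
  bank <- buildFilterBank(M = M, nFft = config@nFft,
                          sampleRate = S@sampleRate)
  fb <- filterBankEnergies(P, bank, floorEpsilon = floorEpsilon)
  feat <- if (representation == "mfcc") dctCoefficients(fb$Elog) else fb$Elog
  tFixed <- as.integer(tFixed)
  nT <- ncol(feat)
  if (nT >= tFixed) {
    feat <- feat[, seq_len(tFixed), drop = FALSE]
  } else {
    feat <- cbind(feat, matrix(0, nrow(feat), tFixed - nT))
  }
  new("MFCCMatrix", coefficients = feat,
      logEnergies = if (keepLogEnergies) fb$Elog else NULL,
      tFixed = tFixed, representation = representation)
}
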