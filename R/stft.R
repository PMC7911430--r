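#' Short-time Fourier transform
#'
#' Windowed DFT of successive frames: column `l` holds the one-sided DFT of
#' `w(n) * x(n + l*hop)` for `n = 0..winLength-1` (zero-padded to `nFft`).
#' Frames are non-centred and start at sample 0; a clip of `L` samples
#' yields `1 + floor((L - winLength)/hop)` columns.
#'
#' @param segment an [AudioSegment-class] or numeric vector.
#' @param config an [STFTConfig-class] (default 2048/2048/256, Hann).
#' @param sampleRate required when `segment` is a bare vector.
#' @return An [STFTMatrix-class] with `nFft/2 + 1` frequency-bin rows.
#' @seealso [istft()], [denoise()]
#' @export
stft <- function(segment, config = STFTConfig(), sampleRate = NULL) {
  if (is(segment, "AudioSegment")) {
    x <- segment@samples
    sampleRate <- segment@sampleRate
  } else {
    x <- as.numeric(segment)
    if (is.null(sampleRate)) stop("stft: sampleRate required for numeric input")
  }
  win <- config@winLength
  hop <- config@hop
  nFft <- config@nFft
  L <- length(x)
  if (L < win)
    stop("stft: clip shorter than one analysis window (", L, " < ", win, ")")
  starts <- seq.int(1L, L - win + 1L, by = hop)
  w <- makeWindow(win, config@windowFn)
  frames <- matrix(x[outer(seq_len(win) - 1L, starts, `+`)], nrow = win)
  frames <- frames * w
  if (nFft > win)
    frames <- rbind(frames, matrix(0, nFft - win, ncol(frames)))
  spec <- mvfft(frames)[seq_len(nFft %/% 2L + 1L), , drop = FALSE]
  new("STFTMatrix", values = spec, config = config,
      sampleRate = as.numeric(sampleRate), nSamples = L)
}

#' Inverse short-time Fourier transform
#'
#' Weighted overlap-add reconstruction: each column is inverse-transformed,
#' multiplied by the synthesis window (same taper as analysis) and summed;
#' the result is normalized by the summed squared window. For a
#' constant-overlap-add window/hop pair this reproduces the interior of the
#' original clip to floating-point accuracy.
#'
#' @param matrix an [STFTMatrix-class].
#' @return An [AudioSegment-class] of the original clip length.
#' @export
istft <- function(matrix) {
  stopifnot(is(matrix, "STFTMatrix"))
  cfg <- matrix@config
  nFft <- cfg@nFft
  win <- cfg@winLength
  hop <- cfg@hop
  X <- matrix@values
  nFrames <- ncol(X)
  # rebuild the full conjugate-symmetric spectrum
  if (nFft %% 2L == 0L) {
    full <- rbind(X, Conj(X[seq.int(nFft %/% 2L, 2L), , drop = FALSE]))
  } else {
    full <- rbind(X, Conj(X[seq.int((nFft + 1L) %/% 2L, 2L), , drop = FALSE]))
  }
  frames <- Re(mvfft(full, inverse = TRUE)) / nFft
  frames <- frames[seq_len(win), , drop = FALSE]
  w <- makeWindow(win, cfg@windowFn)
  covered <- (nFrames - 1L) * hop + win
  num <- numeric(covered)
  den <- numeric(covered)
  w2 <- w * w
  for (l in seq_len(nFrames)) {
    idx <- ((l - 1L) * hop + 1L):((l - 1L) * hop + win)
    num[idx] <- num[idx] + frames[, l] * w
    den[idx] <- den[idx] + w2
  }
  interior <- num
  if (covered > 2L * win) {
    core <- den[(win + 1L):(covered - win)]
    if (length(core) && min(core) < 1e-8)
      stop("istft: window/hop pair does not satisfy constant overlap-add")
  }
  # clamp the normalizer at the clip edges: where the summed squared window
  # is tiny, dividing would amplify spectral leakage of a modified STFT
  floorDen <- 0.01 * max(den)
  y <- num / pmax(den, floorDen)
  L <- matrix@nSamples
  y <- if (covered >= L) y[seq_len(L)] else c(y, numeric(L - covered))
  AudioSegment(y, sampleRate = matrix@sampleRate)
}
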