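# Shared fixtures and oracles. The desk-scale study conditions used
# throughout the suite: 8 kHz clips, STFT 1024/1024/512, 64 mel bands,
# 128-frame feature target.

fixtureStftConfig <- function() {
  STFTConfig(nFft = 1024L, winLength = 1024L, hop = 512L)
}

fixtureFeatures <- function(segments) {
  cfg <- fixtureStftConfig()
  lapply(segments, function(s)
    mfccFeatures(s, M = 64L, tFixed = 128L, config = cfg))
}

snrDbOf <- function(reference, x) {
  10 * log10(mean(reference^2) / mean((reference - x)^2))
}

bandEnergy <- function(x, sampleRate, lo, hi) {
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) / length(x) * sampleRate
  f <- pmin(f, sampleRate - f)
  sum(p[f >= lo & f < hi])
}

spectralCentroid <- function(x, sampleRate) {
  p <- Mod(stats::fft(x))^2
  n <- length(x)
  f <- (seq_len(n) - 1) / n * sampleRate
  half <- seq_len(n %/% 2)
  sum(f[half] * p[half]) / sum(p[half])
}

# autocorrelation f0 oracle: earliest near-maximal peak in the admissible
# lag range (avoids octave errors from the lag-2T peak of periodic signals)
estimateF0 <- function(x, sampleRate, f0Low, f0High) {
  nz <- which(abs(x) > 0.05 * max(abs(x)))
  seg <- x[nz[1]:nz[length(nz)]]
  lags <- seq(floor(sampleRate / f0High), ceiling(sampleRate / f0Low))
  ac <- stats::acf(seg, lag.max = max(lags), plot = FALSE,
                   demean = FALSE)$acf[-1]
  acr <- ac[lags]
  sampleRate / lags[min(which(acr >= 0.95 * max(acr)))]
}

# straight-line brute-force log-Mel/DCT pipeline (Eq-by-Eq loops), the
# independent oracle for the vectorized feature path
bruteForceMfcc <- function(x, sampleRate, M, nFft, winLength, hop) {
  nBins <- nFft %/% 2 + 1
  starts <- seq(1, length(x) - winLength + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(winLength) - 1) / winLength)
  P <- matrix(0, nBins, length(starts))
  for (l in seq_along(starts)) {
    frame <- x[starts[l]:(starts[l] + winLength - 1)] * w
    frame <- c(frame, numeric(nFft - winLength))
    X <- stats::fft(frame)
    P[, l] <- Mod(X[seq_len(nBins)])^2
  }
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  bounds <- round(imel(seq(mel(0), mel(sampleRate / 2), length.out = M + 2)) *
                  nFft / sampleRate)
  B <- matrix(0, M, nBins)
  for (m in seq_len(M)) {
    for (kk in 0:(nBins - 1)) {
      if (kk >= bounds[m] && kk <= bounds[m + 1]) {
        B[m, kk + 1] <- (kk - bounds[m]) / (bounds[m + 1] - bounds[m])
      } else if (kk > bounds[m + 1] && kk <= bounds[m + 2]) {
        B[m, kk + 1] <- (bounds[m + 2] - kk) / (bounds[m + 2] - bounds[m + 1])
      }
    }
  }
  E <- matrix(0, M, ncol(P))
  for (l in seq_len(ncol(P)))
    for (m in seq_len(M))
      E[m, l] <- sum(B[m, ] * P[, l])
  Elog <- log(E + 1e-10)
  out <- matrix(0, M, ncol(P))
  for (l in seq_len(ncol(P)))
    for (n in seq_len(M))
      out[n, l] <- sum(Elog[, l] * cos(n * (seq_len(M) - 0.5) * pi / M))
  out
}

# desk-scale corpus and classifiers, trained once per suite run and shared
# between the end-to-end acceptance checks and the monitoring tests
.fixtureCache <- new.env(parent = emptyenv())

acceptanceFixture <- function() {
  if (!is.null(.fixtureCache$fx)) return(.fixtureCache$fx)
  ds <- makeDataset(nPerClass = 100L, seed = 7L, sampleRate = 8000,
                    audio = "memory")
  feats <- fixtureFeatures(ds$segments)

  t0 <- proc.time()[3]
  binary <- train(buildBinaryCnn(c(64L, 128L)), feats,
                  ds$manifest$binary_label,
                  trainConfig(epochs = 20L, seed = 7L))
  binarySeconds <- proc.time()[3] - t0

  isCall <- ds$manifest$binary_label == 1L
  t0 <- proc.time()[3]
  behavior <- train(buildBehaviorCnn(c(64L, 128L)), feats[isCall],
                    ds$manifest$behavior_label[isCall],
                    trainConfig(epochs = 30L, seed = 7L))
  behaviorSeconds <- proc.time()[3] - t0

  .fixtureCache$fx <- list(
    dataset = ds, features = feats,
    binary = binary, behavior = behavior,
    binarySeconds = binarySeconds, behaviorSeconds = behaviorSeconds
  )
  .fixtureCache$fx
}
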