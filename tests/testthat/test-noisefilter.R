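fakeStft <- function(valueMatrix, nFft = NULL, sampleRate = 8000) {
  if (is.null(nFft)) nFft <- 2L * (nrow(valueMatrix) - 1L)
  cfg <- STFTConfig(nFft = as.integer(nFft),
                    winLength = as.integer(nFft),
                    hop = as.integer(max(1, nFft %/% 4)))
  new("STFTMatrix", values = valueMatrix, config = cfg,
      sampleRate = sampleRate, nSamples = as.integer(nFft))
}

test_that("noise profiles reduce to per-bin dB statistics", {
  # constant magnitude: zero spread, threshold equals the mean
  S <- fakeStft(matrix(complex(modulus = 2, argument = 0.3), 17, 6))
  p <- estimateNoiseProfile(S, nStd = 1.5)
  expect_equal(p@stdPowerDb, rep(0, 17))
  expect_equal(p@thresholdDb, p@meanPowerDb)

  # two columns {a, b}: dB mean (a+b)/2 and population sd |a-b|/2 per bin
  a <- 20 * log10(c(1, 2, 4) + 1e-12)
  b <- 20 * log10(c(3, 2, 1) + 1e-12)
  S2 <- fakeStft(matrix(complex(modulus = c(1, 2, 4, 3, 2, 1)), 3, 2),
                 nFft = 4)
  p2 <- estimateNoiseProfile(S2, nStd = 2)
  expect_equal(p2@meanPowerDb, (a + b) / 2)
  expect_equal(p2@stdPowerDb, abs(a - b) / 2)
  expect_equal(p2@thresholdDb, (a + b) / 2 + 2 * abs(a - b) / 2)

  expect_error(estimateNoiseProfile(fakeStft(matrix(complex(modulus = 1),
                                                    17, 1))),
               "2 time columns")
})

test_that("white-noise thresholds are roughly flat across frequency", {
  x <- withr::with_seed(8, rnorm(4 * 8000))
  S <- stft(x, STFTConfig(nFft = 1024L, hop = 256L), sampleRate = 8000)
  p <- estimateNoiseProfile(S)
  cv <- sd(p@thresholdDb) / abs(mean(p@thresholdDb))
  expect_lt(cv, 0.2)
})

test_that("the raw mask is a per-bin binary gate against the threshold", {
  vals <- matrix(complex(modulus = 10), 17, 5)
  S <- fakeStft(vals)
  pLow <- new("NoiseProfile", meanPowerDb = rep(0, 17),
              stdPowerDb = rep(1, 17), thresholdDb = rep(10, 17), nStd = 1.5)
  expect_true(all(values(computeMask(S, pLow)) == 1))   # 10 dB above gate

  pHigh <- new("NoiseProfile", meanPowerDb = rep(25, 17),
               stdPowerDb = rep(1, 17), thresholdDb = rep(30, 17), nStd = 1.5)
  expect_true(all(values(computeMask(S, pHigh)) == 0))

  pBad <- new("NoiseProfile", meanPowerDb = rep(0, 5), stdPowerDb = rep(0, 5),
              thresholdDb = rep(0, 5), nStd = 1)
  expect_error(computeMask(S, pBad), "mismatch")
})

test_that("sub-400 Hz hum is gated more than the call band", {
  sr <- 8000
  g <- generateCall(CallSpec(3, f0Range = c(450, 600), seed = 30),
                    sampleRate = sr)
  noisy <- addNoise(g$segment, NoiseSpec("low_band_hum", snrDb = 0,
                                         seed = 31))
  S <- stft(noisy, STFTConfig(nFft = 1024L, hop = 256L))
  humOnly <- samples(noisy)[1:sr]           # pre-call second: hum-dominated
  prof <- estimateNoiseProfile(stft(humOnly, S@config, sampleRate = sr))
  m <- values(computeMask(S, prof))
  binHz <- (seq_len(nrow(m)) - 1) * sr / 1024
  humRows <- binHz < 400
  callRows <- binHz >= 400 & binHz < 2000
  expect_lt(mean(m[humRows, ]), mean(m[callRows, ]))
})

test_that("mask smoothing is a mass-preserving 2x4 local average", {
  k <- defaultSmoothingKernel()
  expect_equal(dim(k), c(2L, 4L))
  expect_equal(sum(k), 1)

  ones <- new("TimeFrequencyMask", values = matrix(1, 20, 30),
              smoothingKernel = k)
  sm <- values(smoothMask(ones))
  expect_true(all(sm[3:18, 4:27] == 1))     # interior stays 1
  expect_true(all(sm <= 1))

  spike <- matrix(0, 20, 30); spike[10, 15] <- 1
  sm2 <- values(smoothMask(new("TimeFrequencyMask", values = spike,
                               smoothingKernel = k)))
  expect_equal(sum(sm2), 1)                  # mass conserved
  expect_equal(sum(sm2 > 0), 8L)             # spread over a 2x4 neighbourhood
  expect_true(all(sm2[sm2 > 0] == 1 / 8))

  # checkerboard equals a direct double-loop convolution oracle
  cb <- outer(1:12, 1:16, function(i, j) (i + j) %% 2)
  sm3 <- values(smoothMask(new("TimeFrequencyMask", values = cb,
                               smoothingKernel = k)))
  oracle <- matrix(0, 12, 16)
  for (i in 1:12) for (j in 1:16) {
    acc <- 0
    for (a in 1:2) for (b in 1:4) {
      si <- i + (a - 2L); sj <- j + (b - 3L)
      if (si >= 1 && si <= 12 && sj >= 1 && sj <= 16)
        acc <- acc + k[a, b] * cb[si, sj]
    }
    oracle[i, j] <- acc
  }
  expect_equal(sm3, oracle)
})

test_that("masking is a per-bin contraction", {
  x <- withr::with_seed(9, rnorm(16000))
  S <- stft(x, STFTConfig(nFft = 1024L, hop = 256L), sampleRate = 8000)
  prof <- estimateNoiseProfile(S)
  sm <- smoothMask(computeMask(S, prof))
  masked <- applyMask(S, sm)
  expect_true(all(Mod(values(masked)) <= Mod(values(S)) + 1e-12))
})

test_that("denoise preserves a clean call and suppresses pure noise", {
  sr <- 8000
  g <- generateCall(CallSpec(3, f0Range = c(450, 600), seed = 40),
                    sampleRate = sr)
  clean <- samples(g$segment)
  out <- denoise(g$segment)
  expect_length(samples(out), length(clean))
  expect_gte(snrDbOf(clean, samples(out)), 30)

  n <- withr::with_seed(41, rnorm(2 * sr) * 0.1)
  seg <- AudioSegment(n, sr)
  quiet <- denoise(seg, noiseReference = seg)
  expect_lte(sqrt(mean(samples(quiet)^2) / mean(n^2)), 0.2)
})

test_that("denoising a 0 dB SNR clip improves SNR by at least 6 dB", {
  sr <- 8000
  g <- generateCall(CallSpec(0, seed = 42), sampleRate = sr)
  clean <- samples(g$segment)
  noise <- withr::with_seed(43, rnorm(length(clean)))
  noise <- noise * sqrt(mean(clean^2) / mean(noise^2))
  mix <- clean + noise
  sc <- max(1, max(abs(mix)))
  out <- denoise(AudioSegment(mix / sc, sr))
  expect_gte(snrDbOf(clean / sc, samples(out)), 6)  # input SNR is exactly 0
})

test_that("denoising is nearly idempotent", {
  sr <- 8000
  g <- generateCall(CallSpec(0, seed = 44), sampleRate = sr)
  noisy <- addNoise(g$segment, NoiseSpec("white", snrDb = 5, seed = 45))
  once <- denoise(noisy)
  twice <- denoise(once)
  r1 <- sqrt(mean(samples(once)^2))
  r2 <- sqrt(mean(samples(twice)^2))
  expect_lt(abs(r2 - r1) / r1, 0.05)
})

test_that("extreme gate multipliers give identity and silence", {
  sr <- 8000
  x <- withr::with_seed(46, rnorm(2 * sr) * 0.3)
  seg <- AudioSegment(x, sr)
  passAll <- denoise(seg, noiseReference = seg, nStd = -100)
  interior <- 2049:(length(x) - 2048)
  # near-identity: only reconstruction edges and the smoothed DC row deviate
  expect_gte(snrDbOf(x[interior], samples(passAll)[interior]), 30)
  silence <- denoise(seg, noiseReference = seg, nStd = 100)
  expect_lte(sqrt(mean(samples(silence)^2) / mean(x^2)), 1e-6)
})
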