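test_that("the Mel scale is the standard increasing bijection", {
  expect_equal(melScale(0), 0)
  expect_lt(abs(melScale(1000) - 1000), 1)   # ~1000 mel at 1 kHz
  f <- c(1, 50, 440, 3999.5)
  expect_equal(invMelScale(melScale(f)), f, tolerance = 1e-9)
  expect_true(all(diff(melScale(seq(0, 4000, by = 10))) > 0))
  expect_error(melScale(-1), "non-negative")
  expect_error(invMelScale(-5), "non-negative")
})

test_that("triangular filters peak at 1 and vanish outside their support", {
  bank <- buildFilterBank(M = 16L, nFft = 256L, sampleRate = 8000)
  W <- bank@weights
  b <- bank@boundaries
  for (m in seq_len(16)) {
    expect_equal(W[m, b[m + 1] + 1], 1)                    # apex
    outside <- setdiff(seq_len(ncol(W)) - 1L, seq(b[m], b[m + 2]))
    expect_true(all(W[m, outside + 1L] == 0))              # zero branches
  }
  expect_error(buildFilterBank(M = 200L, nFft = 64L, sampleRate = 8000),
               "collide")
  expect_error(buildFilterBank(M = 4L, nFft = 64L, sampleRate = 8000,
                               fMin = 5000), "Nyquist")
})

test_that("adjacent filters sum to one between their centres", {
  bank <- buildFilterBank(M = 4L, nFft = 64L, sampleRate = 8000)
  W <- bank@weights
  b <- bank@boundaries
  for (m in 1:3) {
    between <- seq(b[m + 1], b[m + 2])    # from centre m to centre m+1
    expect_equal(W[m, between + 1] + W[m + 1, between + 1],
                 rep(1, length(between)))
  }
})

test_that("filter-bank energies match direct matrix multiplication", {
  bank <- buildFilterBank(M = 4L, nFft = 64L, sampleRate = 8000)
  nBins <- 33L

  z <- filterBankEnergies(matrix(0, nBins, 3), bank)
  expect_true(all(z$Elog == log(1e-10)))

  # unit impulse at the centre bin of filter 2
  centre <- bank@boundaries[3] + 1L
  P <- matrix(0, nBins, 1); P[centre, 1] <- 5
  e <- filterBankEnergies(P, bank)
  expect_equal(e$E[2, 1], 5)                       # apex weight is 1
  expect_equal(e$E[3, 1], 5 * bank@weights[3, centre])

  Pr <- withr::with_seed(10, matrix(runif(nBins * 4), nBins, 4))
  er <- filterBankEnergies(Pr, bank)
  expect_equal(er$E, bank@weights %*% Pr)
  expect_error(filterBankEnergies(-Pr, bank), "non-negative")
})

test_that("the DCT stage follows the unnormalized cosine sum", {
  # constant log-energy rows are annihilated (DC orthogonality)
  const <- matrix(3.7, 8, 5)
  expect_lt(max(abs(dctCoefficients(const))), 1e-9 * 8 * 3.7)

  # M = 2 hand evaluation
  ab <- matrix(c(2, 5), 2, 1)
  d <- dctCoefficients(ab)
  expect_equal(d[1, 1], (2 - 5) * cos(pi / 4))
  expect_equal(d[2, 1], 0, tolerance = 1e-12)   # cos((m-1/2)pi) = 0

  # a DCT basis row maps to a single nonzero coefficient (M/2)
  M <- 8
  j <- 3
  basis <- matrix(cos(j * (seq_len(M) - 0.5) * pi / M), M, 1)
  dj <- dctCoefficients(basis)
  expect_equal(dj[j, 1], M / 2)
  expect_lt(max(abs(dj[-j, 1])), 1e-9)
})

test_that("toy pipeline equals the straight-line brute-force oracle", {
  sr <- 8000
  x <- withr::with_seed(11, rnorm(900))
  cfg <- STFTConfig(nFft = 64L, winLength = 64L, hop = 32L)
  got <- values(mfccFeatures(x, M = 4L, tFixed = 40L, config = cfg,
                             sampleRate = sr))
  oracle <- bruteForceMfcc(x, sr, M = 4, nFft = 64, winLength = 64, hop = 32)
  expect_lt(max(abs(got[, seq_len(ncol(oracle))] - oracle)), 1e-9)
  expect_true(all(got[, (ncol(oracle) + 1):40] == 0))   # right zero-padding
})

test_that("the full-scale pipeline yields a 128 x 2000 matrix", {
  sr <- 16000
  g <- generateCall(CallSpec(0, seed = 12), sampleRate = sr, clipSeconds = 5)
  f <- mfccFeatures(g$segment)           # defaults: 128 mels, 2000 frames
  expect_equal(dim(f), c(128L, 2000L))
  nFrames <- 1L + (5L * sr - 2048L) %/% 256L   # framing-convention oracle
  expect_true(any(values(f)[, nFrames] != 0))
  expect_true(all(values(f)[, (nFrames + 1L):2000L] == 0))
})

test_that("silent clips produce identical computed columns", {
  cfg <- STFTConfig(nFft = 512L, winLength = 512L, hop = 256L)
  f <- values(mfccFeatures(numeric(4000), M = 16L, tFixed = 32L,
                           config = cfg, sampleRate = 8000))
  computed <- f[, 1:14]
  expect_true(all(computed == computed[, 1]))
})

test_that("long clips are truncated to exactly tFixed frames", {
  cfg <- STFTConfig(nFft = 512L, winLength = 512L, hop = 256L)
  x <- withr::with_seed(13, rnorm(16000))
  short <- mfccFeatures(x, M = 16L, tFixed = 10L, config = cfg,
                        sampleRate = 8000)
  full <- mfccFeatures(x, M = 16L, tFixed = 80L, config = cfg,
                       sampleRate = 8000)
  expect_equal(dim(short), c(16L, 10L))
  expect_equal(values(short), values(full)[, 1:10])
})

test_that("feature extraction is deterministic and gain-invariant", {
  cfg <- STFTConfig(nFft = 512L, winLength = 512L, hop = 256L)
  x <- withr::with_seed(14, rnorm(8000))
  f1 <- values(mfccFeatures(x, M = 16L, tFixed = 30L, config = cfg,
                            sampleRate = 8000))
  f2 <- values(mfccFeatures(x, M = 16L, tFixed = 30L, config = cfg,
                            sampleRate = 8000))
  expect_identical(f1, f2)

  # scaling the waveform leaves post-DCT coefficients unchanged
  f3 <- values(mfccFeatures(3 * x, M = 16L, tFixed = 30L, config = cfg,
                            sampleRate = 8000))
  expect_lt(max(abs(f3 - f1)), 1e-8)

  # and shifts log-Mel features by a constant 2*log(c)
  l1 <- values(mfccFeatures(x, M = 16L, tFixed = 30L, config = cfg,
                            sampleRate = 8000, representation = "logmel"))
  l3 <- values(mfccFeatures(3 * x, M = 16L, tFixed = 30L, config = cfg,
                            sampleRate = 8000, representation = "logmel"))
  expect_equal(l3 - l1, matrix(2 * log(3), 16, 30), tolerance = 1e-6)
})
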