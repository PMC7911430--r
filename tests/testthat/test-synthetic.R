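test_that("call generation is deterministic per seed", {
  a <- generateCall(CallSpec(0, seed = 50), sampleRate = 8000)
  b <- generateCall(CallSpec(0, seed = 50), sampleRate = 8000)
  expect_identical(samples(a$segment), samples(b$segment))
  expect_identical(a$f0, b$f0)
  c <- generateCall(CallSpec(0, seed = 51), sampleRate = 8000)
  expect_false(identical(samples(a$segment), samples(c$segment)))
})

test_that("class signatures are acoustically distinct", {
  # cough (class 2) is broadband: higher spectral centroid than normal calls
  for (s in 0:9) {
    c2 <- spectralCentroid(samples(generateCall(CallSpec(2, seed = s),
                                                sampleRate = 8000)$segment),
                           8000)
    c3 <- spectralCentroid(samples(generateCall(CallSpec(3, seed = s),
                                                sampleRate = 8000)$segment),
                           8000)
    expect_gt(c2, c3)
  }
})

test_that("the generated fundamental matches an autocorrelation oracle", {
  for (s in 0:9) {
    g <- generateCall(CallSpec(3, seed = s), sampleRate = 16000)
    est <- estimateF0(samples(g$segment), 16000, 80, 180)
    expect_lt(abs(est - g$f0) / g$f0, 0.05)
  }
})

test_that("calls are embedded after the first two seconds of the clip", {
  for (s in 0:4) {
    g <- generateCall(CallSpec(3, seed = s), sampleRate = 8000,
                      clipSeconds = 5)
    x <- samples(g$segment)
    onset <- which(abs(x) > 0.01 * max(abs(x)))[1] / 8000
    expect_gte(onset, 1.5)
    expect_lte(onset, 3.1)
    expect_equal(length(x), 40000L)
  }
})

test_that("invalid call specifications are rejected", {
  expect_error(CallSpec(7), "classIndex")
  expect_error(CallSpec(0, f0Range = c(20, 100)), "f0Range")
  expect_error(CallSpec(0, durationRange = c(-1, 1)), "positive")
})

test_that("addNoise reaches the target SNR exactly", {
  sr <- 8000
  x <- 0.1 * sin(2 * pi * 500 * seq(0, 2 - 1 / sr, by = 1 / sr))
  seg <- AudioSegment(x, sr)
  for (target in c(-5, 0, 10)) {
    noisy <- addNoise(seg, NoiseSpec("white", snrDb = target, seed = 52))
    achieved <- 10 * log10(mean(x^2) / mean((samples(noisy) - x)^2))
    expect_lt(abs(achieved - target), 0.5)
  }

  # at 0 dB the powers add: output RMS ~ sqrt(2) x signal RMS
  noisy0 <- addNoise(seg, NoiseSpec("white", snrDb = 0, seed = 53))
  expect_equal(sqrt(mean(samples(noisy0)^2)) / sqrt(mean(x^2)), sqrt(2),
               tolerance = 0.02)

  # the noiseless limit is the identity
  expect_identical(samples(addNoise(seg, NoiseSpec("white", snrDb = Inf))),
                   x)

  expect_error(addNoise(AudioSegment(c(0, 0, 0), sr),
                        NoiseSpec("white", snrDb = 10)), "silent")
})

test_that("hum noise concentrates its power below the band limit", {
  sr <- 8000
  x <- 0.1 * sin(2 * pi * 1000 * seq(0, 2 - 1 / sr, by = 1 / sr))
  seg <- AudioSegment(x, sr)
  noisy <- addNoise(seg, NoiseSpec("low_band_hum", snrDb = 0, seed = 54))
  noise <- samples(noisy) - x
  frac <- bandEnergy(noise, sr, 0, 400) / bandEnergy(noise, sr, 0, sr / 2)
  expect_gte(frac, 0.9)
})

test_that("transient and speech-like noise kinds are generated", {
  sr <- 8000
  x <- 0.1 * sin(2 * pi * 500 * seq(0, 3 - 1 / sr, by = 1 / sr))
  seg <- AudioSegment(x, sr)
  for (kind in c("transient_clang", "speech_like")) {
    noisy <- addNoise(seg, NoiseSpec(kind, snrDb = 3, seed = 55))
    achieved <- 10 * log10(mean(x^2) / mean((samples(noisy) - x)^2))
    expect_lt(abs(achieved - 3), 0.5)
  }
  nv <- generateNonvocal("transient_clang", sampleRate = sr, seed = 56)
  expect_s4_class(nv, "AudioSegment")
  expect_gt(max(abs(samples(nv))), 0.4)
})

test_that("dataset manifests count and label clips correctly", {
  ds <- makeDataset(nPerClass = 5L, seed = 60L, sampleRate = 4000,
                    audio = "none")
  expect_equal(nrow(ds$manifest), 25L)            # 4 classes + nonvocal
  expect_equal(sum(ds$manifest$binary_label), 20L)
  expect_equal(unname(table(ds$manifest$behavior_label)), rep(5L, 4),
               ignore_attr = TRUE)

  imb <- makeDataset(nPerClass = 1L, seed = 61L, imbalance = TRUE,
                     includeNonvocal = FALSE, audio = "none")
  expect_equal(nrow(imb$manifest), 897L)
  expect_equal(unname(tabulate(imb$manifest$behavior_label + 1L, 4)),
               c(207L, 178L, 56L, 456L))
})

test_that("dataset generation is reproducible and writes valid WAVs", {
  a <- makeDataset(nPerClass = 3L, seed = 62L, sampleRate = 4000,
                   audio = "memory")
  b <- makeDataset(nPerClass = 3L, seed = 62L, sampleRate = 4000,
                   audio = "memory")
  expect_identical(a$manifest, b$manifest)
  for (i in c(1, 7, 15))
    expect_identical(samples(a$segments[[i]]), samples(b$segments[[i]]))

  dir <- withr::local_tempdir()
  ds <- makeDataset(nPerClass = 2L, seed = 63L, sampleRate = 4000,
                    dir = dir, audio = "write")
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(sort(list.files(dir, pattern = "wav$")),
               sort(ds$manifest$file))
  seg <- readWav(file.path(dir, ds$manifest$file[1]))
  expect_equal(sampleRate(seg), 4000)
  expect_length(samples(seg), 20000L)
})
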