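test_that("measureDb follows the calibrated peak-level convention", {
  expect_equal(measureDb(c(0, 1, -0.4), 60), 60)
  expect_equal(measureDb(rep(0.1, 5), 60), 40)
  expect_equal(measureDb(c(0.5, -0.2), 60), 60 + 20 * log10(0.5),
               tolerance = 1e-12)  # 53.9794 dB
  expect_error(measureDb(numeric(0)), "empty")
  expect_error(measureDb(rep(0, 10)), "silent")
})

test_that("measureDb is monotone in the peak amplitude", {
  peaks <- withr::with_seed(1, sort(runif(20, 0.01, 1)))
  levels <- vapply(peaks, function(p) measureDb(c(p / 2, -p)), numeric(1))
  expect_true(all(diff(levels) >= 0))
})

test_that("detectEvents captures fixed-length, non-overlapping events", {
  sr <- 8000
  expect_length(detectEvents(rep(1e-6, 10 * sr), sr, thresholdDb = 60), 0)

  # one 70 dB burst in a quiet stream: one 5 s capture, trigger absorbed
  stream <- rep(0.001, 10 * sr)
  burst <- 10^((70 - 60) / 20)
  stream[(2 * sr):(3 * sr)] <- burst
  ev <- detectEvents(stream, sr, thresholdDb = 60)
  expect_length(ev, 1)
  expect_length(samples(ev[[1]]@segment), 5 * sr)
  expect_equal(ev[[1]]@triggerTime, 2, tolerance = 0.11)
  expect_gte(peakDb(ev[[1]]@segment), 60)

  # two bursts 8 s apart -> two events at the expected trigger times
  stream2 <- rep(0.001, 15 * sr)
  stream2[(1 * sr):(1.4 * sr)] <- burst
  stream2[(9 * sr):(9.4 * sr)] <- burst
  ev2 <- detectEvents(stream2, sr, thresholdDb = 60)
  expect_length(ev2, 2)
  expect_equal(vapply(ev2, function(e) e@triggerTime, numeric(1)), c(1, 9),
               tolerance = 0.11)

  expect_error(detectEvents(stream, sr, recordSeconds = 0), "positive")
  expect_error(detectEvents(rep(0.5, 10), sr), "shorter")
})

test_that("detectEvents tiles the stream when the threshold is always met", {
  sr <- 4000
  stream <- withr::with_seed(2, runif(12 * sr, -1, 1))
  ev <- detectEvents(stream, sr, thresholdDb = -100, recordSeconds = 2)
  tt <- vapply(ev, function(e) e@triggerTime, numeric(1))
  expect_equal(tt, seq(0, 10, by = 2))      # contiguous non-overlapping tiling
  expect_length(detectEvents(stream, sr, thresholdDb = 100), 0)
})

test_that("deduplicateZone keeps the loudest coincident event per zone", {
  mk <- function(peak, t, zone) {
    SensorEvent(AudioSegment(c(0, peak), 8000, zoneId = zone,
                             sensorId = paste0("s", peak)),
                triggerTime = t)
  }
  evs <- list(mk(10^(2/20), 0.1, "z1"), mk(10^(5/20), 0.3, "z1"),
              mk(10^(1/20), 0.5, "z1"), mk(10^(3/20), 0.8, "z1"))
  kept <- deduplicateZone(evs, coincidenceWindow = 1)
  expect_length(kept, 1)
  expect_equal(peakDb(kept[[1]]@segment), 65)   # the 65 dB one survives

  expect_identical(deduplicateZone(evs[2]), evs[2])  # singleton unchanged

  twoZones <- list(mk(0.5, 0.1, "a"), mk(0.9, 0.2, "a"),
                   mk(0.8, 0.1, "b"), mk(0.4, 0.2, "b"))
  kept2 <- deduplicateZone(twoZones)
  expect_length(kept2, 2)
  zones <- vapply(kept2, function(e) e@segment@zoneId, character(1))
  peaks <- vapply(kept2, function(e) peakDb(e@segment), numeric(1))
  expect_setequal(zones, c("a", "b"))
  expect_equal(sort(peaks), sort(c(measureDb(0.9), measureDb(0.8))))
})

test_that("deduplication is a subset-selecting, idempotent bucketing", {
  evs <- withr::with_seed(3, lapply(1:25, function(i) {
    SensorEvent(AudioSegment(runif(10, 0.1, 1), 8000,
                             zoneId = sample(c("z1", "z2", "z3"), 1)),
                triggerTime = runif(1, 0, 6))
  }))
  kept <- deduplicateZone(evs, coincidenceWindow = 1)
  expect_lte(length(kept), length(evs))
  expect_true(all(vapply(kept, function(k)
    any(vapply(evs, identical, logical(1), y = k)), logical(1))))
  expect_identical(deduplicateZone(kept, 1), kept)   # idempotent
  buckets <- unique(data.frame(
    zone = vapply(evs, function(e) e@segment@zoneId, character(1)),
    bucket = floor(vapply(evs, function(e) e@triggerTime, numeric(1)))))
  expect_equal(length(kept), nrow(buckets))
})

test_that("WAV round trips preserve samples to 16-bit precision", {
  sr <- 16000
  x <- 0.8 * sin(2 * pi * 440 * seq(0, 1 - 1 / sr, by = 1 / sr))
  p <- withr::local_tempfile(fileext = ".wav")
  writeWav(AudioSegment(x, sr), p)
  back <- readWav(p)
  expect_equal(sampleRate(back), sr)
  expect_lte(max(abs(samples(back) - x)), 2^-15)

  writeWav(AudioSegment(x, sr), p, type = "float32")
  expect_lte(max(abs(samples(readWav(p)) - x)), 1e-7)

  seg5 <- AudioSegment(numeric(5 * sr) + 0.1, sr)
  writeWav(seg5, p)
  expect_length(samples(readWav(p)), 80000)   # 5 s x 16 kHz
})

test_that("multichannel WAVs are downmixed by channel averaging", {
  sr <- 8000
  left <- seq(-0.5, 0.5, length.out = sr)
  right <- rep(0.25, sr)
  p <- withr::local_tempfile(fileext = ".wav")
  # hand-rolled 2-channel 16-bit PCM file
  con <- file(p, "wb")
  inter <- as.integer(round(rbind(left, right) * 32767))
  dataSize <- 2L * length(inter)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(c(as.integer(sr), as.integer(sr * 4)), con, size = 4,
           endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  writeBin(as.vector(inter), con, size = 2, endian = "little")
  close(con)
  mono <- readWav(p)
  expect_lte(max(abs(samples(mono) - (left + right) / 2)), 2^-15)
})

test_that("malformed WAV headers are rejected", {
  p <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(sample(0:255, 100, replace = TRUE)), p)
  expect_error(readWav(p), "RIFF|malformed")
})
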