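# Synthetic cattle-call and farm-noise generator. The acoustic conventions
# (f0 ranges, harmonic counts, envelopes) are chosen so the four classes are
# distinct and learnable at desk scale; they are synthetic stand-ins, not
# bioacoustic measurements of real cattle.

harmonicStack <- function(f0Trajectory, nHarmonics, sampleRate,
                          ampDecay = function(h) 1 / h) {
  phase <- 2 * pi * cumsum(f0Trajectory) / sampleRate
  x <- numeric(length(f0Trajectory))
  nyq <- sampleRate / 2
  for (h in seq_len(nHarmonics)) {
    if (max(f0Trajectory) * h >= nyq) break
    x <- x + ampDecay(h) * sin(h * phase + runif(1, 0, 2 * pi))
  }
  x
}

riseFallEnvelope <- function(n, riseFrac = 0.2, fallFrac = 0.3) {
  nr <- max(1L, round(n * riseFrac))
  nf <- max(1L, round(n * fallFrac))
  env <- rep(1, n)
  env[seq_len(nr)] <- seq(0, 1, length.out = nr)
  env[(n - nf + 1L):n] <- seq(1, 0, length.out = nf)
  env
}

# FFT brick-wall band filter, keeps energy strictly inside [lo, hi] Hz
bandFilter <- function(x, sampleRate, lo, hi) {
  n <- length(x)
  X <- fft(x)
  freqs <- (seq_len(n) - 1L) / n * sampleRate
  freqs <- pmin(freqs, sampleRate - freqs)  # fold to 0..Nyquist
  X[freqs < lo | freqs > hi] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

#' Generate one synthetic cattle call embedded in a clip
#'
#' Synthesizes a harmonic-stack call with the class-distinct signature of
#' its [CallSpec-class] (0 estrus: long rising-f0 sweep; 1 food
#' anticipating: repeated short pulses; 2 cough: short broadband noisy
#' burst; 3 normal: flat-f0 moderate call) and embeds it 2-3 s into an
#' otherwise silent clip, mirroring where calls sit in captured 5 s
#' recordings. Deterministic for a fixed `spec@seed`.
#'
#' @param spec a [CallSpec-class].
#' @param sampleRate sampling rate in Hz (default 16000).
#' @param clipSeconds clip length in seconds (default 5).
#' @param sensorId,zoneId metadata for the clip.
#' @return List with `segment` (the [AudioSegment-class]), `classIndex` and
#'   the drawn `f0`.
#' @export
generateCall <- function(spec, sampleRate = 16000, clipSeconds = 5,
                         sensorId = "sensor-1", zoneId = "zone-1") {
  stopifnot(is(spec, "CallSpec"))
  gen <- function() {
    n <- round(clipSeconds * sampleRate)
    f0 <- runif(1, spec@f0Range[1], spec@f0Range[2])
    dur <- runif(1, spec@durationRange[1], spec@durationRange[2])
    startS <- runif(1, 2, 3)
    maxStart <- clipSeconds - dur * max(1L, spec@repetition) * 1.6
    startS <- min(startS, max(0.5, maxStart))
    clip <- numeric(n)

    placeCall <- function(clip, callSamples, at) {
      i0 <- max(1L, round(at * sampleRate))
      i1 <- min(n, i0 + length(callSamples) - 1L)
      clip[i0:i1] <- clip[i0:i1] + callSamples[seq_len(i1 - i0 + 1L)]
      clip
    }

    if (spec@classIndex == 0L) {
      # long call with rising fundamental sweep
      m <- round(dur * sampleRate)
      f0t <- seq(f0, 1.5 * f0, length.out = m)
      call <- harmonicStack(f0t, spec@nHarmonics, sampleRate) *
        riseFallEnvelope(m, 0.15, 0.25)
      clip <- placeCall(clip, call, startS)
    } else if (spec@classIndex == 1L) {
      # repeated short flat-f0 pulses
      m <- round(dur * sampleRate)
      gap <- dur * runif(1, 0.4, 0.6)
      at <- startS
      for (r in seq_len(spec@repetition)) {
        pulse <- harmonicStack(rep(f0, m), spec@nHarmonics, sampleRate) *
          riseFallEnvelope(m, 0.3, 0.3)
        clip <- placeCall(clip, pulse, at)
        at <- at + dur + gap
      }
    } else if (spec@classIndex == 2L) {
      # cough: short broadband burst with noisy excitation
      m <- round(dur * sampleRate)
      noise <- c(0, diff(rnorm(m)))          # differenced -> high-band tilt
      burst <- (0.8 * noise / max(abs(noise)) +
                0.3 * harmonicStack(rep(f0, m), spec@nHarmonics, sampleRate)) *
        exp(-seq(0, 6, length.out = m)) * riseFallEnvelope(m, 0.05, 0.5)
      clip <- placeCall(clip, burst, startS)
    } else {
      # normal: flat-f0 moderate call
      m <- round(dur * sampleRate)
      call <- harmonicStack(rep(f0, m), spec@nHarmonics, sampleRate) *
        riseFallEnvelope(m, 0.2, 0.3)
      clip <- placeCall(clip, call, startS)
    }

    peak <- runif(1, 0.5, 0.9)
    clip <- clip / max(abs(clip)) * peak
    list(segment = AudioSegment(clip, sampleRate = sampleRate,
                                sensorId = sensorId, zoneId = zoneId),
         classIndex = spec@classIndex, f0 = f0)
  }
  if (is.na(spec@seed)) gen() else withSeed(spec@seed, gen())
}

#' Generate a non-cattle (noise-only) clip
#'
#' A transient clang or speech-like chatter over a weak white floor; used
#' as the "other sounds" class of the binary corpus.
#'
#' @param kind `"transient_clang"` or `"speech_like"`.
#' @param sampleRate,clipSeconds,sensorId,zoneId as in [generateCall()].
#' @param seed RNG seed (NA = current stream).
#' @return An [AudioSegment-class].
#' @export
generateNonvocal <- function(kind = c("transient_clang", "speech_like"),
                             sampleRate = 16000, clipSeconds = 5,
                             sensorId = "sensor-1", zoneId = "zone-1",
                             seed = NA_integer_) {
  kind <- match.arg(kind)
  gen <- function() {
    n <- round(clipSeconds * sampleRate)
    x <- synthNoise(kind, n, sampleRate, bandLimit = 400)
    x <- x + 0.02 * rnorm(n)
    x <- x / max(abs(x)) * runif(1, 0.5, 0.9)
    AudioSegment(x, sampleRate = sampleRate, sensorId = sensorId,
                 zoneId = zoneId)
  }
  if (is.na(seed)) gen() else withSeed(seed, gen())
}

# raw (unscaled) noise waveforms per kind
synthNoise <- function(kind, n, sampleRate, bandLimit) {
  switch(kind,
    white = rnorm(n),
    low_band_hum = bandFilter(rnorm(n), sampleRate, 0, bandLimit),
    transient_clang = {
      x <- numeric(n)
      at <- round(runif(1, 0.1, 0.7) * n)
      m <- min(n - at, round(0.6 * sampleRate))
      partials <- runif(sample(4:6, 1), 800, min(3500, sampleRate / 2 - 100))
      tt <- seq_len(m) / sampleRate
      burst <- rowSums(vapply(partials, function(f)
        sin(2 * pi * f * tt + runif(1, 0, 2 * pi)) *
          exp(-tt / runif(1, 0.05, 0.2)), numeric(m)))
      attack <- rnorm(m) * exp(-tt / 0.01)
      x[at + seq_len(m)] <- burst + 0.5 * attack
      x
    },
    speech_like = {
      carrier <- bandFilter(rnorm(n), sampleRate,
                            300, min(3000, sampleRate / 2 - 100))
      tt <- seq_len(n) / sampleRate
      syllabic <- pmax(0, sin(2 * pi * runif(1, 3, 5) * tt +
                              runif(1, 0, 2 * pi)))
      carrier * syllabic
    },
    stop("unknown noise kind: ", kind)
  )
}

#' Add synthetic noise to a clip at a target SNR
#'
#' Generates the requested noise kind, scales it so the clip-level
#' signal-to-noise ratio equals `spec@snrDb` exactly, and mixes. If the mix
#' exceeds full scale it is renormalized (signal and noise together, so the
#' SNR is preserved). An infinite `snrDb` is the noiseless identity.
#'
#' @param segment the signal [AudioSegment-class] (non-silent).
#' @param spec a [NoiseSpec-class].
#' @return The noisy [AudioSegment-class].
#' @export
addNoise <- function(segment, spec) {
  stopifnot(is(segment, "AudioSegment"), is(spec, "NoiseSpec"))
  if (is.infinite(spec@snrDb) && spec@snrDb > 0) return(segment)
  x <- segment@samples
  ps <- mean(x^2)
  if (ps == 0)
    stop("addNoise: silent input with a finite SNR request")
  gen <- function() {
    n <- length(x)
    noise <- synthNoise(spec@kind, n, segment@sampleRate, spec@bandLimit)
    pn <- mean(noise^2)
    if (pn == 0) stop("addNoise: degenerate noise realization")
    noise <- noise * sqrt(ps / (pn * 10^(spec@snrDb / 10)))
    y <- x + noise
    if (max(abs(y)) > 1) y <- y / max(abs(y))
    y
  }
  y <- if (is.na(spec@seed)) gen() else withSeed(spec@seed, gen())
  AudioSegment(y, sampleRate = segment@sampleRate,
               startTime = segment@startTime, sensorId = segment@sensorId,
               zoneId = segment@zoneId,
               calibrationOffset = segment@calibrationOffset)
}

#' Generate a labeled synthetic audio corpus
#'
#' Produces clips for the four behavioral call classes (optionally
#' mirroring the 207/178/56/456 field-corpus imbalance) plus, optionally,
#' non-cattle clips, each with a configurable noise mix, and writes a CSV
#' manifest (`file, binary_label, behavior_label, sensor_id, zone_id,
#' timestamp, seed`). Fully deterministic for a fixed `seed`.
#'
#' @param nPerClass clips per behavioral class (ignored in imbalance mode).
#' @param dir output directory (created if needed).
#' @param noiseMix list of [NoiseSpec-class] applied in turn to every call
#'   clip; default white noise and a sub-400 Hz hum, both at 12 dB SNR.
#' @param includeNonvocal also generate `nPerClass` non-cattle clips.
#' @param imbalance use the 207/178/56/456 class quantities (total 897).
#' @param seed master RNG seed.
#' @param sampleRate,clipSeconds clip format (defaults 16 kHz, 5 s).
#' @param audio `"write"` (WAV files on disk), `"memory"` (returned in the
#'   result, nothing written) or `"none"` (manifest bookkeeping only).
#' @param hard narrow the inter-class differences (stress-test mode).
#' @return List with `manifest` (data.frame), `dir`, and `segments` (list,
#'   only for `audio = "memory"`).
#' @export
makeDataset <- function(nPerClass = 100L, dir = tempfile("bovocal-data-"),
                        noiseMix = list(NoiseSpec("white", snrDb = 12),
                                        NoiseSpec("low_band_hum", snrDb = 12)),
                        includeNonvocal = TRUE, imbalance = FALSE, seed = 1L,
                        sampleRate = 16000, clipSeconds = 5,
                        audio = c("write", "memory", "none"), hard = FALSE) {
  audio <- match.arg(audio)
  stopifnot(nPerClass >= 1L)
  counts <- if (imbalance) c(207L, 178L, 56L, 456L) else rep(as.integer(nPerClass), 4L)
  classes <- rep(0:3, counts)
  nCalls <- length(classes)
  nNon <- if (includeNonvocal) as.integer(nPerClass) else 0L
  total <- nCalls + nNon
  if (audio == "write" && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)

  result <- withSeed(seed, {
    clipSeeds <- sample.int(.Machine$integer.max - 1L, total)
    segments <- if (audio == "memory") vector("list", total) else NULL
    rows <- vector("list", total)
    nonKinds <- c("transient_clang", "speech_like")
    for (i in seq_len(total)) {
      sensor <- sprintf("sensor-%d", (i - 1L) %% 4L + 1L)
      zone <- sprintf("zone-%d", ((i - 1L) %/% 4L) %% 3L + 1L)
      isCall <- i <= nCalls
      fname <- sprintf("clip-%04d.wav", i)
      if (audio != "none") {
        if (isCall) {
          cs <- CallSpec(classes[i], seed = clipSeeds[i])
          if (hard) {
            cs@f0Range <- c(100, 200)
            cs@durationRange <- pmax(0.2, pmin(cs@durationRange, 0.8))
          }
          seg <- generateCall(cs, sampleRate = sampleRate,
                              clipSeconds = clipSeconds, sensorId = sensor,
                              zoneId = zone)$segment
        } else {
          seg <- generateNonvocal(nonKinds[(i %% 2L) + 1L],
                                  sampleRate = sampleRate,
                                  clipSeconds = clipSeconds,
                                  sensorId = sensor, zoneId = zone,
                                  seed = clipSeeds[i])
        }
        # the same barn background (noise mix) lies under every clip, so
        # noise presence itself carries no class information
        for (j in seq_along(noiseMix)) {
          ns <- noiseMix[[j]]
          ns@seed <- as.integer((as.numeric(clipSeeds[i]) + j) %%
                                .Machine$integer.max)
          seg <- addNoise(seg, ns)
        }
        if (audio == "write") writeWav(seg, file.path(dir, fname))
        else segments[[i]] <- seg
      }
      rows[[i]] <- data.frame(
        file = fname,
        binary_label = as.integer(isCall),
        behavior_label = if (isCall) classes[i] else NA_integer_,
        sensor_id = sensor, zone_id = zone,
        timestamp = (i - 1L) * 10,
        seed = clipSeeds[i])
    }
    list(manifest = do.call(rbind, rows), segments = segments)
  })

  if (audio == "write")
    write.csv(result$manifest, file.path(dir, "manifest.csv"),
              row.names = FALSE)
  list(manifest = result$manifest, dir = dir, segments = result$segments)
}
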