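#' Measure the calibrated peak level of a clip in decibels
#'
#' Digital clips have no absolute sound-pressure level, so the package uses
#' the convention `dB = 20 * log10(max |amplitude|) + calibrationOffset`.
#' With the default offset of 60, a full-scale clip measures 60 dB, which
#' makes the monitoring pipeline's 60 dB recording threshold meaningful on
#' synthetic/digital data.
#'
#' @param samples numeric amplitude sequence (or an [AudioSegment-class]).
#' @param calibrationOffset dB offset added to the peak level (default 60).
#' @return Peak level in dB (finite real).
#' @examples
#' measureDb(c(0, 0.5, -0.2))        # 60 + 20*log10(0.5)
#' measureDb(rep(0.1, 10))           # 40
#' @export
measureDb <- function(samples, calibrationOffset = 60) {
  if (is(samples, "AudioSegment")) samples <- samples@samples
  if (length(samples) == 0L)
    stop("measureDb: empty sample sequence")
  peak <- max(abs(samples))
  if (peak == 0)
    stop("measureDb: silent segment (all samples zero)")
  20 * log10(peak) + calibrationOffset
}

#' Detect loud events in an audio stream
#'
#' Scans the stream with short sliding analysis windows (default 100 ms,
#' hop 50 ms) and opens a fixed-length recording whenever the window's
#' calibrated level reaches `thresholdDb` (default 60 dB). Each capture
#' lasts exactly `recordSeconds` (default 5 s; zero-padded if the stream
#' ends first), and a trigger that falls inside an active recording is
#' absorbed by it, so events never overlap.
#'
#' @param stream numeric amplitude sequence or an [AudioSegment-class].
#' @param sampleRate sampling rate in Hz (ignored when `stream` is an
#'   `AudioSegment`).
#' @param thresholdDb trigger threshold in dB (default 60).
#' @param recordSeconds capture length in seconds (default 5).
#' @param calibrationOffset see [measureDb()].
#' @param windowSeconds,hopSeconds trigger analysis granularity.
#' @param sensorId,zoneId,startTime metadata stamped on the captures.
#' @return List of [SensorEvent-class] objects (possibly empty).
#' @examples
#' sr <- 8000
#' stream <- c(rep(0, sr), runif(sr, -1, 1), rep(0, 8 * sr))
#' ev <- detectEvents(stream, sr, thresholdDb = 55)
#' length(ev)
#' @export
detectEvents <- function(stream, sampleRate = 16000, thresholdDb = 60,
                         recordSeconds = 5, calibrationOffset = 60,
                         windowSeconds = 0.1, hopSeconds = 0.05,
                         sensorId = "sensor-1", zoneId = "zone-1",
                         startTime = 0) {
  if (is(stream, "AudioSegment")) {
    sampleRate <- stream@sampleRate
    sensorId <- stream@sensorId
    zoneId <- stream@zoneId
    startTime <- stream@startTime
    calibrationOffset <- stream@calibrationOffset
    stream <- stream@samples
  }
  if (recordSeconds <= 0 || windowSeconds <= 0 || hopSeconds <= 0)
    stop("detectEvents: recordSeconds, windowSeconds and hopSeconds must be positive")
  n <- length(stream)
  win <- max(1L, round(windowSeconds * sampleRate))
  hop <- max(1L, round(hopSeconds * sampleRate))
  if (n <= win)
    stop("detectEvents: stream shorter than one analysis window")
  recLen <- round(recordSeconds * sampleRate)

  events <- list()
  nextFree <- 1L  # first sample index not inside an active recording
  start <- 1L
  while (start <= n) {
    if (start >= nextFree) {
      w <- stream[start:min(start + win - 1L, n)]
      peak <- max(abs(w))
      level <- if (peak > 0) 20 * log10(peak) + calibrationOffset else -Inf
      if (level >= thresholdDb) {
        clipEnd <- start + recLen - 1L
        clip <- if (clipEnd <= n) stream[start:clipEnd]
                else c(stream[start:n], numeric(clipEnd - n))
        seg <- AudioSegment(clip, sampleRate = sampleRate,
                            startTime = startTime + (start - 1L) / sampleRate,
                            sensorId = sensorId, zoneId = zoneId,
                            calibrationOffset = calibrationOffset)
        events[[length(events) + 1L]] <-
          SensorEvent(seg, triggerTime = startTime + (start - 1L) / sampleRate,
                      thresholdDb = thresholdDb)
        nextFree <- start + recLen
      }
    }
    start <- start + hop
  }
  events
}

#' Deduplicate coincident events within each sensor zone
#'
#' Sensors sharing a zone record the same sound; among events of one zone
#' whose trigger times fall in the same coincidence window (default 1 s),
#' only the event with the highest peak dB is kept. Events from different
#' zones never collapse.
#'
#' @param events list of [SensorEvent-class].
#' @param coincidenceWindow bucket width in seconds (default 1).
#' @return List of surviving [SensorEvent-class], ordered by trigger time.
#' @export
deduplicateZone <- function(events, coincidenceWindow = 1) {
  if (length(events) == 0L) return(list())
  stopifnot(coincidenceWindow > 0)
  zone <- vapply(events, function(e) e@segment@zoneId, character(1))
  tt <- vapply(events, function(e) e@triggerTime, numeric(1))
  db <- vapply(events, function(e) e@segment@peakDb, numeric(1))
  bucket <- floor(tt / coincidenceWindow)
  key <- paste(zone, bucket, sep = "\r")
  keep <- vapply(split(seq_along(events), key),
                 function(idx) idx[which.max(db[idx])], integer(1))
  keep <- sort(keep)
  events[keep][order(tt[keep])]
}

#' Read a WAV file as a mono AudioSegment
#'
#' Parses RIFF/WAVE with integer PCM (8/16/24/32-bit) or IEEE float
#' (32/64-bit) samples. Multichannel files are downmixed to mono by
#' averaging the channels.
#'
#' @param path WAV file path.
#' @param sensorId,zoneId,startTime,calibrationOffset metadata for the
#'   returned segment.
#' @return An [AudioSegment-class].
#' @export
readWav <- function(path, sensorId = "sensor-1", zoneId = "zone-1",
                    startTime = 0, calibrationOffset = 60) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 44 ||
      rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "WAVE")
    stop("readWav: not a RIFF/WAVE file: ", path)
  pos <- 13L
  fmt <- NULL
  data <- NULL
  while (pos + 8L <= length(raw)) {
    cid <- rawToChar(raw[pos:(pos + 3L)])
    csize <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4,
                     endian = "little")
    body <- raw[(pos + 8L):min(pos + 7L + csize, length(raw))]
    if (cid == "fmt ") {
      fmt <- list(
        audioFormat = readBin(body[1:2], "integer", size = 2,
                              endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", size = 2, endian = "little"),
        sampleRate = readBin(body[5:8], "integer", size = 4, endian = "little"),
        bits = readBin(body[15:16], "integer", size = 2, endian = "little")
      )
    } else if (cid == "data") {
      data <- body
    }
    pos <- pos + 8L + csize + (csize %% 2L)  # chunks are word-aligned
  }
  if (is.null(fmt) || is.null(data))
    stop("readWav: malformed WAV (missing fmt or data chunk): ", path)

  x <- if (fmt$audioFormat == 1L) {
    switch(as.character(fmt$bits),
      "8" = (as.numeric(readBin(data, "integer", n = length(data), size = 1,
                                signed = FALSE)) - 128) / 128,
      "16" = readBin(data, "integer", n = length(data) %/% 2L, size = 2,
                     endian = "little") / 32768,
      "24" = {
        n <- length(data) %/% 3L
        b <- matrix(as.integer(data[seq_len(3L * n)]), nrow = 3L)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      },
      "32" = readBin(data, "integer", n = length(data) %/% 4L, size = 4,
                     endian = "little") / 2147483648,
      stop("readWav: unsupported PCM bit depth: ", fmt$bits)
    )
  } else if (fmt$audioFormat == 3L) {
    size <- fmt$bits %/% 8L
    readBin(data, "numeric", n = length(data) %/% size, size = size,
            endian = "little")
  } else {
    stop("readWav: unsupported WAV format code: ", fmt$audioFormat)
  }

  if (fmt$channels > 1L) {
    usable <- (length(x) %/% fmt$channels) * fmt$channels
    x <- colMeans(matrix(x[seq_len(usable)], nrow = fmt$channels))
  }
  AudioSegment(x, sampleRate = fmt$sampleRate, startTime = startTime,
               sensorId = sensorId, zoneId = zoneId,
               calibrationOffset = calibrationOffset)
}

#' Write an AudioSegment to a WAV file
#'
#' @param segment an [AudioSegment-class] (or a numeric vector).
#' @param path output file path.
#' @param sampleRate required when `segment` is a bare numeric vector.
#' @param type `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(segment, path, sampleRate = NULL, type = c("pcm16", "float32")) {
  type <- match.arg(type)
  if (is(segment, "AudioSegment")) {
    x <- segment@samples
    sampleRate <- segment@sampleRate
  } else {
    x <- as.numeric(segment)
    if (is.null(sampleRate)) stop("writeWav: sampleRate required for numeric input")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  if (type == "pcm16") {
    bits <- 16L; fmtCode <- 1L
    payload <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
    dataSize <- 2L * length(x)
  } else {
    bits <- 32L; fmtCode <- 3L
    dataSize <- 4L * length(x)
  }
  byteRate <- as.integer(sampleRate * bits / 8)
  blockAlign <- as.integer(bits / 8)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmtCode, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(byteRate, con, size = 4, endian = "little")
  writeBin(blockAlign, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (type == "pcm16") {
    writeBin(payload, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}
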