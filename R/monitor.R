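#' Monitoring pipeline configuration
#'
#' All pipeline constants in one declarative object: the 60 dB recording
#' threshold and 5 s capture, the calibration convention, the 1 s zone
#' coincidence window, the STFT analysis (2048/2048/256, Hann), the gate
#' multiplier, the 128-band / 2000-frame feature target and the Adadelta
#' hyperparameters (gamma 0.95, epsilon 1e-7).
#'
#' @param ... overrides of the defaults listed above.
#' @return A named list of configuration values.
#' @export
monitorConfig <- function(...) {
  cfg <- list(
    sampleRate = 16000,
    thresholdDb = 60,
    recordSeconds = 5,
    calibrationOffset = 60,
    coincidenceWindow = 1,
    nFft = 2048L,
    winLength = 2048L,
    hop = 256L,
    windowFn = "hann",
    nStd = 1.5,
    mels = 128L,
    frames = 2000L,
    representation = "mfcc",
    denoise = TRUE,
    gamma = 0.95,
    epsilon = 1e-7,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("monitorConfig: unknown option(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

alertClasses <- function() 0:2  # estrus, food anticipation, cough need action

#' Run the full monitoring pipeline on captured clips
#'
#' For each input clip: zone deduplication (loudest capture per zone per
#' coincidence window), spectral-gating denoise, MFCC features, the binary
#' cattle-voice gate, and - for clips that pass the gate - the four-class
#' behavioral classifier. Every post-deduplication event yields exactly one
#' record; behavioral fields are present only when the clip is recognized
#' as cattle voice, and an alert flag is set for the three actionable
#' classes (estrus, food anticipation, cough).
#'
#' @param input a directory of WAV files, a character vector of WAV paths,
#'   or a list of [AudioSegment-class] clips.
#' @param binaryModel fitted binary [CNNModel-class].
#' @param behaviorModel fitted 4-class [CNNModel-class].
#' @param config a [monitorConfig()] list.
#' @param manifest optional data.frame with columns `file`, `sensor_id`,
#'   `zone_id`, `timestamp` supplying capture metadata for WAV inputs.
#' @param verbose emit one structured log line per stage and event.
#' @return data.frame of prediction records: `timestamp`, `sensor_id`,
#'   `zone_id`, `wav_path`, `is_cattle`, `cattle_probability`,
#'   `behavior_class`, `behavior_name`, `behavior_probability`, `alert`.
#' @export
runPipeline <- function(input, binaryModel, behaviorModel,
                        config = monitorConfig(), manifest = NULL,
                        verbose = FALSE) {
  if (!is(binaryModel, "CNNModel") || !binaryModel@fitted)
    stop("runPipeline: fitted binary model required")
  if (!is(behaviorModel, "CNNModel") || !behaviorModel@fitted)
    stop("runPipeline: fitted behavior model required")

  log <- function(eventId, stage, msg) {
    if (verbose)
      message(sprintf("[bovocal] event=%s stage=%s %s", eventId, stage, msg))
  }

  emptyReport <- data.frame(
    timestamp = numeric(), sensor_id = character(), zone_id = character(),
    wav_path = character(), is_cattle = logical(),
    cattle_probability = numeric(), behavior_class = integer(),
    behavior_name = character(), behavior_probability = numeric(),
    alert = logical())

  # assemble segments
  if (is.character(input)) {
    paths <- if (length(input) == 1L && dir.exists(input)) {
      sort(list.files(input, pattern = "\\.wav$", ignore.case = TRUE,
                      full.names = TRUE))
    } else input
    if (length(paths) == 0L) return(emptyReport)
    segments <- lapply(seq_along(paths), function(i) {
      meta <- if (!is.null(manifest)) {
        manifest[match(basename(paths[i]), manifest$file), ]
      } else NULL
      readWav(paths[i],
              sensorId = if (!is.null(meta) && !is.na(meta$sensor_id))
                           meta$sensor_id else "sensor-1",
              zoneId = if (!is.null(meta) && !is.na(meta$zone_id))
                         meta$zone_id else "zone-1",
              startTime = if (!is.null(meta) && !is.na(meta$timestamp))
                            meta$timestamp else (i - 1) * config$recordSeconds,
              calibrationOffset = config$calibrationOffset)
    })
  } else if (is.list(input)) {
    if (length(input) == 0L) return(emptyReport)
    paths <- rep(NA_character_, length(input))
    segments <- input
  } else {
    stop("runPipeline: unsupported input")
  }

  events <- lapply(seq_along(segments), function(i) {
    SensorEvent(segments[[i]], triggerTime = segments[[i]]@startTime)
  })
  names(events) <- paths
  kept <- deduplicateZone(events, coincidenceWindow = config$coincidenceWindow)
  log("*", "deduplicate", sprintf("%d events in, %d out",
                                  length(events), length(kept)))

  stftCfg <- STFTConfig(nFft = config$nFft, winLength = config$winLength,
                        hop = config$hop, windowFn = config$windowFn)
  shape <- binaryModel@inputShape

  rows <- lapply(seq_along(kept), function(i) {
    ev <- kept[[i]]
    seg <- ev@segment
    eid <- sprintf("%03d", i)
    t0 <- proc.time()[3]
    if (isTRUE(config$denoise)) {
      seg <- denoise(seg, config = stftCfg, nStd = config$nStd)
      log(eid, "denoise", sprintf("duration=%.2fs ok", proc.time()[3] - t0))
    }
    feats <- mfccFeatures(seg, M = shape[1], tFixed = shape[2],
                          config = stftCfg,
                          representation = config$representation)
    log(eid, "featurize", sprintf("shape=%dx%d", nrow(feats@coefficients),
                                  ncol(feats@coefficients)))
    gate <- predict(binaryModel, feats)
    isCattle <- gate$class == 1L
    log(eid, "binary_gate", sprintf("is_cattle=%s p=%.3f", isCattle,
                                    gate$probabilities[gate$class + 1L]))
    if (isCattle) {
      beh <- predict(behaviorModel, feats)
      log(eid, "behavior", sprintf("class=%d p=%.3f", beh$class,
                                   beh$probabilities[beh$class + 1L]))
      data.frame(
        timestamp = ev@triggerTime, sensor_id = seg@sensorId,
        zone_id = seg@zoneId,
        wav_path = if (is.null(names(kept))) NA_character_ else names(kept)[i],
        is_cattle = TRUE,
        cattle_probability = unname(gate$probabilities[2]),
        behavior_class = beh$class,
        behavior_name = behaviorClassLabels()[beh$class + 1L],
        behavior_probability = unname(beh$probabilities[beh$class + 1L]),
        alert = beh$class %in% alertClasses())
    } else {
      data.frame(
        timestamp = ev@triggerTime, sensor_id = seg@sensorId,
        zone_id = seg@zoneId,
        wav_path = if (is.null(names(kept))) NA_character_ else names(kept)[i],
        is_cattle = FALSE,
        cattle_probability = unname(gate$probabilities[2]),
        behavior_class = NA_integer_,
        behavior_name = NA_character_,
        behavior_probability = NA_real_,
        alert = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Export / import a prediction report
#'
#' Lossless serialization of the [runPipeline()] record table as JSON
#' (array of row objects, stable field order) or CSV.
#'
#' @param records data.frame of prediction records.
#' @param path output file.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
exportReport <- function(records, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") {
    jsonlite::write_json(records, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    write.csv(records, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname exportReport
#' @export
importReport <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  format <- match.arg(format, c("json", "csv"))
  df <- if (format == "json") {
    jsonlite::fromJSON(path)
  } else {
    read.csv(path, na.strings = "")
  }
  if (length(df) == 0L || (is.data.frame(df) && nrow(df) == 0L))
    return(df)
  df$behavior_class <- as.integer(df$behavior_class)
  df$is_cattle <- as.logical(df$is_cattle)
  df$alert <- as.logical(df$alert)
  df
}

#' Count actionable alerts in a report
#' @param records data.frame from [runPipeline()].
#' @return Number of records flagged for farmer attention (classes 0-2).
#' @export
alertCount <- function(records) sum(records$alert, na.rm = TRUE)
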