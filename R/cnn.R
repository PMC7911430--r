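# CNN layers operate on minibatch matrices: each column is one sample laid
# out as an H x W x C array in column-major order. Conv blocks are
# 3x3 same-padded convolution -> ReLU -> max pooling.

initConvBlock <- function(inH, inW, inC, filters, pool) {
  outH <- inH %/% pool[1]
  outW <- inW %/% pool[2]
  if (outH < 1L || outW < 1L)
    stop("CNN: input smaller than the receptive field after pooling ",
         "(", inH, "x", inW, " pooled by ", pool[1], "x", pool[2], ")")
  list(type = "conv", kh = 3L, kw = 3L, inC = as.integer(inC),
       outC = as.integer(filters), pool = as.integer(pool),
       inH = as.integer(inH), inW = as.integer(inW),
       outH = as.integer(outH), outW = as.integer(outW),
       W = matrix(0, 9L * inC, filters), b = numeric(filters))
}

initLayerWeights <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      fanIn <- 9L * l$inC
      l$W <- matrix(rnorm(fanIn * l$outC, sd = sqrt(2 / fanIn)),
                    fanIn, l$outC)
      l$b <- numeric(l$outC)
    } else if (l$type == "dense") {
      fanIn <- ncol(l$W)
      sdw <- if (identical(l$activation, "softmax")) sqrt(1 / fanIn)
             else sqrt(2 / fanIn)
      l$W <- matrix(rnorm(length(l$W), sd = sdw), nrow(l$W), fanIn)
      l$b <- numeric(nrow(l$W))
    }
    layers[[i]] <- l
  }
  layers
}

buildCnn <- function(inputShape, filters, pools, denseUnits, nClasses,
                     classLabels, seed = 0L) {
  inputShape <- as.integer(inputShape)
  layers <- list()
  h <- inputShape[1]; w <- inputShape[2]; c <- 1L
  for (i in seq_along(filters)) {
    blk <- initConvBlock(h, w, c, filters[i], pools[[i]])
    layers[[length(layers) + 1L]] <- blk
    h <- blk$outH; w <- blk$outW; c <- blk$outC
  }
  flat <- h * w * c
  layers[[length(layers) + 1L]] <-
    list(type = "dense", activation = "relu",
         W = matrix(0, denseUnits, flat), b = numeric(denseUnits))
  layers[[length(layers) + 1L]] <-
    list(type = "dense", activation = "softmax",
         W = matrix(0, nClasses, denseUnits), b = numeric(nClasses))
  layers <- withSeed(seed, initLayerWeights(layers))
  new("CNNModel", layers = layers, inputShape = inputShape,
      nClasses = as.integer(nClasses), fitted = FALSE, inputScale = 1,
      history = NULL, classLabels = classLabels)
}

#' Build the binary cattle-voice/noise CNN
#'
#' Default stack: three 3x3 convolution blocks (16/32/64 filters, ReLU,
#' max pool 2x4), a 64-unit dense ReLU layer and a 2-unit Softmax output.
#'
#' @param inputShape integer(2): (mel bands, time frames); default the
#'   full-scale 128 x 2000 feature matrix.
#' @param filters convolution filters per block.
#' @param pools list of (freq, time) pool sizes, one per block.
#' @param denseUnits hidden dense width.
#' @param seed RNG seed for the weight initialization (training
#'   re-initializes from its own seed; see [train()]).
#' @return An unfitted [CNNModel-class].
#' @seealso [buildBehaviorCnn()], [train()], [parameterCount()]
#' @export
buildBinaryCnn <- function(inputShape = c(128L, 2000L),
                           filters = c(16L, 32L, 64L),
                           pools = list(c(2L, 4L), c(2L, 4L), c(2L, 4L)),
                           denseUnits = 64L, seed = 0L) {
  buildCnn(inputShape, filters, pools, denseUnits, nClasses = 2L,
           classLabels = c("other", "cattle"), seed = seed)
}

#' Build the four-class behavioral CNN
#'
#' Deeper than the binary gate, matching the design constraint that the
#' behavioral model has more convolution depth and more parameters: four
#' blocks (16/32/64/128 filters; pools 2x4, 2x4, 2x4, 2x2), a 128-unit
#' dense ReLU layer and a 4-unit Softmax over the behavior classes
#' (0 estrus, 1 food anticipating, 2 cough, 3 normal).
#'
#' @inheritParams buildBinaryCnn
#' @return An unfitted [CNNModel-class].
#' @export
buildBehaviorCnn <- function(inputShape = c(128L, 2000L),
                             filters = c(16L, 32L, 64L, 128L),
                             pools = list(c(2L, 4L), c(2L, 4L), c(2L, 4L),
                                          c(2L, 2L)),
                             denseUnits = 128L, seed = 0L) {
  buildCnn(inputShape, filters, pools, denseUnits, nClasses = 4L,
           classLabels = behaviorClassLabels(), seed = seed)
}

#' Number of trainable parameters of a CNN
#' @param model a [CNNModel-class].
#' @return Integer count of weights and biases.
#' @export
parameterCount <- function(model) {
  stopifnot(is(model, "CNNModel"))
  sum(vapply(model@layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

cnnForward <- function(layers, X, cache = FALSE) {
  caches <- vector("list", length(layers))
  A <- X
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      Z <- .convForward(A, l$W, l$b, l$inH, l$inW, l$inC, l$kh, l$kw)
      R <- Z * (Z > 0)
      pl <- .maxPoolForward(R, l$inH, l$inW, l$outC, l$pool[1], l$pool[2])
      if (cache) caches[[i]] <- list(input = A, reluMask = (Z > 0),
                                     argmax = pl$argmax)
      A <- pl$output
    } else {
      Z <- l$W %*% A + l$b
      if (identical(l$activation, "relu")) {
        if (cache) caches[[i]] <- list(input = A, reluMask = (Z > 0))
        A <- Z * (Z > 0)
      } else {
        Zs <- sweep(Z, 2, apply(Z, 2, max), `-`)
        E <- exp(Zs)
        P <- sweep(E, 2, colSums(E), `/`)
        if (cache) caches[[i]] <- list(input = A)
        A <- P
      }
    }
  }
  list(output = A, caches = caches)
}

# gradient of mean cross-entropy wrt all layer weights; dOut = P - Y scaled
cnnBackward <- function(layers, caches, dZ) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cc <- caches[[i]]
    if (l$type == "dense") {
      gW <- dZ %*% t(cc$input)
      gB <- rowSums(dZ)
      dA <- t(l$W) %*% dZ
      grads[[i]] <- list(W = gW, b = gB)
      dZ <- dA
      # apply relu mask of the previous dense layer if that layer cached one
      if (i > 1L && layers[[i - 1L]]$type == "dense" &&
          identical(layers[[i - 1L]]$activation, "relu"))
        dZ <- dZ * caches[[i - 1L]]$reluMask
    } else {
      dR <- .maxPoolBackward(dZ, cc$argmax, l$inH, l$inW, l$outC)
      dConv <- dR * cc$reluMask
      bk <- .convBackward(cc$input, l$W, dConv, l$inH, l$inW, l$inC,
                          l$kh, l$kw)
      grads[[i]] <- list(W = bk$gradWeights, b = bk$gradBias)
      dZ <- bk$gradInput
    }
  }
  grads
}

featuresToMatrix <- function(x, inputShape) {
  flat <- prod(inputShape)
  if (is(x, "MFCCMatrix")) x <- list(x)
  if (is.list(x)) {
    X <- vapply(x, function(f) {
      v <- if (is(f, "MFCCMatrix")) f@coefficients else as.matrix(f)
      if (!all(dim(v) == inputShape))
        stop("feature matrix is ", paste(dim(v), collapse = "x"),
             " but the model expects ", paste(inputShape, collapse = "x"))
      as.numeric(v)
    }, numeric(flat))
    matrix(X, nrow = flat)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (!all(dim(x)[1:2] == inputShape)) stop("feature array shape mismatch")
    matrix(x, nrow = flat)
  } else if (is.matrix(x) && nrow(x) == flat) {
    x
  } else if (is.matrix(x) && all(dim(x) == inputShape)) {
    matrix(as.numeric(x), ncol = 1)
  } else {
    stop("unsupported feature input")
  }
}

#' Train a CNN classifier with Adadelta
#'
#' Stratified train/validation split, minibatch categorical cross-entropy
#' training with the element-wise Adadelta rule of [adadeltaStep()]
#' (no global learning rate), final-epoch model selection. Weights are
#' (re-)initialized deterministically from `config$seed`, so a fixed seed
#' gives bit-reproducible training.
#'
#' @param model an unfitted [CNNModel-class] from [buildBinaryCnn()] or
#'   [buildBehaviorCnn()].
#' @param x features: list of [MFCCMatrix-class], a 3D array
#'   (bands x frames x n), or a pre-flattened matrix (features x n).
#' @param y integer class labels in `0..nClasses-1` (one per sample).
#' @param config a [trainConfig()] list.
#' @return The fitted [CNNModel-class]; per-epoch train/validation loss and
#'   accuracy are in `trainingHistory(model)`.
#' @export
train <- function(model, x, y, config = trainConfig()) {
  stopifnot(is(model, "CNNModel"), inherits(config, "TrainConfig"))
  X <- featuresToMatrix(x, model@inputShape)
  y <- as.integer(y)
  n <- ncol(X)
  if (length(y) != n) stop("train: labels and features differ in length")
  if (any(y < 0L | y >= model@nClasses)) stop("train: label out of range")
  if (length(unique(y)) < 2L)
    stop("train: need at least two classes present in the data")

  scale <- max(abs(X))
  if (scale == 0) scale <- 1
  X <- X / scale

  hist <- withSeed(config$seed, {
    # stratified split
    valIdx <- unlist(lapply(split(seq_len(n), y), function(idx) {
      k <- max(1L, round(length(idx) * config$validationFraction))
      sample(idx, k)
    }), use.names = FALSE)
    trainIdx <- setdiff(seq_len(n), valIdx)

    layers <- initLayerWeights(model@layers)
    opt <- lapply(layers, function(l) {
      if (is.null(l$W)) NULL
      else list(EgW = l$W * 0, EdW = l$W * 0,
                Egb = l$b * 0, Edb = l$b * 0)
    })
    gamma <- config$gamma
    eps <- config$epsilon
    cw <- config$classWeights
    Yval <- diag(model@nClasses)[, y[valIdx] + 1L, drop = FALSE]
    Xval <- X[, valIdx, drop = FALSE]

    hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                       trainAcc = numeric(), valLoss = numeric(),
                       valAcc = numeric())
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(trainIdx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
      epLoss <- 0; epCorrect <- 0
      for (bi in batches) {
        Xb <- X[, bi, drop = FALSE]
        yb <- y[bi]
        Yb <- diag(model@nClasses)[, yb + 1L, drop = FALSE]
        fw <- cnnForward(layers, Xb, cache = TRUE)
        P <- fw$output
        w <- if (is.null(cw)) rep(1, length(bi)) else cw[yb + 1L]
        losses <- -log(pmax(colSums(P * Yb), 1e-12))
        epLoss <- epLoss + sum(losses * w)
        epCorrect <- epCorrect +
          sum(max.col(t(P), ties.method = "first") - 1L == yb)
        dZ <- sweep(P - Yb, 2, w / length(bi), `*`)
        grads <- cnnBackward(layers, fw$caches, dZ)
        for (li in seq_along(layers)) {
          if (is.null(grads[[li]])) next
          uW <- adadeltaCore(layers[[li]]$W, grads[[li]]$W,
                             opt[[li]]$EgW, opt[[li]]$EdW, gamma, eps)
          layers[[li]]$W <- uW$theta
          opt[[li]]$EgW <- uW$Eg; opt[[li]]$EdW <- uW$Ed
          ub <- adadeltaCore(layers[[li]]$b, grads[[li]]$b,
                             opt[[li]]$Egb, opt[[li]]$Edb, gamma, eps)
          layers[[li]]$b <- ub$theta
          opt[[li]]$Egb <- ub$Eg; opt[[li]]$Edb <- ub$Ed
        }
      }
      Pv <- cnnForward(layers, Xval)$output
      valLoss <- mean(-log(pmax(colSums(Pv * Yval), 1e-12)))
      valAcc <- mean(max.col(t(Pv), ties.method = "first") - 1L == y[valIdx])
      hist <- rbind(hist, data.frame(
        epoch = epoch, trainLoss = epLoss / length(trainIdx),
        trainAcc = epCorrect / length(trainIdx),
        valLoss = valLoss, valAcc = valAcc))
    }
    list(layers = layers, history = hist)
  })

  model@layers <- hist$layers
  model@history <- hist$history
  model@inputScale <- scale
  model@fitted <- TRUE
  model
}

#' Per-epoch training history of a fitted CNN
#' @param model a fitted [CNNModel-class].
#' @return data.frame with columns epoch, trainLoss, trainAcc, valLoss,
#'   valAcc.
#' @export
trainingHistory <- function(model) {
  stopifnot(is(model, "CNNModel"))
  model@history
}

#' Predict classes and Softmax probabilities
#'
#' @param object a fitted [CNNModel-class].
#' @param newdata an [MFCCMatrix-class], a list of them, a 3D array or a
#'   pre-flattened feature matrix.
#' @param ... unused.
#' @return For a single input, `list(class = <0-based index>,
#'   probabilities = <named numeric vector summing to 1>)`; for several
#'   inputs, `class` is a vector and `probabilities` a samples x classes
#'   matrix.
#' @export
setMethod("predict", "CNNModel", function(object, newdata, ...) {
  X <- featuresToMatrix(newdata, object@inputShape)
  X <- X / object@inputScale
  P <- cnnForward(object@layers, X)$output
  cls <- max.col(t(P), ties.method = "first") - 1L
  if (ncol(X) == 1L) {
    p <- as.numeric(P[, 1])
    names(p) <- object@classLabels
    list(class = cls[1], probabilities = p)
  } else {
    Pm <- t(P)
    colnames(Pm) <- object@classLabels
    list(class = cls, probabilities = Pm)
  }
})

#' Save / load a fitted CNN checkpoint
#'
#' `saveModel()` serializes the model and writes a JSON sidecar
#' (`<path>.json`) recording the architecture and training configuration;
#' `loadModel()` restores it.
#'
#' @param model a [CNNModel-class].
#' @param path checkpoint file path (RDS).
#' @return `loadModel()` returns the [CNNModel-class]; `saveModel()` the
#'   path, invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CNNModel"))
  saveRDS(model, path)
  spec <- list(
    inputShape = model@inputShape,
    nClasses = model@nClasses,
    classLabels = model@classLabels,
    fitted = model@fitted,
    parameterCount = parameterCount(model),
    layers = lapply(model@layers, function(l) {
      if (l$type == "conv")
        list(type = "conv", filters = l$outC, kernel = c(l$kh, l$kw),
             activation = "relu", pool = l$pool)
      else list(type = "dense", units = nrow(l$W), activation = l$activation)
    })
  )
  jsonlite::write_json(spec, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "CNNModel"))
  model
}
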