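## Classifier families: 2-D image models over 256 x 512 x 3 inputs, and
## 1-D time-series models (single-input over the 1250 x 12 tensor, or
## twelve weight-independent branches over 1250 x 1 each).

IMAGE_BACKBONES <- c("VGG16", "ResNet50V2", "InceptionV3",
                     "InceptionResNetV2", "Xception", "TINY")

#' Image model specification
#'
#' Architecture: backbone feature extractor, global average pooling, a
#' dense layer of `denseSize` units (ReLU), dropout, and a 2-way softmax
#' output. The named backbones are compact from-scratch variants that keep
#' each family's defining topology (plain 3x3 stack, pre-activation
#' residual bottlenecks, multi-branch concatenation, residual-inception
#' hybrid, depthwise-separable stack) at reduced width controlled by
#' `widthScale`; `TINY` is a three-stage conv/pool backbone sized for CPU
#' work.
#'
#' @param backboneId One of `r paste(IMAGE_BACKBONES, collapse = ", ")`.
#' @param denseSize Width of the penultimate dense layer (default 512).
#' @param dropoutRate Dropout rate before the output layer (default 0.5).
#' @param nClasses Number of output classes (2).
#' @param inputShape Input (height, width, channels); default 256 x 512 x 3.
#' @param widthScale Channel-width multiplier for the named backbones.
#' @return A spec list for [buildImageModel()].
#' @export
imageModelSpec <- function(backboneId = "TINY", denseSize = 512L,
                           dropoutRate = 0.5, nClasses = 2L,
                           inputShape = c(256L, 512L, 3L), widthScale = 1) {
  if (!backboneId %in% IMAGE_BACKBONES)
    stopf("unknown backbone '%s'; registry: %s", backboneId,
          paste(IMAGE_BACKBONES, collapse = ", "))
  stopifnot(denseSize >= 1L, dropoutRate >= 0, dropoutRate < 1,
            nClasses == 2L)
  list(type = "image", backboneId = backboneId,
       denseSize = as.integer(denseSize), dropoutRate = dropoutRate,
       nClasses = as.integer(nClasses), inputShape = as.integer(inputShape),
       widthScale = widthScale)
}

#' Time-series model specification
#'
#' Convolutional blocks of 1-D conv (stride 3) + batch normalization +
#' ReLU + max pooling (size 5, stride 3), then global average pooling.
#' `single` runs one stack over the (1250, 12) tensor and applies dropout
#' 0.5 before the 2-way output; `multi` runs 12 weight-independent branches
#' over (1250, 1) each, concatenates the pooled features and connects them
#' directly to the 2-way output (no dropout). A block whose kernel no
#' longer fits the remaining length is dropped, and pooling is skipped when
#' the length is below the pool size.
#'
#' @param mode `"single"` or `"multi"`.
#' @param kernelSize Conv kernel size; the studied sweep is {3,5,7,9,11}
#'   (best 7 for single, 11 for multi), other odd sizes are accepted with a
#'   warning.
#' @param filters Filter counts of the successive blocks.
#' @param convStride,poolSize,poolStride Block geometry.
#' @param dropoutRate Dropout in the single-input head.
#' @param inputLen,nLeads Input geometry (1250 samples x 12 leads).
#' @return A spec list for [buildTsModel()].
#' @export
tsModelSpec <- function(mode = c("single", "multi"), kernelSize = NULL,
                        filters = c(32L, 64L, 128L, 256L), convStride = 3L,
                        poolSize = 5L, poolStride = 3L, dropoutRate = 0.5,
                        inputLen = 1250L, nLeads = 12L) {
  mode <- match.arg(mode)
  if (is.null(kernelSize))
    kernelSize <- if (mode == "single") 7L else 11L
  if (!kernelSize %in% c(3L, 5L, 7L, 9L, 11L))
    warnf("kernel size %d is outside the studied sweep {3,5,7,9,11}",
          kernelSize)
  list(type = "ts", mode = mode, kernelSize = as.integer(kernelSize),
       filters = as.integer(filters), convStride = as.integer(convStride),
       poolSize = as.integer(poolSize), poolStride = as.integer(poolStride),
       dropoutRate = dropoutRate, inputLen = as.integer(inputLen),
       nLeads = as.integer(nLeads))
}

#' Kernel-size sweep grid
#'
#' One time-series spec per kernel size, identical otherwise.
#'
#' @param mode `"single"` or `"multi"`.
#' @param sizes Kernel sizes (default the studied sweep 3, 5, 7, 9, 11).
#' @param ... Further arguments passed to [tsModelSpec()].
#' @return List of specs.
#' @export
kernelSizeGrid <- function(mode = c("single", "multi"),
                           sizes = c(3L, 5L, 7L, 9L, 11L), ...) {
  mode <- match.arg(mode)
  stopifnot(length(sizes) >= 1L)
  lapply(sizes, function(k) tsModelSpec(mode = mode, kernelSize = k, ...))
}

## ---- backbone constructors (return list(mod, outChannels)) -----------

convBnRelu2d <- function(inCh, f, k, s = 1L, p = 0L)
  list(layerConv2d(inCh, f, k, s, p), layerBn(f), layerRelu())

backboneTiny <- function(inCh) {
  layers <- c(list(layerAvgPool(4L, 4L)),
              convBnRelu2d(inCh, 8L, 5L, 2L),
              list(layerMaxPool(2L, 2L)),
              convBnRelu2d(8L, 16L, 3L, 2L),
              list(layerMaxPool(2L, 2L)),
              convBnRelu2d(16L, 32L, 3L, 1L))
  list(mod = seqModList(layers), outCh = 32L)
}

backboneVgg <- function(inCh, scale) {
  f <- pmax(4L, as.integer(round(c(64, 128, 256, 512, 512) * scale / 8)))
  nConv <- c(2L, 2L, 3L, 3L, 3L)
  layers <- list(layerAvgPool(2L, 2L))  # halve the 256x512 input first
  prev <- inCh
  for (st in seq_along(f)) {
    for (i in seq_len(nConv[st])) {
      layers <- c(layers, convBnRelu2d(prev, f[st], 3L, 1L, 1L))
      prev <- f[st]
    }
    layers <- c(layers, list(layerMaxPool(2L, 2L)))
  }
  list(mod = seqModList(layers), outCh = prev)
}

resBlockV2 <- function(inCh, f, stride) {
  main <- seqModList(c(
    list(layerBn(inCh), layerRelu()),
    list(layerConv2d(inCh, f, 1L, stride, 0L)),
    list(layerBn(f), layerRelu()),
    list(layerConv2d(f, f, 3L, 1L, 1L)),
    list(layerBn(f), layerRelu()),
    list(layerConv2d(f, 2L * f, 1L, 1L, 0L))))
  short <- if (stride != 1L || inCh != 2L * f)
    seqMod(layerConv2d(inCh, 2L * f, 1L, stride, 0L)) else NULL
  residualMod(main, short)
}

backboneResnet <- function(inCh, scale) {
  f <- pmax(4L, as.integer(round(c(64, 128, 256) * scale / 8)))
  layers <- c(list(layerAvgPool(2L, 2L)),
              list(layerConv2d(inCh, f[1], 7L, 2L, 3L)),
              list(layerMaxPool(3L, 2L)))
  prev <- f[1]
  for (st in seq_along(f)) {
    layers <- c(layers, list(resBlockV2(prev, f[st], 2L)))
    prev <- 2L * f[st]
    layers <- c(layers, list(resBlockV2(prev, f[st], 1L)))
  }
  layers <- c(layers, list(layerBn(prev), layerRelu()))
  list(mod = seqModList(layers), outCh = prev)
}

inceptionModule <- function(inCh, f) {
  branchcatMod(list(
    seqModList(convBnRelu2d(inCh, f, 1L, 1L, 0L)),
    seqModList(c(convBnRelu2d(inCh, f, 1L, 1L, 0L),
                 convBnRelu2d(f, f, 3L, 1L, 1L))),
    seqModList(c(convBnRelu2d(inCh, f, 1L, 1L, 0L),
                 convBnRelu2d(f, f, 3L, 1L, 1L),
                 convBnRelu2d(f, f, 3L, 1L, 1L)))))
}

backboneInception <- function(inCh, scale) {
  f <- pmax(4L, as.integer(round(32 * scale / 4)))
  layers <- c(list(layerAvgPool(2L, 2L)),
              convBnRelu2d(inCh, f, 3L, 2L),
              convBnRelu2d(f, 2L * f, 3L, 2L),
              list(layerMaxPool(3L, 2L)),
              list(inceptionModule(2L * f, f)),
              list(layerMaxPool(3L, 2L)),
              list(inceptionModule(3L * f, f)))
  list(mod = seqModList(layers), outCh = 3L * f)
}

backboneInceptionResnet <- function(inCh, scale) {
  f <- pmax(4L, as.integer(round(32 * scale / 4)))
  ## inception module projected back to its input width, added residually
  resInc <- function(ch) residualMod(
    seqMod(inceptionModule(ch, f), layerConv2d(3L * f, ch, 1L, 1L, 0L)),
    NULL)
  layers <- c(list(layerAvgPool(2L, 2L)),
              convBnRelu2d(inCh, f, 3L, 2L),
              convBnRelu2d(f, 2L * f, 3L, 2L),
              list(layerMaxPool(3L, 2L)),
              list(resInc(2L * f), layerRelu()),
              list(layerMaxPool(3L, 2L)),
              list(resInc(2L * f), layerRelu()))
  list(mod = seqModList(layers), outCh = 2L * f)
}

sepConvBnRelu <- function(inCh, f) {
  list(layerDwConv2d(inCh, 3L, 1L, 1L), layerConv2d(inCh, f, 1L, 1L, 0L),
       layerBn(f), layerRelu())
}

backboneXception <- function(inCh, scale) {
  f <- pmax(4L, as.integer(round(c(32, 64, 128) * scale / 4)))
  layers <- c(list(layerAvgPool(2L, 2L)),
              convBnRelu2d(inCh, f[1], 3L, 2L))
  prev <- f[1]
  for (st in 2:3) {
    layers <- c(layers, sepConvBnRelu(prev, f[st]),
                sepConvBnRelu(f[st], f[st]),
                list(layerMaxPool(3L, 2L)))
    prev <- f[st]
  }
  list(mod = seqModList(layers), outCh = prev)
}

buildBackbone <- function(id, inCh, scale) {
  switch(id,
         TINY = backboneTiny(inCh),
         VGG16 = backboneVgg(inCh, scale),
         ResNet50V2 = backboneResnet(inCh, scale),
         InceptionV3 = backboneInception(inCh, scale),
         InceptionResNetV2 = backboneInceptionResnet(inCh, scale),
         Xception = backboneXception(inCh, scale))
}

## ---- model builders --------------------------------------------------

#' Build a 2-D image classifier
#'
#' Backbone feature extractor, global average pooling, dense(`denseSize`)
#' with ReLU, dropout, and a 2-way output (softmax applied by
#' [predictProba()] and by the training loss).
#'
#' @param spec An [imageModelSpec()].
#' @param seed Seed for the weight initialization.
#' @return A [CnnModel-class].
#' @export
buildImageModel <- function(spec = imageModelSpec(), seed = 1) {
  stopifnot(identical(spec$type, "image"))
  withSeed(seed, {
    bb <- buildBackbone(spec$backboneId, spec$inputShape[3], spec$widthScale)
    net <- seqModList(c(bb$mod$layers, list(
      layerGap(),
      layerDense(bb$outCh, spec$denseSize), layerRelu(),
      layerDropout(spec$dropoutRate),
      layerDense(spec$denseSize, spec$nClasses))))
    new("CnnModel", spec = spec, net = net, inputKind = "image")
  })
}

tsBlockStack <- function(spec, inCh) {
  layers <- list()
  len <- spec$inputLen
  prev <- inCh
  for (f in spec$filters) {
    if (len < spec$kernelSize) break  # kernel no longer fits: drop block
    layers <- c(layers, list(layerConv1d(prev, f, spec$kernelSize,
                                         spec$convStride),
                             layerBn(f), layerRelu()))
    len <- (len - spec$kernelSize) %/% spec$convStride + 1L
    if (len >= spec$poolSize) {
      layers <- c(layers, list(layerMaxPool(spec$poolSize, spec$poolStride)))
      len <- (len - spec$poolSize) %/% spec$poolStride + 1L
    }
    prev <- f
  }
  list(layers = layers, outCh = prev)
}

#' Build a 1-D time-series classifier
#'
#' `single`: one conv-block stack over the (1250, 12) tensor, GAP, dropout
#' 0.5, 2-way output. `multi`: 12 weight-independent branch stacks over
#' (1250, 1), concatenated GAP features, 2-way output without dropout.
#'
#' @param spec A [tsModelSpec()].
#' @param seed Seed for the weight initialization.
#' @return A [CnnModel-class].
#' @export
buildTsModel <- function(spec = tsModelSpec("single"), seed = 1) {
  stopifnot(identical(spec$type, "ts"))
  withSeed(seed, {
    if (spec$mode == "single") {
      st <- tsBlockStack(spec, spec$nLeads)
      net <- seqModList(c(st$layers, list(
        layerGap(), layerDropout(spec$dropoutRate),
        layerDense(st$outCh, 2L))))
      new("CnnModel", spec = spec, net = net, inputKind = "ts")
    } else {
      ## 12 weight-independent branches, one per lead, realised as
      ## grouped (block-diagonal) convolutions: group g only ever sees
      ## lead g, and the GAP features concatenate group-major --
      ## mathematically identical to 12 parallel (1250, 1) branches.
      layers <- list()
      len <- spec$inputLen
      cinG <- 1L
      for (f in spec$filters) {
        if (len < spec$kernelSize) break
        layers <- c(layers, list(
          layerGConv1d(spec$nLeads, cinG, f, spec$kernelSize,
                       spec$convStride),
          layerBn(f * spec$nLeads), layerRelu()))
        len <- (len - spec$kernelSize) %/% spec$convStride + 1L
        if (len >= spec$poolSize) {
          layers <- c(layers,
                      list(layerMaxPool(spec$poolSize, spec$poolStride)))
          len <- (len - spec$poolSize) %/% spec$poolStride + 1L
        }
        cinG <- f
      }
      net <- seqModList(c(layers, list(
        layerGap(), layerDense(cinG * spec$nLeads, 2L))))
      new("CnnModel", spec = spec, net = net, inputKind = "ts_multi")
    }
  })
}

inputShapeOf <- function(model) {
  if (model@inputKind == "image")
    list(kind = "t2d", dims = list(model@spec$inputShape[1],
                                   model@spec$inputShape[2],
                                   model@spec$inputShape[3]))
  else list(kind = "t1d", dims = list(model@spec$inputLen,
                                      model@spec$nLeads))
}

#' Per-layer summary of a built model
#'
#' @param model A [CnnModel-class].
#' @return data.frame with layer name, output shape, and parameter count.
#' @export
modelSummary <- function(model) {
  stopifnot(is(model, "CnnModel"))
  nnShapes(model@net, inputShapeOf(model))$rows
}

#' Trainable parameter count
#'
#' @param model A [CnnModel-class].
#' @return Integer number of trainable parameters.
#' @export
countParams <- function(model) nnCountParams(model@net)

## ---- batch assembly --------------------------------------------------

## Pack a (H, W, 3) double array in [0,1] into a compact raw vector.
#' Pack an image tensor into raw bytes
#'
#' Compact storage for large cohorts: quantizes a [0,1] image tensor to
#' 8-bit bytes (the renderer's native depth, so nothing is lost for
#' synthetic printouts).
#'
#' @param arr Numeric array (height, width, 3) in [0, 1].
#' @return Raw vector with a `dims` attribute; see [unpackImageTensor()].
#' @export
packImageTensor <- function(arr) {
  r <- as.raw(round(pmin(pmax(arr, 0), 1) * 255))
  attr(r, "dims") <- dim(arr)
  r
}

#' @rdname packImageTensor
#' @param r A raw vector from [packImageTensor()].
#' @export
unpackImageTensor <- function(r) {
  array(as.integer(r) / 255, dim = attr(r, "dims"))
}

itemToMatrix <- function(item) {
  if (is.raw(item)) item <- unpackImageTensor(item)
  if (is(item, "SignalTensor")) item <- tensorValues(item)
  item
}

## Assemble items idx into the model's batched input tensor.
assembleBatch <- function(items, idx, inputKind) {
  n <- length(idx)
  first <- itemToMatrix(items[[idx[1]]])
  if (inputKind == "image") {
    d <- dim(first)
    HW <- d[1] * d[2]
    X <- matrix(0, n * HW, 3L)
    for (i in seq_len(n)) {
      a <- itemToMatrix(items[[idx[i]]])
      X[(i - 1L) * HW + seq_len(HW), ] <- matrix(a, HW, 3L)
    }
    tens2d(X, n, d[1], d[2])
  } else {
    L <- nrow(first); C <- ncol(first)
    X <- matrix(0, n * L, C)
    for (i in seq_len(n))
      X[(i - 1L) * L + seq_len(L), ] <- itemToMatrix(items[[idx[i]]])
    tens1d(X, n, L)  # grouped convs keep the 12 leads weight-separate
  }
}

#' Class probabilities for a set of records
#'
#' Inference-mode forward pass (dropout disabled, batch norm using running
#' statistics); deterministic.
#'
#' @param model A trained [CnnModel-class].
#' @param items List of inputs: image tensors (arrays or packed raw
#'   vectors) for image models, 1250 x 12 matrices or
#'   [SignalTensor-class]es for time-series models.
#' @param batchSize Records per forward pass.
#' @return N x 2 matrix of class probabilities, columns `NOR`, `VPC`;
#'   rows sum to 1.
#' @export
predictProba <- function(model, items, batchSize = 64L) {
  stopifnot(is(model, "CnnModel"))
  n <- length(items)
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("NOR", "VPC")))
  for (s in seq(1L, n, by = batchSize)) {
    idx <- s:min(n, s + batchSize - 1L)
    xb <- assembleBatch(items, idx, model@inputKind)
    z <- nnForward(model@net, xb, training = FALSE)$out$x
    out[idx, ] <- softmaxRows(z)
  }
  out
}
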