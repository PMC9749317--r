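## Training loop: Adam + categorical cross-entropy, early stopping on
## validation loss with best-weights restoration.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 0.0011,
#' categorical cross-entropy, up to 400 epochs, batch size 32, early
#' stopping patience 250 epochs on the validation loss.
#'
#' @param learningRate Adam learning rate.
#' @param epochs Maximum number of epochs.
#' @param batchSize Mini-batch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); `patience = 0` stops at the first non-improving epoch.
#' @param seed Seed controlling shuffling, dropout and any weight noise.
#' @param verbose Print one line per epoch.
#' @return A config list for [trainModel()].
#' @export
trainConfig <- function(learningRate = 0.0011, epochs = 400L,
                        batchSize = 32L, patience = 250L, seed = 1L,
                        verbose = FALSE) {
  stopifnot(learningRate > 0, patience <= epochs)
  list(learningRate = learningRate, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), patience = as.integer(patience),
       seed = as.integer(seed), verbose = isTRUE(verbose))
}

## labels -> one-hot (NOR, VPC) matrix
labelsToY <- function(labels) {
  y <- as.integer(labels == "VPC")
  cbind(NOR = 1 - y, VPC = y)
}

datasetCheck <- function(data) {
  stopifnot(is.list(data), !is.null(data$x), !is.null(data$labels))
  if (length(data$x) == 0L) stopf("empty dataset")
  if (length(data$x) != length(data$labels))
    stopf("x and labels differ in length")
  invisible(TRUE)
}

#' Train a CNN classifier
#'
#' Mini-batch Adam on categorical cross-entropy. Training stops at the
#' epoch limit or once the validation loss has failed to improve for more
#' than `patience` epochs; the best-validation weights are restored
#' (without validation data, the training loss is monitored instead).
#' Deterministic for a fixed seed and single-threaded BLAS.
#'
#' @param model A [CnnModel-class] from [buildImageModel()] or
#'   [buildTsModel()].
#' @param train,validation Datasets: `list(x = <list of inputs>,
#'   labels = <"VPC"/"NOR" vector>)`. Inputs as in [predictProba()].
#' @param config A [trainConfig()].
#' @return `list(model, history)`; history is a data.frame with per-epoch
#'   loss/accuracy (and validation columns when given) plus the epoch whose
#'   weights were restored in attribute `"best_epoch"`.
#' @export
trainModel <- function(model, train, validation = NULL,
                       config = trainConfig()) {
  stopifnot(is(model, "CnnModel"))
  datasetCheck(train)
  if (!is.null(validation)) {
    datasetCheck(validation)
    overlap <- intersect(train$patients %||% character(0),
                         validation$patients %||% character(0))
    if (length(overlap))
      stopf("train and validation share %d patient(s): leakage",
            length(overlap))
  }
  Y <- labelsToY(train$labels)
  n <- length(train$x)
  net <- model@net
  state <- NULL
  step <- 0L
  best <- list(loss = Inf, net = net, epoch = 0L)
  bad <- 0L
  hist <- vector("list", config$epochs)

  evalLoss <- function(net, data) {
    Yv <- labelsToY(data$labels)
    m <- length(data$x)
    tot <- 0; acc <- 0
    for (s in seq(1L, m, by = 64L)) {
      idx <- s:min(m, s + 63L)
      xb <- assembleBatch(data$x, idx, model@inputKind)
      z <- nnForward(net, xb, training = FALSE)$out$x
      r <- softmaxCrossEntropy(z, Yv[idx, , drop = FALSE])
      tot <- tot + r$loss * length(idx)
      acc <- acc + sum(max.col(r$p) == max.col(Yv[idx, , drop = FALSE]))
    }
    c(loss = tot / m, acc = acc / m)
  }

  withSeed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      epLoss <- 0; epAcc <- 0
      for (s in seq(1L, n, by = config$batchSize)) {
        idx <- ord[s:min(n, s + config$batchSize - 1L)]
        xb <- assembleBatch(train$x, idx, model@inputKind)
        fw <- nnForward(net, xb, training = TRUE)
        net <- fw$mod
        r <- softmaxCrossEntropy(fw$out$x, Y[idx, , drop = FALSE])
        epLoss <- epLoss + r$loss * length(idx)
        epAcc <- epAcc + sum(max.col(r$p) == max.col(Y[idx, , drop = FALSE]))
        bw <- nnBackward(net, fw$cache, tensFeat(r$grad),
                         needInput = FALSE)
        step <- step + 1L
        up <- adamStep(net, bw$grads, state, config$learningRate, step)
        net <- up$mod; state <- up$state
      }
      row <- data.frame(epoch = epoch, loss = epLoss / n, acc = epAcc / n)
      if (!is.null(validation)) {
        v <- evalLoss(net, validation)
        row$val_loss <- v[["loss"]]; row$val_acc <- v[["acc"]]
        monitor <- row$val_loss
      } else {
        monitor <- row$loss
      }
      hist[[epoch]] <- row
      if (config$verbose)
        message(sprintf("epoch %d: %s", epoch,
                        paste(sprintf("%s=%.4f", names(row)[-1],
                                      as.numeric(row[-1])),
                              collapse = " ")))
      if (monitor < best$loss) {
        best <- list(loss = monitor, net = net, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad > config$patience) break
      }
    }
  })
  model@net <- best$net
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  attr(history, "best_epoch") <- best$epoch
  list(model = model, history = history)
}
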