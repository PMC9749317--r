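## Minimal CNN engine: batched forward/backward over a layer tree, with
## conv1d/conv2d (valid or zero padding), depthwise conv, batch
## normalization, ReLU, max/average pooling, global average pooling,
## dropout, dense layers, softmax cross-entropy and Adam.
##
## Batched tensors are lists:
##   t1d : x = (N*L)  x C matrix, rows sample-major (row = (i-1)*L + p)
##   t2d : x = (N*H*W) x C matrix, spatial index p = (w-1)*H + h
##   feat: x = N x D matrix
## All heavy lifting is per-tap row gathering plus BLAS matrix products.

tens1d <- function(x, n, len) list(kind = "t1d", x = x, n = n, len = len)
tens2d <- function(x, n, h, w) list(kind = "t2d", x = x, n = n, h = h, w = w)
tensFeat <- function(x) list(kind = "feat", x = x, n = nrow(x))

spatialSize <- function(t) if (t$kind == "t1d") t$len else t$h * t$w

## ---- index templates -------------------------------------------------

## Tap template for 1-D windows over a (padded) length Lp.
tmpl1d <- function(Lp, k, stride) {
  L2 <- (Lp - k) %/% stride + 1L
  if (L2 < 1L) stopf("window of size %d does not fit length %d", k, Lp)
  list(start = (seq_len(L2) - 1L) * stride + 1L, off = 0:(k - 1L),
       P = L2, k = k)
}

## Tap template for 2-D windows over padded (Hp, Wp), column-major spatial.
tmpl2d <- function(Hp, Wp, kh, kw, stride) {
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  if (Ho < 1L || Wo < 1L)
    stopf("window %dx%d does not fit input %dx%d", kh, kw, Hp, Wp)
  list(start = as.vector(outer((seq_len(Ho) - 1L) * stride + 1L,
                               (seq_len(Wo) - 1L) * stride * Hp, "+")),
       off = as.vector(outer(0:(kh - 1L), (0:(kw - 1L)) * Hp, "+")),
       P = Ho * Wo, k = kh * kw, Ho = Ho, Wo = Wo)
}

## Tap plans: for a pooling/conv layer, tap[, t] holds the source row of
## tap t for every output cell (rows ordered cell-major: (i-1)*P + po).
## Pure functions of (geometry, batch size), memoised per shape so repeated
## batches skip the index arithmetic.
.nnCache <- new.env(parent = emptyenv())

tapPlan <- function(tag, Lp, startVec, off, N) {
  key <- paste(tag, Lp, N, length(startVec), length(off), sep = "|")
  plan <- .nnCache[[key]]
  if (is.null(plan)) {
    base <- rep((0:(N - 1L)) * Lp, each = length(startVec)) +
      rep(startVec, N)
    plan <- list(tap = outer(base, off, "+"), nIn = N * Lp,
                 P = length(startVec), k = length(off))
    .nnCache[[key]] <- plan
  }
  plan
}

## im2col via one gather per tap: returns (N*P) x (k*C), columns ordered
## tap-fastest within channel (matching the (k*C) x F weight layout).
im2col <- function(xp, plan, C) {
  k <- plan$k
  Xcol <- matrix(0, nrow(plan$tap), k * C)
  cols0 <- (0:(C - 1L)) * k
  for (t in seq_len(k))
    Xcol[, cols0 + t] <- xp[plan$tap[, t], , drop = FALSE]
  Xcol
}

## col2im: scatter-accumulate the column gradient back onto input rows.
col2im <- function(gXcol, plan, C) {
  k <- plan$k
  gxp <- matrix(0, plan$nIn, C)
  cols0 <- (0:(C - 1L)) * k
  for (t in seq_len(k)) {
    idx <- plan$tap[, t]
    gxp[idx, ] <- gxp[idx, , drop = FALSE] +
      gXcol[, cols0 + t, drop = FALSE]
  }
  gxp
}

## Zero-pad each sample's spatial block. map = interior indices.
padRows <- function(x, N, Lp, map) {
  xp <- matrix(0, N * Lp, ncol(x))
  idx <- rep((0:(N - 1L)) * Lp, each = length(map)) + rep(map, N)
  xp[idx, ] <- x
  list(xp = xp, idx = idx)
}

pad1dMap <- function(L, p) p + seq_len(L)
pad2dMap <- function(H, W, p) {
  Hp <- H + 2L * p
  as.vector(outer(p + seq_len(H), (p + seq_len(W) - 1L) * Hp, "+"))
}

## ---- initialisers ----------------------------------------------------

heInit <- function(nr, nc, fanIn) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)
}

## ---- layer constructors ---------------------------------------------

layerConv1d <- function(inCh, filters, k, stride = 3L, pad = 0L) {
  list(kind = "conv1d", W = heInit(k * inCh, filters, k * inCh),
       b = numeric(filters), k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), inCh = as.integer(inCh),
       filters = as.integer(filters))
}

## Grouped 1-D conv: `groups` weight-independent filter banks, group g
## seeing only its own `cinG` input channels (block-diagonal weights).
## Equivalent to `groups` parallel branches with concatenated outputs.
layerGConv1d <- function(groups, cinG, filters, k, stride = 3L, pad = 0L) {
  W <- array(0, dim = c(k * cinG, filters, groups))
  for (g in seq_len(groups))
    W[, , g] <- heInit(k * cinG, filters, k * cinG)
  list(kind = "gconv1d", W = W,
       b = matrix(0, filters, groups), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       groups = as.integer(groups), cinG = as.integer(cinG),
       filters = as.integer(filters))
}

layerConv2d <- function(inCh, filters, k, stride = 1L, pad = 0L) {
  list(kind = "conv2d", W = heInit(k * k * inCh, filters, k * k * inCh),
       b = numeric(filters), k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), inCh = as.integer(inCh),
       filters = as.integer(filters))
}

layerDwConv2d <- function(inCh, k, stride = 1L, pad = 0L) {
  list(kind = "dwconv2d", W = heInit(k * k, inCh, k * k),
       b = numeric(inCh), k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), inCh = as.integer(inCh))
}

layerBn <- function(ch, momentum = 0.8, eps = 1e-5) {
  list(kind = "bn", gamma = rep(1, ch), beta = numeric(ch),
       rmean = numeric(ch), rvar = rep(1, ch), momentum = momentum,
       eps = eps)
}

layerRelu <- function() list(kind = "relu")
layerMaxPool <- function(size, stride) {
  list(kind = "maxpool", size = as.integer(size), stride = as.integer(stride))
}
layerAvgPool <- function(size, stride) {
  list(kind = "avgpool", size = as.integer(size), stride = as.integer(stride))
}
layerGap <- function() list(kind = "gap")
layerDropout <- function(rate) list(kind = "dropout", rate = rate)
layerDense <- function(inD, outD) {
  list(kind = "dense", W = heInit(inD, outD, inD), b = numeric(outD),
       inD = as.integer(inD), outD = as.integer(outD))
}

seqMod <- function(...) list(kind = "seq", layers = list(...))
seqModList <- function(layers) list(kind = "seq", layers = layers)
residualMod <- function(main, shortcut = NULL)
  list(kind = "residual", main = main, shortcut = shortcut)
branchcatMod <- function(branches) list(kind = "branchcat",
                                        branches = branches)
multiinMod <- function(branches) list(kind = "multiin", branches = branches)

## ---- forward ---------------------------------------------------------

## Forward pass. Returns list(out, cache, mod); mod carries updated batch
## norm running statistics when training.
nnForward <- function(mod, input, training = FALSE) {
  switch(mod$kind,
    seq = {
      caches <- vector("list", length(mod$layers))
      x <- input
      for (i in seq_along(mod$layers)) {
        r <- nnForward(mod$layers[[i]], x, training)
        x <- r$out; caches[[i]] <- r$cache; mod$layers[[i]] <- r$mod
      }
      list(out = x, cache = caches, mod = mod)
    },
    residual = {
      rm_ <- nnForward(mod$main, input, training)
      rs <- if (is.null(mod$shortcut)) list(out = input, cache = NULL,
                                            mod = NULL)
            else nnForward(mod$shortcut, input, training)
      out <- rm_$out; out$x <- out$x + rs$out$x
      if (!is.null(mod$shortcut)) mod$shortcut <- rs$mod
      mod$main <- rm_$mod
      list(out = out, cache = list(main = rm_$cache, short = rs$cache),
           mod = mod)
    },
    branchcat = {
      rs <- lapply(mod$branches, nnForward, input = input,
                   training = training)
      mod$branches <- lapply(rs, `[[`, "mod")
      outs <- lapply(rs, `[[`, "out")
      out <- outs[[1]]
      out$x <- do.call(cbind, lapply(outs, `[[`, "x"))
      list(out = out, cache = list(caches = lapply(rs, `[[`, "cache"),
                                   widths = vapply(outs, function(o)
                                     ncol(o$x), 1L)),
           mod = mod)
    },
    multiin = {
      stopifnot(is.list(input), length(input) == length(mod$branches))
      rs <- mapply(function(br, inp) nnForward(br, inp, training),
                   mod$branches, input, SIMPLIFY = FALSE)
      mod$branches <- lapply(rs, `[[`, "mod")
      outs <- lapply(rs, `[[`, "out")
      out <- tensFeat(do.call(cbind, lapply(outs, `[[`, "x")))
      list(out = out, cache = list(caches = lapply(rs, `[[`, "cache"),
                                   widths = vapply(outs, function(o)
                                     ncol(o$x), 1L)),
           mod = mod)
    },
    conv1d = {
      N <- input$n; L <- input$len; C <- ncol(input$x)
      Lp <- L + 2L * mod$pad
      if (mod$pad > 0L) {
        pr <- padRows(input$x, N, Lp, pad1dMap(L, mod$pad))
        xp <- pr$xp; padIdx <- pr$idx
      } else { xp <- input$x; padIdx <- NULL }
      tm <- tmpl1d(Lp, mod$k, mod$stride)
      plan <- tapPlan(sprintf("c1|%d|%d", mod$k, mod$stride), Lp,
                      tm$start, tm$off, N)
      Xcol <- im2col(xp, plan, C)
      z <- Xcol %*% mod$W
      z <- z + rep(mod$b, each = nrow(z))
      list(out = tens1d(z, N, tm$P),
           cache = list(Xcol = Xcol, plan = plan, C = C,
                        padIdx = padIdx, inLen = L, N = N),
           mod = mod)
    },
    gconv1d = {
      N <- input$n; L <- input$len; C <- ncol(input$x)
      stopifnot(C == mod$groups * mod$cinG)
      Lp <- L + 2L * mod$pad
      if (mod$pad > 0L) {
        pr <- padRows(input$x, N, Lp, pad1dMap(L, mod$pad))
        xp <- pr$xp; padIdx <- pr$idx
      } else { xp <- input$x; padIdx <- NULL }
      tm <- tmpl1d(Lp, mod$k, mod$stride)
      plan <- tapPlan(sprintf("c1|%d|%d", mod$k, mod$stride), Lp,
                      tm$start, tm$off, N)
      Xcol <- im2col(xp, plan, C)
      kc <- mod$k * mod$cinG; f <- mod$filters
      z <- matrix(0, nrow(Xcol), f * mod$groups)
      for (g in seq_len(mod$groups))
        z[, (g - 1L) * f + seq_len(f)] <-
          Xcol[, (g - 1L) * kc + seq_len(kc), drop = FALSE] %*% mod$W[, , g]
      z <- z + rep(as.vector(mod$b), each = nrow(z))
      list(out = tens1d(z, N, tm$P),
           cache = list(Xcol = Xcol, plan = plan, C = C,
                        padIdx = padIdx, inLen = L, N = N),
           mod = mod)
    },
    conv2d = {
      N <- input$n; H <- input$h; W <- input$w; C <- ncol(input$x)
      Hp <- H + 2L * mod$pad; Wp <- W + 2L * mod$pad
      if (mod$pad > 0L) {
        pr <- padRows(input$x, N, Hp * Wp, pad2dMap(H, W, mod$pad))
        xp <- pr$xp; padIdx <- pr$idx
      } else { xp <- input$x; padIdx <- NULL }
      tm <- tmpl2d(Hp, Wp, mod$k, mod$k, mod$stride)
      plan <- tapPlan(sprintf("c2|%d|%d|%d", mod$k, mod$stride, Hp),
                      Hp * Wp, tm$start, tm$off, N)
      Xcol <- im2col(xp, plan, C)
      z <- Xcol %*% mod$W
      z <- z + rep(mod$b, each = nrow(z))
      list(out = tens2d(z, N, tm$Ho, tm$Wo),
           cache = list(Xcol = Xcol, plan = plan, C = C,
                        padIdx = padIdx, N = N),
           mod = mod)
    },
    dwconv2d = {
      N <- input$n; H <- input$h; W <- input$w; C <- ncol(input$x)
      Hp <- H + 2L * mod$pad; Wp <- W + 2L * mod$pad
      if (mod$pad > 0L) {
        pr <- padRows(input$x, N, Hp * Wp, pad2dMap(H, W, mod$pad))
        xp <- pr$xp; padIdx <- pr$idx
      } else { xp <- input$x; padIdx <- NULL }
      tm <- tmpl2d(Hp, Wp, mod$k, mod$k, mod$stride)
      plan <- tapPlan(sprintf("dw|%d|%d|%d", mod$k, mod$stride, Hp),
                      Hp * Wp, tm$start, tm$off, N)
      ## per-channel correlation: accumulate one tap at a time
      z <- matrix(rep(mod$b, each = plan$P * N), plan$P * N, C)
      slices <- vector("list", plan$k)
      for (t in seq_len(plan$k)) {
        slices[[t]] <- xp[plan$tap[, t], , drop = FALSE]
        z <- z + slices[[t]] * rep(mod$W[t, ], each = plan$P * N)
      }
      list(out = tens2d(z, N, tm$Ho, tm$Wo),
           cache = list(slices = slices, plan = plan, C = C,
                        padIdx = padIdx, N = N),
           mod = mod)
    },
    bn = {
      x <- input$x; R <- nrow(x)
      if (training) {
        mu <- colMeans(x)
        xc <- x - rep(mu, each = R)
        v <- colMeans(xc * xc)
        sd_ <- sqrt(v + mod$eps)
        xhat <- xc / rep(sd_, each = R)
        mod$rmean <- mod$momentum * mod$rmean + (1 - mod$momentum) * mu
        mod$rvar <- mod$momentum * mod$rvar + (1 - mod$momentum) * v
      } else {
        sd_ <- sqrt(mod$rvar + mod$eps)
        xhat <- (x - rep(mod$rmean, each = R)) / rep(sd_, each = R)
      }
      out <- input
      out$x <- xhat * rep(mod$gamma, each = R) + rep(mod$beta, each = R)
      list(out = out, cache = list(xhat = xhat, sd = sd_, R = R,
                                   training = training),
           mod = mod)
    },
    relu = {
      out <- input
      keep <- input$x > 0
      out$x <- input$x * keep
      list(out = out, cache = keep, mod = mod)
    },
    maxpool = {
      N <- input$n; C <- ncol(input$x)
      if (input$kind == "t1d") {
        tm <- tmpl1d(input$len, mod$size, mod$stride)
        Lp <- input$len
        outTens <- function(z) tens1d(z, N, tm$P)
      } else {
        tm <- tmpl2d(input$h, input$w, mod$size, mod$size, mod$stride)
        Lp <- input$h * input$w
        outTens <- function(z) tens2d(z, N, tm$Ho, tm$Wo)
      }
      plan <- tapPlan(sprintf("mp|%d|%d|%d", mod$size, mod$stride, Lp),
                      Lp, tm$start, tm$off, N)
      z <- xp <- input$x
      z <- xp[plan$tap[, 1L], , drop = FALSE]
      whichT <- matrix(1L, nrow(z), C)   # winning tap per output cell
      for (t in seq_len(plan$k)[-1L]) {
        s <- xp[plan$tap[, t], , drop = FALSE]
        better <- s > z
        z[better] <- s[better]
        whichT[better] <- t
      }
      list(out = outTens(z),
           cache = list(whichT = whichT, plan = plan, C = C),
           mod = mod)
    },
    avgpool = {
      N <- input$n; C <- ncol(input$x)
      if (input$kind == "t1d") {
        tm <- tmpl1d(input$len, mod$size, mod$stride)
        Lp <- input$len
        outTens <- function(z) tens1d(z, N, tm$P)
      } else {
        tm <- tmpl2d(input$h, input$w, mod$size, mod$size, mod$stride)
        Lp <- input$h * input$w
        outTens <- function(z) tens2d(z, N, tm$Ho, tm$Wo)
      }
      plan <- tapPlan(sprintf("ap|%d|%d|%d", mod$size, mod$stride, Lp),
                      Lp, tm$start, tm$off, N)
      z <- input$x[plan$tap[, 1L], , drop = FALSE]
      for (t in seq_len(plan$k)[-1L])
        z <- z + input$x[plan$tap[, t], , drop = FALSE]
      z <- z / plan$k
      list(out = outTens(z),
           cache = list(plan = plan, C = C),
           mod = mod)
    },
    gap = {
      N <- input$n; L <- spatialSize(input)
      grp <- rep(seq_len(N), each = L)
      z <- rowsum(input$x, grp) / L
      list(out = tensFeat(z), cache = list(L = L, N = N), mod = mod)
    },
    dropout = {
      if (!training || mod$rate <= 0)
        return(list(out = input, cache = NULL, mod = mod))
      keep <- matrix(runif(length(input$x)) >= mod$rate,
                     nrow(input$x), ncol(input$x)) / (1 - mod$rate)
      out <- input
      out$x <- input$x * keep
      list(out = out, cache = keep, mod = mod)
    },
    dense = {
      z <- input$x %*% mod$W
      z <- z + rep(mod$b, each = nrow(z))
      list(out = tensFeat(z), cache = list(x = input$x), mod = mod)
    },
    stopf("unknown layer kind '%s'", mod$kind))
}

## ---- backward --------------------------------------------------------

## Backward pass: returns list(gin = gradient tensor w.r.t. input,
## grads = nested structure matching the module tree). With
## needInput = FALSE the gradient w.r.t. the module input is skipped
## (used for the first layer, whose input is data, not activations).
nnBackward <- function(mod, cache, gout, needInput = TRUE) {
  switch(mod$kind,
    seq = {
      grads <- vector("list", length(mod$layers))
      g <- gout
      for (i in rev(seq_along(mod$layers))) {
        r <- nnBackward(mod$layers[[i]], cache[[i]], g,
                        needInput = needInput || i > 1L)
        g <- r$gin
        grads[i] <- list(r$grads)  # [[<-]] with NULL would drop the slot
      }
      list(gin = g, grads = grads)
    },
    residual = {
      rm_ <- nnBackward(mod$main, cache$main, gout, needInput = TRUE)
      if (is.null(mod$shortcut)) {
        gin <- rm_$gin; gin$x <- gin$x + gout$x
        list(gin = gin, grads = list(main = rm_$grads, short = NULL))
      } else {
        rs <- nnBackward(mod$shortcut, cache$short, gout,
                         needInput = TRUE)
        gin <- rm_$gin; gin$x <- gin$x + rs$gin$x
        list(gin = gin, grads = list(main = rm_$grads, short = rs$grads))
      }
    },
    branchcat = {
      ends <- cumsum(cache$widths)
      starts <- ends - cache$widths + 1L
      gin <- NULL; grads <- vector("list", length(mod$branches))
      for (i in seq_along(mod$branches)) {
        gi <- gout
        gi$x <- gout$x[, starts[i]:ends[i], drop = FALSE]
        r <- nnBackward(mod$branches[[i]], cache$caches[[i]], gi,
                        needInput = TRUE)
        grads[[i]] <- r$grads
        if (is.null(gin)) gin <- r$gin else gin$x <- gin$x + r$gin$x
      }
      list(gin = gin, grads = grads)
    },
    multiin = {
      ends <- cumsum(cache$widths)
      starts <- ends - cache$widths + 1L
      gins <- vector("list", length(mod$branches))
      grads <- vector("list", length(mod$branches))
      for (i in seq_along(mod$branches)) {
        gi <- gout
        gi$x <- gout$x[, starts[i]:ends[i], drop = FALSE]
        r <- nnBackward(mod$branches[[i]], cache$caches[[i]], gi,
                        needInput = needInput)
        grads[[i]] <- r$grads; gins[[i]] <- r$gin
      }
      list(gin = gins, grads = grads)
    },
    gconv1d = {
      cc <- cache
      kc <- mod$k * mod$cinG; f <- mod$filters
      gW <- array(0, dim = dim(mod$W))
      gb <- matrix(colSums(gout$x), f, mod$groups)
      gXcol <- if (needInput) matrix(0, nrow(cc$Xcol), ncol(cc$Xcol))
               else NULL
      for (g in seq_len(mod$groups)) {
        ci <- (g - 1L) * kc + seq_len(kc)
        co <- (g - 1L) * f + seq_len(f)
        gW[, , g] <- crossprod(cc$Xcol[, ci, drop = FALSE],
                               gout$x[, co, drop = FALSE])
        if (needInput)
          gXcol[, ci] <- tcrossprod(gout$x[, co, drop = FALSE],
                                    mod$W[, , g])
      }
      if (!needInput)
        return(list(gin = NULL, grads = list(W = gW, b = gb)))
      gxp <- col2im(gXcol, cc$plan, cc$C)
      gx <- if (is.null(cc$padIdx)) gxp else gxp[cc$padIdx, , drop = FALSE]
      list(gin = tens1d(gx, cc$N, cc$inLen), grads = list(W = gW, b = gb))
    },
    conv1d = , conv2d = {
      cc <- cache
      gW <- crossprod(cc$Xcol, gout$x)
      gb <- colSums(gout$x)
      if (!needInput)
        return(list(gin = NULL, grads = list(W = gW, b = gb)))
      gXcol <- tcrossprod(gout$x, mod$W)
      gxp <- col2im(gXcol, cc$plan, cc$C)
      gx <- if (is.null(cc$padIdx)) gxp
            else gxp[cc$padIdx, , drop = FALSE]
      gin <- if (mod$kind == "conv1d") tens1d(gx, cc$N, cc$inLen)
             else { t <- gout; t$x <- gx; t }  # dims fixed by caller
      list(gin = gin, grads = list(W = gW, b = gb))
    },
    dwconv2d = {
      cc <- cache
      C <- cc$C
      plan <- cc$plan
      gW <- matrix(0, plan$k, C)
      gb <- colSums(gout$x)
      gxp <- if (needInput) matrix(0, plan$nIn, C) else NULL
      R <- plan$P * cc$N
      for (t in seq_len(plan$k)) {
        gW[t, ] <- colSums(cc$slices[[t]] * gout$x)
        if (needInput) {
          idx <- plan$tap[, t]
          gxp[idx, ] <- gxp[idx, , drop = FALSE] +
            gout$x * rep(mod$W[t, ], each = R)
        }
      }
      if (!needInput)
        return(list(gin = NULL, grads = list(W = gW, b = gb)))
      gx <- if (is.null(cc$padIdx)) gxp else gxp[cc$padIdx, , drop = FALSE]
      t <- gout; t$x <- gx
      list(gin = t, grads = list(W = gW, b = gb))
    },
    bn = {
      cc <- cache; R <- cc$R
      ggamma <- colSums(gout$x * cc$xhat)
      gbeta <- colSums(gout$x)
      gxhat <- gout$x * rep(mod$gamma, each = R)
      if (cc$training) {
        m1 <- colMeans(gxhat)
        m2 <- colMeans(gxhat * cc$xhat)
        gx <- (gxhat - rep(m1, each = R) - cc$xhat * rep(m2, each = R)) /
          rep(cc$sd, each = R)
      } else {
        gx <- gxhat / rep(cc$sd, each = R)
      }
      gin <- gout; gin$x <- gx
      list(gin = gin, grads = list(gamma = ggamma, beta = gbeta))
    },
    relu = {
      gin <- gout; gin$x <- gout$x * cache
      list(gin = gin, grads = NULL)
    },
    maxpool = {
      if (!needInput) return(list(gin = NULL, grads = NULL))
      plan <- cache$plan
      gx <- matrix(0, plan$nIn, cache$C)
      for (t in seq_len(plan$k)) {
        sel <- gout$x * (cache$whichT == t)
        idx <- plan$tap[, t]
        gx[idx, ] <- gx[idx, , drop = FALSE] + sel
      }
      gin <- gout; gin$x <- gx
      ## spatial dims of gin are stale but only $x is consumed upstream
      list(gin = gin, grads = NULL)
    },
    avgpool = {
      if (!needInput) return(list(gin = NULL, grads = NULL))
      plan <- cache$plan
      gx <- matrix(0, plan$nIn, ncol(gout$x))
      g <- gout$x / plan$k
      for (t in seq_len(plan$k)) {
        idx <- plan$tap[, t]
        gx[idx, ] <- gx[idx, , drop = FALSE] + g
      }
      gin <- gout; gin$x <- gx
      list(gin = gin, grads = NULL)
    },
    gap = {
      gx <- gout$x[rep(seq_len(cache$N), each = cache$L), ,
                   drop = FALSE] / cache$L
      gin <- gout; gin$x <- gx
      list(gin = gin, grads = NULL)
    },
    dropout = {
      if (is.null(cache)) return(list(gin = gout, grads = NULL))
      gin <- gout; gin$x <- gout$x * cache
      list(gin = gin, grads = NULL)
    },
    dense = {
      gW <- crossprod(cache$x, gout$x)
      gb <- colSums(gout$x)
      gin <- tensFeat(tcrossprod(gout$x, mod$W))
      list(gin = gin, grads = list(W = gW, b = gb))
    },
    stopf("unknown layer kind '%s'", mod$kind))
}

## Caveat encoded above: backward through pooling/conv re-labels only $x;
## upstream layers consume only $x and the true spatial dims from their own
## caches, so the stale dims fields are never read.

## ---- parameter tree utilities ---------------------------------------

TRAINABLE <- list(conv1d = c("W", "b"), gconv1d = c("W", "b"),
                  conv2d = c("W", "b"),
                  dwconv2d = c("W", "b"), dense = c("W", "b"),
                  bn = c("gamma", "beta"))

childSlots <- function(mod) {
  switch(mod$kind,
    seq = "layers", residual = c("main", "shortcut"),
    branchcat = "branches", multiin = "branches", character(0))
}

childList <- function(mod) {
  switch(mod$kind,
    seq = mod$layers,
    residual = Filter(Negate(is.null), list(mod$main, mod$shortcut)),
    branchcat = mod$branches, multiin = mod$branches, list())
}

## Total trainable parameter count.
nnCountParams <- function(mod) {
  own <- sum(vapply(TRAINABLE[[mod$kind]] %||% character(0),
                    function(nm) length(mod[[nm]]), 1))
  own + sum(vapply(childList(mod), nnCountParams, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Walk module + grads trees applying Adam to every trainable array.
## state mirrors the tree; t is the (1-based) step for bias correction.
adamStep <- function(mod, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  nms <- TRAINABLE[[mod$kind]]
  if (!is.null(nms) && !is.null(grads)) {
    if (is.null(state)) state <- list()
    for (nm in nms) {
      g <- grads[[nm]]
      if (is.null(state[[nm]]))
        state[[nm]] <- list(m = g * 0, v = g * 0)
      st <- state[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      mod[[nm]] <- mod[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[nm]] <- st
    }
  }
  switch(mod$kind,
    seq = {
      if (is.null(state)) state <- vector("list", length(mod$layers))
      for (i in seq_along(mod$layers)) {
        r <- adamStep(mod$layers[[i]], grads[[i]], state[[i]], lr, t,
                      beta1, beta2, eps)
        mod$layers[[i]] <- r$mod
        state[i] <- list(r$state)
      }
    },
    residual = {
      if (is.null(state)) state <- list(main = NULL, short = NULL)
      r <- adamStep(mod$main, grads$main, state$main, lr, t, beta1, beta2,
                    eps)
      mod$main <- r$mod; state$main <- r$state
      if (!is.null(mod$shortcut)) {
        r <- adamStep(mod$shortcut, grads$short, state$short, lr, t,
                      beta1, beta2, eps)
        mod$shortcut <- r$mod; state$short <- r$state
      }
    },
    branchcat = , multiin = {
      if (is.null(state)) state <- vector("list", length(mod$branches))
      for (i in seq_along(mod$branches)) {
        r <- adamStep(mod$branches[[i]], grads[[i]], state[[i]], lr, t,
                      beta1, beta2, eps)
        mod$branches[[i]] <- r$mod
        state[i] <- list(r$state)
      }
    })
  list(mod = mod, state = state)
}

## ---- shape inference (summaries, validation) -------------------------

## shape: list(kind = "t1d"/"t2d"/"feat", dims = c(len, ch) / c(h, w, ch)
## / d). Returns data.frame of layers.
nnShapes <- function(mod, shape, rows = NULL, prefix = "") {
  if (is.null(rows)) rows <- data.frame(layer = character(),
                                        output = character(),
                                        n_params = numeric())
  addRow <- function(rows, nm, shape, np) {
    rbind(rows, data.frame(
      layer = paste0(prefix, nm),
      output = paste(unlist(shape$dims), collapse = "x"),
      n_params = np))
  }
  outLen <- function(L, k, s, p) (L + 2L * p - k) %/% s + 1L
  switch(mod$kind,
    seq = {
      for (i in seq_along(mod$layers)) {
        r <- nnShapes(mod$layers[[i]], shape, rows, prefix)
        rows <- r$rows; shape <- r$shape
      }
      list(rows = rows, shape = shape)
    },
    residual = {
      r <- nnShapes(mod$main, shape, rows, paste0(prefix, "res."))
      list(rows = r$rows, shape = r$shape)
    },
    branchcat = {
      ch <- 0L; r <- NULL
      for (i in seq_along(mod$branches)) {
        r <- nnShapes(mod$branches[[i]], shape, rows,
                      paste0(prefix, sprintf("b%d.", i)))
        rows <- r$rows
        ch <- ch + tail(unlist(r$shape$dims), 1)
      }
      sh <- r$shape
      sh$dims[[length(sh$dims)]] <- ch
      list(rows = rows, shape = sh)
    },
    multiin = {
      d <- 0L
      for (i in seq_along(mod$branches)) {
        r <- nnShapes(mod$branches[[i]], shape, rows,
                      paste0(prefix, sprintf("in%d.", i)))
        rows <- r$rows
        d <- d + tail(unlist(r$shape$dims), 1)
      }
      list(rows = rows, shape = list(kind = "feat", dims = list(d)))
    },
    conv1d = {
      L2 <- outLen(shape$dims[[1]], mod$k, mod$stride, mod$pad)
      sh <- list(kind = "t1d", dims = list(L2, mod$filters))
      list(rows = addRow(rows, sprintf("conv1d(k=%d,s=%d,f=%d)", mod$k,
                                       mod$stride, mod$filters),
                         sh, length(mod$W) + length(mod$b)),
           shape = sh)
    },
    gconv1d = {
      L2 <- outLen(shape$dims[[1]], mod$k, mod$stride, mod$pad)
      sh <- list(kind = "t1d",
                 dims = list(L2, mod$filters * mod$groups))
      list(rows = addRow(rows, sprintf(
        "gconv1d(k=%d,s=%d,f=%dx%d groups)", mod$k, mod$stride,
        mod$filters, mod$groups),
                         sh, length(mod$W) + length(mod$b)),
           shape = sh)
    },
    conv2d = {
      sh <- list(kind = "t2d", dims = list(
        outLen(shape$dims[[1]], mod$k, mod$stride, mod$pad),
        outLen(shape$dims[[2]], mod$k, mod$stride, mod$pad), mod$filters))
      list(rows = addRow(rows, sprintf("conv2d(k=%d,s=%d,f=%d)", mod$k,
                                       mod$stride, mod$filters),
                         sh, length(mod$W) + length(mod$b)),
           shape = sh)
    },
    dwconv2d = {
      sh <- list(kind = "t2d", dims = list(
        outLen(shape$dims[[1]], mod$k, mod$stride, mod$pad),
        outLen(shape$dims[[2]], mod$k, mod$stride, mod$pad), mod$inCh))
      list(rows = addRow(rows, sprintf("dwconv2d(k=%d,s=%d)", mod$k,
                                       mod$stride),
                         sh, length(mod$W) + length(mod$b)),
           shape = sh)
    },
    bn = list(rows = addRow(rows, "batchnorm", shape,
                            2 * length(mod$gamma)), shape = shape),
    relu = list(rows = addRow(rows, "relu", shape, 0), shape = shape),
    maxpool = , avgpool = {
      nm <- sprintf("%s(size=%d,s=%d)", mod$kind, mod$size, mod$stride)
      sh <- shape
      if (shape$kind == "t1d") {
        sh$dims[[1]] <- outLen(shape$dims[[1]], mod$size, mod$stride, 0L)
      } else {
        sh$dims[[1]] <- outLen(shape$dims[[1]], mod$size, mod$stride, 0L)
        sh$dims[[2]] <- outLen(shape$dims[[2]], mod$size, mod$stride, 0L)
      }
      list(rows = addRow(rows, nm, sh, 0), shape = sh)
    },
    gap = {
      ch <- tail(unlist(shape$dims), 1)
      sh <- list(kind = "feat", dims = list(ch))
      list(rows = addRow(rows, "gap", sh, 0), shape = sh)
    },
    dropout = list(rows = addRow(rows, sprintf("dropout(%.2f)", mod$rate),
                                 shape, 0), shape = shape),
    dense = {
      sh <- list(kind = "feat", dims = list(mod$outD))
      list(rows = addRow(rows, sprintf("dense(%d)", mod$outD), sh,
                         length(mod$W) + length(mod$b)),
           shape = sh)
    },
    stopf("unknown layer kind '%s'", mod$kind))
}

## ---- loss ------------------------------------------------------------

softmaxRows <- function(z) {
  m <- do.call(pmax, c(as.data.frame(z), list(0 * z[, 1])))
  e <- exp(z - m)
  e / rowSums(e)
}

## Categorical cross-entropy on logits. Y is an N x K one-hot matrix.
## Returns loss and the gradient w.r.t. the logits (already / N).
softmaxCrossEntropy <- function(z, Y) {
  p <- softmaxRows(z)
  eps <- 1e-12
  loss <- -mean(rowSums(Y * log(p + eps)))
  list(loss = loss, grad = (p - Y) / nrow(z), p = p)
}
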