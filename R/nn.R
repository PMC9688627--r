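# A compact neural-network engine: dense / batch-norm / 1-D convolution
# / max-pooling / LSTM / GRU layers with binary cross-entropy loss and
# an Adam optimizer. Sequence inputs are [batch, timesteps, channels]
# arrays; dense inputs are [batch, features] matrices. Every layer
# implements forward (with a cache) and backward (exact gradients,
# checked against numerical differentiation in the test suite).

.glorot <- function(fanIn, fanOut, dims = c(fanIn, fanOut)) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

.sig <- function(z) 1 / (1 + exp(-z))

.st <- function(X, t) matrix(X[, t, ], dim(X)[1], dim(X)[3])

# ---- layer constructors ---------------------------------------------------

.layerDense <- function(inF, units, act = "linear", l2 = 0) {
  list(type = "dense", act = act, l2 = l2,
       params = list(W = .glorot(inF, units),
                     b = matrix(0, 1, units)))
}

.layerBatchNorm <- function(nF, momentum = 0.99, eps = 1e-3) {
  list(type = "batchnorm", momentum = momentum, eps = eps,
       params = list(gamma = matrix(1, 1, nF), beta = matrix(0, 1, nF)),
       runMean = rep(0, nF), runVar = rep(1, nF))
}

.layerConv1d <- function(inC, filters, kernel, act = "relu") {
  list(type = "conv1d", kernel = kernel, filters = filters, act = act,
       params = c(setNames(lapply(seq_len(kernel), function(k)
         .glorot(kernel * inC, filters, c(inC, filters))),
         paste0("W", seq_len(kernel))),
         list(b = matrix(0, 1, filters))))
}

.layerMaxPool <- function(pool = 2) list(type = "maxpool", pool = pool)

.layerFlatten <- function() list(type = "flatten")

.layerLSTM <- function(inC, units, returnSeq = FALSE) {
  list(type = "lstm", units = units, returnSeq = returnSeq,
       params = list(W = .glorot(inC + units, 4 * units,
                                 c(inC, 4 * units)),
                     U = .glorot(inC + units, 4 * units,
                                 c(units, 4 * units)),
                     b = matrix(0, 1, 4 * units)))
}

.layerGRU <- function(inC, units, returnSeq = FALSE) {
  list(type = "gru", units = units, returnSeq = returnSeq,
       params = list(W = .glorot(inC + units, 3 * units,
                                 c(inC, 3 * units)),
                     U = .glorot(inC + units, 3 * units,
                                 c(units, 3 * units)),
                     b = matrix(0, 1, 3 * units)))
}

# ---- forward --------------------------------------------------------------

.actFwd <- function(z, act) {
  switch(act, linear = z, relu = pmax(z, 0), sigmoid = .sig(z),
         tanh = tanh(z))
}

.layerForward <- function(layer, X, training) {
  switch(layer$type,
    dense = {
      Z <- X %*% layer$params$W +
        matrix(layer$params$b, nrow(X), ncol(layer$params$b),
               byrow = TRUE)
      list(out = .actFwd(Z, layer$act), cache = list(X = X, Z = Z),
           layer = layer)
    },
    batchnorm = {
      B <- nrow(X)
      if (training && B > 1) {
        mu <- colMeans(X)
        v <- colMeans(X^2) - mu^2
        layer$runMean <- layer$momentum * layer$runMean +
          (1 - layer$momentum) * mu
        layer$runVar <- layer$momentum * layer$runVar +
          (1 - layer$momentum) * v
      } else {
        mu <- layer$runMean
        v <- layer$runVar
      }
      sdv <- sqrt(v + layer$eps)
      xh <- sweep(sweep(X, 2, mu), 2, sdv, "/")
      out <- sweep(xh, 2, as.numeric(layer$params$gamma), "*")
      out <- sweep(out, 2, as.numeric(layer$params$beta), "+")
      list(out = out,
           cache = list(X = X, xh = xh, mu = mu, sdv = sdv,
                        train = training && B > 1),
           layer = layer)
    },
    conv1d = {
      d <- dim(X)
      Tout <- d[2] - layer$kernel + 1L
      Z <- array(0, c(d[1], Tout, layer$filters))
      for (t in seq_len(Tout)) {
        acc <- matrix(layer$params$b, d[1], layer$filters, byrow = TRUE)
        for (k in seq_len(layer$kernel))
          acc <- acc + .st(X, t + k - 1L) %*%
            layer$params[[paste0("W", k)]]
        Z[, t, ] <- acc
      }
      list(out = .actFwd(Z, layer$act), cache = list(X = X, Z = Z),
           layer = layer)
    },
    maxpool = {
      d <- dim(X)
      Tout <- d[2] %/% layer$pool
      out <- array(0, c(d[1], Tout, d[3]))
      amax <- array(0L, c(d[1], Tout, d[3]))
      for (t in seq_len(Tout)) {
        sl <- X[, ((t - 1) * layer$pool + 1):(t * layer$pool), ,
                drop = FALSE]
        w <- apply(sl, c(1, 3), which.max)
        out[, t, ] <- apply(sl, c(1, 3), max)
        amax[, t, ] <- w
      }
      list(out = out, cache = list(dimX = d, amax = amax),
           layer = layer)
    },
    flatten = {
      d <- dim(X)
      list(out = matrix(X, d[1], prod(d[-1])), cache = list(dimX = d),
           layer = layer)
    },
    lstm = {
      d <- dim(X)
      B <- d[1]; Tn <- d[2]; H <- layer$units
      h <- matrix(0, B, H); cc <- matrix(0, B, H)
      steps <- vector("list", Tn)
      outSeq <- array(0, c(B, Tn, H))
      for (t in seq_len(Tn)) {
        xt <- .st(X, t)
        z <- xt %*% layer$params$W + h %*% layer$params$U +
          matrix(layer$params$b, B, 4 * H, byrow = TRUE)
        i <- .sig(z[, 1:H, drop = FALSE])
        f <- .sig(z[, (H + 1):(2 * H), drop = FALSE])
        g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
        o <- .sig(z[, (3 * H + 1):(4 * H), drop = FALSE])
        cNew <- f * cc + i * g
        hNew <- o * tanh(cNew)
        steps[[t]] <- list(xt = xt, hPrev = h, cPrev = cc, i = i,
                           f = f, g = g, o = o, c = cNew)
        h <- hNew; cc <- cNew
        outSeq[, t, ] <- hNew
      }
      out <- if (layer$returnSeq) outSeq else h
      list(out = out, cache = list(steps = steps, dimX = d),
           layer = layer)
    },
    gru = {
      d <- dim(X)
      B <- d[1]; Tn <- d[2]; H <- layer$units
      h <- matrix(0, B, H)
      steps <- vector("list", Tn)
      outSeq <- array(0, c(B, Tn, H))
      for (t in seq_len(Tn)) {
        xt <- .st(X, t)
        zx <- xt %*% layer$params$W +
          matrix(layer$params$b, B, 3 * H, byrow = TRUE)
        zh <- h %*% layer$params$U
        z <- .sig(zx[, 1:H, drop = FALSE] + zh[, 1:H, drop = FALSE])
        r <- .sig(zx[, (H + 1):(2 * H), drop = FALSE] +
                    zh[, (H + 1):(2 * H), drop = FALSE])
        hh <- tanh(zx[, (2 * H + 1):(3 * H), drop = FALSE] +
                     r * zh[, (2 * H + 1):(3 * H), drop = FALSE])
        hNew <- z * h + (1 - z) * hh
        steps[[t]] <- list(xt = xt, hPrev = h, z = z, r = r, hh = hh,
                           zh3 = zh[, (2 * H + 1):(3 * H),
                                    drop = FALSE])
        h <- hNew
        outSeq[, t, ] <- hNew
      }
      out <- if (layer$returnSeq) outSeq else h
      list(out = out, cache = list(steps = steps, dimX = d),
           layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

.nnForward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- .layerForward(layers[[i]], X, training)
    caches[[i]] <- res$cache
    layers[[i]] <- res$layer          # batch-norm running stats
    X <- res$out
  }
  list(out = X, caches = caches, layers = layers)
}

# ---- backward -------------------------------------------------------------

.actBwd <- function(dY, z, act) {
  switch(act,
         linear = dY,
         relu = dY * (z > 0),
         sigmoid = { s <- .sig(z); dY * s * (1 - s) },
         tanh = dY * (1 - tanh(z)^2))
}

.layerBackward <- function(layer, cache, dY) {
  switch(layer$type,
    dense = {
      dZ <- .actBwd(dY, cache$Z, layer$act)
      grads <- list(W = crossprod(cache$X, dZ) +
                      2 * layer$l2 * layer$params$W,
                    b = matrix(colSums(dZ), 1))
      list(grads = grads, dX = dZ %*% t(layer$params$W))
    },
    batchnorm = {
      gamma <- as.numeric(layer$params$gamma)
      grads <- list(gamma = matrix(colSums(dY * cache$xh), 1),
                    beta = matrix(colSums(dY), 1))
      if (!cache$train) {
        dX <- sweep(sweep(dY, 2, gamma, "*"), 2, cache$sdv, "/")
        return(list(grads = grads, dX = dX))
      }
      B <- nrow(dY)
      dxh <- sweep(dY, 2, gamma, "*")
      xc <- sweep(cache$X, 2, cache$mu)
      iv <- 1 / cache$sdv
      dv <- colSums(dxh * xc) * (-0.5) * iv^3
      dmu <- colSums(sweep(dxh, 2, -iv, "*")) + dv * colMeans(-2 * xc)
      dX <- sweep(dxh, 2, iv, "*") +
        sweep(xc, 2, 2 * dv / B, "*") +
        matrix(dmu / B, B, length(dmu), byrow = TRUE)
      list(grads = grads, dX = dX)
    },
    conv1d = {
      dZ <- .actBwd(dY, cache$Z, layer$act)
      d <- dim(cache$X)
      Tout <- dim(dZ)[2]
      dX <- array(0, d)
      grads <- lapply(layer$params, function(p) array(0, dim(p)))
      for (t in seq_len(Tout)) {
        dzt <- .st(dZ, t)
        grads$b <- grads$b + matrix(colSums(dzt), 1)
        for (k in seq_len(layer$kernel)) {
          nm <- paste0("W", k)
          grads[[nm]] <- grads[[nm]] +
            crossprod(.st(cache$X, t + k - 1L), dzt)
          dX[, t + k - 1L, ] <- .st(dX, t + k - 1L) +
            dzt %*% t(layer$params[[nm]])
        }
      }
      list(grads = grads, dX = dX)
    },
    maxpool = {
      d <- cache$dimX
      dX <- array(0, d)
      Tout <- dim(dY)[2]
      for (t in seq_len(Tout)) {
        base <- (t - 1L) * layer$pool
        for (b in seq_len(d[1])) for (f in seq_len(d[3]))
          dX[b, base + cache$amax[b, t, f], f] <-
            dX[b, base + cache$amax[b, t, f], f] + dY[b, t, f]
      }
      list(grads = list(), dX = dX)
    },
    flatten = list(grads = list(), dX = array(dY, cache$dimX)),
    lstm = {
      d <- cache$dimX
      B <- d[1]; Tn <- d[2]; H <- layer$units
      seqGrad <- layer$returnSeq
      dh <- if (seqGrad) matrix(0, B, H) else dY
      dc <- matrix(0, B, H)
      dX <- array(0, d)
      gW <- array(0, dim(layer$params$W))
      gU <- array(0, dim(layer$params$U))
      gb <- matrix(0, 1, 4 * H)
      for (t in rev(seq_len(Tn))) {
        st <- cache$steps[[t]]
        if (seqGrad) dh <- dh + matrix(dY[, t, ], B, H)
        tc <- tanh(st$c)
        do <- dh * tc
        dct <- dc + dh * st$o * (1 - tc^2)
        di <- dct * st$g
        dg <- dct * st$i
        df <- dct * st$cPrev
        dc <- dct * st$f
        dz <- cbind(di * st$i * (1 - st$i),
                    df * st$f * (1 - st$f),
                    dg * (1 - st$g^2),
                    do * st$o * (1 - st$o))
        gW <- gW + crossprod(st$xt, dz)
        gU <- gU + crossprod(st$hPrev, dz)
        gb <- gb + matrix(colSums(dz), 1)
        dX[, t, ] <- dz %*% t(layer$params$W)
        dh <- dz %*% t(layer$params$U)
      }
      list(grads = list(W = gW, U = gU, b = gb), dX = dX)
    },
    gru = {
      d <- cache$dimX
      B <- d[1]; Tn <- d[2]; H <- layer$units
      seqGrad <- layer$returnSeq
      dh <- if (seqGrad) matrix(0, B, H) else dY
      dX <- array(0, d)
      gW <- array(0, dim(layer$params$W))
      gU <- array(0, dim(layer$params$U))
      gb <- matrix(0, 1, 3 * H)
      U1 <- layer$params$U[, 1:H, drop = FALSE]
      U2 <- layer$params$U[, (H + 1):(2 * H), drop = FALSE]
      U3 <- layer$params$U[, (2 * H + 1):(3 * H), drop = FALSE]
      for (t in rev(seq_len(Tn))) {
        st <- cache$steps[[t]]
        if (seqGrad) dh <- dh + matrix(dY[, t, ], B, H)
        dz <- dh * (st$hPrev - st$hh)
        dhh <- dh * (1 - st$z)
        dhPrev <- dh * st$z
        da3 <- dhh * (1 - st$hh^2)            # preact of candidate
        dr <- da3 * st$zh3
        dzh3 <- da3 * st$r
        dz1 <- dz * st$z * (1 - st$z)
        dz2 <- dr * st$r * (1 - st$r)
        dzx <- cbind(dz1, dz2, da3)
        gW <- gW + crossprod(st$xt, dzx)
        gb <- gb + matrix(colSums(dzx), 1)
        gU <- gU + cbind(crossprod(st$hPrev, dz1),
                         crossprod(st$hPrev, dz2),
                         crossprod(st$hPrev, dzh3))
        dX[, t, ] <- dzx %*% t(layer$params$W)
        dh <- dhPrev + dz1 %*% t(U1) + dz2 %*% t(U2) +
          dzh3 %*% t(U3)
      }
      list(grads = list(W = gW, U = gU, b = gb), dX = dX)
    },
    stop("unknown layer type: ", layer$type))
}

.nnBackward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dY <- dOut
  for (i in rev(seq_along(layers))) {
    res <- .layerBackward(layers[[i]], caches[[i]], dY)
    grads[[i]] <- res$grads
    dY <- res$dX
  }
  grads
}

# ---- loss and optimizer ---------------------------------------------------

.l2Penalty <- function(layers) {
  sum(vapply(layers, function(l)
    if (!is.null(l$l2) && l$l2 > 0) l$l2 * sum(l$params$W^2) else 0,
    numeric(1)))
}

# BCE loss + gradient wrt the network output (probabilities)
.bceLossGrad <- function(p, y) {
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  dP <- (pc - y) / (pc * (1 - pc)) / length(y)
  list(loss = loss, dP = matrix(dP, ncol = 1))
}

.nnLossGrads <- function(layers, X, y, training = TRUE) {
  fw <- .nnForward(layers, X, training)
  lg <- .bceLossGrad(as.numeric(fw$out), y)
  grads <- .nnBackward(fw$layers, fw$caches, lg$dP)
  list(loss = lg$loss + .l2Penalty(layers), grads = grads,
       layers = fw$layers, p = as.numeric(fw$out))
}

.adamInit <- function(layers) {
  lapply(layers, function(l)
    lapply(l$params, function(p)
      list(m = array(0, dim(p)), v = array(0, dim(p)))))
}

.adamStep <- function(layers, grads, state, step, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^step)
      vh <- st$v / (1 - beta2^step)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * mh / (sqrt(vh) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}
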