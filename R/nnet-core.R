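# Native implementations of the two trainable regressors (bidirectional LSTM
# for dFNC window sequences, graph-convolution network for sFNC matrices)
# plus the Adam optimizer they share. Parameters are nested lists of numeric
# arrays; gradients mirror that structure exactly.

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- nested-list parameter utilities ---------------------------------------

paramMap2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- paramMap2(a[[k]], b[[k]], f)
    out
  } else f(a, b)
}

paramMap <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- paramMap(a[[k]], f)
    out
  } else f(a)
}

zerosLike <- function(p) paramMap(p, function(x) x * 0)

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params) list(m = zerosLike(params), v = zerosLike(params),
                                  t = 0L)

adamUpdate <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- paramMap2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- paramMap2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- paramMap2(params,
                      paramMap2(state$m, state$v,
                                function(m, v) (m / bc1) / (sqrt(v / bc2) + eps)),
                      function(p, step) p - lr * step)
  list(params = params, state = state)
}

# ---- bidirectional LSTM ----------------------------------------------------
# Gate layout along the 4H axis: input, forget, cell, output.

lstmInitDirection <- function(inDim, H) {
  sc <- function(fan) 1 / sqrt(fan)
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
  list(Wx = matrix(stats::rnorm(inDim * 4L * H, 0, sc(inDim)), inDim, 4L * H),
       Wh = matrix(stats::rnorm(H * 4L * H, 0, sc(H)), H, 4L * H),
       b = b)
}

lstmInitParams <- function(inputDim, H, layers, bidirectional = TRUE,
                           headBias = 0) {
  nd <- if (bidirectional) 2L else 1L
  lp <- vector("list", layers)
  d <- inputDim
  for (l in seq_len(layers)) {
    lp[[l]] <- lapply(seq_len(nd), function(dd) lstmInitDirection(d, H))
    d <- nd * H
  }
  # head bias starts at the training-mean target so the network learns
  # age deviations rather than the age scale itself
  list(layers = lp,
       head = list(w = matrix(stats::rnorm(d, 0, 1 / sqrt(d)), d, 1L),
                   b = headBias))
}

# Forward pass of one direction over a batch.
# xs: list length W of n x D matrices, already in the direction's time order.
lstmDirForward <- function(xs, p, keepCache = TRUE) {
  W <- length(xs)
  n <- nrow(xs[[1L]])
  H <- ncol(p$Wh) / 4L
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  hs <- vector("list", W)
  cache <- if (keepCache) vector("list", W) else NULL
  idx <- list(i = 1:H, f = (H + 1L):(2L * H), g = (2L * H + 1L):(3L * H),
              o = (3L * H + 1L):(4L * H))
  for (t in seq_len(W)) {
    z <- xs[[t]] %*% p$Wx + h %*% p$Wh +
      matrix(p$b, n, 4L * H, byrow = TRUE)
    gi <- sigmoid(z[, idx$i, drop = FALSE])
    gf <- sigmoid(z[, idx$f, drop = FALSE])
    gg <- tanh(z[, idx$g, drop = FALSE])
    go <- sigmoid(z[, idx$o, drop = FALSE])
    cPrev <- cc
    cc <- gf * cPrev + gi * gg
    tc <- tanh(cc)
    hPrev <- h
    h <- go * tc
    hs[[t]] <- h
    if (keepCache)
      cache[[t]] <- list(x = xs[[t]], hPrev = hPrev, cPrev = cPrev,
                         gi = gi, gf = gf, gg = gg, go = go, tc = tc)
  }
  list(hs = hs, cache = cache)
}

# Backward pass of one direction. dhs: list length W of n x H output grads
# (same time order as the forward). Returns parameter grads and input grads.
lstmDirBackward <- function(dhs, p, cache) {
  W <- length(dhs)
  n <- nrow(dhs[[1L]])
  H <- ncol(p$Wh) / 4L
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dhNext <- matrix(0, n, H); dcNext <- matrix(0, n, H)
  dxs <- vector("list", W)
  for (t in rev(seq_len(W))) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dhNext
    dgo <- dh * cc$tc
    dc <- dh * cc$go * (1 - cc$tc^2) + dcNext
    dgi <- dc * cc$gg
    dgf <- dc * cc$cPrev
    dgg <- dc * cc$gi
    dcNext <- dc * cc$gf
    dz <- cbind(dgi * cc$gi * (1 - cc$gi),
                dgf * cc$gf * (1 - cc$gf),
                dgg * (1 - cc$gg^2),
                dgo * cc$go * (1 - cc$go))
    dWx <- dWx + crossprod(cc$x, dz)
    dWh <- dWh + crossprod(cc$hPrev, dz)
    db <- db + colSums(dz)
    dxs[[t]] <- dz %*% t(p$Wx)
    dhNext <- dz %*% t(p$Wh)
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dxs = dxs)
}

# Full network forward. xs: list length W of n x p matrices.
# dropMasks: NULL (inference) or list per layer boundary of n x D masks.
bilstmForward <- function(xs, params, dropMasks = NULL, keepCache = TRUE) {
  L <- length(params$layers)
  nd <- length(params$layers[[1L]])
  W <- length(xs)
  cache <- list(layers = vector("list", L), dropMasks = dropMasks)
  inp <- xs
  for (l in seq_len(L)) {
    fwd <- lstmDirForward(inp, params$layers[[l]][[1L]], keepCache)
    if (nd == 2L) {
      bwd <- lstmDirForward(rev(inp), params$layers[[l]][[2L]], keepCache)
      out <- lapply(seq_len(W), function(t)
        cbind(fwd$hs[[t]], bwd$hs[[W - t + 1L]]))
    } else {
      bwd <- NULL
      out <- fwd$hs
    }
    if (!is.null(dropMasks) && l < L)
      out <- lapply(out, function(o) o * dropMasks[[l]])
    cache$layers[[l]] <- list(fwd = fwd, bwd = bwd, input = inp)
    inp <- out
  }
  # temporal mean pooling over the final layer's outputs
  pooled <- Reduce(`+`, inp) / W
  pred <- drop(pooled %*% params$head$w) + params$head$b
  cache$pooled <- pooled
  cache$topOut <- inp
  list(pred = pred, cache = cache)
}

bilstmBackward <- function(dpred, params, cache) {
  L <- length(params$layers)
  nd <- length(params$layers[[1L]])
  W <- length(cache$topOut)
  n <- length(dpred)
  H <- ncol(params$layers[[1L]][[1L]]$Wh) / 4L
  gHead <- list(w = crossprod(cache$pooled, matrix(dpred, n, 1L)),
                b = sum(dpred))
  dPooled <- matrix(dpred, n, 1L) %*% t(params$head$w)
  dOut <- lapply(seq_len(W), function(t) dPooled / W)
  gLayers <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (!is.null(cache$dropMasks) && l < L)
      dOut <- lapply(dOut, function(d) d * cache$dropMasks[[l]])
    lc <- cache$layers[[l]]
    if (nd == 2L) {
      dFwd <- lapply(dOut, function(d) d[, 1:H, drop = FALSE])
      dBwd <- lapply(seq_len(W), function(t)
        dOut[[W - t + 1L]][, (H + 1L):(2L * H), drop = FALSE])
      bF <- lstmDirBackward(dFwd, params$layers[[l]][[1L]], lc$fwd$cache)
      bB <- lstmDirBackward(dBwd, params$layers[[l]][[2L]], lc$bwd$cache)
      gLayers[[l]] <- list(bF$grads, bB$grads)
      dOut <- lapply(seq_len(W), function(t)
        bF$dxs[[t]] + bB$dxs[[W - t + 1L]])
    } else {
      bF <- lstmDirBackward(dOut, params$layers[[l]][[1L]], lc$fwd$cache)
      gLayers[[l]] <- list(bF$grads)
      dOut <- bF$dxs
    }
  }
  list(layers = gLayers, head = gHead)
}

# ---- connectome graph-convolution network ----------------------------------
# Node features X = the sFNC matrix itself; adjacency A = |R| row-normalized.
# Two graph-convolution layers with ReLU, global mean pooling, linear head.

gcnInitParams <- function(C, H, headBias = 0) {
  sc <- function(fan) 1 / sqrt(fan)
  list(W1 = matrix(stats::rnorm(C * H, 0, sc(C)), C, H), b1 = numeric(H),
       W2 = matrix(stats::rnorm(H * H, 0, sc(H)), H, H), b2 = numeric(H),
       head = list(w = matrix(stats::rnorm(H, 0, sc(H)), H, 1L),
                   b = headBias))
}

gcnAdjacency <- function(R) {
  A <- abs(R)
  A / rowSums(A)
}

# fixed input gain: correlations live on a +/-0.1-ish scale, far below the
# unit scale the initialization assumes; a constant gain keeps early
# training responsive without changing what the model can represent
gcnFeatureGain <- 10

# mats: list of C x C sFNC matrices (one batch). Returns preds + cache.
gcnForward <- function(mats, params, keepCache = TRUE) {
  n <- length(mats)
  preds <- numeric(n)
  cache <- if (keepCache) vector("list", n) else NULL
  for (s in seq_len(n)) {
    R <- mats[[s]]
    A <- gcnAdjacency(R)
    M1 <- A %*% (gcnFeatureGain * R)
    Z1 <- M1 %*% params$W1 +
      matrix(params$b1, nrow(R), length(params$b1), byrow = TRUE)
    H1 <- pmax(Z1, 0)
    M2 <- A %*% H1
    Z2 <- M2 %*% params$W2 +
      matrix(params$b2, nrow(R), length(params$b2), byrow = TRUE)
    H2 <- pmax(Z2, 0)
    pooled <- colMeans(H2)
    preds[s] <- sum(pooled * params$head$w) + params$head$b
    if (keepCache)
      cache[[s]] <- list(A = A, M1 = M1, Z1 = Z1, H1 = H1, M2 = M2,
                         Z2 = Z2, H2 = H2, pooled = pooled)
  }
  list(pred = preds, cache = cache)
}

gcnBackward <- function(dpred, params, cache) {
  g <- zerosLike(params)
  for (s in seq_along(dpred)) {
    cc <- cache[[s]]
    C <- nrow(cc$A)
    dPooled <- dpred[s] * drop(params$head$w)
    g$head$w <- g$head$w + dpred[s] * matrix(cc$pooled, ncol = 1L)
    g$head$b <- g$head$b + dpred[s]
    dH2 <- matrix(dPooled, C, length(dPooled), byrow = TRUE) / C
    dZ2 <- dH2 * (cc$Z2 > 0)
    g$W2 <- g$W2 + crossprod(cc$M2, dZ2)
    g$b2 <- g$b2 + colSums(dZ2)
    dM2 <- dZ2 %*% t(params$W2)
    dH1 <- crossprod(cc$A, dM2)
    dZ1 <- dH1 * (cc$Z1 > 0)
    g$W1 <- g$W1 + crossprod(cc$M1, dZ1)
    g$b1 <- g$b1 + colSums(dZ1)
  }
  g
}
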