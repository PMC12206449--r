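## Minimal 2-D neural-network primitives with explicit backpropagation.
## Tensors are arrays (N, H, W, C), column-major, so dim(x) <- c(N*H*W, C)
## reinterprets without copying semantics being violated. Convolutions use
## im2col gathers with geometry (index matrices) memoised per layer/input
## shape in a per-model environment.

conv_geometry <- function(H, W, C, kh, kw, stride, pad) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  if (Ho < 1 || Wo < 1) {
    abort_mt(sprintf("Input %dx%d too small for a %dx%d kernel at stride %d.",
                     H, W, kh, kw, stride), "construction_error")
  }
  HpWp <- Hp * Wp
  T_ <- kh * kw
  ho <- rep(seq_len(Ho), Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  idx_sp <- matrix(0L, Ho * Wo, T_)
  for (j in seq_len(kw)) {
    for (i in seq_len(kh)) {
      t <- i + (j - 1L) * kh
      hh <- (ho - 1L) * stride + i
      ww <- (wo - 1L) * stride + j
      idx_sp[, t] <- hh + (ww - 1L) * Hp
    }
  }
  chan_off <- (seq_len(C) - 1L) * HpWp
  # full im2col index, columns ordered (spatial offset fastest, then channel)
  idx_full <- idx_sp[, rep(seq_len(T_), C), drop = FALSE] +
    matrix(rep(chan_off, each = T_), nrow(idx_sp), T_ * C, byrow = TRUE)
  # per-offset scatter targets for the backward pass (distinct within a t)
  target_t <- lapply(seq_len(T_), function(t) {
    as.vector(outer(idx_sp[, t], chan_off, `+`))
  })
  # positions of the unpadded input inside the padded layout
  h <- rep(seq_len(H), W * C)
  w <- rep(rep(seq_len(W), each = H), C)
  cc <- rep(seq_len(C), each = H * W)
  inner_idx <- (h + pad) + (w + pad - 1L) * Hp + (cc - 1L) * HpWp
  list(H = H, W = W, C = C, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, T_ = T_,
       idx_full = idx_full, idx_sp = idx_sp, target_t = target_t,
       inner_idx = inner_idx, stride = stride, pad = pad)
}

get_geom <- function(model, key, H, W, C, kh, kw, stride, pad) {
  env <- model$geom
  if (is.null(env[[key]]) || env[[key]]$H != H || env[[key]]$W != W) {
    env[[key]] <- conv_geometry(H, W, C, kh, kw, stride, pad)
  }
  env[[key]]
}

new_conv <- function(cin, cout, kh = 3L, kw = 3L, stride = 1L, pad = 1L) {
  sd <- sqrt(2 / (kh * kw * cin))
  W <- matrix(stats::rnorm(kh * kw * cin * cout, sd = sd), kh * kw * cin, cout)
  list(type = "conv", params = list(W = W), state = list(),
       kh = kh, kw = kw, stride = stride, pad = pad, cin = cin, cout = cout)
}

new_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn",
       params = list(gamma = rep(1, c), beta = rep(0, c)),
       state = list(rmean = rep(0, c), rvar = rep(1, c)),
       momentum = momentum, eps = eps, c = c)
}

new_dense <- function(cin, cout) {
  # small head init: near-uniform initial softmax, so the starting loss sits
  # at ~ln(C) and transfer fine-tuning does not blow away backbone features
  sd <- 0.01
  list(type = "dense",
       params = list(W = matrix(stats::rnorm(cin * cout, sd = sd), cin, cout),
                     b = rep(0, cout)),
       state = list(), cin = cin, cout = cout)
}

new_maxpool <- function(kh = 3L, kw = 3L, stride = 2L, pad = 1L) {
  list(type = "maxpool", params = list(), state = list(),
       kh = kh, kw = kw, stride = stride, pad = pad)
}

conv_forward <- function(layer, x, geom) {
  d <- dim(x)
  N <- d[1]
  dim(x) <- c(N, d[2] * d[3] * d[4])
  Xp <- matrix(0, N, geom$Hp * geom$Wp * geom$C)
  Xp[, geom$inner_idx] <- x
  M <- Xp[, geom$idx_full, drop = FALSE]
  dim(M) <- c(N * geom$Ho * geom$Wo, geom$T_ * geom$C)
  Y <- M %*% layer$params$W
  dim(Y) <- c(N, geom$Ho, geom$Wo, layer$cout)
  list(y = Y, cache = list(M = M, N = N))
}

conv_backward <- function(layer, cache, dY, geom, want_dw = TRUE, want_dx = TRUE) {
  N <- cache$N
  dim(dY) <- c(N * geom$Ho * geom$Wo, layer$cout)
  grads <- NULL
  if (want_dw) grads <- list(W = crossprod(cache$M, dY))
  dX <- NULL
  if (want_dx) {
    dM <- dY %*% t(layer$params$W)
    dXp <- matrix(0, N, geom$Hp * geom$Wp * geom$C)
    Cin <- geom$C
    T_ <- geom$T_
    HoWo <- geom$Ho * geom$Wo
    for (t in seq_len(T_)) {
      slice <- dM[, t + (seq_len(Cin) - 1L) * T_, drop = FALSE]
      dim(slice) <- c(N, HoWo * Cin)
      tgt <- geom$target_t[[t]]
      dXp[, tgt] <- dXp[, tgt] + slice
    }
    dX <- dXp[, geom$inner_idx, drop = FALSE]
    dim(dX) <- c(N, geom$H, geom$W, geom$C)
  }
  list(grads = grads, dx = dX)
}

bn_forward <- function(layer, x, train) {
  d <- dim(x)
  m <- prod(d[1:3])
  dim(x) <- c(m, d[4])
  g <- layer$params$gamma
  b <- layer$params$beta
  if (train && !isTRUE(layer$frozen)) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = m)
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + layer$eps)
    xhat <- xc * rep(invstd, each = m)
    y <- xhat * rep(g, each = m) + rep(b, each = m)
    mom <- layer$momentum
    layer$state$rmean <- (1 - mom) * layer$state$rmean + mom * mu
    layer$state$rvar <- (1 - mom) * layer$state$rvar + mom * v
    cache <- list(xhat = xhat, invstd = invstd, m = m, mode = "train")
  } else {
    invstd <- 1 / sqrt(layer$state$rvar + layer$eps)
    y <- (x - rep(layer$state$rmean, each = m)) * rep(invstd * g, each = m) +
      rep(b, each = m)
    cache <- list(
      xhat = (x - rep(layer$state$rmean, each = m)) * rep(invstd, each = m),
      invstd = invstd, m = m, mode = "eval"
    )
  }
  dim(y) <- d
  list(y = y, cache = cache, layer = layer)
}

bn_backward <- function(layer, cache, dY, want_dw = TRUE, want_dx = TRUE) {
  d <- dim(dY)
  m <- cache$m
  dim(dY) <- c(m, d[4])
  g <- layer$params$gamma
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  grads <- if (want_dw) list(gamma = dgamma, beta = dbeta) else NULL
  dX <- NULL
  if (want_dx) {
    if (cache$mode == "train") {
      scale <- g * cache$invstd / m
      dX <- (m * dY - rep(dbeta, each = m) -
               cache$xhat * rep(dgamma, each = m)) * rep(scale, each = m)
    } else {
      dX <- dY * rep(g * cache$invstd, each = m)
    }
    dim(dX) <- d
  }
  list(grads = grads, dx = dX)
}

relu_forward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, cache = mask)
}

relu_backward <- function(cache, dY) {
  dY[!cache] <- 0
  dY
}

maxpool_forward <- function(layer, x, geom) {
  d <- dim(x)
  N <- d[1]
  C <- d[4]
  dim(x) <- c(N, d[2] * d[3] * d[4])
  Xp <- matrix(-Inf, N, geom$Hp * geom$Wp * geom$C)
  Xp[, geom$inner_idx] <- x
  HoWoC <- geom$Ho * geom$Wo * C
  best <- matrix(-Inf, N, HoWoC)
  arg <- matrix(1L, N, HoWoC)
  for (t in seq_len(geom$T_)) {
    cand <- Xp[, geom$target_t[[t]], drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- t
  }
  Y <- best
  dim(Y) <- c(N, geom$Ho, geom$Wo, C)
  list(y = Y, cache = list(arg = arg, N = N, C = C))
}

maxpool_backward <- function(layer, cache, dY, geom) {
  N <- cache$N
  C <- cache$C
  dim(dY) <- c(N, geom$Ho * geom$Wo * C)
  dXp <- matrix(0, N, geom$Hp * geom$Wp * geom$C)
  for (t in seq_len(geom$T_)) {
    mask <- cache$arg == t
    if (!any(mask)) next
    contrib <- dY * mask
    tgt <- geom$target_t[[t]]
    dXp[, tgt] <- dXp[, tgt] + contrib
  }
  dX <- dXp[, geom$inner_idx, drop = FALSE]
  dim(dX) <- c(N, geom$H, geom$W, geom$C)
  dX
}

gap_forward <- function(x) {
  d <- dim(x)
  N <- d[1]
  HW <- d[2] * d[3]
  C <- d[4]
  dim(x) <- c(N, HW, C)
  y <- matrix(0, N, C)
  for (c in seq_len(C)) y[, c] <- rowMeans(x[, , c, drop = FALSE])
  list(y = y, cache = list(dims = d))
}

gap_backward <- function(cache, dY) {
  d <- cache$dims
  HW <- d[2] * d[3]
  per <- dY / HW  # dX[n,h,w,c] = dY[n,c] / HW
  dX <- array(0, d)
  for (c in seq_len(d[4])) dX[, , , c] <- per[, c]
  dX
}

dense_forward <- function(layer, x) {
  y <- x %*% layer$params$W
  y <- y + rep(layer$params$b, each = nrow(x))
  list(y = y, cache = list(x = x))
}

dense_backward <- function(layer, cache, dY, want_dw = TRUE) {
  grads <- if (want_dw) {
    list(W = crossprod(cache$x, dY), b = colSums(dY))
  } else {
    NULL
  }
  list(grads = grads, dx = dY %*% t(layer$params$W))
}
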