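# Minimal CNN engine in base R. Activations are 4-d arrays laid out
# (height, width, sample, channel); convolutions are computed as nine
# offset-shifted matrix products against BLAS, which is fast enough at
# desk scale and gives exact input gradients for the attribution module.

conv_forward <- function(X, W) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- dim(W)[4]
  P <- array(0, c(H + 2, Wd + 2, N, Cin))
  P[2:(H + 1), 2:(Wd + 1), , ] <- X
  Ymat <- matrix(0, H * Wd * N, Cout)
  for (di in 0:2) for (dj in 0:2) {
    Xs <- P[di + seq_len(H), dj + seq_len(Wd), , , drop = FALSE]
    dim(Xs) <- c(H * Wd * N, Cin)
    Ymat <- Ymat + Xs %*% matrix(W[di + 1, dj + 1, , ], Cin, Cout)
  }
  list(Y = array(Ymat, c(H, Wd, N, Cout)), cache = list(P = P, dimX = d, W = W))
}

conv_backward <- function(dY, cache, want_dW = TRUE) {
  d <- cache$dimX; H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  W <- cache$W; Cout <- dim(W)[4]
  dYmat <- matrix(dY, H * Wd * N, Cout)
  dW <- if (want_dW) array(0, dim(W)) else NULL
  dP <- array(0, dim(cache$P))
  for (di in 0:2) for (dj in 0:2) {
    if (want_dW) {
      Xs <- cache$P[di + seq_len(H), dj + seq_len(Wd), , , drop = FALSE]
      dim(Xs) <- c(H * Wd * N, Cin)
      dW[di + 1, dj + 1, , ] <- crossprod(Xs, dYmat)
    }
    dXs <- tcrossprod(dYmat, matrix(W[di + 1, dj + 1, , ], Cin, Cout))
    dim(dXs) <- c(H, Wd, N, Cin)
    dP[di + seq_len(H), dj + seq_len(Wd), , ] <-
      dP[di + seq_len(H), dj + seq_len(Wd), , , drop = FALSE] + dXs
  }
  dX <- dP[2:(H + 1), 2:(Wd + 1), , , drop = FALSE]
  dim(dX) <- d
  list(dX = dX, dW = dW)
}

bn_forward <- function(X, gamma, beta, rm, rv, training,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(X); m <- prod(d[1:3]); C <- d[4]
  Xm <- matrix(X, m, C)
  if (training) {
    mu <- colMeans(Xm)
    xc <- Xm - rep(mu, each = m)
    v <- colMeans(xc * xc)
    rm <- momentum * rm + (1 - momentum) * mu
    rv <- momentum * rv + (1 - momentum) * v
  } else {
    mu <- rm; v <- rv
    xc <- Xm - rep(mu, each = m)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = m)
  Y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  dim(Y) <- d
  list(Y = Y, rm = rm, rv = rv,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, d = d,
                    training = training))
}

bn_backward <- function(dY, cache) {
  d <- cache$d; m <- prod(d[1:3])
  dYm <- matrix(dY, m, d[4])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  if (cache$training) {
    dxhat <- dYm * rep(cache$gamma, each = m)
    t1 <- colSums(dxhat) / m
    t2 <- colSums(dxhat * cache$xhat) / m
    dX <- (dxhat - rep(t1, each = m) - cache$xhat * rep(t2, each = m)) *
      rep(cache$istd, each = m)
  } else {
    dX <- dYm * rep(cache$gamma * cache$istd, each = m)
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) list(Y = pmax(X, 0), cache = X > 0)
relu_backward <- function(dY, mask) dY * mask

pool_forward <- function(X) {
  d <- dim(X)
  Ho <- d[1] %/% 2; Wo <- d[2] %/% 2
  ri <- seq_len(Ho) * 2 - 1; ci <- seq_len(Wo) * 2 - 1
  a <- X[ri, ci, , , drop = FALSE];      b <- X[ri, ci + 1, , , drop = FALSE]
  cc <- X[ri + 1, ci, , , drop = FALSE]; dd <- X[ri + 1, ci + 1, , , drop = FALSE]
  Y <- pmax(a, b, cc, dd)
  list(Y = Y, cache = list(a = a, b = b, cc = cc, dd = dd, Y = Y,
                           d = d, ri = ri, ci = ci))
}

pool_backward <- function(dY, cache) {
  ga <- cache$a == cache$Y
  gb <- (cache$b == cache$Y) & !ga
  gc <- (cache$cc == cache$Y) & !ga & !gb
  gd <- !(ga | gb | gc)
  dX <- array(0, cache$d)
  dX[cache$ri, cache$ci, , ] <- dY * ga
  dX[cache$ri, cache$ci + 1, , ] <- dY * gb
  dX[cache$ri + 1, cache$ci, , ] <- dY * gc
  dX[cache$ri + 1, cache$ci + 1, , ] <- dY * gd
  dX
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# flattened image rows <-> (side, side, N, 1) arrays; rows are row-major
# images, i.e. element (i-1)*side + j is pixel (i, j)
rows_to_array <- function(M, side) {
  N <- nrow(M)
  X <- aperm(array(t(M), c(side, side, N)), c(2, 1, 3))
  dim(X) <- c(side, side, N, 1)
  X
}

array_to_rows <- function(X) {
  d <- dim(X)
  A <- aperm(array(X, d[1:3]), c(2, 1, 3))
  t(matrix(A, d[1] * d[2], d[3]))
}

cnn_forward <- function(params, rstats, Xarr, training = FALSE) {
  caches <- vector("list", 4)
  A <- Xarr
  for (b in 1:4) {
    cv <- conv_forward(A, params[[paste0("conv", b)]])
    bn <- bn_forward(cv$Y, params[[paste0("g", b)]], params[[paste0("bb", b)]],
                     rstats$rm[[b]], rstats$rv[[b]], training)
    if (training) { rstats$rm[[b]] <- bn$rm; rstats$rv[[b]] <- bn$rv }
    rl <- relu_forward(bn$Y)
    caches[[b]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
    A <- rl$Y
    if (b == 2 || b == 4) {
      pl <- pool_forward(A)
      caches[[b]]$pool <- pl$cache
      A <- pl$Y
    }
  }
  d <- dim(A)
  flat <- t(matrix(aperm(A, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]))
  n <- nrow(flat)
  h1 <- flat %*% params$fc1W + rep(params$fc1b, each = n)
  r1 <- pmax(h1, 0)
  logits <- r1 %*% params$fc2W + rep(params$fc2b, each = n)
  list(logits = logits,
       caches = list(blocks = caches, flat = flat, dimA = d, h1 = h1, r1 = r1),
       rstats = rstats)
}

cnn_backward <- function(params, caches, dlogits, want_params = TRUE) {
  grads <- list()
  if (want_params) {
    grads$fc2W <- crossprod(caches$r1, dlogits)
    grads$fc2b <- colSums(dlogits)
  }
  dh1 <- tcrossprod(dlogits, params$fc2W) * (caches$h1 > 0)
  if (want_params) {
    grads$fc1W <- crossprod(caches$flat, dh1)
    grads$fc1b <- colSums(dh1)
  }
  dflat <- tcrossprod(dh1, params$fc1W)
  d <- caches$dimA
  dA <- aperm(array(t(dflat), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  for (b in 4:1) {
    cb <- caches$blocks[[b]]
    if (b == 2 || b == 4) dA <- pool_backward(dA, cb$pool)
    dA <- relu_backward(dA, cb$relu)
    bnb <- bn_backward(dA, cb$bn)
    if (want_params) {
      grads[[paste0("g", b)]] <- bnb$dgamma
      grads[[paste0("bb", b)]] <- bnb$dbeta
    }
    cvb <- conv_backward(bnb$dX, cb$conv, want_dW = want_params)
    if (want_params) grads[[paste0("conv", b)]] <- cvb$dW
    dA <- cvb$dX
  }
  list(grads = grads, dX = dA)
}

adam_init <- function(params) {
  z <- lapply(params, function(p) { p[] <- 0; p })
  list(m = z, v = z, t = 0L)
}

adam_update <- function(params, grads, st, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, st = st)
}
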