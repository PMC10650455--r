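# Minimal sequence-network engine: dense / conv1d / maxpool1d / batchnorm /
# multi-head attention layers with hand-derived backward passes, plus Adam.
# All sequence arrays are channels-last: dim (N, T, C). Column-major collapse
# of (N, T) into rows makes im2col and batchnorm reshape-free.

sigm <- function(x) 1 / (1 + exp(-x))

# uniform init in [-1/sqrt(fan), 1/sqrt(fan)], the usual recurrent-net default
nn_init <- function(dims, fan) {
  array(stats::runif(prod(dims), -1 / sqrt(fan), 1 / sqrt(fan)), dim = dims)
}

# slice step t of an (N, T, C) array as an (N, C) matrix
slice_t <- function(a, t) {
  d <- dim(a)
  m <- a[, t, , drop = FALSE]
  dim(m) <- c(d[1], d[3])
  m
}

## dense -----------------------------------------------------------------

dense_fwd <- function(x, W, b) {
  y <- x %*% W
  y + rep(b, each = nrow(x))
}

dense_bwd <- function(dy, x, W) {
  list(dx = tcrossprod(dy, W), dW = crossprod(x, dy), db = colSums(dy))
}

## conv1d (stride 1, symmetric zero padding) ------------------------------
# W is (K*C, F) with rows ordered channel-fastest within tap; b length F.
# In the (N*Tp, C) matrix view of the padded input, the im2col block for tap
# k is a contiguous row range, so the patch matrix is assembled with K block
# copies and the convolution is a single GEMM.

conv1d_fwd <- function(x, W, b, K, pad) {
  y <- conv1d_sg_fwd(x, W, b, K, pad)
  list(y = y, x = x)
}

conv1d_bwd <- function(dy, cache, W, K, pad) {
  d <- dim(dy)
  g <- conv1d_sg_bwd(dy, cache$x, W, K, pad)
  dim(dy) <- c(d[1] * d[2], d[3])
  list(dx = g$dx, dW = g$dW, db = colSums(dy))
}

## max pooling ------------------------------------------------------------

maxpool_fwd <- function(x, k, stride, pad = 0L) {
  d <- dim(x)
  r <- maxpool1d_fwd(x, k, stride, pad)
  list(y = r$y, arg = r$arg, dims = d)
}

maxpool_bwd <- function(dy, cache, k, stride, pad = 0L) {
  d <- cache$dims
  maxpool1d_bwd(dy, cache$arg, d[1], d[2], d[3], k, stride, pad)
}

## batch normalization ----------------------------------------------------
# Normalizes over all leading dims per channel (last dim). Training uses the
# batch statistics (population variance) and updates running moments; eval
# uses the accumulated running moments.

bn_fwd <- function(x, gamma, beta, rm, rv, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[length(d)]
  M <- prod(d) / C
  xm <- x
  dim(xm) <- c(M, C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    rm <- (1 - momentum) * rm + momentum * mu
    corr <- if (M > 1) M / (M - 1) else 1
    rv <- (1 - momentum) * rv + momentum * v * corr
  } else {
    mu <- rm
    v <- rv
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = M)) * rep(istd, each = M)
  y <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd, dims = d, M = M, C = C,
       rm = rm, rv = rv, training = training)
}

bn_bwd <- function(dy, cache, gamma) {
  M <- cache$M; C <- cache$C
  dim(dy) <- c(M, C)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(gamma, each = M)
  if (cache$training) {
    mu_dx <- colMeans(dxhat)
    mu_dxx <- colMeans(dxhat * cache$xhat)
    dx <- rep(cache$istd, each = M) *
      (dxhat - rep(mu_dx, each = M) - cache$xhat * rep(mu_dxx, each = M))
  } else {
    dx <- dxhat * rep(cache$istd, each = M)
  }
  dim(dx) <- cache$dims
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## multi-head self-attention ----------------------------------------------
# Tokens are time steps; model width D split into n_heads heads of D/n_heads.

mha_fwd <- function(x, p, n_heads) {
  d <- dim(x); N <- d[1]; Tt <- d[2]; D <- d[3]
  dk <- D %/% n_heads
  xm <- x
  dim(xm) <- c(N * Tt, D)
  Q <- dense_fwd(xm, p$Wq, p$bq)
  K <- dense_fwd(xm, p$Wk, p$bk)
  V <- dense_fwd(xm, p$Wv, p$bv)
  O <- matrix(0, N * Tt, D)
  P_list <- vector("list", N * n_heads)
  scale <- 1 / sqrt(dk)
  for (n in seq_len(N)) {
    rows <- seq.int(n, by = N, length.out = Tt)  # rows of sample n (N-fastest order)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      Vh <- V[rows, cols, drop = FALSE]
      S <- tcrossprod(Qh, Kh) * scale
      S <- S - apply(S, 1L, max)
      P <- exp(S)
      P <- P / rowSums(P)
      O[rows, cols] <- P %*% Vh
      P_list[[(n - 1L) * n_heads + h]] <- P
    }
  }
  y <- dense_fwd(O, p$Wo, p$bo)
  dim(y) <- d
  list(y = y, xm = xm, Q = Q, K = K, V = V, O = O, P = P_list,
       dims = d, dk = dk, n_heads = n_heads)
}

mha_bwd <- function(dy, cache, p) {
  d <- cache$dims; N <- d[1]; Tt <- d[2]; D <- d[3]
  dk <- cache$dk; n_heads <- cache$n_heads
  scale <- 1 / sqrt(dk)
  dim(dy) <- c(N * Tt, D)
  go <- dense_bwd(dy, cache$O, p$Wo)
  dO <- go$dx
  dQ <- matrix(0, N * Tt, D)
  dK <- matrix(0, N * Tt, D)
  dV <- matrix(0, N * Tt, D)
  for (n in seq_len(N)) {
    rows <- seq.int(n, by = N, length.out = Tt)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      P <- cache$P[[(n - 1L) * n_heads + h]]
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dP <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] * scale
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) * scale
    }
  }
  gq <- dense_bwd(dQ, cache$xm, p$Wq)
  gk <- dense_bwd(dK, cache$xm, p$Wk)
  gv <- dense_bwd(dV, cache$xm, p$Wv)
  dx <- gq$dx + gk$dx + gv$dx
  dim(dx) <- d
  list(dx = dx,
       dWq = gq$dW, dbq = gq$db, dWk = gk$dW, dbk = gk$db,
       dWv = gv$dW, dbv = gv$db, dWo = go$dW, dbo = go$db)
}

## temporal mean ----------------------------------------------------------

tmean_fwd <- function(x) {
  d <- dim(x)
  xm <- aperm(x, c(2L, 1L, 3L))
  dim(xm) <- c(d[2], d[1] * d[3])
  y <- colMeans(xm)
  dim(y) <- c(d[1], d[3])
  list(y = y, dims = d)
}

tmean_bwd <- function(dy, cache) {
  d <- cache$dims
  dxm <- matrix(as.vector(dy) / d[2], nrow = d[2], ncol = d[1] * d[3],
                byrow = TRUE)
  dim(dxm) <- c(d[2], d[1], d[3])
  aperm(dxm, c(2L, 1L, 3L))
}

## Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
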