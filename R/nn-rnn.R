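# LSTM and GRU layers with backpropagation through time.
# Input/output sequences are (N, T, C) arrays; hidden/cell states start at 0.

## LSTM -------------------------------------------------------------------
# Gate columns of W (D, 4H), U (H, 4H), b (4H): [input | forget | cell | output].

lstm_init <- function(D, H) {
  list(W = nn_init(c(D, 4L * H), H),
       U = nn_init(c(H, 4L * H), H),
       b = nn_init(4L * H, H))
}

lstm_fwd <- function(x, p) {
  d <- dim(x); N <- d[1]; Tt <- d[2]; D <- d[3]
  H <- nrow(p$U)
  xm <- x
  dim(xm) <- c(N * Tt, D)
  XW <- xm %*% p$W
  XW <- XW + rep(p$b, each = N * Tt)
  dim(XW) <- c(N, Tt, 4L * H)
  r <- lstm_seq_fwd(XW, p$U, N, Tt, H)
  list(h_seq = r$h,
       cache = list(xm = xm, Hs = r$h, Cs = r$c, G = r$g, dims = d, H = H))
}

# dHs: gradient wrt the full output sequence (N, T, H)
lstm_bwd <- function(dHs, cache, p) {
  d <- cache$dims; N <- d[1]; Tt <- d[2]
  H <- cache$H
  r <- lstm_seq_bwd(dHs, cache$G, cache$Cs, cache$Hs, p$U, N, Tt, H)
  dXW <- r$dXW
  dim(dXW) <- c(N * Tt, 4L * H)
  dW <- crossprod(cache$xm, dXW)
  dx <- tcrossprod(dXW, p$W)
  dim(dx) <- d
  list(dx = dx, dW = dW, dU = r$dU, db = r$db)
}

## GRU --------------------------------------------------------------------
# Gate columns of W (D, 3H), U (H, 3H), b (3H): [reset | update | candidate];
# candidate uses the reset-gated recurrent term: n = tanh(xWn + r*(h Un) + bn).

gru_init <- function(D, H) {
  list(W = nn_init(c(D, 3L * H), H),
       U = nn_init(c(H, 3L * H), H),
       b = nn_init(3L * H, H))
}

gru_fwd <- function(x, p) {
  d <- dim(x); N <- d[1]; Tt <- d[2]; D <- d[3]
  H <- nrow(p$U)
  xm <- x
  dim(xm) <- c(N * Tt, D)
  XW <- xm %*% p$W
  dim(XW) <- c(N, Tt, 3L * H)
  ir <- seq_len(H); iz <- H + ir; in_ <- 2L * H + ir
  h <- matrix(0, N, H)
  Hs <- array(0, c(N, Tt, H))
  Gr <- array(0, c(N, Tt, H)); Gz <- Gr; Gn <- Gr; An <- Gr
  bfull <- rep(p$b, each = N)
  for (t in seq_len(Tt)) {
    HU <- h %*% p$U
    z0 <- slice_t(XW, t) + bfull
    r <- sigm(z0[, ir, drop = FALSE] + HU[, ir, drop = FALSE])
    zg <- sigm(z0[, iz, drop = FALSE] + HU[, iz, drop = FALSE])
    a <- HU[, in_, drop = FALSE]
    n <- tanh(z0[, in_, drop = FALSE] + r * a)
    h <- (1 - zg) * n + zg * h
    Hs[, t, ] <- h
    Gr[, t, ] <- r; Gz[, t, ] <- zg; Gn[, t, ] <- n; An[, t, ] <- a
  }
  list(h_seq = Hs,
       cache = list(xm = xm, Hs = Hs, Gr = Gr, Gz = Gz, Gn = Gn, An = An,
                    dims = d, H = H))
}

gru_bwd <- function(dHs, cache, p) {
  d <- cache$dims; N <- d[1]; Tt <- d[2]
  H <- cache$H
  ir <- seq_len(H); iz <- H + ir; in_ <- 2L * H + ir
  Ur <- p$U[, ir, drop = FALSE]
  Uz <- p$U[, iz, drop = FALSE]
  Un <- p$U[, in_, drop = FALSE]
  dXW <- array(0, c(N, Tt, 3L * H))
  dU <- matrix(0, H, 3L * H)
  db <- numeric(3L * H)
  dh_next <- matrix(0, N, H)
  dz <- matrix(0, N, 3L * H)
  for (t in rev(seq_len(Tt))) {
    r <- slice_t(cache$Gr, t); zg <- slice_t(cache$Gz, t)
    n <- slice_t(cache$Gn, t); a <- slice_t(cache$An, t)
    h_prev <- if (t > 1L) slice_t(cache$Hs, t - 1L) else matrix(0, N, H)
    dh <- slice_t(dHs, t) + dh_next
    dzg <- dh * (h_prev - n) * zg * (1 - zg)
    dn_pre <- dh * (1 - zg) * (1 - n * n)
    da <- dn_pre * r
    dr <- dn_pre * a * r * (1 - r)
    dz[, ir] <- dr
    dz[, iz] <- dzg
    dz[, in_] <- dn_pre
    dh_prev <- dh * zg +
      tcrossprod(da, Un) + tcrossprod(dr, Ur) + tcrossprod(dzg, Uz)
    dU[, ir] <- dU[, ir] + crossprod(h_prev, dr)
    dU[, iz] <- dU[, iz] + crossprod(h_prev, dzg)
    dU[, in_] <- dU[, in_] + crossprod(h_prev, da)
    db <- db + colSums(dz)
    dXW[, t, ] <- dz
    dh_next <- dh_prev
  }
  dim(dXW) <- c(N * Tt, 3L * H)
  dW <- crossprod(cache$xm, dXW)
  dx <- tcrossprod(dXW, p$W)
  dim(dx) <- d
  list(dx = dx, dW = dW, dU = dU, db = db)
}

# run a layer on the time-reversed sequence (for the backward direction of
# a bidirectional layer); returns outputs re-reversed to original order
rnn_reverse_time <- function(x) {
  x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
}
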