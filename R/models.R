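#' Build a surgical-skill sequence classifier
#'
#' Constructs one of the six benchmark architectures mapping a force sequence
#' (`in_channels` x T) to the probability that the trial was performed by an
#' Expert. Weights are freshly initialized from `init_seed`; the model is
#' trained with [fit_model()] or [train_one_fold()].
#'
#' The architectures:
#' \describe{
#'   \item{lstm}{four stacked LSTM layers, 64 hidden units, readout of the
#'     final-layer hidden state at the last non-padded step, affine head.}
#'   \item{bilstm}{four bidirectional LSTM layers (64 units per direction);
#'     the readout concatenates the final forward and final backward states
#'     (128 values).}
#'   \item{gru}{as `lstm` with GRU cells.}
#'   \item{cldnn}{two Conv1D-ReLU-MaxPool blocks (64 then 128 filters, each
#'     pool halving T), four LSTM layers (64 units), then two affine layers.}
#'   \item{tcn}{four Conv1D(kernel 25, stride 1) + BatchNorm + ReLU +
#'     MaxPool(kernel 3, stride 1) blocks with 64, 32, 16, 16 filters;
#'     temporal resolution is preserved throughout; temporal average then an
#'     affine head.}
#'   \item{transformer}{pointwise convolution lifting the signal to width 16,
#'     one 8-head self-attention block, batch normalization, temporal
#'     average, and a two-layer head.}
#' }
#' All heads end in a single logit passed through a sigmoid, trained with
#' binary cross-entropy (Expert encoded as 1).
#'
#' @param arch One of `"lstm"`, `"bilstm"`, `"gru"`, `"cldnn"`, `"tcn"`,
#'   `"transformer"`.
#' @param in_channels Number of input channels: 1 for the raw force trace, 3
#'   when training on [rfft_stack()] input.
#' @param init_seed Integer seed for weight initialization; builds are pure
#'   functions of `(arch, in_channels, init_seed)`.
#' @return An object of class `skill_model`.
#' @examples
#' m <- build_model("tcn", init_seed = 1)
#' x <- matrix(rnorm(300), nrow = 1)
#' predict_prob(m, list(rnorm(300)))
#' @export
build_model <- function(arch = c("lstm", "bilstm", "gru", "cldnn", "tcn",
                                 "transformer"),
                        in_channels = 1L, init_seed = 1L) {
  arch <- match.arg(arch)
  stopifnot(in_channels %in% c(1L, 3L))
  params <- withr::with_seed(init_seed, init_params(arch, in_channels))
  bn <- init_bn_state(arch)
  structure(list(arch = arch, in_channels = as.integer(in_channels),
                 init_seed = as.integer(init_seed),
                 params = params, bn = bn),
            class = "skill_model")
}

#' @export
print.skill_model <- function(x, ...) {
  cat(sprintf("<skill_model> arch=%s in_channels=%d params=%d\n",
              x$arch, x$in_channels, count_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model A `skill_model`.
#' @return Integer count of scalar parameters.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

init_params <- function(arch, C) {
  H <- 64L
  p <- list()
  rnn_stack <- function(init, d_in, n = 4L, prefix) {
    out <- list()
    d <- d_in
    for (l in seq_len(n)) {
      lay <- init(d, H)
      out[[paste0(prefix, l, ".W")]] <- lay$W
      out[[paste0(prefix, l, ".U")]] <- lay$U
      out[[paste0(prefix, l, ".b")]] <- lay$b
      d <- H
    }
    out
  }
  if (arch == "lstm") {
    p <- rnn_stack(lstm_init, C, prefix = "r")
    p[["head.W"]] <- nn_init(c(H, 1L), H)
    p[["head.b"]] <- nn_init(1L, H)
  } else if (arch == "gru") {
    p <- rnn_stack(gru_init, C, prefix = "g")
    p[["head.W"]] <- nn_init(c(H, 1L), H)
    p[["head.b"]] <- nn_init(1L, H)
  } else if (arch == "bilstm") {
    d <- C
    for (l in 1:4) {
      for (dir in c("f", "b")) {
        lay <- lstm_init(d, H)
        p[[paste0("r", l, dir, ".W")]] <- lay$W
        p[[paste0("r", l, dir, ".U")]] <- lay$U
        p[[paste0("r", l, dir, ".b")]] <- lay$b
      }
      d <- 2L * H
    }
    p[["head.W"]] <- nn_init(c(2L * H, 1L), 2L * H)
    p[["head.b"]] <- nn_init(1L, 2L * H)
  } else if (arch == "cldnn") {
    K <- 5L
    p[["c1.W"]] <- nn_init(c(C * K, 64L), C * K)
    p[["c1.b"]] <- nn_init(64L, C * K)
    p[["c2.W"]] <- nn_init(c(64L * K, 128L), 64L * K)
    p[["c2.b"]] <- nn_init(128L, 64L * K)
    p <- c(p, rnn_stack(lstm_init, 128L, prefix = "r"))
    p[["fc1.W"]] <- nn_init(c(H, H), H)
    p[["fc1.b"]] <- nn_init(H, H)
    p[["head.W"]] <- nn_init(c(H, 1L), H)
    p[["head.b"]] <- nn_init(1L, H)
  } else if (arch == "tcn") {
    K <- 25L
    dims <- c(C, 64L, 32L, 16L, 16L)
    for (l in 1:4) {
      p[[paste0("c", l, ".W")]] <- nn_init(c(dims[l] * K, dims[l + 1L]),
                                           dims[l] * K)
      p[[paste0("c", l, ".b")]] <- nn_init(dims[l + 1L], dims[l] * K)
      p[[paste0("bn", l, ".gamma")]] <- rep(1, dims[l + 1L])
      p[[paste0("bn", l, ".beta")]] <- rep(0, dims[l + 1L])
    }
    p[["head.W"]] <- nn_init(c(16L, 1L), 16L)
    p[["head.b"]] <- nn_init(1L, 16L)
  } else if (arch == "transformer") {
    D <- 16L
    p[["c1.W"]] <- nn_init(c(C, D), C)
    p[["c1.b"]] <- nn_init(D, C)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      p[[paste0("att.", nm)]] <- nn_init(c(D, D), D)
    }
    for (nm in c("bq", "bk", "bv", "bo")) {
      p[[paste0("att.", nm)]] <- nn_init(D, D)
    }
    p[["bn1.gamma"]] <- rep(1, D)
    p[["bn1.beta"]] <- rep(0, D)
    p[["fc1.W"]] <- nn_init(c(D, D), D)
    p[["fc1.b"]] <- nn_init(D, D)
    p[["bn2.gamma"]] <- rep(1, D)
    p[["bn2.beta"]] <- rep(0, D)
    p[["head.W"]] <- nn_init(c(D, 1L), D)
    p[["head.b"]] <- nn_init(1L, D)
  }
  p
}

init_bn_state <- function(arch) {
  if (arch == "tcn") {
    dims <- c(64L, 32L, 16L, 16L)
    st <- list()
    for (l in 1:4) {
      st[[paste0("bn", l)]] <- list(rm = rep(0, dims[l]), rv = rep(1, dims[l]))
    }
    st
  } else if (arch == "transformer") {
    list(bn1 = list(rm = rep(0, 16L), rv = rep(1, 16L)),
         bn2 = list(rm = rep(0, 16L), rv = rep(1, 16L)))
  } else {
    list()
  }
}

# gather per-sample hidden state at time index idx[n]: (N,T,H) -> (N,H)
gather_t <- function(Hs, idx) {
  d <- dim(Hs); N <- d[1]; H <- d[3]
  m <- Hs[cbind(rep(seq_len(N), times = H),
                rep(idx, times = H),
                rep(seq_len(H), each = N))]
  dim(m) <- c(N, H)
  m
}

scatter_t <- function(dims, idx, dm) {
  out <- array(0, dims)
  N <- dims[1]; H <- dims[3]
  out[cbind(rep(seq_len(N), times = H),
            rep(idx, times = H),
            rep(seq_len(H), each = N))] <- as.vector(dm)
  out
}

#' Forward pass of a skill model
#'
#' Low-level forward map from a batch of fixed-length sequences to Expert
#' probabilities. Most users should call [predict_prob()] or
#' [predict.skill_fit()] instead.
#'
#' @param model A `skill_model`.
#' @param x Numeric array `(N, T, channels)`.
#' @param lens Integer vector of true (non-padded) lengths per sample;
#'   defaults to T for all. Recurrent readouts use the last valid step.
#' @param training Logical; `TRUE` uses batch statistics in normalization
#'   layers (and updates running moments), `FALSE` uses accumulated running
#'   statistics.
#' @param with_cache Keep intermediate activations for backpropagation.
#' @param with_features Keep named intermediate feature maps (batch size 1).
#' @return List with `prob`, `logit`, updated `model`, and optionally
#'   `cache` / `features`.
#' @keywords internal
#' @export
model_forward <- function(model, x, lens = NULL, training = FALSE,
                          with_cache = FALSE, with_features = FALSE) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  if (d[3] != model$in_channels) {
    stop(sprintf("input has %d channels but model expects %d",
                 d[3], model$in_channels))
  }
  if (is.null(lens)) lens <- rep(d[2], d[1])
  lens <- pmin(pmax(as.integer(lens), 1L), d[2])
  res <- switch(model$arch,
    lstm = fwd_rnn(model, x, lens, kind = "lstm", prefix = "r"),
    gru = fwd_rnn(model, x, lens, kind = "gru", prefix = "g"),
    bilstm = fwd_bilstm(model, x, lens),
    cldnn = fwd_cldnn(model, x, lens),
    tcn = fwd_tcn(model, x, training),
    transformer = fwd_transformer(model, x, training))
  out <- list(logit = res$logit, prob = sigm(res$logit), model = res$model)
  if (with_cache) out$cache <- res$cache
  if (with_features) out$features <- res$features
  out
}

model_backward <- function(model, cache, dlogit) {
  switch(model$arch,
    lstm = bwd_rnn(model, cache, dlogit, kind = "lstm", prefix = "r"),
    gru = bwd_rnn(model, cache, dlogit, kind = "gru", prefix = "g"),
    bilstm = bwd_bilstm(model, cache, dlogit),
    cldnn = bwd_cldnn(model, cache, dlogit),
    tcn = bwd_tcn(model, cache, dlogit),
    transformer = bwd_transformer(model, cache, dlogit))
}

## plain recurrent stacks -------------------------------------------------

fwd_rnn <- function(model, x, lens, kind, prefix) {
  p <- model$params
  fwd <- if (kind == "lstm") lstm_fwd else gru_fwd
  seqs <- vector("list", 4L)
  inp <- x
  for (l in 1:4) {
    lay <- list(W = p[[paste0(prefix, l, ".W")]],
                U = p[[paste0(prefix, l, ".U")]],
                b = p[[paste0(prefix, l, ".b")]])
    r <- fwd(inp, lay)
    seqs[[l]] <- r$cache
    inp <- r$h_seq
  }
  hlast <- gather_t(inp, lens)
  logit <- dense_fwd(hlast, p[["head.W"]], p[["head.b"]])[, 1L]
  list(logit = logit, model = model,
       cache = list(seqs = seqs, hlast = hlast, lens = lens,
                    out_dims = dim(inp)),
       features = list(h_last = hlast[1L, ]))
}

bwd_rnn <- function(model, cache, dlogit, kind, prefix) {
  p <- model$params
  bwd <- if (kind == "lstm") lstm_bwd else gru_bwd
  g <- list()
  gd <- dense_bwd(matrix(dlogit, ncol = 1L), cache$hlast, p[["head.W"]])
  g[["head.W"]] <- gd$dW
  g[["head.b"]] <- gd$db
  dHs <- scatter_t(cache$out_dims, cache$lens, gd$dx)
  for (l in 4:1) {
    lay <- list(W = p[[paste0(prefix, l, ".W")]],
                U = p[[paste0(prefix, l, ".U")]],
                b = p[[paste0(prefix, l, ".b")]])
    r <- bwd(dHs, cache$seqs[[l]], lay)
    g[[paste0(prefix, l, ".W")]] <- r$dW
    g[[paste0(prefix, l, ".U")]] <- r$dU
    g[[paste0(prefix, l, ".b")]] <- r$db
    dHs <- r$dx
  }
  g
}

## bidirectional LSTM -----------------------------------------------------

fwd_bilstm <- function(model, x, lens) {
  p <- model$params
  H <- 64L
  caches <- vector("list", 4L)
  inp <- x
  for (l in 1:4) {
    pf <- list(W = p[[paste0("r", l, "f.W")]], U = p[[paste0("r", l, "f.U")]],
               b = p[[paste0("r", l, "f.b")]])
    pb <- list(W = p[[paste0("r", l, "b.W")]], U = p[[paste0("r", l, "b.U")]],
               b = p[[paste0("r", l, "b.b")]])
    rf <- lstm_fwd(inp, pf)
    rb <- lstm_fwd(rnn_reverse_time(inp), pb)
    hb <- rnn_reverse_time(rb$h_seq)
    d <- dim(inp)
    out <- array(0, c(d[1], d[2], 2L * H))
    out[, , seq_len(H)] <- rf$h_seq
    out[, , H + seq_len(H)] <- hb
    caches[[l]] <- list(f = rf$cache, b = rb$cache)
    inp <- out
  }
  d <- dim(inp)
  hf <- gather_t(inp[, , seq_len(H), drop = FALSE], lens)
  hbk <- gather_t(inp[, , H + seq_len(H), drop = FALSE], rep(1L, d[1]))
  hlast <- cbind(hf, hbk)
  logit <- dense_fwd(hlast, p[["head.W"]], p[["head.b"]])[, 1L]
  list(logit = logit, model = model,
       cache = list(caches = caches, hlast = hlast, lens = lens,
                    out_dims = d),
       features = list(h_last = hlast[1L, ]))
}

bwd_bilstm <- function(model, cache, dlogit) {
  p <- model$params
  H <- 64L
  g <- list()
  gd <- dense_bwd(matrix(dlogit, ncol = 1L), cache$hlast, p[["head.W"]])
  g[["head.W"]] <- gd$dW
  g[["head.b"]] <- gd$db
  d <- cache$out_dims
  dout <- array(0, d)
  dout[, , seq_len(H)] <- scatter_t(c(d[1], d[2], H), cache$lens,
                                    gd$dx[, seq_len(H), drop = FALSE])
  dout[, , H + seq_len(H)] <- scatter_t(c(d[1], d[2], H), rep(1L, d[1]),
                                        gd$dx[, H + seq_len(H), drop = FALSE])
  for (l in 4:1) {
    pf <- list(W = p[[paste0("r", l, "f.W")]], U = p[[paste0("r", l, "f.U")]],
               b = p[[paste0("r", l, "f.b")]])
    pb <- list(W = p[[paste0("r", l, "b.W")]], U = p[[paste0("r", l, "b.U")]],
               b = p[[paste0("r", l, "b.b")]])
    dHf <- dout[, , seq_len(H), drop = FALSE]
    dHb <- rnn_reverse_time(dout[, , H + seq_len(H), drop = FALSE])
    rf <- lstm_bwd(dHf, cache$caches[[l]]$f, pf)
    rb <- lstm_bwd(dHb, cache$caches[[l]]$b, pb)
    g[[paste0("r", l, "f.W")]] <- rf$dW
    g[[paste0("r", l, "f.U")]] <- rf$dU
    g[[paste0("r", l, "f.b")]] <- rf$db
    g[[paste0("r", l, "b.W")]] <- rb$dW
    g[[paste0("r", l, "b.U")]] <- rb$dU
    g[[paste0("r", l, "b.b")]] <- rb$db
    dout <- rf$dx + rnn_reverse_time(rb$dx)
  }
  g
}

## CLDNN ------------------------------------------------------------------

fwd_cldnn <- function(model, x, lens) {
  p <- model$params
  Tt <- dim(x)[2]
  if (Tt < 4L) stop("CLDNN requires sequences of at least 4 steps")
  c1 <- conv1d_fwd(x, p[["c1.W"]], p[["c1.b"]], K = 5L, pad = 2L)
  a1 <- pmax(c1$y, 0)
  p1 <- maxpool_fwd(a1, k = 2L, stride = 2L)
  c2 <- conv1d_fwd(p1$y, p[["c2.W"]], p[["c2.b"]], K = 5L, pad = 2L)
  a2 <- pmax(c2$y, 0)
  p2 <- maxpool_fwd(a2, k = 2L, stride = 2L)
  T4 <- dim(p2$y)[2]
  seqs <- vector("list", 4L)
  inp <- p2$y
  for (l in 1:4) {
    lay <- list(W = p[[paste0("r", l, ".W")]], U = p[[paste0("r", l, ".U")]],
                b = p[[paste0("r", l, ".b")]])
    r <- lstm_fwd(inp, lay)
    seqs[[l]] <- r$cache
    inp <- r$h_seq
  }
  ridx <- pmin(pmax(lens %/% 4L, 1L), T4)
  hlast <- gather_t(inp, ridx)
  z1 <- dense_fwd(hlast, p[["fc1.W"]], p[["fc1.b"]])
  a3 <- pmax(z1, 0)
  logit <- dense_fwd(a3, p[["head.W"]], p[["head.b"]])[, 1L]
  features <- list(
    f1 = t(matrix(p1$y[1L, , ], dim(p1$y)[2], dim(p1$y)[3])),
    f2 = t(matrix(p2$y[1L, , ], dim(p2$y)[2], dim(p2$y)[3])),
    f3 = matrix(seqs[[1L]]$Hs[1L, , ], T4, 64L),
    f4 = matrix(seqs[[2L]]$Hs[1L, , ], T4, 64L),
    f5 = matrix(seqs[[3L]]$Hs[1L, , ], T4, 64L),
    f6 = matrix(seqs[[4L]]$Hs[1L, , ], T4, 64L),
    f7 = z1[1L, ],
    f8 = a3[1L, ])
  list(logit = logit, model = model, features = features,
       cache = list(c1 = c1, a1pos = c1$y > 0, p1 = p1,
                    c2 = c2, a2pos = c2$y > 0, p2 = p2,
                    seqs = seqs, hlast = hlast, z1 = z1, a3 = a3,
                    ridx = ridx, rnn_dims = dim(inp)))
}

bwd_cldnn <- function(model, cache, dlogit) {
  p <- model$params
  g <- list()
  gh <- dense_bwd(matrix(dlogit, ncol = 1L), cache$a3, p[["head.W"]])
  g[["head.W"]] <- gh$dW
  g[["head.b"]] <- gh$db
  da3 <- gh$dx * (cache$z1 > 0)
  gf <- dense_bwd(da3, cache$hlast, p[["fc1.W"]])
  g[["fc1.W"]] <- gf$dW
  g[["fc1.b"]] <- gf$db
  dHs <- scatter_t(cache$rnn_dims, cache$ridx, gf$dx)
  for (l in 4:1) {
    lay <- list(W = p[[paste0("r", l, ".W")]], U = p[[paste0("r", l, ".U")]],
                b = p[[paste0("r", l, ".b")]])
    r <- lstm_bwd(dHs, cache$seqs[[l]], lay)
    g[[paste0("r", l, ".W")]] <- r$dW
    g[[paste0("r", l, ".U")]] <- r$dU
    g[[paste0("r", l, ".b")]] <- r$db
    dHs <- r$dx
  }
  dp2 <- maxpool_bwd(dHs, cache$p2, k = 2L, stride = 2L)
  dc2 <- dp2 * cache$a2pos
  gc2 <- conv1d_bwd(dc2, cache$c2, p[["c2.W"]], K = 5L, pad = 2L)
  g[["c2.W"]] <- gc2$dW
  g[["c2.b"]] <- gc2$db
  dp1 <- maxpool_bwd(gc2$dx, cache$p1, k = 2L, stride = 2L)
  dc1 <- dp1 * cache$a1pos
  gc1 <- conv1d_bwd(dc1, cache$c1, p[["c1.W"]], K = 5L, pad = 2L)
  g[["c1.W"]] <- gc1$dW
  g[["c1.b"]] <- gc1$db
  g
}

## TCN --------------------------------------------------------------------

fwd_tcn <- function(model, x, training) {
  p <- model$params
  Tt <- dim(x)[2]
  if (Tt < 25L) stop("TCN requires sequences of at least 25 steps")
  blocks <- vector("list", 4L)
  features <- list()
  inp <- x
  for (l in 1:4) {
    cv <- conv1d_fwd(inp, p[[paste0("c", l, ".W")]], p[[paste0("c", l, ".b")]],
                     K = 25L, pad = 12L)
    st <- model$bn[[paste0("bn", l)]]
    bn <- bn_fwd(cv$y, p[[paste0("bn", l, ".gamma")]],
                 p[[paste0("bn", l, ".beta")]],
                 st$rm, st$rv, training)
    model$bn[[paste0("bn", l)]] <- list(rm = bn$rm, rv = bn$rv)
    a <- pmax(bn$y, 0)
    pl <- maxpool_fwd(a, k = 3L, stride = 1L, pad = 1L)
    blocks[[l]] <- list(cv = cv, bn = bn, apos = bn$y > 0, pl = pl)
    inp <- pl$y
    features[[paste0("F", l)]] <- t(matrix(inp[1L, , ],
                                           dim(inp)[2], dim(inp)[3]))
  }
  tm <- tmean_fwd(inp)
  logit <- dense_fwd(tm$y, p[["head.W"]], p[["head.b"]])[, 1L]
  list(logit = logit, model = model, features = features,
       cache = list(blocks = blocks, tm = tm, pooled = tm$y))
}

bwd_tcn <- function(model, cache, dlogit) {
  p <- model$params
  g <- list()
  gh <- dense_bwd(matrix(dlogit, ncol = 1L), cache$pooled, p[["head.W"]])
  g[["head.W"]] <- gh$dW
  g[["head.b"]] <- gh$db
  dx <- tmean_bwd(gh$dx, cache$tm)
  for (l in 4:1) {
    bl <- cache$blocks[[l]]
    dpl <- maxpool_bwd(dx, bl$pl, k = 3L, stride = 1L, pad = 1L)
    da <- dpl * bl$apos
    gb <- bn_bwd(da, bl$bn, p[[paste0("bn", l, ".gamma")]])
    g[[paste0("bn", l, ".gamma")]] <- gb$dgamma
    g[[paste0("bn", l, ".beta")]] <- gb$dbeta
    gc <- conv1d_bwd(gb$dx, bl$cv, p[[paste0("c", l, ".W")]],
                     K = 25L, pad = 12L)
    g[[paste0("c", l, ".W")]] <- gc$dW
    g[[paste0("c", l, ".b")]] <- gc$db
    dx <- gc$dx
  }
  g
}

## Transformer ------------------------------------------------------------

fwd_transformer <- function(model, x, training) {
  p <- model$params
  cv <- conv1d_fwd(x, p[["c1.W"]], p[["c1.b"]], K = 1L, pad = 0L)
  att_p <- list(Wq = p[["att.Wq"]], bq = p[["att.bq"]],
                Wk = p[["att.Wk"]], bk = p[["att.bk"]],
                Wv = p[["att.Wv"]], bv = p[["att.bv"]],
                Wo = p[["att.Wo"]], bo = p[["att.bo"]])
  att <- mha_fwd(cv$y, att_p, n_heads = 8L)
  bn1 <- bn_fwd(att$y, p[["bn1.gamma"]], p[["bn1.beta"]],
                model$bn$bn1$rm, model$bn$bn1$rv, training)
  model$bn$bn1 <- list(rm = bn1$rm, rv = bn1$rv)
  tm <- tmean_fwd(bn1$y)
  z1 <- dense_fwd(tm$y, p[["fc1.W"]], p[["fc1.b"]])
  a1 <- pmax(z1, 0)
  bn2 <- bn_fwd(a1, p[["bn2.gamma"]], p[["bn2.beta"]],
                model$bn$bn2$rm, model$bn$bn2$rv, training)
  model$bn$bn2 <- list(rm = bn2$rm, rv = bn2$rv)
  logit <- dense_fwd(bn2$y, p[["head.W"]], p[["head.b"]])[, 1L]
  features <- list(
    f1 = t(matrix(cv$y[1L, , ], dim(cv$y)[2], dim(cv$y)[3])),
    f2 = tm$y[1L, ])
  list(logit = logit, model = model, features = features,
       cache = list(cv = cv, att = att, att_p = att_p, bn1 = bn1, tm = tm,
                    z1 = z1, a1 = a1, bn2 = bn2, pooled = tm$y))
}

bwd_transformer <- function(model, cache, dlogit) {
  p <- model$params
  g <- list()
  gh <- dense_bwd(matrix(dlogit, ncol = 1L), cache$bn2$y, p[["head.W"]])
  g[["head.W"]] <- gh$dW
  g[["head.b"]] <- gh$db
  gb2 <- bn_bwd(gh$dx, cache$bn2, p[["bn2.gamma"]])
  g[["bn2.gamma"]] <- gb2$dgamma
  g[["bn2.beta"]] <- gb2$dbeta
  da1 <- gb2$dx * (cache$z1 > 0)
  gf <- dense_bwd(da1, cache$tm$y, p[["fc1.W"]])
  g[["fc1.W"]] <- gf$dW
  g[["fc1.b"]] <- gf$db
  dbn1 <- tmean_bwd(gf$dx, cache$tm)
  gb1 <- bn_bwd(dbn1, cache$bn1, p[["bn1.gamma"]])
  g[["bn1.gamma"]] <- gb1$dgamma
  g[["bn1.beta"]] <- gb1$dbeta
  ga <- mha_bwd(gb1$dx, cache$att, cache$att_p)
  g[["att.Wq"]] <- ga$dWq; g[["att.bq"]] <- ga$dbq
  g[["att.Wk"]] <- ga$dWk; g[["att.bk"]] <- ga$dbk
  g[["att.Wv"]] <- ga$dWv; g[["att.bv"]] <- ga$dbv
  g[["att.Wo"]] <- ga$dWo; g[["att.bo"]] <- ga$dbo
  gc <- conv1d_bwd(ga$dx, cache$cv, p[["c1.W"]], K = 1L, pad = 0L)
  g[["c1.W"]] <- gc$dW
  g[["c1.b"]] <- gc$db
  g
}

#' Predict Expert probabilities for a list of traces
#'
#' Evaluation-mode forward pass on full-length (variable T) traces, one at a
#' time, as done at test time.
#'
#' @param model A `skill_model`.
#' @param traces List of numeric force traces (already preprocessed) or, for
#'   3-channel models, matrices with 3 rows as produced by [rfft_stack()].
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, traces) {
  vapply(traces, function(tr) {
    x <- trace_to_input(tr, model$in_channels)
    model_forward(model, x)$prob
  }, numeric(1))
}

# convert a single trace (vector or 3xT matrix) to an (1, T, C) input array
trace_to_input <- function(tr, in_channels) {
  if (is.matrix(tr)) {
    if (nrow(tr) != in_channels) {
      stop(sprintf("trace has %d channels but model expects %d",
                   nrow(tr), in_channels))
    }
    x <- array(0, c(1L, ncol(tr), nrow(tr)))
    x[1L, , ] <- t(tr)
  } else {
    if (in_channels != 1L) {
      stop(sprintf("trace has 1 channel but model expects %d", in_channels))
    }
    x <- array(tr, c(1L, length(tr), 1L))
  }
  x
}

# binary cross-entropy from logits; returns loss and dloss/dlogit
bce_from_logits <- function(logit, y) {
  # softplus(z) - y z, computed stably
  sp <- ifelse(logit > 0, logit + log1p(exp(-logit)), log1p(exp(logit)))
  loss <- mean(sp - y * logit)
  dlogit <- (sigm(logit) - y) / length(y)
  list(loss = loss, dlogit = dlogit)
}
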