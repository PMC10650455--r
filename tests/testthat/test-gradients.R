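# Finite-difference verification of the hand-derived backward passes, at
# layer level for each primitive and at model level for the composite
# architectures.

test_that("dense, batchnorm and temporal-mean backward passes are exact", {
  withr::with_seed(1, {
    N <- 3; D <- 4; Fd <- 2
    x <- matrix(rnorm(N * D), N)
    W <- matrix(rnorm(D * Fd), D)
    b <- rnorm(Fd)
    R <- matrix(rnorm(N * Fd), N)
    loss_d <- function(p) sum(forceskill:::dense_fwd(x, p$W, p$b) * R)
    g <- forceskill:::dense_bwd(R, x, W)
    for (i in seq_along(W)) {
      expect_grad_close(g$dW[i], num_grad_entry(loss_d, list(W = W, b = b),
                                                "W", i))
    }
    expect_grad_close(g$db[1], num_grad_entry(loss_d, list(W = W, b = b),
                                              "b", 1))

    xa <- array(rnorm(3 * 6 * 2), c(3, 6, 2))
    gam <- c(1.2, 0.8); bet <- c(0.1, -0.2)
    Ra <- array(rnorm(36), c(3, 6, 2))
    loss_bn <- function(p) {
      r <- forceskill:::bn_fwd(xa, p$gam, p$bet, c(0, 0), c(1, 1), TRUE)
      sum(r$y * Ra)
    }
    fwd <- forceskill:::bn_fwd(xa, gam, bet, c(0, 0), c(1, 1), TRUE)
    g2 <- forceskill:::bn_bwd(Ra, fwd, gam)
    for (i in 1:2) {
      expect_grad_close(g2$dgamma[i],
                        num_grad_entry(loss_bn, list(gam = gam, bet = bet),
                                       "gam", i))
    }
    # input gradient via a wiggled element
    eps <- 1e-5
    xa2 <- xa; xa2[2, 3, 1] <- xa2[2, 3, 1] + eps
    xa3 <- xa; xa3[2, 3, 1] <- xa3[2, 3, 1] - eps
    num <- (sum(forceskill:::bn_fwd(xa2, gam, bet, c(0, 0), c(1, 1),
                                    TRUE)$y * Ra) -
            sum(forceskill:::bn_fwd(xa3, gam, bet, c(0, 0), c(1, 1),
                                    TRUE)$y * Ra)) / (2 * eps)
    expect_grad_close(g2$dx[2, 3, 1], num)

    tm <- forceskill:::tmean_fwd(xa)
    Rm <- matrix(rnorm(6), 3)
    gtm <- forceskill:::tmean_bwd(Rm, tm)
    expect_equal(gtm[2, 4, 1], Rm[2, 1] / 6, tolerance = 1e-12)
  })
})

test_that("conv1d and maxpool backward passes are exact", {
  withr::with_seed(2, {
    N <- 2; Tt <- 9; C <- 2; Fd <- 3; K <- 3; pad <- 1
    x <- array(rnorm(N * Tt * C), c(N, Tt, C))
    W <- matrix(rnorm(K * C * Fd), K * C)
    b <- rnorm(Fd)
    fw <- forceskill:::conv1d_fwd(x, W, b, K, pad)
    R <- array(rnorm(length(fw$y)), dim(fw$y))
    loss <- function(p) {
      sum(forceskill:::conv1d_fwd(x, p$W, p$b, K, pad)$y * R)
    }
    g <- forceskill:::conv1d_bwd(R, fw, W, K, pad)
    for (i in seq_along(W)) {
      expect_grad_close(g$dW[i], num_grad_entry(loss, list(W = W, b = b),
                                                "W", i))
    }
    expect_grad_close(g$db[2], num_grad_entry(loss, list(W = W, b = b),
                                              "b", 2))
    eps <- 1e-5
    for (idx in list(c(1, 1, 1), c(2, 5, 2), c(1, 9, 1))) {
      x2 <- x; x2[idx[1], idx[2], idx[3]] <- x2[idx[1], idx[2], idx[3]] + eps
      x3 <- x; x3[idx[1], idx[2], idx[3]] <- x3[idx[1], idx[2], idx[3]] - eps
      num <- (sum(forceskill:::conv1d_fwd(x2, W, b, K, pad)$y * R) -
              sum(forceskill:::conv1d_fwd(x3, W, b, K, pad)$y * R)) /
        (2 * eps)
      expect_grad_close(g$dx[idx[1], idx[2], idx[3]], num)
    }

    for (cfgp in list(c(2, 2, 0), c(3, 1, 1))) {
      pl <- forceskill:::maxpool_fwd(x, cfgp[1], cfgp[2], cfgp[3])
      Rp <- array(rnorm(length(pl$y)), dim(pl$y))
      gd <- forceskill:::maxpool_bwd(Rp, pl, cfgp[1], cfgp[2], cfgp[3])
      for (idx in list(c(1, 2, 1), c(2, 7, 2))) {
        x2 <- x; x2[idx[1], idx[2], idx[3]] <- x2[idx[1], idx[2], idx[3]] + eps
        x3 <- x; x3[idx[1], idx[2], idx[3]] <- x3[idx[1], idx[2], idx[3]] - eps
        num <- (sum(forceskill:::maxpool_fwd(x2, cfgp[1], cfgp[2],
                                             cfgp[3])$y * Rp) -
                sum(forceskill:::maxpool_fwd(x3, cfgp[1], cfgp[2],
                                             cfgp[3])$y * Rp)) / (2 * eps)
        expect_grad_close(gd[idx[1], idx[2], idx[3]], num)
      }
    }
  })
})

test_that("LSTM and GRU backpropagation through time is exact", {
  withr::with_seed(3, {
    N <- 2; Tt <- 6; D <- 3; H <- 4
    x <- array(rnorm(N * Tt * D), c(N, Tt, D))
    for (kind in c("lstm", "gru")) {
      init <- if (kind == "lstm") forceskill:::lstm_init else
        forceskill:::gru_init
      fwd <- if (kind == "lstm") forceskill:::lstm_fwd else
        forceskill:::gru_fwd
      bwd <- if (kind == "lstm") forceskill:::lstm_bwd else
        forceskill:::gru_bwd
      p <- init(D, H)
      r <- fwd(x, p)
      R <- array(rnorm(length(r$h_seq)), dim(r$h_seq))
      loss <- function(pp) sum(fwd(x, pp)$h_seq * R)
      g <- bwd(R, r$cache, p)
      for (nm in c("W", "U", "b")) {
        idx <- sample(length(p[[nm]]), 4)
        for (i in idx) {
          expect_grad_close(g[[paste0("d", nm)]][i],
                            num_grad_entry(loss, p, nm, i), tol = 1e-3)
        }
      }
      eps <- 1e-5
      x2 <- x; x2[1, 2, 1] <- x2[1, 2, 1] + eps
      x3 <- x; x3[1, 2, 1] <- x3[1, 2, 1] - eps
      num <- (sum(fwd(x2, p)$h_seq * R) - sum(fwd(x3, p)$h_seq * R)) /
        (2 * eps)
      expect_grad_close(g$dx[1, 2, 1], num, tol = 1e-3)
    }
  })
})

test_that("multi-head attention backward pass is exact", {
  withr::with_seed(4, {
    N <- 2; Tt <- 5; D <- 4
    x <- array(rnorm(N * Tt * D), c(N, Tt, D))
    p <- list()
    for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[nm]] <- matrix(rnorm(D * D), D)
    for (nm in c("bq", "bk", "bv", "bo")) p[[nm]] <- rnorm(D)
    r <- forceskill:::mha_fwd(x, p, n_heads = 2L)
    R <- array(rnorm(length(r$y)), dim(r$y))
    loss <- function(pp) sum(forceskill:::mha_fwd(x, pp, 2L)$y * R)
    g <- forceskill:::mha_bwd(R, r, p)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      for (i in sample(length(p[[nm]]), 3)) {
        expect_grad_close(g[[paste0("d", nm)]][i],
                          num_grad_entry(loss, p, nm, i), tol = 1e-3)
      }
    }
    eps <- 1e-5
    x2 <- x; x2[2, 3, 1] <- x2[2, 3, 1] + eps
    x3 <- x; x3[2, 3, 1] <- x3[2, 3, 1] - eps
    num <- (sum(forceskill:::mha_fwd(x2, p, 2L)$y * R) -
            sum(forceskill:::mha_fwd(x3, p, 2L)$y * R)) / (2 * eps)
    expect_grad_close(g$dx[2, 3, 1], num, tol = 1e-3)
  })
})

test_that("composite architectures pass end-to-end gradient checks", {
  for (a in c("cldnn", "tcn", "transformer")) {
    check_model_gradients(a)
  }
})
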