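archs <- c("lstm", "bilstm", "gru", "cldnn", "tcn", "transformer")

test_that("all architectures map any input into a probability", {
  withr::with_seed(2, {
    for (a in archs) {
      m <- build_model(a, init_seed = 3)
      for (Tt in c(40, 300)) {
        x <- array(rnorm(2 * Tt), c(2, Tt, 1))
        p <- model_forward(m, x)$prob
        expect_length(p, 2L)
        expect_true(all(p >= 0 & p <= 1))
      }
    }
  })
})

test_that("model building is a pure function of architecture and seed", {
  withr::with_seed(4, x <- array(rnorm(300), c(1, 300, 1)))
  for (a in archs) {
    m1 <- build_model(a, init_seed = 11)
    m2 <- build_model(a, init_seed = 11)
    m3 <- build_model(a, init_seed = 12)
    expect_identical(m1$params, m2$params)
    expect_false(identical(m1$params, m3$params))
    expect_identical(model_forward(m1, x)$prob, model_forward(m2, x)$prob)
    # evaluation-mode forward is deterministic
    expect_identical(model_forward(m1, x)$prob, model_forward(m1, x)$prob)
  }
})

test_that("recurrent readout widths and parameter ordering match design", {
  lstm <- build_model("lstm", init_seed = 1)
  bil <- build_model("bilstm", init_seed = 1)
  gru <- build_model("gru", init_seed = 1)
  x <- array(rnorm(120), c(1, 120, 1))
  expect_length(model_forward(lstm, x, with_features = TRUE)$features$h_last,
                64L)
  expect_length(model_forward(bil, x, with_features = TRUE)$features$h_last,
                128L)
  expect_length(model_forward(gru, x, with_features = TRUE)$features$h_last,
                64L)
  expect_gt(count_params(bil), count_params(lstm))
  expect_lt(count_params(gru), count_params(lstm))
})

test_that("CLDNN intermediate feature maps have the documented shapes", {
  m <- build_model("cldnn", init_seed = 5)
  x <- array(rnorm(300), c(1, 300, 1))
  f <- model_forward(m, x, with_features = TRUE)$features
  expect_equal(dim(f$f1), c(64L, 150L))
  expect_equal(dim(f$f2), c(128L, 75L))
  for (nm in c("f3", "f4", "f5", "f6")) {
    expect_equal(dim(f[[nm]]), c(75L, 64L))
  }
  expect_length(f$f7, 64L)
  expect_length(f$f8, 64L)
  expect_error(model_forward(m, array(rnorm(3), c(1, 3, 1))), "at least 4")
})

test_that("TCN preserves temporal resolution through all four blocks", {
  m <- build_model("tcn", init_seed = 6)
  for (Tt in c(25, 300, 517)) {
    x <- array(rnorm(Tt), c(1, Tt, 1))
    f <- model_forward(m, x, with_features = TRUE)$features
    expect_equal(dim(f$F4), c(16L, Tt))
    expect_equal(dim(f$F1), c(64L, Tt))
    expect_equal(dim(f$F2), c(32L, Tt))
    expect_equal(dim(f$F3), c(16L, Tt))
  }
  # odd and even lengths both pass the padding arithmetic
  expect_length(model_forward(m, array(rnorm(299), c(1, 299, 1)))$prob, 1L)
  expect_length(model_forward(m, array(rnorm(300), c(1, 300, 1)))$prob, 1L)
  expect_error(model_forward(m, array(rnorm(24), c(1, 24, 1))), "at least 25")
})

test_that("transformer lifts to 16 channels and pools a 16-d descriptor", {
  m <- build_model("transformer", init_seed = 7)
  x <- array(rnorm(210), c(1, 210, 1))
  f <- model_forward(m, x, with_features = TRUE)$features
  expect_equal(dim(f$f1), c(16L, 210L))
  expect_length(f$f2, 16L)
})

test_that("channel mismatches are rejected", {
  m <- build_model("tcn", in_channels = 3, init_seed = 1)
  expect_error(model_forward(m, array(rnorm(60), c(1, 60, 1))),
               "channels")
  expect_error(predict_prob(build_model("tcn"), list(rfft_stack(rnorm(60)))),
               "channels")
})

test_that("gradients flow to every parameter of every architecture", {
  withr::with_seed(8, {
    x <- array(rnorm(3 * 60), c(3, 60, 1))
    y <- c(1, 0, 1)
    for (a in archs) {
      m <- build_model(a, init_seed = 9)
      fw <- model_forward(m, x, training = TRUE, with_cache = TRUE)
      l <- forceskill:::bce_from_logits(fw$logit, y)
      g <- forceskill:::model_backward(m, fw$cache, l$dlogit)
      expect_setequal(names(g), names(m$params))
      nonzero <- vapply(g, function(gr) any(abs(gr) > 0), logical(1))
      expect_true(all(nonzero), label = paste("dead branch in", a))
    }
  })
})

test_that("variable-length evaluation matches padded training readout", {
  # readout at the last valid step: padding with zeros must not change the
  # recurrent prediction for the same trial
  withr::with_seed(10, {
    tr <- rnorm(120)
    for (a in c("lstm", "gru")) {
      m <- build_model(a, init_seed = 2)
      p_full <- model_forward(m, array(tr, c(1, 120, 1)))$prob
      xpad <- array(0, c(1, 200, 1))
      xpad[1, 1:120, 1] <- tr
      p_pad <- model_forward(m, xpad, lens = 120)$prob
      expect_equal(p_pad, p_full, tolerance = 1e-12)
    }
  })
})
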