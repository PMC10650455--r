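# direct O(T^2) DFT as the spectral oracle
dft_direct <- function(x) {
  Tt <- length(x)
  vapply(0:(Tt - 1), function(k) {
    sum(x * exp(-2i * pi * k * (seq_len(Tt) - 1) / Tt))
  }, complex(1))
}

test_that("rfft_stack matches a direct DFT and keeps the raw force row", {
  withr::with_seed(1, x <- runif(12, 0, 5))
  m <- rfft_stack(x)
  expect_equal(dim(m), c(3L, 12L))
  expect_equal(m[1, ], x, ignore_attr = TRUE)
  sp <- dft_direct(x)[1:7]
  expect_equal(m[2, 1:7], Re(sp), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m[3, 1:7], Im(sp), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m[2:3, 8:12], matrix(0, 2, 5), ignore_attr = TRUE)

  # constant input: energy only in coefficient 0, imaginary part vanishes
  mc <- rfft_stack(rep(3, 10))
  expect_equal(mc[3, ], rep(0, 10), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(mc[2, 1], 30, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(mc[2, 2:10], rep(0, 9), tolerance = 1e-9, ignore_attr = TRUE)

  # pure sinusoid at DFT bin 3: spectrum nonzero only at coefficient 3
  Tt <- 32
  s <- cos(2 * pi * 3 * (0:(Tt - 1)) / Tt)
  ms <- rfft_stack(s)
  mag <- sqrt(ms[2, 1:17]^2 + ms[3, 1:17]^2)
  expect_true(all(mag[-4] < 1e-9))
  expect_gt(mag[4], 1)
  expect_error(rfft_stack(1.5), "at least 2")
})

test_that("quantization matches a brute-force nearest-level oracle", {
  expect_equal(augment_quantize(c(0, 0.26, 1), apply_prob = 1, seed = 1),
               c(0, 2 / 9, 1))
  withr::with_seed(10, {
    for (rep in 1:20) {
      x <- runif(40, -2, 7)
      q <- augment_quantize(x, apply_prob = 1)
      lv <- seq(min(x), max(x), length.out = 10)
      oracle <- vapply(x, function(v) {
        d <- abs(v - lv)
        lv[which(d == min(d))[1]]  # ties to the lower level
      }, numeric(1))
      expect_equal(q, oracle)
      expect_lte(length(unique(q)), 10L)
    }
  })
  x <- rnorm(20)
  expect_identical(augment_quantize(x, apply_prob = 0, seed = 2), x)
  expect_identical(augment_quantize(rep(2, 15), apply_prob = 1, seed = 3),
                   rep(2, 15))
})

test_that("drift multiplies anchors by 1.1-1.5 and fixes the endpoints", {
  withr::with_seed(4, {
    for (rep in 1:10) {
      x <- runif(80, 1, 4)
      y <- augment_drift(x, apply_prob = 1)
      ratio <- y / x
      expect_equal(ratio[1], 1, tolerance = 1e-9)
      expect_equal(ratio[80], 1, tolerance = 1e-9)
      # five interior anchors carry multipliers inside [1.1, 1.5]
      anchors <- which(ratio >= 1.1 - 1e-9 & ratio <= 1.5 + 1e-9)
      expect_gte(length(anchors), 5L)
    }
  })
  x <- rnorm(30)
  expect_identical(augment_drift(x, apply_prob = 0, seed = 1), x)
  expect_equal(augment_drift(rep(0, 30), apply_prob = 1, seed = 2),
               rep(0, 30))
  expect_error(augment_drift(rnorm(6), apply_prob = 1), "at least 7")
})

test_that("time warp preserves length and maps constants to themselves", {
  withr::with_seed(5, {
    for (rep in 1:100) {
      Tt <- sample(100:400, 1)
      x <- runif(Tt, 0, 5)
      y <- augment_time_warp(x, apply_prob = 1)
      expect_length(y, Tt)
      expect_true(all(y >= min(x) - 1e-12 & y <= max(x) + 1e-12))
    }
  })
  expect_equal(augment_time_warp(rep(1.7, 200), apply_prob = 1, seed = 6),
               rep(1.7, 200))
  x <- rnorm(120)
  expect_identical(augment_time_warp(x, apply_prob = 0, seed = 7), x)
  expect_error(augment_time_warp(rnorm(99), apply_prob = 1), "at least 100")
})

test_that("gaussian noise recovers its nominal moments", {
  withr::with_seed(8, {
    x <- runif(1e5, 0, 5)
    y <- augment_gaussian_noise(x)
    d <- y - x
    expect_lt(abs(mean(d)), 3 * 0.1 / sqrt(1e5))
    expect_lt(abs(sd(d) - 0.1) / 0.1, 0.01)
  })
  x <- rnorm(50)
  expect_identical(augment_gaussian_noise(x, sd = 0), x)
  expect_identical(augment_gaussian_noise(x, seed = 3),
                   augment_gaussian_noise(x, seed = 3))
})

test_that("temporal jitter permutes segments, preserving the sample multiset", {
  withr::with_seed(9, {
    for (rep in 1:10) {
      x <- rnorm(300)
      y <- augment_temporal_jitter(x)
      expect_length(y, 300)
      expect_equal(sort(y), sort(x))
      # blocks of 10 stay contiguous
      blocks_in <- split(x, rep(1:30, each = 10))
      blocks_out <- split(y, rep(1:30, each = 10))
      expect_setequal(
        unname(vapply(blocks_out, paste, character(1), collapse = ",")),
        unname(vapply(blocks_in, paste, character(1), collapse = ",")))
    }
  })
  expect_error(augment_temporal_jitter(rnorm(299)), "length 300")
})

test_that("probability gates fire at their configured frequency", {
  withr::with_seed(11, {
    x <- runif(40, 1, 2)
    fired <- replicate(1e4, !identical(augment_quantize(x), x))
    expect_gte(mean(fired), 0.47)
    expect_lte(mean(fired), 0.53)
  })
})

test_that("augmentation operators are pure functions of input and seed", {
  x <- runif(100, 0, 5)
  for (nm in c("quantize", "drift", "timewarp", "gaussian_noise")) {
    cfg <- augmentation_config(nm)
    expect_identical(apply_augmentation(x, cfg, seed = 42),
                     apply_augmentation(x, cfg, seed = 42))
  }
  cfg <- augmentation_config("temporal_jitter")
  x300 <- runif(300)
  expect_identical(apply_augmentation(x300, cfg, seed = 1),
                   apply_augmentation(x300, cfg, seed = 1))
  expect_identical(apply_augmentation(x, augmentation_config("fft")),
                   rfft_stack(x))
})
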