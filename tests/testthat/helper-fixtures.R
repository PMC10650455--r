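# Shared fixtures: small synthetic cohorts, a perfectly separated trial set
# for capacity checks, and a finite-difference gradient utility.

tiny_cohort <- function(seed = 42, n_experts = 3, n_novices = 3,
                        trials = c(4, 4), lens = c(60, 140)) {
  generate_cohort(cohort_spec(n_experts = n_experts, n_novices = n_novices,
                              trials_per_surgeon = trials,
                              length_range = lens, seed = seed))
}

# 16 trials, two cleanly separated force levels (8 Expert high, 8 Novice low)
separated_set <- function(Tt = 60) {
  withr::with_seed(99, {
    traces <- c(
      lapply(1:8, function(i) {
        2 + 0.3 * sin(seq_len(Tt) / 5 + i) + stats::rnorm(Tt, 0, 0.05)
      }),
      lapply(1:8, function(i) {
        0.5 + 0.3 * cos(seq_len(Tt) / 7 + i) + stats::rnorm(Tt, 0, 0.05)
      }))
    list(traces = traces, labels = rep(c(1, 0), each = 8))
  })
}

# central-difference derivative of scalar function f at params[[name]][i]
num_grad_entry <- function(f, params, name, i, eps = 1e-5) {
  p1 <- params; p1[[name]][i] <- p1[[name]][i] + eps
  p2 <- params; p2[[name]][i] <- p2[[name]][i] - eps
  (f(p1) - f(p2)) / (2 * eps)
}

expect_grad_close <- function(ana, num, tol = 1e-4) {
  denom <- max(1e-6, abs(ana) + abs(num))
  expect_lt(abs(ana - num) / denom, tol)
}

# model-level finite-difference check: compares analytic gradients of the
# training loss with central differences for sampled parameter entries
check_model_gradients <- function(arch, Tt = 28, N = 3, n_entries = 2,
                                  tol = 5e-3) {
  withr::with_seed(7, {
    m <- build_model(arch, init_seed = 7)
    x <- array(stats::rnorm(N * Tt), c(N, Tt, 1))
    lens <- sample(5:Tt, N, replace = TRUE)
    y <- rep_len(c(1, 0), N)
    lossfun <- function(params) {
      mm <- m
      mm$params <- params
      r <- model_forward(mm, x, lens, training = TRUE)
      forceskill:::bce_from_logits(r$logit, y)$loss
    }
    r <- model_forward(m, x, lens, training = TRUE, with_cache = TRUE)
    l <- forceskill:::bce_from_logits(r$logit, y)
    g <- forceskill:::model_backward(m, r$cache, l$dlogit)
    for (nm in names(m$params)) {
      idx <- sample(length(m$params[[nm]]),
                    min(n_entries, length(m$params[[nm]])))
      for (i in idx) {
        num <- num_grad_entry(lossfun, m$params, nm, i)
        ana <- g[[nm]][i]
        # analytically-zero gradients drown in finite-difference noise
        if (abs(num) < 1e-7 && abs(ana) < 1e-7) next
        expect_grad_close(ana, num, tol)
      }
    }
  })
}
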