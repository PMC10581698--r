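test_that("parameter count equals the layer-wise closed form", {
  cfg <- model_config(L = 32L, kernels = c(7L, 5L, 3L), channels = c(4L, 6L, 8L),
                      in_channels = 6L)
  m <- build_model(cfg)
  # input BN (2*6) + per block (k*cin*cout + cout bias + 2*cout BN) + head
  expected <- 2 * 6 +
    (7 * 6 * 4 + 4 + 2 * 4) +
    (5 * 4 * 6 + 6 + 2 * 6) +
    (3 * 6 * 8 + 8 + 2 * 8) +
    (1 * 8 * 2 + 2)
  expect_equal(n_parameters(m), expected)
})

test_that("the full preset satisfies the published scale constraints", {
  cfg <- model_preset("full")
  expect_identical(cfg$n_blocks, 5L)
  expect_identical(cfg$channels[1L], 8L)
  n <- n_parameters(build_model(cfg))
  expect_gt(n, 130000 * 0.8)
  expect_lt(n, 130000 * 1.2)
})

test_that("receptive field follows the closed form", {
  expect_identical(receptive_field(c(3L, 3L, 3L, 3L, 3L)), 11L)
  expect_identical(receptive_field(c(1L)), 1L)
  expect_identical(receptive_field(model_config(L = 8L, kernels = c(5L, 3L),
                                                channels = c(2L, 2L))), 7L)
  expect_error(model_config(L = 8L, kernels = c(4L, 3L), channels = c(2L, 2L)),
               "even")
})

test_that("forward pass is finite, shape-correct and deterministic in eval mode", {
  cfg <- model_config(L = 16L, kernels = c(5L, 3L), channels = c(4L, 4L))
  m <- build_model(cfg, seed = 2L)
  set.seed(1)
  x <- matrix(rnorm(6 * cfg$L1), nrow = 6)
  f1 <- forward(m, x)
  f2 <- forward(m, x)
  expect_identical(dim(f1$log_tmrca), c(16L, 1L))
  expect_true(all(is.finite(f1$log_tmrca)) && all(is.finite(f1$breakpoint_logit)))
  expect_identical(f1$log_tmrca, f2$log_tmrca)
  expect_identical(f1$breakpoint_logit, f2$breakpoint_logit)
  x[3, 7] <- NA
  expect_error(forward(m, x), class = "tmrcanet_input_error")
  expect_error(forward(m, matrix(0, 5, cfg$L1)), "channels")
  expect_error(forward(m, matrix(0, 6, cfg$L1 + 1)), "L1")
})

test_that("perturbing one input site only moves outputs within the receptive field", {
  cfg <- model_config(L = 40L, kernels = c(5L, 3L, 3L), channels = c(4L, 4L, 4L))
  m <- build_model(cfg, seed = 5L)
  set.seed(3)
  x <- matrix(rnorm(6 * cfg$L1), nrow = 6)
  base <- forward(m, x)
  p <- 25L                                  # input position to perturb
  x2 <- x
  x2[2, p] <- x2[2, p] + 3
  pert <- forward(m, x2)
  changed <- which(abs(pert$log_tmrca - base$log_tmrca) > 1e-12 |
                   abs(pert$breakpoint_logit - base$breakpoint_logit) > 1e-12)
  # output j reads inputs j .. j + 2*context; input p reaches outputs
  # p - 2*context .. p
  expect_true(all(changed >= p - 2L * cfg$context & changed <= p))
  expect_gt(length(changed), 0L)
})

test_that("outputs are translation-covariant away from edges", {
  cfg <- model_config(L = 24L, kernels = c(5L, 3L), channels = c(4L, 4L))
  m <- build_model(cfg, seed = 9L)
  set.seed(6)
  long <- matrix(rnorm(6 * (cfg$L1 + 10)), nrow = 6)
  s <- 4L
  f0 <- forward(m, long[, 1:cfg$L1])
  fs <- forward(m, long[, (1 + s):(cfg$L1 + s)])
  expect_equal(f0$log_tmrca[(1 + s):cfg$L, 1], fs$log_tmrca[1:(cfg$L - s), 1],
               tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(L = 8L, kernels = c(5L, 3L), channels = c(4L, 3L))
  m <- build_model(cfg, seed = 3L)
  set.seed(42)
  N <- 2L
  x <- array(rnorm(6 * cfg$L1 * N), c(6L, cfg$L1, N))
  lab <- list(tmrca = matrix(exp(rnorm(cfg$L * N, 8, 1)), cfg$L),
              breakpoint = matrix(rbinom(cfg$L * N, 1, 0.2), cfg$L))
  unc <- list(s_reg = 0.1, s_cls = -0.2)
  fw <- forward(m, x, training = TRUE, keep_cache = TRUE)
  g <- attr(multitask_loss(fw, lab, unc), "grads")
  bw <- backward(m, fw, g$d_log_tmrca, g$d_breakpoint_logit)
  f <- function(model, xx) {
    as.numeric(multitask_loss(forward(model, xx, training = TRUE), lab, unc))
  }
  eps <- 1e-6
  for (nm in c("b1.W", "b2.gamma", "head.W", "bn0.gamma")) {
    for (ii in sample(length(m$params[[nm]]), 3L)) {
      m2 <- m; m2$params[[nm]][ii] <- m$params[[nm]][ii] + eps
      m3 <- m; m3$params[[nm]][ii] <- m$params[[nm]][ii] - eps
      num <- (f(m2, x) - f(m3, x)) / (2 * eps)
      expect_lt(abs(num - bw$grads[[nm]][ii]),
                1e-4 * max(abs(num), 1e-3))
    }
  }
  for (ii in sample(length(x), 5L)) {
    x2 <- x; x2[ii] <- x[ii] + eps
    x3 <- x; x3[ii] <- x[ii] - eps
    num <- (f(m, x2) - f(m, x3)) / (2 * eps)
    expect_lt(abs(num - bw$d_input[ii]), 1e-4 * max(abs(num), 1e-3))
  }
})

test_that("the model accepts alternative input channel counts", {
  cfg <- model_config(L = 10L, kernels = c(3L, 3L), channels = c(4L, 4L),
                      in_channels = 6L)
  m <- build_model(cfg)
  set.seed(2)
  f <- forward(m, matrix(rnorm(6 * cfg$L1), nrow = 6))
  expect_identical(nrow(f$log_tmrca), 10L)
})
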