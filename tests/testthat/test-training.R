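test_that("huber and class-weight components follow their closed forms", {
  out <- list(log_tmrca = matrix(log(100), 1, 1),
              breakpoint_logit = matrix(0, 1, 1))
  lab <- list(tmrca = 100, breakpoint = 0)
  l <- multitask_loss(out, lab, list(s_reg = 0, s_cls = 0))
  expect_identical(unname(attr(l, "parts")["huber"]), 0)

  # residual 0.5 below delta: Huber term r^2/2 = 0.125
  out2 <- list(log_tmrca = matrix(log(100) + 0.5, 1, 1),
               breakpoint_logit = matrix(0, 1, 1))
  expect_equal(unname(attr(multitask_loss(out2, lab,
                                          list(s_reg = 0, s_cls = 0)),
                           "parts")["huber"]), 0.125)

  # inverse-frequency class weights: 9 background vs 1 breakpoint site
  w <- class_weights(c(rep(0, 9), 1))
  expect_equal(unname(w["w1"] / w["w0"]), 9)

  expect_error(multitask_loss(out, list(tmrca = -5, breakpoint = 0),
                              list(s_reg = 0, s_cls = 0)),
               class = "tmrcanet_label_error")
})

test_that("uncertainty gradients push the log-variances toward log(2*loss)", {
  out <- list(log_tmrca = matrix(c(1, 4), 2, 1),
              breakpoint_logit = matrix(c(0, 0), 2, 1))
  lab <- list(tmrca = exp(c(1, 1)), breakpoint = c(0, 1))
  g <- attr(multitask_loss(out, lab, list(s_reg = 0, s_cls = 0)), "grads")
  H <- unname(attr(multitask_loss(out, lab, list(s_reg = 0, s_cls = 0)),
                   "parts")["huber"])
  expect_equal(g$d_s_reg, -H + 0.5)
  # large regression loss drives s_reg up (negative gradient)
  expect_lt(g$d_s_reg, 0)
})

test_that("relatedness pairing is a deterministic perfect matching", {
  set.seed(1)
  n2 <- 10L
  m <- matrix(runif(n2 * n2, 100, 50000), n2, n2)
  m <- (m + t(m)) / 2; diag(m) <- 0
  p1 <- relatedness_pairing(m, seed = 4L)
  p2 <- relatedness_pairing(m, seed = 4L)
  expect_identical(p1, p2)
  expect_setequal(as.vector(p1), 1:n2)
  expect_identical(nrow(p1), n2 %/% 2L)
  expect_error(relatedness_pairing(m[1:9, 1:9], seed = 1L),
               class = "tmrcanet_pairing_error")

  # all-equal matrix: still a valid matching with lowest-index tie-breaks
  eq <- matrix(1, 8, 8); diag(eq) <- 0
  pe <- relatedness_pairing(eq, seed = 2L)
  expect_setequal(as.vector(pe), 1:8)
})

test_that("relatedness pairing agrees with a literal re-execution of the procedure", {
  literal <- function(m, seed) {
    set.seed(seed)
    remaining <- seq_len(nrow(m))
    first <- sample(remaining, 2L)
    pairs <- matrix(first, ncol = 2L)
    processed <- first
    remaining <- setdiff(remaining, first)
    while (length(remaining)) {
      anchor <- processed[sample.int(length(processed), 1L)]
      x <- remaining[which.min(m[anchor, remaining])]
      rem2 <- setdiff(remaining, x)
      y <- rem2[which.min(m[x, rem2])]
      pairs <- rbind(pairs, c(x, y))
      processed <- c(processed, x, y)
      remaining <- setdiff(remaining, c(x, y))
    }
    pairs
  }
  set.seed(9)
  m <- matrix(runif(16, 1, 10), 4, 4); m <- (m + t(m)) / 2; diag(m) <- 0
  for (s in 1:20)
    expect_identical(unname(relatedness_pairing(m, seed = s)),
                     unname(literal(m, s)))
  m8 <- matrix(runif(64, 1, 10), 8, 8); m8 <- (m8 + t(m8)) / 2; diag(m8) <- 0
  for (s in 1:10)
    expect_identical(unname(relatedness_pairing(m8, seed = s)),
                     unname(literal(m8, s)))
})

uniform_matching_test <- function(n2, seed) {
  set.seed(seed)
  matrix(sample.int(n2), ncol = 2L, byrow = TRUE)
}

test_that("relatedness pairing selects closer pairs than uniform pairing", {
  cfg <- sim_config(n_haplotypes = 12L, region_length = 3e5, seed = 77L)
  m <- pairwise_mean_tmrca(cfg)
  rel <- uni <- numeric(60)
  for (s in seq_along(rel)) {
    pr <- relatedness_pairing(m, seed = s)
    pu <- uniform_matching_test(nrow(m), s)
    rel[s] <- mean(m[pr])
    uni[s] <- mean(m[pu])
  }
  expect_lt(mean(rel), mean(uni))
})

test_that("epochs draw fresh, non-overlapping simulation seeds and modes alternate", {
  tc <- desk_train_config()
  e1 <- make_epoch(tc, 1L)
  e2 <- make_epoch(tc, 2L)
  expect_identical(e1$mode, "uniform")
  expect_identical(e2$mode, "relatedness")
  expect_identical(anyDuplicated(e1$seeds), 0L)
  expect_length(e1$seeds, tc$sims_per_epoch)
  expect_length(intersect(e1$seeds, e2$seeds), 0L)
  # validation seeds disjoint from training seeds
  vs <- vapply(seq_len(tc$validation_sims), function(i)
    derive_seed(tc$master_seed, sprintf("validation/sim%d", i)), 0L)
  expect_length(intersect(vs, c(e1$seeds, e2$seeds)), 0L)
  expect_gt(length(e1$examples), 0L)
  ex <- e1$examples[[1L]]
  expect_identical(dim(ex$x), c(6L, tc$model$L1))
  expect_length(ex$tmrca, tc$model$L)
})

test_that("validation retains the closest 5% of pairs and weights densities inversely", {
  y <- rep(1:20, each = 5)   # one distinct value per bin: uniform occupancy
  w <- tmrcanet:::density_weights(y, n_bins = 20L)
  expect_true(all(abs(w - 1) < 1e-12))
  tc <- desk_train_config()
  vs <- build_validation_set(tc)
  n_pairs_total <- tc$validation_sims * choose(tc$sim$n_haplotypes, 2)
  expect_identical(nrow(vs$pairs), as.integer(floor(n_pairs_total * tc$validation_frac)))
  expect_false(is.unsorted(vs$pairs$mean_tmrca))
})

test_that("training improves the validation score and is fully deterministic", {
  tc <- desk_train_config(epochs = 4L)
  ck <- train(tc)
  expect_s3_class(ck, "tmrca_checkpoint")
  expect_lt(min(ck$history$val_score), ck$history$val_score[1L])
  expect_identical(ck$best_score, min(ck$history$val_score))
  ck2 <- train(desk_train_config(epochs = 4L))
  expect_identical(ck$history, ck2$history)
  expect_identical(ck$model$params, ck2$model$params)
})

test_that("finetune rejects a mismatched model configuration", {
  tc <- desk_train_config()
  ck <- train(tc)
  other <- desk_train_config()
  other$model <- model_config(L = 32L, kernels = c(9L, 5L, 3L),
                              channels = c(8L, 8L, 8L))
  expect_error(finetune(ck, other), class = "tmrcanet_config_error")
})
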