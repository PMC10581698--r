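test_that("piecewise refinement follows the threshold convention", {
  tr <- list(tmrca = c(10, 20, 30, 40), p_break = c(0, 0, 0.9, 0))
  seg <- make_piecewise(tr, 0.7)
  expect_identical(seg$start, c(1L, 3L))
  expect_identical(seg$end, c(2L, 4L))
  expect_equal(seg$tmrca, c(15, 35))

  # no exceedance: a single segment at the track mean
  flat <- make_piecewise(list(tmrca = c(5, 7, 9), p_break = c(0, 0, 0)), 0.5)
  expect_identical(nrow(flat), 1L)
  expect_equal(flat$tmrca, 7)
  high <- make_piecewise(list(tmrca = 1:10, p_break = rep(0.9, 10)), 0.99)
  expect_identical(nrow(high), 1L)
  # strict inequality: probability equal to the threshold does not split
  eq <- make_piecewise(list(tmrca = c(1, 2), p_break = c(0, 0.7)), 0.7)
  expect_identical(nrow(eq), 1L)
})

test_that("piecewise output preserves the mean and nests across thresholds", {
  for (s in 1:100) {
    tr <- random_track(n = sample(20:150, 1), seed = 4000 + s)
    th <- runif(1, 0.05, 0.95)
    seg <- make_piecewise(tr, th)
    expect_identical(seg$start[1L], 1L)
    expect_identical(seg$end[nrow(seg)], length(tr$tmrca))
    expect_true(all(seg$start[-1L] == seg$end[-nrow(seg)] + 1L))
    expect_equal(mean(tmrcanet:::piecewise_track(seg)), mean(tr$tmrca))
    # lowering the threshold only splits: boundaries are nested
    th2 <- th * runif(1, 0.3, 0.95)
    seg2 <- make_piecewise(tr, th2)
    expect_true(all(seg$start %in% seg2$start))
  }
})

test_that("window stitching predicts each site exactly once", {
  cfg <- model_config(L = 16L, kernels = c(5L, 3L), channels = c(4L, 4L))
  model <- build_model(cfg, seed = 7L)
  # panel of exactly L sites: stitched result equals the single window
  p <- random_panel(6L, 16L, seed = 21L)
  track <- predict_pair(model, p, c(1L, 2L))
  x <- pair_features(p, c(1L, 2L), model_window(cfg))
  fw <- forward(model, x)
  expect_equal(track$tmrca, pmax(exp(fw$log_tmrca[, 1L]), 1))
  expect_equal(track$p_break, plogis(fw$breakpoint_logit[, 1L]))

  # arbitrary site counts, including non-multiples of L
  for (n in c(5L, 16L, 23L, 48L)) {
    pn <- random_panel(6L, n, seed = 100L + n)
    tn <- predict_pair(model, pn, c(2L, 3L))
    expect_length(tn$tmrca, n)
    expect_true(all(is.finite(tn$tmrca)))
    expect_true(all(tn$p_break >= 0 & tn$p_break <= 1))
    expect_true(all(tn$tmrca >= 1))
  }
})

test_that("threshold tuning returns the grid argmin with its curve", {
  cfg <- model_config(L = 16L, kernels = c(5L, 3L), channels = c(4L, 4L))
  model <- build_model(cfg, seed = 3L)
  ck <- structure(list(model = model), class = "tmrca_checkpoint")
  ds <- simulate_dataset(sim_config(n_haplotypes = 6L, region_length = 1e5,
                                    seed = 41L))
  expect_error(tune_threshold(ck, list(ds), grid = numeric(0)),
               class = "tmrcanet_config_error")
  single <- tune_threshold(ck, list(ds), grid = 0.5, pairs_per_dataset = 3L)
  expect_equal(as.numeric(single), 0.5)
  multi <- tune_threshold(ck, list(ds), grid = c(0.4, 0.6, 0.8),
                          pairs_per_dataset = 3L)
  curve <- attr(multi, "curve")
  expect_equal(min(curve$mae), curve$mae[curve$threshold == as.numeric(multi)])
})

test_that("BED export writes 0-based half-open intervals spanning the track", {
  tr <- list(tmrca = c(10, 20, 30, 40), p_break = c(0, 0, 0.9, 0),
             positions = c(100, 200, 300, 400), pair = c(1L, 2L), chrom = "1")
  seg <- make_piecewise(tr, 0.7)
  path <- tempfile(fileext = ".bed")
  write_segments_bed(seg, tr, path)
  bed <- read.table(path, sep = "\t")
  expect_identical(bed$V2, c(99L, 299L))
  expect_identical(bed$V3, c(299L, 400L))
  expect_identical(bed$V4, rep("1-2", 2L))
})
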