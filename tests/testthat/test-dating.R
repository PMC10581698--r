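make_pairset <- function(conc, disc, k = 2L) {
  structure(list(variant = 1L, concordant = conc, discordant = disc,
                 derived_count = k), class = "variant_pairset")
}

test_that("pair collection matches the closed-form pair counts", {
  ds <- cached_dataset()
  panel <- ds$panel
  n <- panel$n_haplotypes
  sites <- which(panel$derived_counts >= 2L & panel$derived_counts <= n - 2L)
  for (s in sites[seq_len(min(10L, length(sites)))]) {
    ps <- collect_pairs(panel, ds$labels, s)
    k <- panel$derived_counts[s]
    expect_length(ps$concordant, choose(k, 2))
    expect_length(ps$discordant, k * (n - k))
  }
  singleton <- which(panel$derived_counts == 1L)[1L]
  if (!is.na(singleton))
    expect_error(collect_pairs(panel, ds$labels, singleton),
                 class = "tmrcanet_singleton")
  # subsampling caps each side reproducibly
  s2 <- sites[which.max(panel$derived_counts[sites])]
  ps_a <- collect_pairs(panel, ds$labels, s2, max_pairs = 5L, seed = 3L)
  ps_b <- collect_pairs(panel, ds$labels, s2, max_pairs = 5L, seed = 3L)
  expect_lte(length(ps_a$concordant), 5L)
  expect_lte(length(ps_a$discordant), 5L)
  expect_identical(ps_a, ps_b)
})

test_that("outlier rejection reproduces the worked examples", {
  f0 <- reject_outliers(make_pairset(c(50, 80), c(120, 200)))
  expect_equal(f0$rejected_fraction, 0)
  expect_equal(f0$pairset$concordant, c(50, 80))
  expect_equal(f0$pairset$discordant, c(120, 200))

  f1 <- reject_outliers(make_pairset(c(100, 5000), c(300, 400)))
  expect_equal(f1$pairset$concordant, 100)
  expect_equal(f1$pairset$discordant, c(300, 400))
  expect_equal(f1$rejected_fraction, 1 / 4)

  # one rejection either way: tie broken to the smallest threshold
  f2 <- reject_outliers(make_pairset(10, 5))
  expect_equal(f2$rejected_fraction, 1 / 2)
  expect_equal(f2$threshold, 5)
  expect_true(f2$degenerate)   # the concordant side is emptied

  expect_error(reject_outliers(make_pairset(numeric(0), c(1, 2))), "non-empty")
})

test_that("outlier rejection equals an exhaustive scan over all real thresholds", {
  brute <- function(conc, disc) {
    obs <- sort(unique(c(conc, disc)))
    cand <- sort(unique(c(obs, obs - 1e-9, obs + 1e-9,
                          min(obs) - 1, max(obs) + 1,
                          (head(obs, -1) + tail(obs, -1)) / 2)))
    rej <- vapply(cand, function(t) sum(conc > t) + sum(disc < t), 0)
    min(rej)
  }
  for (s in 1:300) {
    set.seed(7000 + s)
    conc <- exp(rnorm(sample(1:50, 1), 7, 2))
    disc <- exp(rnorm(sample(1:50, 1), 8, 2))
    f <- reject_outliers(make_pairset(conc, disc))
    n_rej <- (length(conc) - length(f$pairset$concordant)) +
      (length(disc) - length(f$pairset$discordant))
    expect_identical(n_rej, as.integer(brute(conc, disc)))
    # the kept sets are exactly those implied by the returned threshold
    expect_equal(f$pairset$concordant, conc[conc <= f$threshold])
    expect_equal(f$pairset$discordant, disc[disc >= f$threshold])
  }
})

test_that("variant dating combines the filtered bounds", {
  e1 <- date_variant(make_pairset(80, c(120, 200)))
  expect_equal(e1$lower, 80)
  expect_equal(e1$upper, 120)
  expect_equal(e1$age, 100)
  expect_true(e1$consistent)

  e2 <- date_variant(make_pairset(c(100, 5000), c(300, 400)))
  expect_equal(e2$age, 200)
  expect_equal(e2$rejected_fraction, 1 / 4)

  # invariance to pair order and to duplicating every observation
  base <- make_pairset(c(40, 90, 70), c(150, 110, 300))
  shuf <- make_pairset(c(90, 70, 40), c(300, 150, 110))
  dup <- make_pairset(rep(c(40, 90, 70), 2), rep(c(150, 110, 300), 2))
  expect_equal(date_variant(base)[c("lower", "upper", "age")],
               date_variant(shuf)[c("lower", "upper", "age")])
  expect_equal(date_variant(base)[c("lower", "upper", "age", "rejected_fraction")],
               date_variant(dup)[c("lower", "upper", "age", "rejected_fraction")])
})

test_that("true TMRCAs from a recombination-free genealogy bound the mutation time", {
  cfg <- sim_config(n_haplotypes = 16L, region_length = 1.5e5,
                    recombination_rate = 0, seed = 61L)
  ds <- simulate_dataset(cfg, want_mut_times = TRUE)
  dt <- date_panel(ds$panel, ds$labels, seed = 2L)
  single <- ds$panel$n_mut[dt$site] == 1L
  expect_gt(sum(single), 0L)
  expect_true(all(dt$rejected_fraction[single] == 0))
  mt <- ds$panel$mut_time[dt$site]
  expect_true(all(mt[single] >= dt$lower[single] - 1e-9))
  expect_true(all(mt[single] <= dt$upper[single] + 1e-9))
})

test_that("group aggregation takes kept-pair-weighted bound averages", {
  ests <- list(list(lower = 100, upper = 300, n_concordant_kept = 2,
                    n_discordant_kept = 3),
               list(lower = 200, upper = 500, n_concordant_kept = 1,
                    n_discordant_kept = 1))
  agg <- aggregate_groups(ests)
  expect_equal(agg$lower, 400 / 3)
  expect_equal(agg$upper, 350)
  expect_equal(agg$age, (400 / 3 + 350) / 2)

  # single population: identity
  one <- aggregate_groups(ests[1L])
  expect_equal(one$lower, 100)
  expect_equal(one$upper, 300)
  expect_equal(one$age, 200)

  # zero weight on one side excludes that population from that side
  ests2 <- list(list(lower = 100, upper = 300, n_concordant_kept = 2,
                     n_discordant_kept = 0),
                list(lower = 900, upper = 500, n_concordant_kept = 1,
                     n_discordant_kept = 4))
  agg2 <- aggregate_groups(ests2)
  expect_equal(agg2$upper, 500)
  expect_equal(agg2$lower, (2 * 100 + 1 * 900) / 3)

  expect_error(aggregate_groups(list()), class = "tmrcanet_undatable")
})
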