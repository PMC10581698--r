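test_that("configuration invariants are enforced", {
  expect_error(sim_config(beta_alpha = 2.5), class = "tmrcanet_config_error")
  expect_error(sim_config(beta_alpha = 1.0), class = "tmrcanet_config_error")
  expect_error(sim_config(n_haplotypes = 7L), "even")
  expect_error(demographic_model(c(1, 2), c(1e4, 1e4)), "generation 0")
  expect_error(demographic_model(c(0, 0), c(1e4, 1e4)), "strictly increasing")
  expect_error(genetic_map(c(5, 1), c(0, 1)), "strictly increasing")
})

test_that("simulation is deterministic and labels tile the panel", {
  ds <- cached_dataset()
  ds2 <- simulate_dataset(sim_config(n_haplotypes = 10L, region_length = 3e5,
                                     seed = 11L),
                          pairs = "all", want_mut_times = TRUE)
  expect_identical(ds$panel$alleles, ds2$panel$alleles)
  expect_identical(ds$panel$positions, ds2$panel$positions)
  expect_identical(ds$labels, ds2$labels)
  expect_true(all(diff(ds$panel$positions) > 0))
  expect_true(all(ds$panel$derived_counts > 0 &
                  ds$panel$derived_counts < ds$panel$n_haplotypes))
  for (key in sample(names(ds$labels$segments), 5)) {
    seg <- ds$labels$segments[[key]]
    expect_identical(seg$starts[1L], 1L)
    expect_true(all(diff(seg$starts) > 0))
    expect_true(all(seg$tmrca > 0))
    expect_true(all(diff(seg$tmrca) != 0))
  }
  # breakpoint labels: site i is 1 iff the segment of i-1 and i differ
  tr <- tmrca_track(ds$labels, 3, 7)
  bp <- breakpoint_track(ds$labels, 3, 7)
  expect_identical(bp, c(0L, as.integer(diff(tr) != 0)))
})

test_that("no recombination yields a single segment and no breakpoints", {
  cfg <- sim_config(n_haplotypes = 8L, region_length = 2e5,
                    recombination_rate = 0, seed = 5L)
  ds <- simulate_dataset(cfg)
  for (seg in ds$labels$segments) expect_length(seg$starts, 1L)
  grid <- ds$labels$pairs
  for (r in seq_len(nrow(grid)))
    expect_identical(sum(breakpoint_track(ds$labels, grid[r, 1], grid[r, 2])), 0L)
})

test_that("neutral constant-size expectations hold across replicates", {
  # E[pi] = 4*Ne*mu per bp, E[S] = theta * a_{n-1} * L, E[pairwise TMRCA] = 2*Ne
  Ne <- 1e4; mu <- 1.65e-8; len <- 4e5; n_hap <- 10L
  n_rep <- 12L
  a_n <- sum(1 / seq_len(n_hap - 1L))
  pis <- s_counts <- mean_ts <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_haplotypes = n_hap, region_length = len,
                      mutation_rate = mu, seed = 100L + i)
    ds <- simulate_dataset(cfg, pairs = "none")
    s_counts[i] <- ds$panel$n_sites
    k <- ds$panel$derived_counts
    # mean pairwise difference per bp from the site frequency spectrum
    pis[i] <- sum(2 * k * (n_hap - k) / (n_hap * (n_hap - 1))) / len
    mt <- pairwise_mean_tmrca(cfg)
    mean_ts[i] <- mean(mt[upper.tri(mt)])
  }
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(pis) - 4 * Ne * mu), 4 * se(pis) + 0.05 * 4 * Ne * mu)
  expect_lt(abs(mean(s_counts) - 4 * Ne * mu * a_n * len),
            4 * se(s_counts) + 0.05 * 4 * Ne * mu * a_n * len)
  expect_lt(abs(mean(mean_ts) - 2 * Ne), 4 * se(mean_ts) + 0.05 * 2 * Ne)
})

test_that("error injection respects rates and preserves genotypes under switches", {
  ds <- cached_dataset()
  expect_identical(inject_errors(ds$panel, 0, 0), ds$panel)

  # forced flip on a tiny hand-built panel: every allele complemented
  p1 <- haplotype_panel(matrix(c(0L, 1L, 1L, 0L), ncol = 1L), 10, 0.1)
  f1 <- inject_errors(p1, 0, 1, seed = 2L)
  expect_identical(as.vector(f1$alleles), c(1L, 0L, 0L, 1L))

  # binomial check on ~1e5 allele calls
  big <- random_panel(20L, 5000L, seed = 8L)
  rate <- 0.01
  fe <- inject_errors(big, 0, rate, seed = 3L)
  keep <- attr(fe, "kept_sites")
  flipped <- mean(fe$alleles != big$alleles[, keep])
  n_calls <- length(big$alleles)
  expect_lt(abs(flipped - rate), 3 * sqrt(rate * (1 - rate) / n_calls) + 1e-4)

  # switch errors rephase but never change a diploid's unordered genotype
  sw <- inject_errors(big, 0.2, 0, seed = 9L)
  for (d in seq_len(10L)) {
    g_old <- pmin(big$alleles[2 * d - 1, ], big$alleles[2 * d, ]) * 10 +
      pmax(big$alleles[2 * d - 1, ], big$alleles[2 * d, ])
    g_new <- pmin(sw$alleles[2 * d - 1, ], sw$alleles[2 * d, ]) * 10 +
      pmax(sw$alleles[2 * d - 1, ], sw$alleles[2 * d, ])
    expect_identical(g_new, g_old)
  }
  expect_false(identical(sw$alleles, big$alleles))
  expect_error(inject_errors(haplotype_panel(matrix(c(0L, 1L, 1L), ncol = 1L),
                                             5, 0), 0.1, 0),
               class = "tmrcanet_config_error")
})

test_that("array ascertainment matches the target spectrum up to feasibility", {
  panel <- random_panel(20L, 800L, seed = 4L)
  maf <- pmin(panel$derived_counts, 20L - panel$derived_counts) / 20L

  # all mass on one bin: every retained site falls in it
  spec1 <- structure(c(0, 0, 0, 1, 0), edges = seq(0, 0.5, by = 0.1))
  a1 <- ascertain_array(panel, spec1, target_density = NULL, seed = 2L)
  maf1 <- pmin(a1$derived_counts, 20L - a1$derived_counts) / 20L
  expect_true(all(maf1 > 0.3 & maf1 <= 0.4))

  # half density: site count within rounding of half
  full_cm <- diff(range(panel$map_cM))
  dens <- panel$n_sites / full_cm
  uni <- structure(rep(0.2, 5), edges = seq(0, 0.5, by = 0.1))
  a2 <- suppressWarnings(ascertain_array(panel, uni, target_density = dens / 2,
                                         seed = 2L))
  expect_lt(abs(a2$n_sites - panel$n_sites / 2), 0.1 * panel$n_sites)
  expect_true(all(diff(attr(a2, "kept_sites")) > 0))   # order preserved

  # empty bin with positive mass warns and renormalizes
  only_rare <- panel
  expect_warning(
    ascertain_array(panel, structure(c(0.5, 0.5, 0, 0, 0),
                                     edges = c(0, 0.02, 0.04, 0.1, 0.3, 0.5)),
                    seed = 1L),
    "renormaliz")
})

test_that("gene conversion off reproduces the plain configuration exactly", {
  base <- sim_config(n_haplotypes = 8L, region_length = 2e5, seed = 31L)
  gc0 <- sim_config(n_haplotypes = 8L, region_length = 2e5, seed = 31L,
                    ncgc_rate = 0, ncgc_tract_length = 300)
  d1 <- simulate_dataset(base)
  d2 <- simulate_dataset(gc0)
  expect_identical(d1$panel$alleles, d2$panel$alleles)
  expect_identical(d1$labels, d2$labels)
})

test_that("gene conversion fragments the pairwise TMRCA labels", {
  # NCGC tracts change the local genealogy over short intervals, so at a
  # conversion rate well above the crossover rate the exact per-pair labels
  # carry many more segments. Paired by seed across configurations.
  n_rep <- 8L
  mean_segments <- function(ncgc_rate, seed) {
    cfg <- sim_config(n_haplotypes = 8L, region_length = 3e5, seed = seed,
                      ncgc_rate = ncgc_rate, ncgc_tract_length = 300)
    ds <- simulate_dataset(cfg)
    mean(vapply(ds$labels$segments, function(s) length(s$starts), 0L))
  }
  with_gc <- vapply(seq_len(n_rep), function(i) mean_segments(4e-8, 500L + i), 0)
  without <- vapply(seq_len(n_rep), function(i) mean_segments(0, 500L + i), 0)
  expect_true(all(with_gc > without))
})

test_that("empty regions signal an empty panel", {
  cfg <- sim_config(n_haplotypes = 4L, region_length = 200,
                    mutation_rate = 1e-12, seed = 3L)
  expect_warning(ds <- simulate_dataset(cfg), class = "tmrcanet_empty_panel")
  expect_identical(ds$panel$n_sites, 0L)
})
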