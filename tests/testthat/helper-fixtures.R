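# In-code fixtures: random panels and tracks built deterministically.

random_panel <- function(n_hap = 10L, n_sites = 50L, seed = 1L) {
  set.seed(seed)
  repeat {
    a <- matrix(rbinom(n_hap * n_sites, 1L, runif(1, 0.2, 0.5)),
                nrow = n_hap)
    dc <- colSums(a)
    if (all(dc > 0L & dc < n_hap)) break
  }
  pos <- sort(sample.int(n_sites * 50L, n_sites))
  cm <- cumsum(runif(n_sites, 0, 0.01))
  haplotype_panel(a, pos, cm)
}

random_track <- function(n = 200L, seed = 1L) {
  set.seed(seed)
  list(tmrca = exp(rnorm(n, 8, 1.5)), p_break = runif(n),
       positions = sort(sample.int(n * 100L, n)), pair = c(1L, 2L),
       chrom = "1")
}

# small simulated dataset cached across tests in one session
cached_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(
        sim_config(n_haplotypes = 10L, region_length = 3e5, seed = 11L),
        pairs = "all", want_mut_times = TRUE)
    cache
  }
})

desk_train_config <- function(epochs = 2L, ..., master_seed = 5L) {
  train_config(
    sim = sim_config(n_haplotypes = 8L, region_length = 4e5, seed = 1L),
    model = model_config(L = 64L, kernels = c(9L, 5L, 3L),
                         channels = c(8L, 8L, 8L)),
    epochs = epochs, sims_per_epoch = 4L, batch_size = 16L,
    validation_sims = 2L, master_seed = master_seed, ...)
}
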