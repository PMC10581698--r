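#' Simulation configuration
#'
#' Bundles everything needed to generate one coalescent training/validation/
#' test dataset: demography, recombination (constant rate or a [genetic_map()]),
#' mutation rate, sample size, region length, data modality, ascertainment
#' reference size, error rates, and optional Beta-coalescent multiple mergers
#' and non-crossover gene conversion (NCGC).
#'
#' Defaults reflect the benchmark conditions used throughout the package:
#' a constant diploid population of Ne = 10,000, mutation rate 1.65e-8 per bp
#' per generation and crossover rate 1e-8 per bp per generation.
#'
#' @param demographic_model a [demographic_model()].
#' @param recombination_rate constant crossover rate per bp per generation
#'   (ignored when `genetic_map` is given).
#' @param genetic_map optional [genetic_map()] for variable recombination.
#' @param mutation_rate per bp per generation.
#' @param n_haplotypes even number of phased haplotypes (2 per diploid).
#' @param region_length region length in bp.
#' @param modality `"sequencing"` or `"array"`.
#' @param polymorphism_reference_size diploid count: retained sites are those
#'   polymorphic in this many randomly chosen individuals (`NULL` = all
#'   simulated individuals).
#' @param switch_error_rate per-heterozygous-site phase switch probability.
#' @param genotyping_error_rate per-allele-call flip probability.
#' @param beta_alpha `NULL` for the Kingman coalescent, or alpha in (1, 2]
#'   for Beta-coalescent multiple mergers.
#' @param ncgc_rate non-crossover gene conversion initiation rate per bp per
#'   generation (0 disables NCGC).
#' @param ncgc_tract_length mean NCGC tract length in bp (geometric).
#' @param array_target_spectrum MAF-bin target densities for array
#'   ascertainment (`NULL` = bundled default spectrum).
#' @param array_target_density target sites per cM for array ascertainment
#'   (`NULL` = keep current density).
#' @param seed integer simulation seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(demographic_model = tmrcanet::demographic_model(0, 10000),
                       recombination_rate = 1e-8,
                       genetic_map = NULL,
                       mutation_rate = 1.65e-8,
                       n_haplotypes = 20L,
                       region_length = 1e6,
                       modality = c("sequencing", "array"),
                       polymorphism_reference_size = NULL,
                       switch_error_rate = 0,
                       genotyping_error_rate = 0,
                       beta_alpha = NULL,
                       ncgc_rate = 0,
                       ncgc_tract_length = 300,
                       array_target_spectrum = NULL,
                       array_target_density = NULL,
                       seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(inherits(demographic_model, "demographic_model"),
            region_length > 0, n_haplotypes >= 2)
  if (n_haplotypes %% 2 != 0) stop("n_haplotypes must be even (phased diploids)")
  assert_prob(switch_error_rate, "switch_error_rate")
  assert_prob(genotyping_error_rate, "genotyping_error_rate")
  if (!is.null(beta_alpha) && (beta_alpha <= 1 || beta_alpha > 2))
    stop_tmrcanet("beta_alpha must lie in (1, 2]", "tmrcanet_config_error")
  if (ncgc_rate < 0 || mutation_rate < 0 || recombination_rate < 0)
    stop("rates must be non-negative")
  structure(list(
    demographic_model = demographic_model,
    recombination_rate = recombination_rate,
    genetic_map = genetic_map,
    mutation_rate = mutation_rate,
    n_haplotypes = as.integer(n_haplotypes),
    region_length = region_length,
    modality = modality,
    polymorphism_reference_size = polymorphism_reference_size,
    switch_error_rate = switch_error_rate,
    genotyping_error_rate = genotyping_error_rate,
    beta_alpha = beta_alpha,
    ncgc_rate = ncgc_rate,
    ncgc_tract_length = ncgc_tract_length,
    array_target_spectrum = array_target_spectrum,
    array_target_density = array_target_density,
    seed = as.integer(seed)), class = "sim_config")
}

# backend sim spec for one simulation; `from` shifts the genetic-map window
backend_spec <- function(config, seed, pairs = "none", want_panel = TRUE,
                         want_divergence = FALSE, want_mut_times = FALSE,
                         save_trees = NULL, map_from = 0) {
  if (is.null(config$genetic_map)) {
    recomb <- list(rate = config$recombination_rate)
  } else {
    win <- map_window(config$genetic_map, map_from, config$region_length)
    recomb <- list(map = map_to_rates(win, config$region_length))
  }
  list(seed = seed,
       n_haplotypes = config$n_haplotypes,
       length = config$region_length,
       mutation_rate = config$mutation_rate,
       recombination = recomb,
       demography = list(times = config$demographic_model$times,
                         sizes = config$demographic_model$sizes),
       beta_alpha = config$beta_alpha,
       gc_rate = config$ncgc_rate,
       gc_tract = config$ncgc_tract_length,
       ref_subsample = config$polymorphism_reference_size,
       pairs = if (identical(pairs, "all") || identical(pairs, "none")) pairs
               else lapply(seq_len(nrow(pairs)),
                           function(i) c(pairs[i, 1L] - 1L, pairs[i, 2L] - 1L)),
       want_panel = want_panel,
       want_divergence = want_divergence,
       want_mut_times = want_mut_times,
       save_trees = save_trees)
}

panel_from_backend <- function(sim, config, map_from = 0) {
  pos <- as.numeric(unlist(sim$positions))
  n_sites <- length(pos)
  n_hap <- config$n_haplotypes
  if (n_sites == 0L) {
    alleles <- matrix(integer(0), nrow = n_hap, ncol = 0L)
  } else {
    alleles <- matrix(0L, nrow = n_hap, ncol = n_sites)
    for (i in seq_len(n_hap))
      alleles[i, ] <- as.integer(strsplit(sim$haplotypes[[i]], "")[[1L]])
  }
  if (is.null(config$genetic_map)) {
    cm <- (pos - 1) * config$recombination_rate * 1e8 / 1e6
  } else {
    win <- map_window(config$genetic_map, map_from, config$region_length)
    cm <- interp_cM(win, pos)
  }
  mt <- if (!is.null(sim$mut_time))
    vapply(sim$mut_time, function(x) if (is.null(x)) NA_real_ else x, 0) else NULL
  haplotype_panel(alleles, pos, cm,
                  mut_time = mt,
                  n_mut = if (!is.null(sim$n_mut)) as.integer(unlist(sim$n_mut)) else NULL)
}

#' Phased haplotype panel
#'
#' A phased 0/1 derived-allele matrix with physical (bp) and genetic (cM)
#' site coordinates. Haplotypes `2i - 1` and `2i` form diploid individual `i`.
#'
#' @param alleles n_haplotypes x n_sites integer 0/1 matrix (1 = derived).
#' @param positions bp positions per site, strictly increasing, 1-based.
#' @param map_cM genetic map position per site in cM.
#' @param mut_time optional true mutation ages (generations; NA where the
#'   site carries more than one mutation).
#' @param n_mut optional number of mutations overlaid per site.
#' @param chrom chromosome label used in exports.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, positions, map_cM,
                            mut_time = NULL, n_mut = NULL, chrom = "1") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_sites <- ncol(alleles)
  stopifnot(length(positions) == n_sites, length(map_cM) == n_sites)
  if (n_sites > 1 && any(diff(positions) <= 0))
    stop("site positions must be strictly increasing")
  dc <- if (n_sites) colSums(alleles) else integer(0)
  if (n_sites && any(dc == 0L | dc == nrow(alleles)))
    stop("panel contains monomorphic sites")
  structure(list(alleles = alleles,
                 positions = as.numeric(positions),
                 map_cM = as.numeric(map_cM),
                 derived_counts = as.integer(dc),
                 n_haplotypes = nrow(alleles),
                 n_sites = n_sites,
                 mut_time = mut_time,
                 n_mut = n_mut,
                 chrom = chrom), class = "haplotype_panel")
}

#' @exportS3Method base::print
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d sites, %.3g-%.3g bp (%.3g cM)\n",
              x$n_haplotypes, x$n_sites,
              if (x$n_sites) x$positions[1L] else NA,
              if (x$n_sites) x$positions[x$n_sites] else NA,
              if (x$n_sites) diff(range(x$map_cM)) else 0))
  invisible(x)
}

# subset sites of a panel, keeping truth side-cars aligned
panel_subset <- function(panel, keep) {
  haplotype_panel(panel$alleles[, keep, drop = FALSE],
                  panel$positions[keep], panel$map_cM[keep],
                  mut_time = panel$mut_time[keep],
                  n_mut = panel$n_mut[keep],
                  chrom = panel$chrom)
}

labels_from_backend <- function(sim_labels, positions, n_sites) {
  segs <- list()
  pairs <- matrix(integer(0), 0L, 2L)
  pos0 <- positions - 1          # backend breaks are 0-based bp
  for (lab in sim_labels) {
    h1 <- lab$h1 + 1L; h2 <- lab$h2 + 1L
    breaks <- as.numeric(unlist(lab$breaks))
    tm <- as.numeric(unlist(lab$tmrcas))
    if (n_sites > 0L) {
      site_seg <- findInterval(pos0, breaks)      # >= 1 since breaks[1] = 0
      track <- tm[site_seg]
      starts <- c(1L, which(diff(track) != 0) + 1L)
      segs[[pair_key(h1, h2)]] <- list(starts = starts, tmrca = track[starts])
    } else {
      segs[[pair_key(h1, h2)]] <- list(starts = integer(0), tmrca = numeric(0))
    }
    pairs <- rbind(pairs, c(h1, h2))
  }
  true_labels(pairs, segs, n_sites)
}

#' Ground-truth pairwise TMRCA labels
#'
#' Per-pair piecewise-constant TMRCA along the panel's retained sites,
#' extracted exactly from the simulated genealogy. Segments are stored as
#' 1-based start sites plus the constant TMRCA value; segments tile
#' `[1, n_sites]`. Breakpoint labels follow the convention that site `i`
#' carries a breakpoint iff the TMRCA segment of sites `i - 1` and `i`
#' differ (the first site is never a breakpoint).
#'
#' @param pairs two-column matrix of haplotype indices (1-based, h1 < h2).
#' @param segments named list keyed `"h1-h2"`, each with `starts` and `tmrca`.
#' @param n_sites number of panel sites the labels tile.
#' @export
true_labels <- function(pairs, segments, n_sites) {
  structure(list(pairs = pairs, segments = segments,
                 n_sites = as.integer(n_sites)),
            class = "true_labels")
}

#' @exportS3Method base::print
print.true_labels <- function(x, ...) {
  cat(sprintf("true_labels: %d pair(s) over %d sites\n", nrow(x$pairs), x$n_sites))
  invisible(x)
}

#' Per-site true TMRCA track for one pair
#' @param labels a [true_labels()] object.
#' @param h1,h2 haplotype indices (1-based).
#' @return Numeric vector of length `n_sites`.
#' @export
tmrca_track <- function(labels, h1, h2) {
  seg <- labels$segments[[pair_key(h1, h2)]]
  if (is.null(seg)) stop("no labels recorded for pair ", pair_key(h1, h2))
  if (labels$n_sites == 0L) return(numeric(0))
  ends <- c(seg$starts[-1L] - 1L, labels$n_sites)
  rep(seg$tmrca, ends - seg$starts + 1L)
}

#' Per-site breakpoint indicator track for one pair
#' @inheritParams tmrca_track
#' @return Integer 0/1 vector of length `n_sites`.
#' @export
breakpoint_track <- function(labels, h1, h2) {
  seg <- labels$segments[[pair_key(h1, h2)]]
  if (is.null(seg)) stop("no labels recorded for pair ", pair_key(h1, h2))
  out <- integer(labels$n_sites)
  st <- seg$starts[seg$starts > 1L]
  out[st] <- 1L
  out
}

# restrict labels to a subset of sites (e.g. after array ascertainment)
labels_subset <- function(labels, keep) {
  segs <- lapply(labels$segments, function(seg) {
    ends <- c(seg$starts[-1L] - 1L, labels$n_sites)
    track <- rep(seg$tmrca, ends - seg$starts + 1L)[keep]
    if (length(track) == 0L) return(list(starts = integer(0), tmrca = numeric(0)))
    starts <- c(1L, which(diff(track) != 0) + 1L)
    list(starts = starts, tmrca = track[starts])
  })
  true_labels(labels$pairs, segs, length(keep))
}

#' Simulate a dataset with exact genealogical ground truth
#'
#' Runs one coalescent-with-recombination realization under the given
#' configuration, overlays mutations, applies the modality's site
#' ascertainment, and extracts per-pair piecewise TMRCA labels from the
#' genealogy. Labels describe the true genealogy and are therefore immune to
#' the error injection applied to the returned panel.
#'
#' Order of operations: sequencing-polymorphism filter (backend), array
#' ascertainment (when `modality = "array"`), label extraction on the final
#' site set, then phasing/genotyping error injection on the panel only.
#'
#' @param config a [sim_config()].
#' @param pairs `"all"`, or a two-column matrix of 1-based haplotype index
#'   pairs to label, or `"none"`.
#' @param want_mut_times also record true mutation ages per site.
#' @return A list with elements `panel` ([haplotype_panel()]) and `labels`
#'   ([true_labels()]).
#' @export
simulate_dataset <- function(config, pairs = "all", want_mut_times = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.matrix(pairs)) {
    stopifnot(ncol(pairs) == 2L)
    pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  }
  res <- run_backend(list(mode = "simulate",
                          sims = list(backend_spec(config, config$seed,
                                                   pairs = pairs,
                                                   want_mut_times = want_mut_times))))
  sim <- res$sims[[1L]]
  panel <- panel_from_backend(sim, config)
  if (panel$n_sites == 0L)
    warning(structure(class = c("tmrcanet_empty_panel", "warning", "condition"),
                      list(message = "degenerate region: no polymorphic sites retained",
                           call = NULL)))
  if (config$modality == "array" && panel$n_sites > 0L) {
    asc <- ascertain_array(panel,
                           target_spectrum = config$array_target_spectrum,
                           target_density = config$array_target_density,
                           seed = derive_seed(config$seed, "ascertain"))
    keep <- attr(asc, "kept_sites")
    panel <- asc
  } else {
    keep <- seq_len(panel$n_sites)
  }
  labels <- if (!identical(pairs, "none") && !is.null(sim$labels)) {
    full <- labels_from_backend(sim$labels,
                                positions = as.numeric(unlist(sim$positions)),
                                n_sites = length(unlist(sim$positions)))
    labels_subset(full, keep)
  } else NULL
  if (config$switch_error_rate > 0 || config$genotyping_error_rate > 0)
    panel <- inject_errors(panel, config$switch_error_rate,
                           config$genotyping_error_rate,
                           seed = derive_seed(config$seed, "errors"))
  list(panel = panel, labels = labels)
}

#' Span-weighted mean pairwise TMRCA matrix for a configuration
#'
#' Simulates the genealogy only (no mutations needed) and returns, for every
#' unordered haplotype pair, the genomic-span-weighted mean TMRCA in
#' generations. This is the relatedness summary used for pair sampling and
#' validation ranking.
#'
#' @param config a [sim_config()].
#' @param seed optional seed override.
#' @return A symmetric `n_haplotypes` x `n_haplotypes` matrix (diagonal 0).
#' @export
pairwise_mean_tmrca <- function(config, seed = NULL) {
  spec <- backend_spec(config, seed %||% config$seed, pairs = "none",
                       want_panel = FALSE, want_divergence = TRUE)
  spec$mutation_rate <- 0
  res <- run_backend(list(mode = "simulate", sims = list(spec)))
  flat <- as.numeric(unlist(res$sims[[1L]]$mean_tmrca))
  n <- config$n_haplotypes
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- NA
  grid <- pair_grid(n)
  for (k in seq_len(nrow(grid))) {
    m[grid[k, 1L], grid[k, 2L]] <- flat[k]
    m[grid[k, 2L], grid[k, 1L]] <- flat[k]
  }
  m
}

#' Inject phasing switch errors and genotyping errors
#'
#' Switch errors swap the two haplotypes of each diploid from a heterozygous
#' site onward; switch events occur independently at each heterozygous site
#' with probability `switch_rate`, so the swapped state persists until the
#' next switch. Genotyping errors flip individual allele calls independently
#' with probability `genotyping_rate`. Ground-truth labels are untouched by
#' construction (they live on the genealogy, not the calls). Sites that
#' become monomorphic after error injection are dropped from the panel.
#'
#' @param panel a [haplotype_panel()].
#' @param switch_rate per-heterozygous-site switch probability.
#' @param genotyping_rate per-allele-call flip probability.
#' @param seed integer seed.
#' @return A new [haplotype_panel()] (attribute `kept_sites` maps its sites
#'   back to the input panel's site indices).
#' @export
inject_errors <- function(panel, switch_rate, genotyping_rate, seed = 1L) {
  assert_prob(switch_rate, "switch_rate")
  assert_prob(genotyping_rate, "genotyping_rate")
  if (switch_rate > 0 && panel$n_haplotypes %% 2 != 0)
    stop_tmrcanet("switch errors need haplotypes paired into diploids (even count)",
                  "tmrcanet_config_error")
  if (switch_rate == 0 && genotyping_rate == 0) return(panel)
  a <- panel$alleles
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  if (switch_rate > 0 && panel$n_sites > 0) {
    for (d in seq_len(panel$n_haplotypes %/% 2L)) {
      i <- 2L * d - 1L; j <- 2L * d
      het <- which(a[i, ] != a[j, ])
      if (!length(het)) next
      sw <- stats::rbinom(length(het), 1L, switch_rate)
      if (!any(sw == 1L)) next
      parity <- integer(panel$n_sites)
      parity[het] <- sw
      parity <- cumsum(parity) %% 2L
      flip <- parity == 1L
      tmp <- a[i, flip]; a[i, flip] <- a[j, flip]; a[j, flip] <- tmp
    }
  }
  if (genotyping_rate > 0 && panel$n_sites > 0) {
    flips <- matrix(stats::rbinom(length(a), 1L, genotyping_rate),
                    nrow = nrow(a))
    a <- abs(a - flips)
  }
  dc <- colSums(a)
  keep <- which(dc > 0L & dc < nrow(a))
  out <- haplotype_panel(a[, keep, drop = FALSE],
                         panel$positions[keep], panel$map_cM[keep],
                         mut_time = panel$mut_time[keep],
                         n_mut = panel$n_mut[keep], chrom = panel$chrom)
  attr(out, "kept_sites") <- keep
  out
}

#' Default SNP-array target frequency spectrum
#'
#' A synthetic stand-in for a genotyping-array minor-allele-frequency
#' spectrum: 10 equal-width MAF bins on (0, 0.5] with mass shifted toward
#' common variants, mimicking the flat-by-design site selection of
#' commercial arrays. Override with any measured spectrum.
#'
#' @return Numeric vector of 10 bin masses summing to 1, with bin edges as
#'   attribute `edges`.
#' @export
default_array_spectrum <- function() {
  path <- system.file("extdata", "array_maf_spectrum_synthetic.tsv",
                      package = "tmrcanet")
  tab <- utils::read.table(path, header = TRUE)
  structure(tab$mass / sum(tab$mass), edges = c(tab$lower[1L], tab$upper))
}

site_maf <- function(panel) {
  pmin(panel$derived_counts, panel$n_haplotypes - panel$derived_counts) /
    panel$n_haplotypes
}

#' Ascertain array-like sites by target MAF spectrum and density
#'
#' Subsamples panel sites so that the retained sites' MAF histogram matches
#' the target bin masses (up to feasibility: a bin cannot contribute more
#' sites than it has) and the overall density approximates
#' `target_density` sites per cM. Site order is preserved. Target mass
#' falling on bins with no available sites is redistributed proportionally
#' over the non-empty bins, with a warning.
#'
#' @param panel a [haplotype_panel()].
#' @param target_spectrum bin masses summing to 1, with `edges` attribute
#'   (default: [default_array_spectrum()]).
#' @param target_density sites per cM (`NULL` keeps the input site count).
#' @param seed integer seed for the within-bin subsampling.
#' @return A new [haplotype_panel()] with attribute `kept_sites` (indices
#'   into the input panel).
#' @export
ascertain_array <- function(panel, target_spectrum = NULL,
                            target_density = NULL, seed = 1L) {
  spectrum <- target_spectrum %||% default_array_spectrum()
  edges <- attr(spectrum, "edges") %||%
    seq(0, 0.5, length.out = length(spectrum) + 1L)
  if (abs(sum(spectrum) - 1) > 1e-8)
    stop("target spectrum must sum to 1 over bins")
  maf <- site_maf(panel)
  bin <- findInterval(maf, edges, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin < 1L] <- 1L
  avail <- tabulate(bin, nbins = length(spectrum))
  mass <- as.numeric(spectrum)
  if (any(mass > 0 & avail == 0L)) {
    warning("target mass on empty MAF bins; renormalizing over non-empty bins")
    mass[avail == 0L] <- 0
    if (sum(mass) == 0) mass[avail > 0L] <- 1   # all mass was infeasible
    mass <- mass / sum(mass)
  }
  cm_span <- if (panel$n_sites > 1) diff(range(panel$map_cM)) else 0
  n_target <- if (is.null(target_density)) panel$n_sites
              else round(target_density * cm_span)
  n_target <- max(1L, min(n_target, panel$n_sites))
  # allocate per-bin counts by mass, redistributing infeasible remainders so
  # the density target is met whenever enough sites exist overall
  want <- pmin(round(mass * n_target), avail)
  repeat {
    deficit <- n_target - sum(want)
    open <- which(want < avail & mass > 0)
    if (deficit <= 0L || length(open) == 0L) break
    extra <- pmin(avail[open] - want[open],
                  pmax(1L, round(mass[open] / sum(mass[open]) * deficit)))
    want[open] <- want[open] + extra
    if (sum(want) >= n_target) {
      over <- sum(want) - n_target
      for (b in rev(open)) {
        cut <- min(over, want[b])
        want[b] <- want[b] - cut
        over <- over - cut
        if (over == 0L) break
      }
      break
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  keep <- integer(0)
  for (b in seq_along(mass)) {
    if (want[b] == 0L) next
    cand <- which(bin == b)
    keep <- c(keep, if (length(cand) == want[b]) cand
                    else sample(cand, want[b]))
  }
  keep <- sort(keep)
  out <- panel_subset(panel, keep)
  attr(out, "kept_sites") <- keep
  out
}
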