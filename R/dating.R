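# Allele-age dating from pairwise TMRCAs.
#
# For a focal variant, concordant pairs (both haplotypes carry the derived
# allele) coalesce below the mutation, so the maximum concordant TMRCA is a
# lower bound on the allele age; discordant pairs (exactly one carrier)
# coalesce above it, so the minimum discordant TMRCA is an upper bound.
# Noisy TMRCA estimates can invert the bounds, so outlier pairs are first
# rejected by the threshold that minimizes the total number of rejections.

#' Collect concordant/discordant pair TMRCAs for one variant
#'
#' @param panel a [haplotype_panel()].
#' @param tmrca_source a [true_labels()] object covering all needed pairs,
#'   or a named list keyed `"h1-h2"` of per-site TMRCA tracks or
#'   `tmrca_track`/`piecewise_tmrca` objects.
#' @param variant 1-based site index of the focal variant.
#' @param max_pairs cap per side; beyond it pairs are subsampled uniformly
#'   (seeded). Bounds the quadratic growth in sample size.
#' @param seed subsampling seed.
#' @return A `variant_pairset`: lists of concordant and discordant TMRCAs at
#'   the variant's site, plus the derived count.
#' @export
collect_pairs <- function(panel, tmrca_source, variant, max_pairs = 10000L,
                          seed = 1L) {
  stopifnot(variant >= 1L, variant <= panel$n_sites)
  carriers <- which(panel$alleles[, variant] == 1L)
  k <- length(carriers)
  if (k < 2L)
    stop_tmrcanet("undatable: singleton (derived allele carried by a single haplotype)",
                  "tmrcanet_singleton")
  noncarriers <- setdiff(seq_len(panel$n_haplotypes), carriers)
  conc <- if (k >= 2L) t(utils::combn(carriers, 2L)) else matrix(0L, 0L, 2L)
  disc <- as.matrix(expand.grid(h1 = carriers, h2 = noncarriers))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  if (nrow(conc) > max_pairs) conc <- conc[sample.int(nrow(conc), max_pairs), , drop = FALSE]
  if (nrow(disc) > max_pairs) disc <- disc[sample.int(nrow(disc), max_pairs), , drop = FALSE]
  get_t <- make_tmrca_getter(tmrca_source)
  structure(list(
    variant = variant,
    concordant = vapply(seq_len(nrow(conc)),
                        function(i) get_t(conc[i, 1L], conc[i, 2L], variant), 0),
    discordant = vapply(seq_len(nrow(disc)),
                        function(i) get_t(disc[i, 1L], disc[i, 2L], variant), 0),
    derived_count = k), class = "variant_pairset")
}

make_tmrca_getter <- function(source) {
  if (inherits(source, "true_labels")) {
    cache <- new.env(parent = emptyenv())
    function(h1, h2, site) {
      key <- pair_key(h1, h2)
      tr <- cache[[key]]
      if (is.null(tr)) {
        tr <- tmrca_track(source, h1, h2)
        cache[[key]] <- tr
      }
      tr[site]
    }
  } else if (is.list(source)) {
    function(h1, h2, site) {
      el <- source[[pair_key(h1, h2)]]
      if (is.null(el)) stop("tmrca source missing pair ", pair_key(h1, h2))
      if (inherits(el, "piecewise_tmrca")) piecewise_track(el)[site]
      else if (is.list(el)) el$tmrca[site]
      else el[site]
    }
  } else stop("unsupported tmrca source")
}

#' Reject outlier pair TMRCAs for dating
#'
#' Scans candidate thresholds (the observed TMRCA values; the rejection
#' count is piecewise constant between observations, so these suffice) and
#' keeps the threshold minimizing the number of rejected pairs, where a
#' concordant pair is rejected if strictly above the threshold and a
#' discordant pair if strictly below it. Ties break to the smallest
#' rejected fraction, then the smallest threshold.
#'
#' @param pairset a `variant_pairset` with both sides non-empty.
#' @return List with the filtered `pairset`, the `threshold`,
#'   `rejected_fraction`, and `degenerate` (TRUE when a side was emptied).
#' @export
reject_outliers <- function(pairset) {
  conc <- pairset$concordant
  disc <- pairset$discordant
  if (length(conc) == 0L || length(disc) == 0L)
    stop("both concordant and discordant lists must be non-empty")
  cand <- sort(unique(c(conc, disc)))
  rej <- vapply(cand, function(t) sum(conc > t) + sum(disc < t), 0)
  best <- which(rej == min(rej))[1L]       # candidates sorted: first = smallest
  thr <- cand[best]
  kept <- pairset
  kept$concordant <- conc[conc <= thr]
  kept$discordant <- disc[disc >= thr]
  n_tot <- length(conc) + length(disc)
  list(pairset = kept, threshold = thr,
       rejected_fraction = rej[best] / n_tot,
       degenerate = length(kept$concordant) == 0L || length(kept$discordant) == 0L)
}

#' Date one variant from its pair TMRCAs
#'
#' Applies [reject_outliers()], then takes the lower bound `tc` as the
#' maximum surviving concordant TMRCA, the upper bound `td` as the minimum
#' surviving discordant TMRCA, and the point age as their midpoint. When
#' filtering empties one side, the estimate comes from the surviving side
#' alone and is flagged degenerate; when the surviving bounds still invert
#' (`tc > td`, possible under noise), the midpoint is reported with
#' `consistent = FALSE`.
#'
#' @param pairset a `variant_pairset`.
#' @return An `allele_age` list: `lower` (tc), `upper` (td), `age`,
#'   `rejected_fraction`, `n_concordant_kept`, `n_discordant_kept`,
#'   `degenerate`, `consistent`.
#' @export
date_variant <- function(pairset) {
  f <- reject_outliers(pairset)
  kc <- f$pairset$concordant
  kd <- f$pairset$discordant
  tc <- if (length(kc)) max(kc) else NA_real_
  td <- if (length(kd)) min(kd) else NA_real_
  age <- mean(c(tc, td), na.rm = TRUE)
  structure(list(variant = pairset$variant,
                 derived_count = pairset$derived_count,
                 lower = tc, upper = td, age = age,
                 rejected_fraction = f$rejected_fraction,
                 threshold = f$threshold,
                 n_concordant_kept = length(kc),
                 n_discordant_kept = length(kd),
                 degenerate = f$degenerate,
                 consistent = !is.na(tc) && !is.na(td) && tc <= td),
            class = "allele_age")
}

#' Date every non-singleton variant of a panel
#'
#' Convenience wrapper running [collect_pairs()] and [date_variant()] across
#' all sites. Singletons are undatable (no concordant pair exists) and are
#' skipped, as are variants flagged as lacking a confident ancestral state.
#'
#' @param panel a [haplotype_panel()].
#' @param tmrca_source see [collect_pairs()].
#' @param max_pairs,seed see [collect_pairs()].
#' @param undatable optional logical vector marking sites to skip (e.g.
#'   missing ancestral-state calls from [read_panel()]).
#' @return A data.frame with one row per dated variant: site, pos,
#'   derived_count, lower (tc), upper (td), age, rejected_fraction, kept
#'   pair counts and flags.
#' @export
date_panel <- function(panel, tmrca_source, max_pairs = 10000L, seed = 1L,
                       undatable = NULL) {
  rows <- list()
  for (s in seq_len(panel$n_sites)) {
    if (!is.null(undatable) && undatable[s]) next
    if (panel$derived_counts[s] < 2L) next
    ps <- collect_pairs(panel, tmrca_source, s, max_pairs = max_pairs,
                        seed = derive_seed(seed, sprintf("date/site%d", s)))
    est <- date_variant(ps)
    rows[[length(rows) + 1L]] <- data.frame(
      site = s, pos = panel$positions[s],
      derived_count = est$derived_count,
      lower = est$lower, upper = est$upper, age = est$age,
      rejected_fraction = est$rejected_fraction,
      n_concordant_kept = est$n_concordant_kept,
      n_discordant_kept = est$n_discordant_kept,
      degenerate = est$degenerate, consistent = est$consistent)
  }
  do.call(rbind, rows) %||% data.frame()
}

#' Aggregate allele-age estimates across population groups
#'
#' Combines per-population estimates for the same variant: the lower bounds
#' are averaged weighted by each population's surviving concordant pair
#' count, the upper bounds weighted by the surviving discordant counts, and
#' the age is the mean of the two weighted averages. Populations with zero
#' weight on a side are excluded from that side's average.
#'
#' @param estimates list of `allele_age` objects (or rows of
#'   [date_panel()] output) for one variant across populations.
#' @return An `allele_age` with aggregated bounds and age.
#' @export
aggregate_groups <- function(estimates) {
  if (length(estimates) == 0L)
    stop_tmrcanet("variant datable in no population", "tmrcanet_undatable")
  lows <- vapply(estimates, function(e) e$lower %||% NA_real_, 0)
  ups <- vapply(estimates, function(e) e$upper %||% NA_real_, 0)
  wc <- vapply(estimates, function(e) e$n_concordant_kept %||% 0, 0)
  wd <- vapply(estimates, function(e) e$n_discordant_kept %||% 0, 0)
  okl <- wc > 0 & !is.na(lows)
  oku <- wd > 0 & !is.na(ups)
  if (!any(okl) && !any(oku))
    stop_tmrcanet("variant datable in no population", "tmrcanet_undatable")
  lower <- if (any(okl)) sum(wc[okl] * lows[okl]) / sum(wc[okl]) else NA_real_
  upper <- if (any(oku)) sum(wd[oku] * ups[oku]) / sum(wd[oku]) else NA_real_
  structure(list(lower = lower, upper = upper,
                 age = mean(c(lower, upper), na.rm = TRUE),
                 n_concordant_kept = sum(wc[okl]),
                 n_discordant_kept = sum(wd[oku]),
                 rejected_fraction = NA_real_,
                 degenerate = !any(okl) || !any(oku),
                 consistent = !any(okl) || !any(oku) ||
                   (lower <= upper)), class = "allele_age")
}

#' Write a dating table as TSV
#'
#' Columns: chrom, pos (1-based), derived count, tc, td, age (generations),
#' rejected fraction and kept pair counts.
#'
#' @param dating result of [date_panel()].
#' @param panel the panel it was computed on.
#' @param path output file.
#' @export
write_dating_tsv <- function(dating, panel, path) {
  tab <- cbind(chrom = panel$chrom, dating)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
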