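# Postprocessing: stitch window predictions into a full-chromosome per-site
# track and refine it into a piecewise-constant TMRCA function using the
# predicted breakpoint probabilities.

#' Predict the per-site TMRCA track for one haplotype pair
#'
#' Tiles the panel with windows of stride `L` (each providing its `L`
#' central sites, with `context` sites of overlap supplied on each side and
#' edge padding at the chromosome ends), so every site is predicted exactly
#' once from the window in which it is central.
#'
#' @param checkpoint a `tmrca_checkpoint` (or bare `tmrca_model`).
#' @param panel a [haplotype_panel()].
#' @param pair length-2 haplotype index vector.
#' @param channels feature representation (must match the model's input).
#' @return A `tmrca_track`: list with per-site `tmrca` (generations,
#'   floored at 1) and `p_break` (breakpoint probability).
#' @export
predict_pair <- function(checkpoint, panel, pair, channels = "logic") {
  model <- if (inherits(checkpoint, "tmrca_checkpoint")) checkpoint$model
           else checkpoint
  stopifnot(inherits(model, "tmrca_model"))
  cfg <- model$config
  window <- model_window(cfg)
  n <- panel$n_sites
  if (n == 0L) stop("cannot predict on an empty panel")
  tracks <- pair_tracks(panel, pair[1L], pair[2L], channels)
  tm <- numeric(n)
  pb <- numeric(n)
  for (s in seq(1L, n, by = cfg$L)) {
    x <- window_tracks(tracks, s - cfg$context, cfg$L1)
    fw <- forward(model, x, training = FALSE)
    take <- min(cfg$L, n - s + 1L)
    tm[s:(s + take - 1L)] <- fw$log_tmrca[seq_len(take), 1L]
    pb[s:(s + take - 1L)] <- fw$breakpoint_logit[seq_len(take), 1L]
  }
  structure(list(tmrca = pmax(exp(tm), 1), p_break = stats::plogis(pb),
                 positions = panel$positions, pair = pair,
                 chrom = panel$chrom),
            class = "tmrca_track")
}

#' Refine a raw track into a piecewise-constant TMRCA function
#'
#' Sites whose predicted breakpoint probability strictly exceeds the
#' threshold open a new segment at that site (the boundary falls between the
#' site and its predecessor); each segment's value is the arithmetic mean of
#' the raw per-site TMRCAs it spans. The site-weighted mean of the result
#' equals the raw track mean exactly, and lowering the threshold only ever
#' splits segments (the segmentations are nested across thresholds).
#'
#' @param track a `tmrca_track` (or any list with `tmrca` and `p_break`).
#' @param threshold breakpoint probability threshold in (0, 1). The tuned
#'   defaults are 0.7 for sequencing data and 0.55 for array data.
#' @return A `piecewise_tmrca`: data.frame with `start`, `end` (1-based,
#'   inclusive site indices) and `tmrca`.
#' @export
make_piecewise <- function(track, threshold = 0.7) {
  stopifnot(threshold > 0, threshold < 1)
  p <- track$p_break
  v <- track$tmrca
  n <- length(v)
  starts <- c(1L, which(p > threshold & seq_along(p) > 1L))
  starts <- sort(unique(starts))
  ends <- c(starts[-1L] - 1L, n)
  seg <- data.frame(start = starts, end = ends,
                    tmrca = vapply(seq_along(starts), function(i)
                      mean(v[starts[i]:ends[i]]), 0))
  class(seg) <- c("piecewise_tmrca", "data.frame")
  attr(seg, "threshold") <- threshold
  seg
}

# per-site expansion of a piecewise_tmrca
piecewise_track <- function(seg) {
  rep(seg$tmrca, seg$end - seg$start + 1L)
}

#' Tune the breakpoint probability threshold on labelled held-out data
#'
#' Grid-searches the threshold minimizing the mean absolute error (in
#' generations) of the piecewise-constant output against the true per-site
#' TMRCA, across all supplied datasets and pairs.
#'
#' @param checkpoint a `tmrca_checkpoint`.
#' @param datasets list of `list(panel =, labels =)` held-out simulations
#'   (as returned by [simulate_dataset()]).
#' @param grid candidate thresholds.
#' @param pairs_per_dataset cap on pairs evaluated per dataset.
#' @param channels feature representation.
#' @return The grid value with minimum MAE (ties to the smaller threshold),
#'   with the full grid curve as attribute `curve`.
#' @export
tune_threshold <- function(checkpoint, datasets, grid = seq(0.3, 0.9, by = 0.05),
                           pairs_per_dataset = 10L, channels = "logic") {
  if (length(grid) == 0L)
    stop_tmrcanet("empty threshold grid", "tmrcanet_config_error")
  err <- numeric(length(grid))
  n_tot <- 0L
  for (ds in datasets) {
    pr <- ds$labels$pairs
    take <- seq_len(min(nrow(pr), pairs_per_dataset))
    for (r in take) {
      pair <- pr[r, ]
      truth <- tmrca_track(ds$labels, pair[1L], pair[2L])
      track <- predict_pair(checkpoint, ds$panel, pair, channels)
      for (gi in seq_along(grid)) {
        seg <- make_piecewise(track, grid[gi])
        err[gi] <- err[gi] + sum(abs(piecewise_track(seg) - truth))
      }
      n_tot <- n_tot + length(truth)
    }
  }
  mae <- err / n_tot
  best <- grid[which.min(mae)]
  structure(best, curve = data.frame(threshold = grid, mae = mae))
}

#' Write piecewise segments as a BED-like TSV
#'
#' Columns: chrom, start, end (0-based half-open bp, spanning from each
#' boundary site's position to the next boundary's), pair id, segment TMRCA,
#' mean breakpoint probability over the segment's sites.
#'
#' @param seg a `piecewise_tmrca`.
#' @param track the `tmrca_track` it was derived from.
#' @param path output file.
#' @export
write_segments_bed <- function(seg, track, path) {
  pos <- track$positions
  n <- length(pos)
  start_bp <- pos[seg$start] - 1
  end_bp <- c(pos[seg$start[-1L]] - 1, pos[n])
  pair_id <- paste(track$pair, collapse = "-")
  mean_p <- vapply(seq_len(nrow(seg)), function(i)
    mean(track$p_break[seg$start[i]:seg$end[i]]), 0)
  tab <- data.frame(chrom = track$chrom, start = format(start_bp, scientific = FALSE, trim = TRUE),
                    end = format(end_bp, scientific = FALSE, trim = TRUE),
                    pair = pair_id, tmrca = seg$tmrca, mean_p_break = mean_p)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
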