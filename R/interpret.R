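# Interpretability: saliency maps (input x gradient against the normalized
# input), MAF perturbation probes, and probing of first-block channels for
# the XOR/AND logic functions.

#' Saliency map for one target site
#'
#' Performs a forward pass in evaluation mode, rescales the predicted
#' log-TMRCA at the target site by `rescale` (1e6 by default, which avoids
#' vanishing gradients without reweighting inputs the way exponentiation
#' would), takes the absolute gradient with respect to the normalized input
#' (the activations after the leading batch-norm layer, so all features are
#' on one standardized scale), and multiplies elementwise by the absolute
#' normalized input ("input x gradient").
#'
#' @param checkpoint a `tmrca_checkpoint` or `tmrca_model`.
#' @param features a channels x `L1` feature matrix (see [pair_features()]).
#' @param target_site site index within the central window, in `[1, L]`.
#' @param rescale gradient rescaling constant.
#' @return A `saliency_map`: non-negative channels x `L1` grid plus the
#'   target site.
#' @export
saliency_map <- function(checkpoint, features, target_site, rescale = 1e6) {
  model <- if (inherits(checkpoint, "tmrca_checkpoint")) checkpoint$model else checkpoint
  cfg <- model$config
  if (target_site < 1L || target_site > cfg$L)
    stop_tmrcanet(sprintf("target site %d outside the central window [1, %d]",
                          target_site, cfg$L), "tmrcanet_window_error")
  fw <- forward(model, features, training = FALSE, keep_cache = TRUE)
  d_log <- matrix(0, cfg$L, 1L)
  d_log[target_site, 1L] <- rescale
  bw <- backward(model, fw, d_log, matrix(0, cfg$L, 1L))
  grid <- abs(bw$d_normalized_input[, , 1L]) * abs(bw$normalized_input[, , 1L])
  rownames(grid) <- rownames(features)
  structure(list(grid = grid, target_site = as.integer(target_site),
                 rescale = rescale), class = "saliency_map")
}

#' Summarize saliency over site groups
#'
#' Mean saliency per channel within caller-defined site groups (e.g.
#' heterozygous high-MAF sites, or high-recombination-rate regions),
#' supporting the feature-combination summaries of the saliency analysis.
#'
#' @param smap a `saliency_map`.
#' @param groups named list of logical vectors over the `L1` window sites.
#' @return Matrix channels x groups of mean saliency.
#' @export
saliency_summary <- function(smap, groups) {
  vapply(groups, function(g) rowMeans(smap$grid[, g, drop = FALSE]),
         numeric(nrow(smap$grid)))
}

#' MAF perturbation probe
#'
#' Measures the mean change in predicted TMRCA (generations) when the MAF
#' channel is perturbed according to allele sharing: mode
#' `"lower_and_sites"` subtracts 0.05 from the MAF at homozygous-derived
#' (AND = 1) sites, and mode `"raise_xor_sites"` adds 0.05 at heterozygous
#' (XOR = 1) sites. MAF values below 0.05 are clamped to the singleton
#' frequency `1 / n_haplotypes` when lowering; values above 0.45 are
#' clamped to 0.5 when raising. All other channels are held fixed.
#'
#' @param checkpoint a `tmrca_checkpoint` or `tmrca_model`.
#' @param panel a [haplotype_panel()].
#' @param pairs two-column matrix of haplotype pairs to average over.
#' @param mode `"lower_and_sites"` or `"raise_xor_sites"`.
#' @param delta perturbation magnitude.
#' @return Mean (perturbed - baseline) predicted TMRCA over all sites and
#'   pairs, with per-pair means as attribute `per_pair`.
#' @export
perturb_maf <- function(checkpoint, panel, pairs,
                        mode = c("lower_and_sites", "raise_xor_sites"),
                        delta = 0.05) {
  mode <- match.arg(mode)
  model <- if (inherits(checkpoint, "tmrca_checkpoint")) checkpoint$model else checkpoint
  cfg <- model$config
  singleton <- 1 / panel$n_haplotypes
  per_pair <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    pair <- pairs[r, ]
    tracks <- pair_tracks(panel, pair[1L], pair[2L], "logic")
    pert <- perturbed_maf_tracks(tracks, mode, delta, singleton)
    base_t <- predict_windows(model, tracks, panel$n_sites)
    pert_t <- predict_windows(model, pert, panel$n_sites)
    per_pair[r] <- mean(pert_t - base_t)
  }
  structure(mean(per_pair), per_pair = per_pair, mode = mode)
}

# apply the MAF perturbation with its clamp rules to a feature track set
perturbed_maf_tracks <- function(tracks, mode, delta, singleton) {
  pert <- tracks
  maf <- pert["maf", ]
  if (delta > 0) {
    if (mode == "lower_and_sites") {
      sel <- pert["and", ] == 1
      maf[sel] <- ifelse(maf[sel] < 0.05, singleton, maf[sel] - delta)
    } else {
      sel <- pert["xor", ] == 1
      maf[sel] <- ifelse(maf[sel] > 0.45, 0.5, maf[sel] + delta)
    }
  }
  pert["maf", ] <- maf
  pert
}

# tile full-panel tracks through the model, natural-scale TMRCA per site
predict_windows <- function(model, tracks, n_sites) {
  cfg <- model$config
  out <- numeric(n_sites)
  for (s in seq(1L, n_sites, by = cfg$L)) {
    x <- window_tracks(tracks, s - cfg$context, cfg$L1)
    fw <- forward(model, x, training = FALSE)
    take <- min(cfg$L, n_sites - s + 1L)
    out[s:(s + take - 1L)] <- pmax(exp(fw$log_tmrca[seq_len(take), 1L]), 1)
  }
  out
}

#' Correlate first-block channels with the XOR/AND logic functions
#'
#' For a model trained on raw haplotype channels, measures the Pearson
#' correlation between each channel of the first convolution block's output
#' and the XOR / AND tracks of the pair, restricted to the `L2` central
#' sites the block computes, averaged over pairs. Constant channels yield
#' `NA` (undefined), not 0.
#'
#' @param checkpoint a `tmrca_checkpoint` or `tmrca_model` with raw-channel
#'   input.
#' @param panel a [haplotype_panel()].
#' @param pairs two-column matrix of haplotype pairs.
#' @param offset window start site (context included), 1-based.
#' @return Matrix channels x 2 (`xor`, `and`) of mean correlations, with the
#'   max-|r| channel assignment as attribute `assignment`.
#' @export
channel_logic_correlation <- function(checkpoint, panel, pairs,
                                      offset = 1L) {
  model <- if (inherits(checkpoint, "tmrca_checkpoint")) checkpoint$model else checkpoint
  cfg <- model$config
  k1 <- cfg$kernels[1L]
  L2 <- cfg$L1 - (k1 - 1L)
  trim <- (k1 - 1L) %/% 2L
  acc <- array(0, c(cfg$channels[1L], 2L))
  cnt <- array(0, c(cfg$channels[1L], 2L))
  for (r in seq_len(nrow(pairs))) {
    pair <- pairs[r, ]
    raw <- pair_features(panel, pair, model_window(cfg), offset = offset,
                         channels = "raw")
    logic <- pair_features(panel, pair, model_window(cfg), offset = offset,
                           channels = "logic")
    act <- block_activations(model, raw, block = 1L)[, , 1L]
    central <- (trim + 1L):(trim + L2)
    xor_c <- logic["xor", central]
    and_c <- logic["and", central]
    for (ch in seq_len(nrow(act))) {
      for (g in 1:2) {
        gate <- if (g == 1L) xor_c else and_c
        if (stats::sd(act[ch, ]) == 0 || stats::sd(gate) == 0) next
        acc[ch, g] <- acc[ch, g] + stats::cor(act[ch, ], gate)
        cnt[ch, g] <- cnt[ch, g] + 1
      }
    }
  }
  r <- acc / cnt
  r[cnt == 0] <- NA_real_
  dimnames(r) <- list(channel = seq_len(nrow(r)), gate = c("xor", "and"))
  best <- apply(abs(r), 2L, function(col)
    if (all(is.na(col))) NA_integer_ else which.max(col))
  structure(r, assignment = best)
}
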