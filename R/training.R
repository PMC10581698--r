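# Training: imbalance-aware pair sampling, per-epoch fresh simulations,
# multitask optimization with homoscedastic uncertainty, validation focused
# on the closest pairs, model selection at the minimum validation score, and
# transfer learning by fine-tuning all layers of a donor checkpoint.

#' Relatedness-informed disjoint pairing of haplotypes
#'
#' Builds a perfect matching over `2n` haplotypes that oversamples closely
#' related (recent-TMRCA) pairs: the first pair is sampled uniformly; each
#' subsequent pair is seeded by a uniformly drawn already-processed
#' haplotype, takes the remaining haplotype with the smallest mean TMRCA to
#' that anchor, and completes the pair with the remaining haplotype closest
#' to it. Ties break to the lowest index.
#'
#' @param mean_tmrca symmetric matrix of mean pairwise TMRCAs over `2n`
#'   haplotypes (see [pairwise_mean_tmrca()]).
#' @param seed integer seed.
#' @return An `n` x 2 matrix of haplotype indices; every haplotype appears
#'   exactly once.
#' @export
relatedness_pairing <- function(mean_tmrca, seed = 1L) {
  n2 <- nrow(mean_tmrca)
  stopifnot(is.matrix(mean_tmrca), ncol(mean_tmrca) == n2)
  if (n2 %% 2L != 0L || n2 < 4L)
    stop_tmrcanet("need an even number (>= 4) of haplotypes to pair",
                  "tmrcanet_pairing_error")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  remaining <- seq_len(n2)
  first <- sample(remaining, 2L)
  pairs <- matrix(first, ncol = 2L)
  processed <- first
  remaining <- setdiff(remaining, first)
  while (length(remaining) > 0L) {
    anchor <- processed[sample.int(length(processed), 1L)]
    x <- remaining[which.min(mean_tmrca[anchor, remaining])]
    rem2 <- setdiff(remaining, x)
    y <- rem2[which.min(mean_tmrca[x, rem2])]
    pairs <- rbind(pairs, c(x, y))
    processed <- c(processed, x, y)
    remaining <- setdiff(remaining, c(x, y))
  }
  dimnames(pairs) <- list(NULL, c("h1", "h2"))
  pairs
}

# uniform random perfect matching (the alternate epoch mode)
uniform_matching <- function(n2, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n2)
  matrix(perm, ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("h1", "h2")))
}

flat_to_matrix <- function(flat, n) {
  m <- matrix(0, n, n)
  grid <- pair_grid(n)
  for (k in seq_len(nrow(grid))) {
    m[grid[k, 1L], grid[k, 2L]] <- flat[k]
    m[grid[k, 2L], grid[k, 1L]] <- flat[k]
  }
  m
}

#' Training configuration
#'
#' @param sim a [sim_config()] describing the training simulations (its
#'   `seed` field is ignored; per-simulation seeds derive from
#'   `master_seed`).
#' @param model a [model_config()].
#' @param epochs number of training epochs.
#' @param sims_per_epoch fresh coalescent simulations per epoch, each
#'   contributing one haplotype pair.
#' @param batch_size training windows per optimizer step.
#' @param lr Adam learning rate for network weights.
#' @param lr_uncertainty plain-gradient step size for the two task
#'   log-variances.
#' @param validation_sims number of held-out simulations for validation.
#' @param validation_frac fraction of closest pairs retained for validation.
#' @param huber_delta,log_floor loss parameters, see [multitask_loss()].
#' @param channels feature representation, `"logic"` or `"raw"`.
#' @param shuffle_labels diagnostic: permute one task's labels across sites
#'   and windows each epoch (`"tmrca"` or `"breakpoint"`), turning that task
#'   into pure noise. Used to probe the homoscedastic uncertainty weighting,
#'   whose learned log-variance for a noise task should rise above the
#'   informative task's.
#' @param master_seed master seed; all stage seeds derive from it.
#' @param log_path optional TSV file appended with per-epoch metrics.
#' @param verbose print per-epoch progress.
#' @export
train_config <- function(sim, model, epochs = 15L, sims_per_epoch = 64L,
                         batch_size = 32L, lr = 1e-3, lr_uncertainty = 0.05,
                         validation_sims = 6L, validation_frac = 0.05,
                         huber_delta = 1, log_floor = 1,
                         channels = c("logic", "raw"),
                         shuffle_labels = c("none", "tmrca", "breakpoint"),
                         master_seed = 1L, log_path = NULL, verbose = FALSE) {
  stopifnot(inherits(sim, "sim_config"), inherits(model, "model_config"))
  channels <- match.arg(channels)
  shuffle_labels <- match.arg(shuffle_labels)
  n_feat <- 6L
  if (model$in_channels != n_feat)
    stop(sprintf("model expects %d input channels but the feature builder produces %d",
                 model$in_channels, n_feat))
  structure(list(sim = sim, model = model, epochs = as.integer(epochs),
                 sims_per_epoch = as.integer(sims_per_epoch),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_uncertainty = lr_uncertainty,
                 validation_sims = as.integer(validation_sims),
                 validation_frac = validation_frac,
                 huber_delta = huber_delta, log_floor = log_floor,
                 channels = channels, shuffle_labels = shuffle_labels,
                 master_seed = as.integer(master_seed),
                 log_path = log_path, verbose = isTRUE(verbose)),
            class = "train_config")
}

# cut one (panel, labels, pair) into fixed-length training windows
dataset_windows <- function(panel, labels, pair, window, channels) {
  n <- panel$n_sites
  if (n == 0L) return(list())
  tracks <- pair_tracks(panel, pair[1L], pair[2L], channels)
  y <- tmrca_track(labels, pair[1L], pair[2L])
  b <- breakpoint_track(labels, pair[1L], pair[2L])
  L <- window$L
  out <- list()
  if (n >= L) {
    for (s in seq(1L, n - L + 1L, by = L)) {
      x <- window_tracks(tracks, s - window$context, window$L1)
      out[[length(out) + 1L]] <- list(x = x, tmrca = y[s:(s + L - 1L)],
                                      breakpoint = b[s:(s + L - 1L)])
    }
  } else {
    x <- window_tracks(tracks, 1L - window$context, window$L1)
    pad <- L - n
    out[[1L]] <- list(x = x, tmrca = c(y, rep(y[n], pad)),
                      breakpoint = c(b, integer(pad)))
  }
  out
}

stack_examples <- function(examples) {
  N <- length(examples)
  d <- dim(examples[[1L]]$x)
  x <- array(0, c(d[1L], d[2L], N))
  for (i in seq_len(N)) x[, , i] <- examples[[i]]$x
  list(x = x,
       tmrca = vapply(examples, function(e) e$tmrca, numeric(length(examples[[1L]]$tmrca))),
       breakpoint = vapply(examples, function(e) e$breakpoint,
                           numeric(length(examples[[1L]]$breakpoint))))
}

# simulate `n_sims` independent datasets, keeping tree files for later label
# extraction; returns panels, mean-TMRCA matrices, seeds and tree paths
sim_batch <- function(config, seeds, map_offsets, trees_dir) {
  specs <- vector("list", length(seeds))
  paths <- file.path(trees_dir, sprintf("sim%03d.trees", seq_along(seeds)))
  for (i in seq_along(seeds))
    specs[[i]] <- backend_spec(config$sim, seeds[i], pairs = "none",
                               want_panel = TRUE, want_divergence = TRUE,
                               save_trees = paths[i],
                               map_from = map_offsets[i])
  res <- run_backend(list(mode = "simulate", sims = specs))
  list(sims = res$sims, trees = paths)
}

extract_pair_labels <- function(trees, pairs0) {
  jobs <- lapply(seq_along(trees), function(i)
    list(trees = trees[i], pairs = list(pairs0[[i]])))
  run_backend(list(mode = "labels", jobs = jobs))$jobs
}

#' Generate one epoch of training data
#'
#' Runs `sims_per_epoch` fresh, independently seeded coalescent simulations
#' (different genomic map regions when a non-constant genetic map is
#' configured), selects one haplotype pair per simulation according to the
#' epoch's sampling mode (uniform on odd epochs, relatedness-informed on
#' even epochs), extracts that pair's exact TMRCA labels, and cuts the
#' result into fixed-length training windows.
#'
#' @param config a [train_config()].
#' @param epoch epoch number (1-based; determines the sampling mode and the
#'   simulation seed stream).
#' @param mode optional override of the sampling mode.
#' @return List with `examples`, `mode`, `seeds`.
#' @export
make_epoch <- function(config, epoch, mode = NULL) {
  mode <- mode %||% if (epoch %% 2L == 1L) "uniform" else "relatedness"
  n_sims <- config$sims_per_epoch
  seeds <- vapply(seq_len(n_sims), function(i)
    derive_seed(config$master_seed, sprintf("train/epoch%d/sim%d", epoch, i)), 0L)
  if (anyDuplicated(seeds)) seeds <- seeds + seq_along(seeds) - 1L
  map_offsets <- epoch_map_offsets(config, epoch, n_sims)
  trees_dir <- file.path(tempdir(), sprintf("tmrcanet_epoch%d_%d", epoch,
                                            Sys.getpid()))
  dir.create(trees_dir, showWarnings = FALSE, recursive = TRUE)
  on.exit(unlink(trees_dir, recursive = TRUE), add = TRUE)
  batch <- sim_batch(config, seeds, map_offsets, trees_dir)
  n_hap <- config$sim$n_haplotypes
  chosen <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    pseed <- derive_seed(config$master_seed,
                         sprintf("pairing/epoch%d/sim%d", epoch, i))
    if (mode == "relatedness") {
      m <- flat_to_matrix(as.numeric(unlist(batch$sims[[i]]$mean_tmrca)), n_hap)
      matching <- relatedness_pairing(m, seed = pseed)
    } else {
      matching <- uniform_matching(n_hap, seed = pseed)
    }
    draw <- derive_seed(config$master_seed,
                        sprintf("draw/epoch%d/sim%d", epoch, i)) %%
      nrow(matching) + 1L
    chosen[[i]] <- sort(matching[draw, ])
  }
  labs <- extract_pair_labels(batch$trees,
                              lapply(chosen, function(p) c(p[1L] - 1L, p[2L] - 1L)))
  window <- model_window(config$model)
  examples <- list()
  for (i in seq_len(n_sims)) {
    sim <- batch$sims[[i]]
    panel <- panel_from_backend(sim, config$sim, map_offsets[i])
    if (panel$n_sites == 0L) next
    labels <- labels_from_backend(labs[[i]]$labels,
                                  positions = panel$positions,
                                  n_sites = panel$n_sites)
    examples <- c(examples, dataset_windows(panel, labels, chosen[[i]],
                                            window, config$channels))
  }
  list(examples = examples, mode = mode, seeds = seeds)
}

epoch_map_offsets <- function(config, epoch, n_sims) {
  gm <- config$sim$genetic_map
  if (is.null(gm)) return(rep(0, n_sims))
  span <- max(gm$positions) - config$sim$region_length
  if (span <= 0) return(rep(0, n_sims))
  vapply(seq_len(n_sims), function(i) {
    u <- derive_seed(config$master_seed,
                     sprintf("region/epoch%d/sim%d", epoch, i)) / 2147483562
    u * span
  }, 0)
}

# ---- validation ------------------------------------------------------------

#' Build the validation set for a training configuration
#'
#' Simulates `validation_sims` held-out datasets (seed stream disjoint from
#' training), pools all haplotype pairs, ranks them by mean true TMRCA
#' ascending, retains the closest `validation_frac` fraction, and extracts
#' windows with exact labels for those pairs.
#'
#' @param config a [train_config()].
#' @return List of validation examples plus bookkeeping.
#' @export
build_validation_set <- function(config) {
  n_sims <- config$validation_sims
  seeds <- vapply(seq_len(n_sims), function(i)
    derive_seed(config$master_seed, sprintf("validation/sim%d", i)), 0L)
  map_offsets <- vapply(seq_len(n_sims), function(i) {
    gm <- config$sim$genetic_map
    if (is.null(gm)) return(0)
    span <- max(gm$positions) - config$sim$region_length
    if (span <= 0) return(0)
    derive_seed(config$master_seed, sprintf("valregion/sim%d", i)) / 2147483562 * span
  }, 0)
  trees_dir <- file.path(tempdir(), sprintf("tmrcanet_val_%d", Sys.getpid()))
  dir.create(trees_dir, showWarnings = FALSE, recursive = TRUE)
  on.exit(unlink(trees_dir, recursive = TRUE), add = TRUE)
  batch <- sim_batch(config, seeds, map_offsets, trees_dir)
  n_hap <- config$sim$n_haplotypes
  grid <- pair_grid(n_hap)
  pool <- do.call(rbind, lapply(seq_len(n_sims), function(i) {
    data.frame(sim = i, h1 = grid[, 1L], h2 = grid[, 2L],
               mean_tmrca = as.numeric(unlist(batch$sims[[i]]$mean_tmrca)))
  }))
  n_keep <- floor(nrow(pool) * config$validation_frac)
  if (n_keep < 1L) {
    warning("fewer than 1/validation_frac pairs available; using the single closest pair")
    n_keep <- 1L
  }
  keep <- pool[order(pool$mean_tmrca), ][seq_len(n_keep), ]
  jobs <- lapply(seq_len(n_sims), function(i) {
    sel <- keep[keep$sim == i, , drop = FALSE]
    list(trees = batch$trees[i],
         pairs = lapply(seq_len(nrow(sel)),
                        function(r) c(sel$h1[r] - 1L, sel$h2[r] - 1L)))
  })
  jobs <- jobs[vapply(jobs, function(j) length(j$pairs) > 0L, TRUE)]
  sims_used <- sort(unique(keep$sim))
  labres <- run_backend(list(mode = "labels", jobs = jobs))$jobs
  window <- model_window(config$model)
  examples <- list()
  ji <- 0L
  for (i in sims_used) {
    ji <- ji + 1L
    sim <- batch$sims[[i]]
    panel <- panel_from_backend(sim, config$sim, map_offsets[i])
    if (panel$n_sites == 0L) next
    labels <- labels_from_backend(labres[[ji]]$labels,
                                  positions = panel$positions,
                                  n_sites = panel$n_sites)
    sel <- keep[keep$sim == i, , drop = FALSE]
    for (r in seq_len(nrow(sel)))
      examples <- c(examples,
                    dataset_windows(panel, labels, c(sel$h1[r], sel$h2[r]),
                                    window, config$channels))
  }
  list(examples = examples, pairs = keep, seeds = seeds)
}

#' Validation score: density-weighted Huber loss on log-TMRCA
#'
#' Scores a model on a validation set built by [build_validation_set()].
#' Per-site weights are inversely proportional to the empirical density of
#' the true log-TMRCA over 20 equal-width bins (clipped at 100x the median
#' weight, normalized to mean 1), emphasizing under-represented recent and
#' extremely old TMRCAs.
#'
#' @param model a `tmrca_model`.
#' @param validation_set result of [build_validation_set()].
#' @param delta,log_floor as in [multitask_loss()].
#' @return Scalar score (0 for a perfect model).
#' @export
validation_score <- function(model, validation_set, delta = 1, log_floor = 1) {
  ex <- validation_set$examples
  if (length(ex) == 0L) stop("empty validation set")
  batch <- stack_examples(ex)
  y <- log(pmax(as.numeric(batch$tmrca), log_floor))
  w <- density_weights(y, n_bins = 20L, clip = 100)
  fw <- forward(model, batch$x, training = FALSE)
  r <- as.numeric(fw$log_tmrca) - y
  sum(w * huber(r, delta)) / sum(w)
}

density_weights <- function(y, n_bins = 20L, clip = 100) {
  if (length(unique(y)) == 1L) return(rep(1, length(y)))
  breaks <- seq(min(y), max(y), length.out = n_bins + 1L)
  bin <- findInterval(y, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  w <- 1 / counts[bin]
  w <- pmin(w, clip * stats::median(w))
  w / mean(w)
}

# ---- main loop -------------------------------------------------------------

#' Train a model
#'
#' Runs the full training protocol: per-epoch fresh simulations with
#' alternating uniform/relatedness pair sampling, multitask loss with
#' learned homoscedastic task uncertainties, Adam (lr 0.001 by default) on
#' the network weights, and model selection at the minimum validation score.
#' The regression and classification head biases are initialized from the
#' first epoch's label mean and breakpoint base rate.
#'
#' @param config a [train_config()].
#' @param init_model optional warm-start model (used by [finetune()]); all
#'   layers are updated.
#' @return A `tmrca_checkpoint`: list with the best `model`, per-epoch
#'   `history`, `best_epoch`, `best_score`, and provenance.
#' @export
train <- function(config, init_model = NULL) {
  stopifnot(inherits(config, "train_config"))
  warm <- !is.null(init_model)
  model <- init_model %||%
    build_model(config$model, seed = derive_seed(config$master_seed, "init"))
  if (!identical(model$config[c("L", "kernels", "channels", "in_channels")],
                 config$model[c("L", "kernels", "channels", "in_channels")]))
    stop_tmrcanet("checkpoint model configuration does not match the training configuration",
                  "tmrcanet_config_error")
  valset <- build_validation_set(config)
  opt <- adam_init(model$params)
  skip <- c("s_reg", "s_cls")
  history <- NULL
  best_score <- Inf
  best <- model
  best_epoch <- NA_integer_
  for (epoch in seq_len(config$epochs)) {
    data <- make_epoch(config, epoch)
    ex <- data$examples
    if (length(ex) == 0L) stop("epoch produced no training windows")
    if (epoch == 1L && !warm) {
      all_t <- unlist(lapply(ex, function(e) e$tmrca))
      all_b <- unlist(lapply(ex, function(e) e$breakpoint))
      model$params[["head.b"]] <-
        c(mean(log(pmax(all_t, config$log_floor))),
          max(-6, min(6, stats::qlogis(max(mean(all_b), 1e-4)))))
    }
    ord <- order(vapply(seq_along(ex), function(i)
      derive_seed(config$master_seed, sprintf("shuffle/epoch%d/%d", epoch, i)), 0L))
    ex <- ex[ord]
    if (config$shuffle_labels != "none") {
      old_rs <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(derive_seed(config$master_seed, sprintf("labelperm/%d", epoch)))
      pooled <- unlist(lapply(ex, `[[`, config$shuffle_labels))
      pooled <- sample(pooled)
      at <- 0L
      for (i in seq_along(ex)) {
        n_i <- length(ex[[i]][[config$shuffle_labels]])
        ex[[i]][[config$shuffle_labels]] <- pooled[(at + 1L):(at + n_i)]
        at <- at + n_i
      }
      if (!is.null(old_rs)) assign(".Random.seed", old_rs, globalenv())
    }
    n_batches <- ceiling(length(ex) / config$batch_size)
    ep_loss <- ep_h <- ep_b <- 0
    for (bi in seq_len(n_batches)) {
      idx <- ((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size,
                                                      length(ex))
      batch <- stack_examples(ex[idx])
      fw <- forward(model, batch$x, training = TRUE, keep_cache = TRUE)
      model$running <- fw$running
      loss <- multitask_loss(fw,
                             list(tmrca = batch$tmrca,
                                  breakpoint = batch$breakpoint),
                             list(s_reg = model$params$s_reg,
                                  s_cls = model$params$s_cls),
                             delta = config$huber_delta,
                             log_floor = config$log_floor)
      g <- attr(loss, "grads")
      bw <- backward(model, fw, g$d_log_tmrca, g$d_breakpoint_logit)
      step <- adam_step(model$params, bw$grads, opt, lr = config$lr, skip = skip)
      model$params <- step$params
      opt <- step$state
      model$params$s_reg <- model$params$s_reg - config$lr_uncertainty * g$d_s_reg
      model$params$s_cls <- model$params$s_cls - config$lr_uncertainty * g$d_s_cls
      parts <- attr(loss, "parts")
      ep_loss <- ep_loss + as.numeric(loss)
      ep_h <- ep_h + parts[["huber"]]
      ep_b <- ep_b + parts[["bce"]]
    }
    val <- validation_score(model, valset, delta = config$huber_delta,
                            log_floor = config$log_floor)
    row <- data.frame(epoch = epoch, mode = data$mode,
                      train_loss = ep_loss / n_batches,
                      huber = ep_h / n_batches, bce = ep_b / n_batches,
                      s_reg = model$params$s_reg, s_cls = model$params$s_cls,
                      val_score = val)
    history <- rbind(history, row)
    if (!is.null(config$log_path))
      utils::write.table(row, config$log_path, sep = "\t", append = file.exists(config$log_path),
                         col.names = !file.exists(config$log_path),
                         row.names = FALSE, quote = FALSE)
    if (config$verbose)
      message(sprintf("epoch %d (%s): loss %.4f, val %.4f", epoch, data$mode,
                      row$train_loss, val))
    if (val < best_score) {
      best_score <- val
      best <- model
      best_epoch <- epoch
    }
  }
  structure(list(model = best, history = history, best_epoch = best_epoch,
                 best_score = best_score, train_config = config,
                 master_seed = config$master_seed,
                 finetuned = warm), class = "tmrca_checkpoint")
}

#' Fine-tune a trained checkpoint in a new setting (transfer learning)
#'
#' Initializes every layer from the donor checkpoint and retrains all layers
#' under the new configuration (e.g. a different demographic model, data
#' modality or error rates).
#'
#' @param checkpoint a `tmrca_checkpoint`.
#' @param config a [train_config()] for the new setting; its model
#'   configuration must match the donor's.
#' @return A new `tmrca_checkpoint`.
#' @export
finetune <- function(checkpoint, config) {
  stopifnot(inherits(checkpoint, "tmrca_checkpoint"))
  train(config, init_model = checkpoint$model)
}

#' @exportS3Method base::print
print.tmrca_checkpoint <- function(x, ...) {
  cat(sprintf("tmrca_checkpoint: best epoch %d (validation score %.4f)%s\n",
              x$best_epoch, x$best_score,
              if (isTRUE(x$finetuned)) ", fine-tuned" else ""))
  print(x$model)
  invisible(x)
}

#' Save / load checkpoints
#'
#' Checkpoints embed the model configuration and training provenance
#' (master seed, history), so a loaded checkpoint is usable for inference
#' and fine-tuning without the original session.
#'
#' @param checkpoint a `tmrca_checkpoint`.
#' @param path file path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "tmrca_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "tmrca_checkpoint")) stop("not a tmrca_checkpoint file")
  x
}
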