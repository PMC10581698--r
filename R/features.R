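#' Window specification for the convolutional input
#'
#' The network predicts the `L` central sites of each window; `context`
#' additional sites are supplied on each side so that every central site
#' sees a full receptive field. The full input length is
#' `L1 = L + 2 * context`.
#'
#' @param L number of central (predicted) sites, >= 1.
#' @param context sites of context on each side, >= 0.
#' @return An object of class `window_spec` with fields `L`, `context`, `L1`.
#' @export
window_spec <- function(L, context) {
  stopifnot(L >= 1, context >= 0)
  structure(list(L = as.integer(L), context = as.integer(context),
                 L1 = as.integer(L + 2 * context)), class = "window_spec")
}

# per-site run length of the maximal constant run containing each site
ibs_run_lengths <- function(xor) {
  if (length(xor) == 0L) return(integer(0))
  r <- rle(xor)
  rep(r$lengths, r$lengths)
}

#' Brute-force reference for IBS run lengths
#'
#' Literal O(n^2) scan: for each site, walk left and right while the track
#' value is unchanged and count the run (including the site itself).
#' A deliberately naive reference implementation used to validate the
#' production run-length computation.
#'
#' @param xor binary mismatch track (0 = identical-by-state).
#' @return Integer run length per site.
#' @export
ibs_run_oracle <- function(xor) {
  n <- length(xor)
  out <- integer(n)
  for (i in seq_len(n)) {
    len <- 1L
    j <- i - 1L
    while (j >= 1L && xor[j] == xor[i]) { len <- len + 1L; j <- j - 1L }
    j <- i + 1L
    while (j <= n && xor[j] == xor[i]) { len <- len + 1L; j <- j + 1L }
    out[i] <- len
  }
  out
}

# full-panel per-pair feature tracks; windowing slices these
pair_tracks <- function(panel, h1, h2, channels = c("logic", "raw")) {
  channels <- match.arg(channels)
  if (h1 == h2)
    stop_tmrcanet("self-pair requested: a haplotype cannot be paired with itself",
                  "tmrcanet_pair_error")
  a1 <- panel$alleles[h1, ]
  a2 <- panel$alleles[h2, ]
  x <- as.integer(xor(a1, a2))
  maf <- site_maf(panel)
  dbp <- c(0, diff(panel$positions))
  dcm <- c(0, diff(panel$map_cM))
  ibs <- ibs_run_lengths(x)
  if (channels == "logic") {
    rbind(xor = x, and = as.integer(a1 & a2), maf = maf,
          dist_bp = dbp, dist_cM = dcm, ibs_run = ibs)
  } else {
    rbind(hap1 = a1, hap2 = a2, maf = maf,
          dist_bp = dbp, dist_cM = dcm, ibs_run = ibs)
  }
}

# slice tracks to [offset, offset + L1 - 1] with edge padding:
# allele-derived channels (xor/and or hap1/hap2) and distances pad with 0,
# maf and ibs_run replicate the edge value
window_tracks <- function(tracks, offset, L1) {
  n <- ncol(tracks)
  idx <- offset:(offset + L1 - 1L)
  inside <- idx >= 1L & idx <= n
  out <- matrix(0, nrow(tracks), L1, dimnames = list(rownames(tracks), NULL))
  out[, inside] <- tracks[, idx[inside]]
  repl <- rownames(tracks) %in% c("maf", "ibs_run")
  if (any(!inside) && n > 0L) {
    left <- idx < 1L
    right <- idx > n
    out[repl, left] <- tracks[repl, 1L]
    out[repl, right] <- tracks[repl, n]
  }
  out
}

#' Per-pair, per-site input features for one window
#'
#' Builds the 6-channel input representation for a haplotype pair over a
#' window of `L1 = L + 2 * context` sites starting at site `offset`:
#' per-site XOR and AND of the two haplotypes, minor allele frequency
#' (computed from the full panel), physical and genetic distance from the
#' previous retained site (0 at the panel's first site), and the length of
#' the maximal identical-by-state run containing the site (computed over the
#' whole panel, not the window). With `channels = "raw"` the XOR/AND
#' channels are replaced by the two raw haplotype tracks.
#'
#' Windows overhanging the panel edge are padded: allele and distance
#' channels with 0, MAF and IBS run with the edge value. Distances are left
#' raw (bp, cM); standardization is the job of the network's leading batch
#' normalization layer.
#'
#' @param panel a [haplotype_panel()].
#' @param pair length-2 vector of haplotype indices (1-based, distinct).
#' @param window a [window_spec()].
#' @param offset 1-based site index of the window's first (context) site;
#'   may run off the panel only when `pad = TRUE`.
#' @param pad allow edge padding.
#' @param channels `"logic"` (default, 6 channels) or `"raw"`.
#' @return A channels x `L1` numeric matrix with named rows.
#' @export
pair_features <- function(panel, pair, window, offset = 1L - window$context,
                          pad = TRUE, channels = "logic") {
  stopifnot(inherits(window, "window_spec"), length(pair) == 2L)
  tracks <- pair_tracks(panel, pair[1L], pair[2L], channels)
  if (!pad && (offset < 1L || offset + window$L1 - 1L > panel$n_sites))
    stop_tmrcanet("window exceeds panel bounds and padding is disabled",
                  "tmrcanet_window_error")
  window_tracks(tracks, as.integer(offset), window$L1)
}
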