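# MAF-adjusted, quantile-normalized allele-age annotations in stratified
# LD-score-regression (.annot) format.

#' Build a MAF-adjusted quantile-normalized allele-age annotation
#'
#' Drops variants with MAF < `maf_min` (rare variants are excluded from the
#' heritability annotation), assigns the rest to equal-width MAF bins on
#' `[maf_min, maf_max]`, and within each bin quantile-normalizes the allele
#' ages to a standard normal via the rank-based inverse-normal transform
#' `qnorm((rank - 0.5) / n)`, with tied ages sharing the mean of their rank
#' range. The transform is rank-preserving, so the annotation is invariant
#' to any monotone transform of the raw ages within a bin.
#'
#' @param ages positive allele ages (generations).
#' @param mafs minor allele frequencies in (0, 0.5].
#' @param n_bins number of MAF bins.
#' @param maf_min,maf_max annotated MAF range.
#' @param edges optional explicit bin edges (overrides `n_bins`).
#' @return A data.frame with `index` (into the input), `maf_bin` (1-based)
#'   and `normalized_age`; bin edges as attribute `edges`.
#' @export
build_annotation <- function(ages, mafs, n_bins = 10L, maf_min = 0.05,
                             maf_max = 0.5, edges = NULL) {
  stopifnot(length(ages) == length(mafs))
  if (any(ages <= 0, na.rm = TRUE)) stop("ages must be positive")
  if (any(mafs <= 0 | mafs > 0.5, na.rm = TRUE))
    stop("MAFs must lie in (0, 0.5]")
  edges <- edges %||% seq(maf_min, maf_max, length.out = n_bins + 1L)
  keep <- which(!is.na(ages) & !is.na(mafs) & mafs >= maf_min)
  if (length(keep) == 0L)
    return(structure(data.frame(index = integer(0), maf_bin = integer(0),
                                normalized_age = numeric(0)), edges = edges))
  bin <- findInterval(mafs[keep], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  z <- numeric(length(keep))
  for (b in unique(bin)) {
    sel <- which(bin == b)
    n <- length(sel)
    if (n == 1L) {
      warning(sprintf("MAF bin %d holds a single variant; normalized value set to 0", b))
      z[sel] <- 0
      next
    }
    r <- rank(ages[keep][sel], ties.method = "average")
    z[sel] <- stats::qnorm((r - 0.5) / n)
  }
  structure(data.frame(index = keep, maf_bin = bin, normalized_age = z),
            edges = edges)
}

#' Aggregate per-population dating tables into combined ages
#'
#' For each variant key present in at least one table, delegates to
#' [aggregate_groups()] over the populations where the variant was dated.
#'
#' @param tables named list of [date_panel()] outputs (one per population).
#' @param key columns identifying a variant across tables.
#' @return A data.frame of combined `lower`, `upper`, `age` and pooled kept
#'   pair counts per variant key.
#' @export
aggregate_annotation_inputs <- function(tables, key = c("pos")) {
  keys <- unique(do.call(rbind, lapply(tables, function(t) t[, key, drop = FALSE])))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    ests <- list()
    for (t in tables) {
      m <- t
      for (k in key) m <- m[m[[k]] == keys[i, k], , drop = FALSE]
      if (nrow(m) == 1L)
        ests[[length(ests) + 1L]] <- list(lower = m$lower, upper = m$upper,
                                          n_concordant_kept = m$n_concordant_kept,
                                          n_discordant_kept = m$n_discordant_kept)
    }
    agg <- tryCatch(aggregate_groups(ests), tmrcanet_undatable = function(e) NULL)
    if (is.null(agg)) return(NULL)
    cbind(keys[i, , drop = FALSE],
          data.frame(lower = agg$lower, upper = agg$upper, age = agg$age,
                     n_concordant_kept = agg$n_concordant_kept,
                     n_discordant_kept = agg$n_discordant_kept))
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Write an annotation as an S-LDSC .annot-style table
#'
#' Whitespace-separated columns CHR, BP, SNP, CM, ANNOT, plus a sidecar
#' `<path>.bins` file recording the MAF bin edges.
#'
#' @param annotation result of [build_annotation()].
#' @param chrom,bp,snp,cm per-variant metadata vectors indexed like the
#'   inputs to [build_annotation()] (subset via `annotation$index`).
#' @param path output file.
#' @export
write_annot <- function(annotation, chrom, bp, snp, cm, path) {
  i <- annotation$index
  tab <- data.frame(CHR = chrom[i], BP = bp[i], SNP = snp[i], CM = cm[i],
                    ANNOT = annotation$normalized_age)
  utils::write.table(tab, path, sep = " ", row.names = FALSE, quote = FALSE)
  writeLines(paste(attr(annotation, "edges"), collapse = " "),
             paste0(path, ".bins"))
  invisible(path)
}
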