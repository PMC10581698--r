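# File-format adapters. VCF is the exchange format for phased panels
# (reading via vcfR); the native container is an RDS snapshot of the panel
# list. All VCF/TSV coordinates are 1-based; BED-like outputs are 0-based
# half-open.

#' Write a haplotype panel as phased VCF
#'
#' Minimal biallelic VCF with phased GT fields (two haplotypes per sample
#' column) and the ancestral allele recorded in the INFO AA tag. Alleles
#' are written with REF = ancestral, so the stored 0/1 matrix round-trips.
#'
#' @param panel a [haplotype_panel()].
#' @param path output file.
#' @param aa_missing optional logical vector: sites whose ancestral call
#'   should be written as missing (`AA=.`).
#' @export
write_panel_vcf <- function(panel, path, aa_missing = NULL) {
  n_dip <- panel$n_haplotypes %/% 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("sample%03d", seq_len(n_dip))), collapse = "\t")),
    con)
  if (panel$n_sites == 0L) return(invisible(path))
  aa <- rep("A", panel$n_sites)
  if (!is.null(aa_missing)) aa[aa_missing] <- "."
  gt <- matrix("", n_dip, panel$n_sites)
  for (d in seq_len(n_dip))
    gt[d, ] <- paste(panel$alleles[2L * d - 1L, ], panel$alleles[2L * d, ],
                     sep = "|")
  lines <- vapply(seq_len(panel$n_sites), function(s)
    paste(c(panel$chrom, format(panel$positions[s], scientific = FALSE, trim = TRUE),
            ".", "A", "G", ".", "PASS", paste0("AA=", aa[s]), "GT", gt[, s]),
          collapse = "\t"), "")
  writeLines(lines, con)
  invisible(path)
}

#' Read a phased panel from VCF with ancestral/derived recoding
#'
#' Reads phased biallelic records, recodes alleles so that 1 is the derived
#' allele using the INFO AA tag (when AA equals the ALT allele, REF carriers
#' are the derived ones and the coding is complemented). Records with a
#' missing or low-confidence (lowercase) ancestral call keep their REF/ALT
#' coding and are flagged undatable; multiallelic records are skipped (count
#' reported as an attribute); unphased genotypes are an error.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param genetic_map optional [genetic_map()] for cM coordinates; otherwise
#'   a constant `rate_cM_per_Mb` is assumed.
#' @param rate_cM_per_Mb constant map rate fallback.
#' @return A [haplotype_panel()] with attributes `undatable` (logical per
#'   site) and `n_multiallelic_skipped`.
#' @export
read_panel <- function(path, genetic_map = NULL, rate_cM_per_Mb = 1) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_multi <- sum(multi)
  keep <- which(!multi)
  if (length(keep) == 0L) stop("no biallelic records in ", path)
  fix <- fix[keep, , drop = FALSE]
  gtm <- gt[keep, -1L, drop = FALSE]        # drop FORMAT column
  unphased <- which(grepl("/", gtm, fixed = TRUE))
  if (length(unphased)) {
    rec <- ((unphased[1L] - 1L) %% nrow(gtm)) + 1L
    stop_tmrcanet(sprintf("unphased genotype at %s:%s", fix[rec, "CHROM"],
                          fix[rec, "POS"]), "tmrcanet_vcf_error")
  }
  n_sites <- nrow(fix)
  n_dip <- ncol(gtm)
  alleles <- matrix(0L, 2L * n_dip, n_sites)
  for (d in seq_len(n_dip)) {
    parts <- strsplit(sub(":.*$", "", gtm[, d]), "|", fixed = TRUE)
    alleles[2L * d - 1L, ] <- as.integer(vapply(parts, `[`, "", 1L))
    alleles[2L * d, ] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  aa <- rep(NA_character_, n_sites)
  m <- regmatches(fix[, "INFO"], regexpr("AA=[^;]*", fix[, "INFO"]))
  has_aa <- grepl("AA=", fix[, "INFO"])
  aa[has_aa] <- sub("^AA=", "", m)
  low_conf <- !is.na(aa) & aa == tolower(aa) & aa != toupper(aa) &
    toupper(aa) %in% c("A", "C", "G", "T")
  ref <- toupper(fix[, "REF"]); alt <- toupper(fix[, "ALT"])
  aa_up <- toupper(aa)
  undatable <- is.na(aa) | !(aa_up %in% c("A", "C", "G", "T")) |
    !(aa_up == ref | aa_up == alt) | low_conf
  flip <- !undatable & aa_up == alt
  if (any(flip)) alleles[, flip] <- 1L - alleles[, flip]
  pos <- as.numeric(fix[, "POS"])
  poly <- colSums(alleles) > 0L & colSums(alleles) < nrow(alleles)
  alleles <- alleles[, poly, drop = FALSE]
  pos <- pos[poly]
  undatable <- undatable[poly]
  cm <- if (!is.null(genetic_map)) interp_cM(genetic_map, pos)
        else (pos - 1) * rate_cM_per_Mb / 1e6
  out <- haplotype_panel(alleles, pos, cm, chrom = fix[1L, "CHROM"])
  attr(out, "undatable") <- undatable
  attr(out, "n_multiallelic_skipped") <- n_multi
  out
}

#' Native panel container
#'
#' Compressed single-file snapshot of a panel (alleles, positions, genetic
#' map and truth side-cars) for training-set caching.
#'
#' @param panel a [haplotype_panel()].
#' @param path file path.
#' @export
write_panel_native <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  saveRDS(panel, path)
  invisible(path)
}

#' @rdname write_panel_native
#' @export
read_panel_native <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "haplotype_panel")) stop("not a haplotype_panel file")
  x
}
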