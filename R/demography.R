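#' Piecewise-constant demographic model
#'
#' A demographic history given as epochs of constant diploid effective
#' population size. Epoch start times are in generations before present,
#' strictly increasing and beginning at 0.
#'
#' @param times numeric vector of epoch start times (generations); first must
#'   be 0, strictly increasing.
#' @param sizes numeric vector of diploid effective population sizes, one per
#'   epoch, all positive.
#' @return An object of class `demographic_model`.
#' @examples
#' demographic_model(0, 10000)                 # constant Ne = 10,000
#' demographic_model(c(0, 1000), c(5e3, 2e4))  # recent bottleneck
#' @export
demographic_model <- function(times, sizes) {
  stopifnot(length(times) == length(sizes), length(times) >= 1L)
  if (times[1L] != 0) stop("first epoch must start at generation 0")
  if (any(diff(times) <= 0)) stop("epoch start times must be strictly increasing")
  if (any(sizes <= 0)) stop("all population sizes must be positive")
  structure(list(times = as.numeric(times), sizes = as.numeric(sizes)),
            class = "demographic_model")
}

#' Read a demographic model from a two-column table
#'
#' Whitespace-separated columns: epoch start time (generations) and diploid
#' effective population size. The first generation must be 0. Lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @return A [demographic_model()].
#' @export
read_demographic_model <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("expected two columns: generation, diploid Ne")
  demographic_model(tab[[1L]], tab[[2L]])
}

#' @exportS3Method base::print
print.demographic_model <- function(x, ...) {
  cat(sprintf("Demographic model with %d epoch(s)\n", length(x$times)))
  for (i in seq_along(x$times))
    cat(sprintf("  from generation %g: Ne = %g\n", x$times[i], x$sizes[i]))
  invisible(x)
}

#' Genetic map
#'
#' Position-to-map interpolation table. Physical positions (bp) must be
#' strictly increasing and map positions (cM) non-decreasing.
#'
#' @param positions physical positions in bp.
#' @param map_cM cumulative genetic map positions in cM.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(positions, map_cM) {
  stopifnot(length(positions) == length(map_cM), length(positions) >= 2L)
  if (any(diff(positions) <= 0)) stop("map positions (bp) must be strictly increasing")
  if (any(diff(map_cM) < 0)) stop("map positions (cM) must be non-decreasing")
  structure(list(positions = as.numeric(positions), map_cM = as.numeric(map_cM)),
            class = "genetic_map")
}

#' Constant-rate genetic map over a region
#'
#' @param rate_cM_per_Mb constant recombination rate in cM/Mb.
#' @param length_bp region length in bp.
#' @export
constant_genetic_map <- function(rate_cM_per_Mb, length_bp) {
  genetic_map(c(1, length_bp), c(0, rate_cM_per_Mb * (length_bp - 1) / 1e6))
}

#' Read a genetic map in HapMap or PLINK dialect
#'
#' HapMap-style maps have a header line and (at least) three columns:
#' position (bp), rate (cM/Mb), cumulative map (cM); a leading chromosome
#' column is tolerated. PLINK maps have four header-less columns:
#' chromosome, identifier, cM, bp. The dialect is auto-detected from the
#' presence of a non-numeric header.
#'
#' @param path file path.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "\\s+")[[1L]]
  num <- !is.na(suppressWarnings(as.numeric(toks)))
  # PLINK rows look like "1 rs123 0.01 1000": header-less, id in column 2
  is_plink <- length(toks) == 4L && !num[2L] && num[3L] && num[4L]
  has_header <- !is_plink && any(!num)
  if (has_header) {
    tab <- utils::read.table(path, header = TRUE)
    num <- vapply(tab, is.numeric, logical(1L))
    tab <- tab[num]
    if (ncol(tab) < 3L) stop("HapMap-style map needs numeric position, rate and cM columns")
    # columns: position, rate, cumulative cM (after dropping any chromosome col)
    if (ncol(tab) > 3L) tab <- tab[, (ncol(tab) - 2L):ncol(tab)]
    genetic_map(tab[[1L]], tab[[3L]])
  } else {
    tab <- utils::read.table(path, header = FALSE)
    if (ncol(tab) == 4L) return(genetic_map(tab[[4L]], tab[[3L]]))
    if (ncol(tab) == 3L) return(genetic_map(tab[[1L]], tab[[3L]]))
    stop("header-less map must be PLINK 4-column (chr, id, cM, bp) or 3-column (bp, rate, cM)")
  }
}

# interpolated cM at arbitrary bp positions (linear, constant-extrapolated)
interp_cM <- function(map, pos) {
  stats::approx(map$positions, map$map_cM, xout = pos, rule = 2)$y
}

# per-interval recombination rate (per bp per generation) for the backend:
# positions vector of length k+1 starting at 0, rates vector of length k
map_to_rates <- function(map, length_bp) {
  pos <- map$positions
  cm <- map$map_cM
  if (pos[1L] > 0) { pos <- c(0, pos); cm <- c(cm[1L], cm) }
  if (pos[length(pos)] < length_bp) {
    pos <- c(pos, length_bp)
    cm <- c(cm, cm[length(cm)])
  } else {
    keep <- pos <= length_bp
    pos <- c(pos[keep], length_bp)
    cm <- c(cm[keep], interp_cM(map, length_bp))
  }
  rate <- diff(cm) / 100 / diff(pos)   # cM -> crossover probability per bp
  list(positions = pos, rates = pmax(rate, 0))
}

# restrict a map to [from, from + length_bp), re-origined at 0 cM
map_window <- function(map, from, length_bp) {
  to <- from + length_bp
  inner <- map$positions > from & map$positions < to
  pos <- c(from, map$positions[inner], to)
  cm <- interp_cM(map, pos)
  genetic_map(pos - from + 1, cm - cm[1L])
}
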