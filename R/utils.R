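#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a stage label
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the run's master seed and a short label naming the stage, so that
#' identical configurations replay identically while distinct stages (and
#' distinct epochs, simulations, ...) receive distinct streams.
#'
#' @param master integer master seed.
#' @param label character stage label, e.g. `"epoch3/sim12"`.
#' @return An integer seed in `[1, 2147483562]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483563
  h <- 17
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% m
  as.integer((h + (abs(master) %% m) * 40014) %% (m - 1) + 1)
}

stop_tmrcanet <- function(msg, class, ...) {
  stop(structure(class = c(class, "tmrcanet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name))
  invisible(x)
}

# pairs (i < j) in the fixed package-wide order matching combn()
pair_grid <- function(n) {
  idx <- utils::combn(n, 2L)
  cbind(h1 = idx[1L, ], h2 = idx[2L, ])
}

pair_key <- function(h1, h2) paste(pmin(h1, h2), pmax(h1, h2), sep = "-")
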