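# Multitask loss: Huber on log-TMRCA (regression) plus class-weighted binary
# cross-entropy on breakpoint indicators (classification), combined with
# learned homoscedastic task uncertainties:
#
#   loss = exp(-s_reg) * Huber + exp(-s_cls) * wBCE + s_reg/2 + s_cls/2
#
# with both task terms averaged per site and the Huber transition delta = 1
# on the natural-log scale. Class weights are inversely proportional to the
# class counts in the batch.

log_sigmoid <- function(z) ifelse(z > 0, -log1p(exp(-z)), z - log1p(exp(z)))

huber <- function(r, delta = 1) {
  a <- abs(r)
  ifelse(a <= delta, 0.5 * r * r, delta * (a - 0.5 * delta))
}

huber_grad <- function(r, delta = 1) pmax(pmin(r, delta), -delta)

#' Inverse-frequency class weights for breakpoint labels
#'
#' Weights `w_c = N / (2 * n_c)` so that `w1 / w0` equals the inverse ratio
#' of class counts. When a class is absent from the batch both weights
#' fall back to 1.
#'
#' @param b 0/1 breakpoint labels.
#' @return Named numeric vector `c(w0, w1)`.
#' @export
class_weights <- function(b) {
  n1 <- sum(b == 1); n0 <- length(b) - n1
  if (n0 == 0 || n1 == 0) return(c(w0 = 1, w1 = 1))
  c(w0 = length(b) / (2 * n0), w1 = length(b) / (2 * n1))
}

#' Multitask training loss
#'
#' @param output list with `log_tmrca` and `breakpoint_logit` (from
#'   [forward()]).
#' @param labels list with `tmrca` (generations, positive) and `breakpoint`
#'   (0/1), each conforming to the output shape.
#' @param uncertainty list with scalars `s_reg`, `s_cls` (learned
#'   log-variances).
#' @param weights optional `c(w0, w1)`; default computed from the labels via
#'   [class_weights()].
#' @param delta Huber transition point on the log scale.
#' @param log_floor TMRCA values are floored here (generations) before
#'   taking logs.
#' @return Scalar loss with attribute `parts` (unweighted task terms) and
#'   attribute `grads` (gradients w.r.t. both outputs and both scalars).
#' @export
multitask_loss <- function(output, labels, uncertainty, weights = NULL,
                           delta = 1, log_floor = 1) {
  t_true <- as.numeric(labels$tmrca)
  if (any(t_true <= 0))
    stop_tmrcanet("labels contain non-positive TMRCA", "tmrcanet_label_error")
  y <- log(pmax(t_true, log_floor))
  yhat <- as.numeric(output$log_tmrca)
  z <- as.numeric(output$breakpoint_logit)
  b <- as.numeric(labels$breakpoint)
  stopifnot(length(yhat) == length(y), length(z) == length(b))
  n <- length(y)
  w <- weights %||% class_weights(b)
  r <- yhat - y
  H <- mean(huber(r, delta))
  bce_el <- -(w[2L] * b * log_sigmoid(z) + w[1L] * (1 - b) * log_sigmoid(-z))
  B <- mean(bce_el)
  sr <- uncertainty$s_reg; sc <- uncertainty$s_cls
  loss <- exp(-sr) * H + exp(-sc) * B + sr / 2 + sc / 2
  p <- stats::plogis(z)
  d_yhat <- exp(-sr) * huber_grad(r, delta) / n
  d_z <- exp(-sc) * (w[2L] * b * (p - 1) + w[1L] * (1 - b) * p) / n
  structure(loss,
            parts = c(huber = H, bce = B),
            grads = list(d_log_tmrca = matrix(d_yhat, nrow = nrow(as.matrix(output$log_tmrca))),
                         d_breakpoint_logit = matrix(d_z, nrow = nrow(as.matrix(output$breakpoint_logit))),
                         d_s_reg = -exp(-sr) * H + 0.5,
                         d_s_cls = -exp(-sc) * B + 0.5))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, skip = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (nm %in% skip) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
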