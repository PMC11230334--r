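# The three training objectives: binary cross-entropy (BCE), its
# class-weighted variant (WBCE) for the success/fail imbalance, and the
# contrastive loss over cosine similarity of the two encoded
# representations. These numeric forms are the reference definitions; the
# tape equivalents used during training (ad_loss_*) are checked against
# them in the tests.

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

check_batch <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop("labels and predictions differ in length (", length(y), " vs ",
         length(y_hat), ")")
  }
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  invisible(NULL)
}

#' Binary cross-entropy loss
#'
#' `-sum_i [ y_i log(p_i) + (1 - y_i) log(1 - p_i) ]`, with probabilities
#' clamped to `[eps, 1 - eps]` (eps = 1e-7) before taking logs.
#'
#' @param y Binary labels (1 = success, 0 = fail).
#' @param y_hat Predicted probabilities in `[0, 1]`.
#' @param reduction `"sum"` (the loss as written over the cohort) or
#'   `"mean"` (per-example average, the training default).
#' @return Non-negative scalar.
#' @export
bce <- function(y, y_hat, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  check_batch(y, y_hat)
  if (any(y_hat < 0 | y_hat > 1)) stop("probabilities must lie in [0, 1]")
  p <- clamp_prob(y_hat)
  li <- -(y * log(p) + (1 - y) * log(1 - p))
  if (reduction == "sum") sum(li) else mean(li)
}

#' Class-weighted binary cross-entropy loss
#'
#' BCE with the positive-class (minority, "success") log-likelihood terms
#' scaled by `beta`, penalizing misclassification of eligible patients more
#' heavily under class imbalance. Reduces to [bce()] at `beta = 1`.
#'
#' @inheritParams bce
#' @param beta Positive weight on the positive-class terms. A common choice
#'   is the fail/success count ratio of the training split (2.6 at a
#'   50:130 imbalance).
#' @return Non-negative scalar.
#' @export
wbce <- function(y, y_hat, beta, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (beta <= 0) stop("beta must be positive")
  check_batch(y, y_hat)
  if (any(y_hat < 0 | y_hat > 1)) stop("probabilities must lie in [0, 1]")
  p <- clamp_prob(y_hat)
  li <- -(beta * y * log(p) + (1 - y) * log(1 - p))
  if (reduction == "sum") sum(li) else mean(li)
}

#' Cosine similarity
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return `u . v / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity undefined for zero vectors (encoder collapse?)")
  }
  sum(u * v) / (nu * nv)
}

#' Contrastive loss over cosine similarities
#'
#' `sum_i [ (1 - y_i) d_i^2 + y_i max(0, margin - d_i)^2 ]` where `d_i` is
#' the cosine similarity between the two encoded representations of pair i.
#' Success pairs are pushed toward similarity >= margin; fail pairs toward
#' zero similarity.
#'
#' @param y Binary labels.
#' @param d_w Cosine similarities in `[-1, 1]`.
#' @param margin Positive hinge level (default 1, the maximum attainable
#'   cosine similarity).
#' @param reduction `"sum"` or `"mean"`.
#' @return Non-negative scalar.
#' @export
contrastive <- function(y, d_w, margin = 1, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (margin <= 0) stop("margin must be positive")
  check_batch(y, d_w)
  if (any(d_w < -1 - 1e-9 | d_w > 1 + 1e-9)) {
    stop("similarities must lie in [-1, 1]")
  }
  li <- (1 - y) * d_w^2 + y * pmax(0, margin - d_w)^2
  if (reduction == "sum") sum(li) else mean(li)
}
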