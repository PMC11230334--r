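# Training and evaluation: Adam optimization (default 50 epochs at
# learning rate 0.005), stratified k-fold cross-validation, class-wise F1,
# and paired comparison of two cross-validated models.

#' Training configuration
#'
#' @param epochs Number of training epochs (default 50).
#' @param learning_rate Adam learning rate (default 0.005).
#' @param k_folds Cross-validation folds (default 5).
#' @param seed Global seed; fans out to fold assignment, parameter
#'   initialization and batch shuffling.
#' @param batch_size Minibatch size; `NULL` = full batch for coarse input
#'   and 16 for fine (token-level) input.
#' @param beta WBCE weight; `NULL` derives it from the training split's
#'   fail/success ratio.
#' @param margin Contrastive hinge level.
#' @param reduction Loss reduction, `"mean"` (default) or `"sum"`.
#' @param val_fraction Fraction of the training split held out for
#'   monitoring only (the final model is always the last-epoch model).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, learning_rate = 0.005, k_folds = 5L,
                         seed = 1L, batch_size = NULL, beta = NULL,
                         margin = 1, reduction = "mean",
                         val_fraction = 0.1) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (k_folds < 2L) stop("k_folds must be >= 2")
  stopifnot(reduction %in% c("mean", "sum"),
            val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 batch_size = batch_size, beta = beta, margin = margin,
                 reduction = reduction, val_fraction = val_fraction),
            class = "train_config")
}

#' Stratified k-fold split
#'
#' Every index lands in exactly one test fold; per-fold class counts differ
#' from perfect proportionality by at most one sample. Reproducible by
#' seed.
#'
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(train_idx, test_idx)`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  classes <- unique(labels)
  counts <- table(labels)
  if (k > min(counts)) {
    stop("k = ", k, " exceeds the minority-class count (", min(counts), ")")
  }
  fold_of <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train_idx = which(fold_of != f), test_idx = which(fold_of == f))
  })
}

#' F1 score from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`, defined as 0 when the denominator is 0.
#'
#' @param tp,fp,fn Non-negative confusion counts for the class treated as
#'   positive.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("confusion counts must be non-negative")
  denom <- 2 * tp + fp + fn
  if (denom == 0) 0 else 2 * tp / denom
}

confusion_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fn <- sum(truth == 1 & pred == 0)
  f1_pos <- f1_score(tp, fp, fn)
  f1_neg <- f1_score(tn, fn, fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       f1_pos = f1_pos, f1_neg = f1_neg,
       f1_overall = (f1_pos + f1_neg) / 2)
}

batch_loss_node <- function(model, pairs, y, beta, config, train = TRUE) {
  ad_tape_reset()
  if (model$loss == "contrastive") {
    br <- siamese_branch_nodes(model, pairs, train = train)
    d <- ad_cosine_rows(br$ehr, br$crit)
    ad_loss_contrastive(d, y, margin = config$margin,
                        reduction = config$reduction)
  } else {
    z <- logit_nodes(model, pairs, train = train)
    b <- if (model$loss == "wbce") beta else 1
    ad_loss_bce_logits(z, y, beta = b, reduction = config$reduction)
  }
}

#' Train a model on embedded pairs
#'
#' Adam optimization of the model's configured loss. The WBCE weight, when
#' unset, is computed from the training split only (fail/success ratio).
#' With a fixed seed the result is bit-stable across runs on one machine.
#'
#' @param model A `tm_siamese` or `tm_single` model.
#' @param pairs List of labelled `tm_pair`s containing both classes.
#' @param config A `train_config`.
#' @return The trained model, with a `history` field: per-epoch training
#'   loss (and monitoring loss when `val_fraction > 0`) and the `beta`
#'   used.
#' @export
train <- function(model, pairs, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  y_all <- vapply(pairs, function(p) p$label, numeric(1))
  if (any(is.na(y_all))) stop("all training pairs must be labelled")
  if (length(unique(y_all)) < 2L) {
    stop("training requires both classes to be present")
  }
  set.seed(config$seed)
  n <- length(pairs)
  val_idx <- integer(0)
  if (config$val_fraction > 0 && n >= 10L) {
    nv <- max(1L, floor(n * config$val_fraction))
    val_idx <- sample(n, nv)
  }
  fit_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y_all[fit_idx])) < 2L) { # keep both classes in the fit set
    val_idx <- integer(0); fit_idx <- seq_len(n)
  }
  beta <- config$beta
  if (is.null(beta)) beta <- model$beta
  if (is.null(beta)) {
    beta <- sum(y_all[fit_idx] == 0) / max(1, sum(y_all[fit_idx] == 1))
  }
  model$beta <- beta
  bs <- config$batch_size
  if (is.null(bs)) bs <- if (model$granularity == "coarse")
    length(fit_idx) else 16L
  params <- model_params(model)
  opt <- adam_new(params, lr = config$learning_rate)
  hist_train <- numeric(config$epochs)
  hist_val <- if (length(val_idx)) numeric(config$epochs) else NULL
  for (ep in seq_len(config$epochs)) {
    ord <- sample(fit_idx)
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, length(ord), by = bs)) {
      bidx <- ord[start:min(start + bs - 1L, length(ord))]
      loss <- batch_loss_node(model, pairs[bidx], y_all[bidx], beta, config,
                              train = TRUE)
      ad_backward(loss)
      adam_step(opt)
      ep_loss <- ep_loss + as.numeric(loss$value) * length(bidx)
      ep_n <- ep_n + length(bidx)
    }
    hist_train[ep] <- ep_loss / ep_n
    if (length(val_idx)) {
      vl <- batch_loss_node(model, pairs[val_idx], y_all[val_idx], beta,
                            config, train = FALSE)
      hist_val[ep] <- as.numeric(vl$value)
    }
  }
  model$history <- list(train_loss = hist_train, val_loss = hist_val,
                        beta = beta, epochs = config$epochs)
  model
}

cv_fold_result <- function(fold_index, truth, pred, history = NULL,
                           test_idx = NULL) {
  cm <- confusion_metrics(truth, pred)
  c(list(fold_index = fold_index), cm,
    list(n_test = length(truth), history = history, test_idx = test_idx))
}

cv_report_from_folds <- function(folds, config, seed, label = NULL) {
  structure(list(
    folds = folds,
    mean_f1 = mean(vapply(folds, function(f) f$f1_overall, numeric(1))),
    mean_f1_pos = mean(vapply(folds, function(f) f$f1_pos, numeric(1))),
    mean_f1_neg = mean(vapply(folds, function(f) f$f1_neg, numeric(1))),
    config = config, seed = seed, label = label
  ), class = "tm_cv_report")
}

#' @export
print.tm_cv_report <- function(x, ...) {
  cat("<tm_cv_report>", if (!is.null(x$label)) x$label else "", "\n")
  cat(sprintf("  folds: %d  mean F1 (macro): %.4f  F1-Pos: %.4f  F1-Neg: %.4f\n",
              length(x$folds), x$mean_f1, x$mean_f1_pos, x$mean_f1_neg))
  invisible(x)
}

# shared CV engine: fit_fn(train_idx, fold_seed) -> fitted object;
# predict_fn(fitted, test_idx) -> 0/1 labels
cv_engine <- function(labels, k, seed, fit_fn, predict_fn, config,
                      label = NULL) {
  folds <- stratified_kfold(labels, k = k, seed = seed)
  res <- vector("list", k)
  for (f in seq_len(k)) {
    fold_seed <- (seed * 1000L + f) %% 2147483647L
    fitted <- fit_fn(folds[[f]]$train_idx, fold_seed)
    pred <- predict_fn(fitted, folds[[f]]$test_idx)
    hist <- if (!is.null(fitted$history)) fitted$history$train_loss else NULL
    res[[f]] <- cv_fold_result(f, labels[folds[[f]]$test_idx], pred,
                               history = hist,
                               test_idx = folds[[f]]$test_idx)
  }
  cv_report_from_folds(res, config, seed, label = label)
}

#' Stratified k-fold cross-validation of a pair-classification model
#'
#' A fresh model is built per fold (no parameter leakage; the WBCE weight
#' is derived from that fold's training split only), trained for the
#' configured epochs, and evaluated on the held-out fold. The headline
#' `mean_f1` is the macro-F1 (mean of the positive- and negative-class F1)
#' averaged over folds; both class F1s are always reported.
#'
#' @param model_factory Function `(seed) -> unfitted model`; called once
#'   per fold so each fold trains from a fresh initialization.
#' @param pairs List of labelled `tm_pair`s.
#' @param config A `train_config`.
#' @param label Optional report label.
#' @return A `tm_cv_report`.
#' @export
cross_validate <- function(model_factory, pairs, config = train_config(),
                           label = NULL) {
  labels <- vapply(pairs, function(p) p$label, numeric(1))
  cv_engine(
    labels, k = config$k_folds, seed = config$seed,
    fit_fn = function(train_idx, fold_seed) {
      m <- model_factory(fold_seed)
      fold_cfg <- config
      fold_cfg$seed <- fold_seed
      train(m, pairs[train_idx], fold_cfg)
    },
    predict_fn = function(fitted, test_idx) {
      model_predict(fitted, pairs[test_idx])
    },
    config = config, label = label
  )
}

#' Paired comparison of two cross-validation reports
#'
#' Requires the same fold structure (same k, same seed, identical test
#' index sets). Reports per-fold macro-F1 differences, the mean relative
#' gain `(mean_A - mean_B) / mean_B`, and a two-sided paired t-test
#' p-value on the per-fold F1 scores. With zero variance in the
#' differences (including identical reports) the p-value is 1, with a
#' warning.
#'
#' @param report_a,report_b `tm_cv_report` objects from the same folds.
#' @return List with `fold_diffs`, `mean_a`, `mean_b`, `mean_diff`,
#'   `relative_gain`, `p_value`.
#' @export
compare_models <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "tm_cv_report"),
            inherits(report_b, "tm_cv_report"))
  if (length(report_a$folds) != length(report_b$folds)) {
    stop("reports have different numbers of folds")
  }
  ta <- lapply(report_a$folds, function(f) sort(f$test_idx))
  tb <- lapply(report_b$folds, function(f) sort(f$test_idx))
  if (!identical(ta, tb)) {
    stop("reports were computed on different folds; rerun with a shared seed")
  }
  fa <- vapply(report_a$folds, function(f) f$f1_overall, numeric(1))
  fb <- vapply(report_b$folds, function(f) f$f1_overall, numeric(1))
  d <- fa - fb
  if (stats::sd(d) == 0) {
    warning("zero variance in per-fold differences; p-value set to 1")
    p <- 1
  } else {
    p <- stats::t.test(fa, fb, paired = TRUE)$p.value
  }
  ma <- mean(fa); mb <- mean(fb)
  list(fold_diffs = d, mean_a = ma, mean_b = mb, mean_diff = ma - mb,
       relative_gain = if (mb > 0) (ma - mb) / mb else NA_real_,
       p_value = p)
}
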