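test_that("stratified folds partition the data with balanced classes", {
  labels <- c(rep(1, 50), rep(0, 130))
  folds <- stratified_kfold(labels, k = 5, seed = 42)
  test_sets <- lapply(folds, function(f) f$test_idx)
  expect_equal(sort(unlist(test_sets)), 1:180)
  for (f in folds) {
    expect_length(f$test_idx, 36L)
    expect_equal(sum(labels[f$test_idx] == 1), 10L)
    expect_equal(length(intersect(f$train_idx, f$test_idx)), 0L)
  }
  # pairwise disjoint
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(test_sets[[i]], test_sets[[j]]), 0L)
  }
  expect_identical(stratified_kfold(labels, 5, seed = 42), folds)
  expect_false(identical(stratified_kfold(labels, 5, seed = 43), folds))
  expect_error(stratified_kfold(c(1, 1, 0, 0, 0), k = 3), "minority")
})

test_that("f1_score follows its definition with the zero convention", {
  expect_equal(f1_score(10, 0, 0), 1)
  expect_equal(f1_score(1, 1, 1), 0.5)
  expect_equal(f1_score(0, 0, 0), 0)
  expect_error(f1_score(-1, 0, 0), "non-negative")
})

test_that("training reduces the loss on separable synthetic data", {
  pairs <- tiny_coarse(n = 40, s = 1, seed = 6)
  set.seed(41)
  model <- siamese_model(build_encoder(encoder_config("mlp", 8)),
                         granularity = "coarse")
  fit <- train(model, pairs, train_config(epochs = 50, seed = 4))
  expect_length(fit$history$train_loss, 50L)
  expect_lt(fit$history$train_loss[50], fit$history$train_loss[1])
})

test_that("training validates inputs and is seed-reproducible", {
  pairs <- tiny_coarse(n = 20)
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  one_class <- Filter(function(p) p$label == 0, pairs)
  set.seed(42)
  m <- siamese_model(build_encoder(encoder_config("mlp", 8)),
                     granularity = "coarse")
  expect_error(train(m, one_class, train_config()), "both classes")
  fit_once <- function() {
    set.seed(7)
    mm <- siamese_model(build_encoder(encoder_config("mlp", 8)),
                        granularity = "coarse")
    train(mm, pairs, train_config(epochs = 8, seed = 7))
  }
  f1 <- fit_once(); f2 <- fit_once()
  v1 <- lapply(tm_ns$model_params(f1), function(p) p$value)
  v2 <- lapply(tm_ns$model_params(f2), function(p) p$value)
  expect_identical(v1, v2)
  expect_identical(f1$history, f2$history)
})

test_that("the WBCE weight comes from the training split only", {
  pairs <- tiny_coarse(n = 30, seed = 8)
  set.seed(43)
  m <- siamese_model(build_encoder(encoder_config("mlp", 8)),
                     loss = "wbce", granularity = "coarse")
  fit <- train(m, pairs, train_config(epochs = 2, seed = 5,
                                      val_fraction = 0))
  y <- vapply(pairs, function(p) p$label, numeric(1))
  expect_equal(fit$history$beta, sum(y == 0) / sum(y == 1))
})

test_that("cross-validation plumbing: oracle and constant predictors", {
  labels <- c(rep(1, 15), rep(0, 30))
  oracle <- tm_ns$cv_engine(labels, k = 5, seed = 9,
                            fit_fn = function(idx, s) list(),
                            predict_fn = function(f, idx) labels[idx],
                            config = list())
  expect_equal(oracle$mean_f1, 1)
  const_neg <- tm_ns$cv_engine(labels, k = 5, seed = 9,
                               fit_fn = function(idx, s) list(),
                               predict_fn = function(f, idx)
                                 rep(0L, length(idx)),
                               config = list())
  expect_equal(const_neg$mean_f1_pos, 0)
  for (f in const_neg$folds) expect_equal(f$f1_pos, 0)
  # the headline mean is the arithmetic mean of the fold scores
  expect_equal(oracle$mean_f1,
               mean(vapply(oracle$folds, function(f) f$f1_overall,
                           numeric(1))))
})

test_that("compare_models computes paired gains and handles degeneracy", {
  mk_report <- function(f1s, seed = 1) {
    labels <- c(rep(1, 10), rep(0, 10))
    folds <- stratified_kfold(labels, 5, seed)
    fl <- lapply(seq_along(f1s), function(i) {
      list(fold_index = i, tp = 1, fp = 0, tn = 1, fn = 0,
           f1_pos = f1s[i], f1_neg = f1s[i], f1_overall = f1s[i],
           n_test = 4, history = NULL, test_idx = folds[[i]]$test_idx)
    })
    tm_ns$cv_report_from_folds(fl, list(), seed)
  }
  a <- mk_report(c(0.9, 0.8, 0.85, 0.9, 0.95))
  b <- mk_report(c(0.6, 0.6, 0.7, 0.65, 0.6))
  cmp <- compare_models(a, b)
  expect_equal(cmp$relative_gain, (0.88 - 0.63) / 0.63, tolerance = 1e-12)
  expect_equal(cmp$mean_diff, 0.25, tolerance = 1e-12)
  expect_lt(cmp$p_value, 0.05)
  # identical reports: zero gain, p = 1 with a warning
  expect_warning(self_cmp <- compare_models(a, a), "zero variance")
  expect_equal(self_cmp$mean_diff, 0)
  expect_equal(self_cmp$p_value, 1)
  # constant positive shift: zero-variance warning, gain preserved
  shifted <- mk_report(c(0.9, 0.8, 0.85, 0.9, 0.95) - 0.1)
  expect_warning(cs <- compare_models(a, shifted), "zero variance")
  expect_equal(cs$mean_diff, 0.1, tolerance = 1e-12)
  # different folds are refused
  c_other <- mk_report(c(0.6, 0.6, 0.7, 0.65, 0.6), seed = 2)
  expect_error(compare_models(a, c_other), "different folds")
})
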