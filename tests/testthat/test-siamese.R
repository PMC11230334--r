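test_that("fusion algebra: identities, symmetry, widths, errors", {
  v <- c(1.5, -2, 0.25)
  z <- rep(0, 3)
  expect_equal(fuse(v, z, "add"), v)
  expect_equal(fuse(c(2, 3), c(4, 5), "multiply"), c(8, 15))
  expect_equal(fuse(v, v, "mean"), v)
  expect_length(fuse(rnorm(5), rnorm(5), "concat"), 10L)
  a <- rnorm(4); b <- rnorm(4)
  for (m in c("add", "multiply", "mean")) {
    expect_equal(fuse(a, b, m), fuse(b, a, m))
  }
  expect_false(isTRUE(all.equal(fuse(a, b, "concat"), fuse(b, a, "concat"))))
  expect_error(fuse(rnorm(3), rnorm(4), "add"), "equal lengths")
  expect_error(fuse(a, b, "hadamard"), "unknown fusion")
})

test_that("weight sharing is structural: one parameter set drives both branches", {
  pairs <- tiny_coarse()
  set.seed(21)
  model <- siamese_model(build_encoder(encoder_config("mlp", 8,
                                                      projection_dim = 6)),
                         granularity = "coarse")
  trained <- train(model, pairs, train_config(epochs = 5, seed = 2))
  # the same input encoded through the EHR branch and the criteria branch
  # is bit-identical, before and after training
  x <- pairs[[1]]$ehr_rep
  probe <- list(embedded_pair("probe", "coarse", x, x, 1))
  br <- tm_ns$siamese_branch_nodes(trained, probe)
  expect_identical(br$ehr$value, br$crit$value)
  # single storage: the branch parameters are the same environments
  expect_identical(trained$encoder$params, model$encoder$params)
})

test_that("forward probabilities live strictly inside (0, 1)", {
  pairs <- tiny_coarse()
  set.seed(22)
  model <- siamese_model(build_encoder(encoder_config("mlp", 8)),
                         granularity = "coarse")
  p <- forward_pair(model, pairs)
  expect_true(all(p > 0 & p < 1))
  # zeroed head gives exactly 0.5 for every pair
  model$head_W$value[] <- 0
  model$head_b$value[] <- 0
  expect_equal(forward_pair(model, pairs), rep(0.5, length(pairs)))
})

test_that("early fusion concatenates EHR-then-criteria", {
  pc <- embedded_pair("p", "coarse", 1:16, 17:32, 1)
  expect_equal(early_fusion_input(pc), c(1:16, 17:32))
  pf <- embedded_pair("p", "fine", matrix(1, 12, 8), matrix(2, 9, 8), 0)
  ef <- early_fusion_input(pf)
  expect_equal(dim(ef), c(21L, 8L))
  expect_equal(ef[1, 1], 1); expect_equal(ef[13, 1], 2)
  # order is fixed: swapping the inputs changes the result
  swapped <- early_fusion_input(embedded_pair("p", "coarse", 17:32, 1:16, 1))
  expect_false(isTRUE(all.equal(early_fusion_input(pc), swapped)))
})

test_that("predict_label thresholds with ties resolving to positive", {
  expect_equal(predict_label(0.7, 0.5), 1L)
  expect_equal(predict_label(0.5, 0.5), 1L)
  expect_equal(predict_label(0.2, 0.5), 0L)
  expect_equal(predict_label(c(0.1, 0.9)), c(0L, 1L))
  expect_error(predict_label(0.5, 1.5), "threshold")
})

test_that("contrastive prediction thresholds cosine similarity monotonically", {
  set.seed(23)
  enc <- build_encoder(encoder_config("mlp", 8, projection_dim = 4))
  model <- siamese_model(enc, loss = "contrastive", granularity = "coarse")
  pairs <- tiny_coarse()
  d <- pair_similarity(model, pairs)
  expect_true(all(d >= -1 - 1e-9 & d <= 1 + 1e-9))
  # identical representations reach d = 1, labelled 1 at any threshold <= 1
  same <- embedded_pair("s", "coarse", pairs[[1]]$ehr_rep,
                        pairs[[1]]$ehr_rep, 1)
  expect_equal(pair_similarity(model, same), 1, tolerance = 1e-9)
  expect_equal(predict_contrastive(model, same, sim_threshold = 1), 1L)
  # decisions are monotone in d_w
  pred <- predict_contrastive(model, pairs, sim_threshold = 0.3)
  expect_equal(pred, as.integer(d >= 0.3))
  expect_true(all(predict_contrastive(model, pairs, sim_threshold = -1.1)
                  == 1L))
  # BCE-trained models refuse the contrastive decision rule
  mb <- siamese_model(build_encoder(encoder_config("mlp", 8)),
                      loss = "wbce", granularity = "coarse")
  expect_error(predict_contrastive(mb, pairs), "contrastive")
})

test_that("gradient flows to the shared encoder from both branches", {
  set.seed(24)
  enc <- build_encoder(encoder_config("mlp", 8, projection_dim = 4))
  model <- siamese_model(enc, fusion = "add", loss = "bce",
                         granularity = "coarse")
  # one branch zeroed out: a step still updates the shared encoder
  pr <- embedded_pair("p", "coarse", rep(1e-8, 8), rnorm(8), 1)
  before <- lapply(tm_ns$model_params(model), function(p) p$value)
  trained <- train(model, list(pr, embedded_pair("q", "coarse", rnorm(8),
                                                 rnorm(8), 0)),
                   train_config(epochs = 1, seed = 3, val_fraction = 0))
  after <- lapply(tm_ns$model_params(trained), function(p) p$value)
  changed <- mapply(function(a, b) !isTRUE(all.equal(a, b)), before, after)
  expect_true(any(changed[seq_len(length(changed) - 2L)])) # encoder params
})

test_that("granularity and encoder family must agree", {
  expect_error(siamese_model(build_encoder(encoder_config("lstm", 8)),
                             granularity = "coarse"),
               "coarse")
  expect_error(siamese_model(build_encoder(encoder_config("mlp", 8)),
                             granularity = "fine"),
               "fine")
  expect_error(single_encoder_model(build_encoder(encoder_config("mlp", 8)),
                                    loss = "contrastive",
                                    granularity = "coarse"),
               "contrastive")
  set.seed(25)
  m <- siamese_model(build_encoder(encoder_config("mlp", 8)),
                     granularity = "coarse")
  expect_error(forward_pair(m, tiny_fine(n = 4)), "granularity")
})
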