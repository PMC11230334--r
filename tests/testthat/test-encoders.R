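test_that("encoder configs validate families and dimensions", {
  expect_error(encoder_config("transformer", input_dim = 8),
               "unknown encoder family")
  cfg <- encoder_config("lstm", input_dim = 8)
  expect_equal(cfg$hidden_units, 50L)
  expect_equal(cfg$dropout_rate, 0.5)
  expect_equal(encoder_config("mlp", input_dim = 8)$dropout_rate, 0.1)
  expect_error(encoder_config("mlp", input_dim = 8, dropout_rate = 1),
               "dropout")
})

test_that("output dimensions follow the family contracts", {
  expect_equal(build_encoder(encoder_config("lstm", 8), seed = 1)$output_dim,
               50L)
  expect_equal(build_encoder(encoder_config("bilstm", 8), seed = 1)$output_dim,
               100L)
  expect_equal(build_encoder(encoder_config("bigru", 8, hidden_units = 7),
                             seed = 1)$output_dim, 14L)
  expect_equal(build_encoder(encoder_config("mlp", 8, projection_dim = 64),
                             seed = 1)$output_dim, 64L)
  expect_equal(build_encoder(encoder_config("cnn", 8, cnn_filters = 10),
                             seed = 1)$output_dim, 10L)
  expect_equal(build_encoder(encoder_config("cnn_lstm", 8,
                                            hidden_units = 9),
                             seed = 1)$output_dim, 9L)
})

test_that("encode is deterministic in evaluation mode and shape-correct", {
  set.seed(2)
  x <- matrix(rnorm(40), 5, 8)
  for (fam in c("lstm", "gru", "bilstm", "bigru", "lstm_att", "cnn",
                "cnn_lstm")) {
    enc <- build_encoder(encoder_config(fam, 8, hidden_units = 6,
                                        cnn_filters = 4, kernel_size = 2),
                         seed = 3)
    v1 <- encode(enc, x)
    v2 <- encode(enc, x)
    expect_identical(v1, v2)
    expect_length(v1, enc$output_dim)
    expect_true(all(is.finite(v1)))
  }
  # bounded inputs give finite outputs
  xb <- matrix(runif(40, -10, 10), 5, 8)
  enc <- build_encoder(encoder_config("lstm", 8), seed = 4)
  expect_true(all(is.finite(encode(enc, xb))))
})

test_that("recurrent encoders handle a length-1 sequence", {
  for (fam in c("lstm", "gru", "bilstm", "bigru", "lstm_att",
                "bigru_att")) {
    enc <- build_encoder(encoder_config(fam, 8, hidden_units = 4), seed = 5)
    v <- encode(enc, matrix(rnorm(8), 1, 8))
    expect_length(v, enc$output_dim)
    expect_true(all(is.finite(v)))
  }
})

test_that("MLP rejects token-sequence input; sequence families reject D mismatch", {
  mlp <- build_encoder(encoder_config("mlp", 8), seed = 6)
  expect_error(encode(mlp, matrix(rnorm(24), 3, 8)), "sequence")
  expect_error(encode(mlp, rnorm(5)), "does not match")
  lstm <- build_encoder(encoder_config("lstm", 8), seed = 6)
  expect_error(encode(lstm, matrix(rnorm(15), 3, 5)), "does not match")
})

test_that("self-attention pooling is a proper convex combination", {
  h <- matrix(rnorm(12), 3, 4)
  out <- self_attention_pool(h)
  expect_equal(sum(out$weights), 1, tolerance = 1e-6)
  expect_true(all(out$weights >= 0))
  # L = 1: output equals the single hidden state
  one <- self_attention_pool(h[1, , drop = FALSE])
  expect_equal(one$pooled, h[1, ])
  # identical states: output equals that state regardless of weights
  same <- matrix(rep(h[2, ], each = 5), 5, 4)
  expect_equal(self_attention_pool(same)$pooled, h[2, ],
               tolerance = 1e-10)
  expect_error(self_attention_pool(matrix(numeric(0), 0, 4)))
})

test_that("attention weights inside the encoders sum to 1 per sequence", {
  pairs <- tiny_fine(n = 6)
  for (fam in c("lstm_att", "gru_att", "bilstm_att", "bigru_att")) {
    enc <- build_encoder(encoder_config(fam, 8, hidden_units = 4,
                                        dropout_rate = 0), seed = 7)
    sb <- tm_ns$seq_batch(lapply(pairs, function(p) p$ehr_rep))
    out <- tm_ns$encoder_forward(enc, sb, train = FALSE)
    w <- attr(out, "attention")
    expect_equal(unname(rowSums(w)), rep(1, length(pairs)),
                 tolerance = 1e-6)
    expect_true(all(w >= 0))
    # padded positions carry zero attention
    expect_true(all(w[sb$mask == 0] == 0))
  }
})

test_that("cnn_extract pools convolution features over valid positions", {
  # constant rows and an averaging filter: output independent of length
  d <- 4; w <- 3; row <- c(1, -2, 0.5, 3)
  filt <- matrix(0, w * d, 1)
  filt[, 1] <- rep(1 / w, w * d) # averages the window
  for (L in c(3, 5, 9)) {
    x <- matrix(rep(row, each = L), L, d)
    expect_equal(cnn_extract(x, filt, kernel_size = w), sum(row),
                 tolerance = 1e-12)
  }
  # L = w: mean over exactly one position
  set.seed(8)
  x <- matrix(rnorm(12), 3, 4)
  f2 <- matrix(rnorm(24), 12, 2)
  win <- as.vector(t(x))
  expect_equal(cnn_extract(x, f2, kernel_size = 3), as.vector(win %*% f2))
  # shape contract and minimum-length error naming the bound
  expect_length(cnn_extract(matrix(rnorm(40), 10, 4), n_filters = 7,
                            kernel_size = 3), 7L)
  expect_error(cnn_extract(matrix(rnorm(8), 2, 4), kernel_size = 3),
               "minimum length 3")
})

test_that("encoder configs round-trip through YAML", {
  cfg <- encoder_config("bigru_att", input_dim = 32, hidden_units = 20,
                        dropout_rate = 0.3)
  cfg2 <- encoder_config_from_yaml(text = encoder_config_to_yaml(cfg))
  expect_equal(cfg, cfg2)
})
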