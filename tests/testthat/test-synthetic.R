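test_that("coarse generation matches the cohort shape exactly", {
  pairs <- generate_coarse(synthetic_spec(seed = 51))
  expect_length(pairs, 180L)
  y <- vapply(pairs, function(p) p$label, numeric(1))
  expect_equal(sum(y == 1), 50L)
  expect_equal(sum(y == 0), 130L)
  expect_identical(generate_coarse(synthetic_spec(seed = 51)), pairs)
  expect_false(identical(generate_coarse(synthetic_spec(seed = 52)), pairs))
  expect_error(synthetic_spec(pos_fraction = 1.5), "pos_fraction")
  expect_error(synthetic_spec(embed_dim = 1), "embed_dim")
  expect_error(synthetic_spec(separation = 1.2), "separation")
})

test_that("full coupling with vanishing noise aligns positive pairs", {
  pairs <- generate_coarse(synthetic_spec(n_pairs = 60, pos_fraction = 0.5,
                                          separation = 1, sigma = 1e-4,
                                          seed = 53))
  cs <- vapply(pairs, function(p)
    cosine_similarity(p$ehr_rep, p$criteria_rep), numeric(1))
  y <- vapply(pairs, function(p) p$label, numeric(1))
  expect_gt(min(cs[y == 1]), 0.999)
  expect_lt(mean(abs(cs[y == 0])), 0.5)
})

test_that("fine generation respects token-length bounds and centroids", {
  spec <- synthetic_spec(n_pairs = 30, token_length_range = c(5, 30),
                         seed = 54)
  pairs <- generate_fine(spec)
  lens <- unlist(lapply(pairs, function(p)
    c(nrow(p$ehr_rep), nrow(p$criteria_rep))))
  expect_true(all(lens >= 5 & lens <= 30))
  expect_identical(generate_fine(spec), pairs)
  # law of large numbers: the token-row mean approaches the centroid
  long <- generate_fine(synthetic_spec(n_pairs = 2, pos_fraction = 0.5,
                                       embed_dim = 16,
                                       token_length_range = c(1e4, 1e4),
                                       sigma = 0.1, seed = 55))
  coarse <- generate_coarse(synthetic_spec(n_pairs = 2, pos_fraction = 0.5,
                                           embed_dim = 16, sigma = 0.1,
                                           seed = 55))
  for (i in 1:2) {
    expect_lt(max(abs(colMeans(long[[i]]$ehr_rep) - coarse[[i]]$ehr_rep)),
              0.02)
  }
})

test_that("at zero separation positive and negative similarities coincide", {
  ps <- numeric(20)
  for (s in 1:20) {
    pairs <- generate_coarse(synthetic_spec(n_pairs = 80,
                                            pos_fraction = 0.5,
                                            separation = 0, seed = 100 + s))
    cs <- vapply(pairs, function(p)
      cosine_similarity(p$ehr_rep, p$criteria_rep), numeric(1))
    y <- vapply(pairs, function(p) p$label, numeric(1))
    ps[s] <- stats::wilcox.test(cs[y == 1], cs[y == 0])$p.value
  }
  # no seed shows a real positive/negative difference
  expect_gt(min(stats::p.adjust(ps, "holm")), 0.01)
})

test_that("structured labels are the AND/NOT formula over rule features", {
  rules <- default_rule_set()
  ds <- generate_structured(synthetic_spec(n_pairs = 90,
                                           pos_fraction = 1 / 3,
                                           label_noise = 0, seed = 56),
                            rules)
  recomputed <- vapply(seq_along(ds$records), function(i)
    tm_ns$rules_label(ds$features[i, ], rules), integer(1))
  expect_equal(recomputed, ds$labels)
  expect_equal(sum(ds$labels == 1), 30L)
  ds2 <- generate_structured(synthetic_spec(n_pairs = 90,
                                            pos_fraction = 1 / 3,
                                            label_noise = 0, seed = 56),
                             rules)
  expect_identical(ds$features, ds2$features)
})

test_that("label noise flips at the configured binomial rate", {
  ds <- generate_structured(synthetic_spec(n_pairs = 2000,
                                           pos_fraction = 0.3,
                                           label_noise = 0.2, seed = 57))
  flip_rate <- mean(ds$labels != ds$clean_labels)
  se <- sqrt(0.2 * 0.8 / 2000)
  expect_lt(abs(flip_rate - 0.2), 3 * se)
})

test_that("unsatisfiable rule sets are detected", {
  contradictory <- list(
    criterion_rule("a", "inclusion", "age_range", lo = 60, hi = 70),
    criterion_rule("b", "exclusion", "age_range", lo = 0, hi = 200)
  )
  expect_error(
    generate_structured(synthetic_spec(n_pairs = 20, pos_fraction = 0.5,
                                       seed = 58), contradictory),
    "unsatisfiable")
})

test_that("generated data round-trips through the cache bit-exactly", {
  pairs <- generate_coarse(synthetic_spec(n_pairs = 12, seed = 59))
  path <- tempfile(fileext = ".rds")
  save_embedding_cache(pairs, path, spec = list(seed = 59))
  back <- load_embedding_cache(path)
  attr(back, "spec") <- NULL
  expect_identical(back, pairs)
  fine <- generate_fine(synthetic_spec(n_pairs = 6, seed = 60))
  path2 <- tempfile(fileext = ".rds")
  save_embedding_cache(fine, path2)
  back2 <- load_embedding_cache(path2)
  attr(back2, "spec") <- NULL
  expect_identical(back2, fine)
})
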