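# Shared fixtures: tiny cohorts and a finite-difference gradient checker.

tm_ns <- asNamespace("trialmatch")

tiny_coarse <- function(n = 20, s = 0.8, seed = 3, d = 8) {
  generate_coarse(synthetic_spec(n_pairs = n, pos_fraction = 0.4,
                                 embed_dim = d, separation = s, seed = seed))
}

tiny_fine <- function(n = 10, s = 0.8, seed = 4, d = 8, lens = c(3, 6)) {
  generate_fine(synthetic_spec(n_pairs = n, pos_fraction = 0.4,
                               embed_dim = d, separation = s,
                               token_length_range = lens, seed = seed))
}

# max |analytic - central difference| over a sample of coordinates of
# every parameter, for an arbitrary tape-built scalar loss. Central
# differences are meaningless where the loss is locally non-smooth (a
# ReLU or hinge kink between the two probe points), so coordinates whose
# second-difference probe reveals a kink at the eps scale are skipped:
# smooth coordinates have |up + dn - 2 c| ~ f'' eps^2 (~1e-10), a
# crossed kink ~ |slope jump| * eps (~1e-5).
gradcheck <- function(params, build_loss, n_coords = 2, eps = 1e-5,
                      seed = 1) {
  set.seed(seed)
  tm_ns$ad_zero_grad(params)
  tm_ns$ad_backward(build_loss())
  center <- as.numeric(build_loss()$value)
  maxerr <- 0
  for (p in params) {
    g <- p$grad
    if (is.null(g)) g <- p$value * 0
    idx <- sample(length(p$value), min(n_coords, length(p$value)))
    for (i in idx) {
      orig <- p$value[i]
      p$value[i] <- orig + eps
      up <- as.numeric(build_loss()$value)
      p$value[i] <- orig - eps
      dn <- as.numeric(build_loss()$value)
      p$value[i] <- orig
      if (abs(up + dn - 2 * center) > 1e-8) next
      maxerr <- max(maxerr, abs((up - dn) / (2 * eps) - g[i]))
    }
  }
  tm_ns$ad_zero_grad(params)
  maxerr
}

# macro-F1 of Bernoulli(0.5) guessing on an n_pos/n_neg cohort
random_guess_f1 <- function(n_pos, n_neg, seed) {
  set.seed(seed)
  truth <- c(rep(1, n_pos), rep(0, n_neg))
  pred <- stats::rbinom(n_pos + n_neg, 1, 0.5)
  cm <- tm_ns$confusion_metrics(truth, pred)
  cm$f1_overall
}
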