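# Synthetic cohort generator.
#
# Emulates the statistical structure the matching task assumes, at desk
# scale and fully offline: (a) coarse document-level embedded pairs whose
# EHR-criteria semantic coupling carries the eligibility label, (b) fine
# token-level embedding sequences of variable length, and (c) structured
# event records paired with criterion rules for the rule-based baseline.
# The default cohort shape mirrors a small single-site trial-screening
# study: 180 patients, 50 eligible ("success") and 130 not ("fail").
#
# Positive pairs are coupled to the trial's latent direction t rather than
# being copies of the criteria vector, so eligibility is a latent semantic
# relation, not surface similarity. The separation parameter s in [0, 1]
# controls that coupling: s = 0 means no signal, s = 1 full alignment.

#' Synthetic-cohort specification
#'
#' @param n_pairs Number of patient-trial pairs (default 180).
#' @param pos_fraction Fraction of eligible pairs (default 50/180).
#' @param embed_dim Embedding dimension D (default 64, >= 2).
#' @param separation Coupling strength s in `[0, 1]` between the EHR
#'   representation and the trial's latent direction for eligible pairs.
#' @param sigma Spherical Gaussian noise scale (default 0.1).
#' @param token_length_range Length-2 integer range of token counts per
#'   document (fine mode).
#' @param label_noise Probability in `[0, 0.5]` of flipping a label; at
#'   0.5 the labels carry no information (useful as a negative control).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pairs = 180L, pos_fraction = 50 / 180,
                           embed_dim = 64L, separation = 0.9, sigma = 0.1,
                           token_length_range = c(5L, 30L),
                           label_noise = 0, seed = 1L) {
  if (pos_fraction <= 0 || pos_fraction >= 1) {
    stop("pos_fraction must lie strictly between 0 and 1")
  }
  if (embed_dim < 2L) stop("embed_dim must be >= 2")
  if (separation < 0 || separation > 1) stop("separation must lie in [0, 1]")
  if (label_noise < 0 || label_noise > 0.5) {
    stop("label_noise must lie in [0, 0.5]")
  }
  if (length(token_length_range) != 2L ||
      token_length_range[1] > token_length_range[2] ||
      token_length_range[1] < 1L) {
    stop("token_length_range must be a valid (lo, hi) with lo >= 1")
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 pos_fraction = pos_fraction,
                 embed_dim = as.integer(embed_dim),
                 separation = separation, sigma = sigma,
                 token_length_range = as.integer(token_length_range),
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

unit_vec <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

# latent centroids for one cohort: per-pair EHR and criteria document
# vectors plus labels (before noise is added to tokens in fine mode)
synthetic_centroids <- function(spec) {
  d <- spec$embed_dim
  s <- spec$separation
  n <- spec$n_pairs
  n_pos <- round(n * spec$pos_fraction)
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  trial_dir <- unit_vec(d)
  ehr <- matrix(0, n, d); crit <- matrix(0, n, d)
  for (i in seq_len(n)) {
    crit[i, ] <- trial_dir + stats::rnorm(d, sd = spec$sigma)
    g <- unit_vec(d)
    ehr[i, ] <- if (labels[i] == 1L) {
      s * trial_dir + (1 - s) * g + stats::rnorm(d, sd = spec$sigma)
    } else {
      g + stats::rnorm(d, sd = spec$sigma)
    }
  }
  if (spec$label_noise > 0) {
    flip <- stats::rbinom(n, 1L, spec$label_noise) == 1L
    labels[flip] <- 1L - labels[flip]
  }
  list(ehr = ehr, crit = crit, labels = labels, trial_dir = trial_dir)
}

#' Generate a coarse-grained synthetic cohort
#'
#' Document-level embedded pairs. Criteria vectors sit near the trial's
#' latent direction; eligible EHR vectors are pulled toward it with
#' strength `separation`, ineligible ones are independent random
#' directions. Class counts match `round(n_pairs * pos_fraction)` exactly.
#'
#' @param spec A `synthetic_spec`.
#' @return List of labelled coarse `tm_pair`s.
#' @export
generate_coarse <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    cs <- synthetic_centroids(spec)
    lapply(seq_len(spec$n_pairs), function(i) {
      embedded_pair(sprintf("pair_%03d", i), "coarse",
                    cs$ehr[i, ], cs$crit[i, ], cs$labels[i])
    })
  })
}

#' Generate a fine-grained synthetic cohort
#'
#' Token-level pairs: each document's token rows are its latent centroid
#' (built as in [generate_coarse()]) plus per-token Gaussian noise; token
#' counts are drawn uniformly from `token_length_range`.
#'
#' @param spec A `synthetic_spec`.
#' @return List of labelled fine `tm_pair`s.
#' @export
generate_fine <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lr <- spec$token_length_range
  with_local_seed(spec$seed, {
    cs <- synthetic_centroids(spec)
    d <- spec$embed_dim
    lapply(seq_len(spec$n_pairs), function(i) {
      le <- sample(lr[1]:lr[2], 1L)
      lc <- sample(lr[1]:lr[2], 1L)
      ehr_m <- matrix(rep(cs$ehr[i, ], each = le), le, d) +
        matrix(stats::rnorm(le * d, sd = spec$sigma), le, d)
      crit_m <- matrix(rep(cs$crit[i, ], each = lc), lc, d) +
        matrix(stats::rnorm(lc * d, sd = spec$sigma), lc, d)
      embedded_pair(sprintf("pair_%03d", i), "fine", ehr_m, crit_m,
                    cs$labels[i])
    })
  })
}

#' Default synthetic eligibility rule set
#'
#' A compact cognitive-disorder-trial flavoured rule set: age window,
#' a qualifying dementia diagnosis, a minimum cognitive-score lab value,
#' and two exclusions (a disqualifying comorbid diagnosis and a
#' disqualifying medication).
#'
#' @return List of `tm_rule`s.
#' @export
default_rule_set <- function() {
  list(
    criterion_rule("incl_age", "inclusion", "age_range", lo = 55, hi = 90),
    criterion_rule("incl_dx", "inclusion", "has_code",
                   event_type = "diagnosis", code = "G30"),
    criterion_rule("incl_mmse", "inclusion", "numeric_threshold",
                   event_type = "lab", code = "MMSE", op = ">=", bound = 16),
    criterion_rule("excl_dx", "exclusion", "has_code",
                   event_type = "diagnosis", code = "F03"),
    criterion_rule("excl_med", "exclusion", "has_code",
                   event_type = "medication", code = "anticoagulant")
  )
}

rule_codes <- function(rules) {
  has <- Filter(function(r) r$kind == "has_code", rules)
  num <- Filter(function(r) r$kind == "numeric_threshold", rules)
  list(has = has, num = num)
}

random_record <- function(id, rules) {
  rc <- rule_codes(rules)
  ev <- list()
  for (r in rc$has) {
    if (stats::runif(1) < 0.5) {
      ev[[length(ev) + 1L]] <- data.frame(event_type = r$event_type,
                                          code = r$code, value = NA_real_)
    }
  }
  for (r in rc$num) {
    if (stats::runif(1) < 0.8) {
      ev[[length(ev) + 1L]] <- data.frame(
        event_type = r$event_type, code = r$code,
        value = stats::runif(1, r$bound - 10, r$bound + 10))
    }
  }
  # distractor events outside the rule vocabulary
  nd <- sample(0:3, 1L)
  if (nd > 0) {
    ev[[length(ev) + 1L]] <- data.frame(
      event_type = sample(EVENT_TYPES, nd, replace = TRUE),
      code = paste0("X", sample(100:999, nd)), value = NA_real_)
  }
  events <- if (length(ev)) do.call(rbind, ev) else NULL
  structured_record(id, events, age = sample(40:95, 1L),
                    gender = sample(c("F", "M"), 1L))
}

# construct a record aimed at satisfying all inclusion and no exclusion
# rule; the label is still computed honestly from the rules afterwards
targeted_positive_record <- function(id, rules) {
  pol <- vapply(rules, function(r) r$polarity, character(1))
  age_ok <- Filter(function(a) {
    all(vapply(rules, function(r) {
      if (r$kind != "age_range") return(TRUE)
      sat <- a >= r$lo && a <= r$hi
      if (r$polarity == "inclusion") sat else !sat
    }, logical(1)))
  }, 18:100)
  age <- if (length(age_ok)) sample(unlist(age_ok), 1L) else sample(40:95, 1L)
  gen_ok <- Filter(function(g) {
    all(vapply(rules, function(r) {
      if (r$kind != "gender_is") return(TRUE)
      sat <- identical(g, r$gender)
      if (r$polarity == "inclusion") sat else !sat
    }, logical(1)))
  }, c("F", "M"))
  gender <- if (length(gen_ok)) sample(unlist(gen_ok), 1L) else
    sample(c("F", "M"), 1L)
  ev <- list()
  rc <- rule_codes(rules)
  for (r in rc$has) {
    if (r$polarity == "inclusion") {
      ev[[length(ev) + 1L]] <- data.frame(event_type = r$event_type,
                                          code = r$code, value = NA_real_)
    }
  }
  # per numeric code, find a value satisfying every inclusion and no
  # exclusion threshold on that code
  num_keys <- unique(vapply(rc$num, function(r)
    paste(r$event_type, r$code, sep = "\r"), character(1)))
  for (key in num_keys) {
    parts <- strsplit(key, "\r")[[1]]
    krules <- Filter(function(r) r$event_type == parts[1] &&
                       r$code == parts[2], rc$num)
    bounds <- vapply(krules, function(r) r$bound, numeric(1))
    cand <- sort(unique(c(outer(bounds, c(-5, -1, -0.5, 0, 0.5, 1, 5), "+"))))
    ok <- Filter(function(v) {
      all(vapply(krules, function(r) {
        cmp <- switch(r$op, "<" = `<`, "<=" = `<=`, ">" = `>`, ">=" = `>=`)
        sat <- cmp(v, r$bound)
        if (r$polarity == "inclusion") sat else !sat
      }, logical(1)))
    }, cand)
    incl_here <- any(vapply(krules, function(r)
      r$polarity == "inclusion", logical(1)))
    if (length(ok)) {
      ev[[length(ev) + 1L]] <- data.frame(event_type = parts[1],
                                          code = parts[2],
                                          value = sample(unlist(ok), 1L))
    } else if (!incl_here) {
      NULL # omit the event entirely; exclusion thresholds then fail
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else NULL
  structured_record(id, events, age = age, gender = gender)
}

#' Generate structured records with rule-determined labels
#'
#' Samples patient records such that the noiseless label is exactly
#' "all inclusion rules satisfied AND no exclusion rule satisfied", then
#' flips labels with probability `label_noise`. Class balance is steered
#' toward `pos_fraction` by rejection sampling; an unsatisfiable rule set
#' raises an error after a bounded number of attempts.
#'
#' @param spec A `synthetic_spec`.
#' @param rules Non-empty list of `tm_rule`s (default [default_rule_set()]).
#' @return List with `records` (list of `tm_record`), `labels` (0/1 after
#'   noise), `clean_labels` (before noise), `features` (n x R matrix).
#' @export
generate_structured <- function(spec, rules = default_rule_set()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(rules) == 0L) stop("the rule list must be non-empty")
  n <- spec$n_pairs
  n_pos <- round(n * spec$pos_fraction)
  n_neg <- n - n_pos
  with_local_seed(spec$seed + 7L, {
    pos <- list(); neg <- list()
    attempts <- 0L
    max_attempts <- 400L * n
    while ((length(pos) < n_pos || length(neg) < n_neg) &&
           attempts < max_attempts) {
      attempts <- attempts + 1L
      id <- sprintf("pt_%05d", attempts)
      rec <- if (length(pos) < n_pos && attempts %% 2L == 0L) {
        targeted_positive_record(id, rules)
      } else {
        random_record(id, rules)
      }
      lab <- rules_label(rule_feature_vector(rec, rules), rules)
      if (lab == 1L && length(pos) < n_pos) {
        pos[[length(pos) + 1L]] <- rec
      } else if (lab == 0L && length(neg) < n_neg) {
        neg[[length(neg) + 1L]] <- rec
      }
    }
    if (length(pos) < n_pos) {
      stop("could not generate eligible records; the rule set appears ",
           "unsatisfiable")
    }
    if (length(neg) < n_neg) {
      stop("could not generate ineligible records; the rule set appears ",
           "always satisfied")
    }
    ord <- sample(n)
    records <- c(pos, neg)[ord]
    clean <- c(rep(1L, n_pos), rep(0L, n_neg))[ord]
    labels <- clean
    if (spec$label_noise > 0) {
      flip <- stats::rbinom(n, 1L, spec$label_noise) == 1L
      labels[flip] <- 1L - labels[flip]
    }
    feats <- t(vapply(records, rule_feature_vector, rules = rules,
                      integer(length(rules))))
    list(records = records, labels = labels, clean_labels = clean,
         features = feats)
  })
}
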