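# Rule-based baseline: criterion predicates over structured patient
# records (the portable stand-in for institution-specific SQL cohort
# queries), binary rule-feature extraction, and classic-ML classifiers
# (logistic regression, SVM, random forest) evaluated under the same
# stratified folds and metrics as the neural models.

EVENT_TYPES <- c("diagnosis", "medication", "allergy", "family_history",
                 "lab", "admission")

#' Structured patient record
#'
#' @param patient_id Identifier.
#' @param events Data frame with columns `event_type` (one of diagnosis,
#'   medication, allergy, family_history, lab, admission), `code`
#'   (character), and optional `value` (numeric, e.g. a lab result).
#' @param age Age in years (>= 0).
#' @param gender Categorical gender code.
#' @return A `tm_record`.
#' @export
structured_record <- function(patient_id, events, age, gender) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(event_type = character(0), code = character(0),
                         value = numeric(0))
  }
  if (!"value" %in% names(events)) events$value <- NA_real_
  stopifnot(all(c("event_type", "code") %in% names(events)))
  bad <- setdiff(unique(events$event_type), EVENT_TYPES)
  if (length(bad)) {
    stop("unknown event_type(s): ", paste(bad, collapse = ", "))
  }
  if (age < 0) stop("age must be >= 0")
  structure(list(patient_id = patient_id, events = events,
                 age = age, gender = gender),
            class = "tm_record")
}

#' Criterion rule
#'
#' A predicate over a structured record, mirroring one eligibility
#' statement. Supported kinds: `has_code(event_type, code)`,
#' `numeric_threshold(event_type, code, op, bound)` with op one of
#' `<, <=, >, >=`, `age_range(lo, hi)` (inclusive), `gender_is(g)`.
#'
#' @param rule_id Identifier.
#' @param polarity `"inclusion"` or `"exclusion"`. Exclusion does not
#'   negate the predicate at feature-extraction time; the classifier sees
#'   raw satisfied/not-satisfied indicators.
#' @param kind Predicate kind.
#' @param event_type,code,op,bound,lo,hi,gender Predicate parameters, as
#'   required by the kind.
#' @return A `tm_rule`.
#' @export
criterion_rule <- function(rule_id, polarity = c("inclusion", "exclusion"),
                           kind = c("has_code", "numeric_threshold",
                                    "age_range", "gender_is"),
                           event_type = NULL, code = NULL, op = NULL,
                           bound = NULL, lo = NULL, hi = NULL,
                           gender = NULL) {
  polarity <- match.arg(polarity)
  kind <- match.arg(kind)
  if (kind %in% c("has_code", "numeric_threshold")) {
    if (is.null(event_type) || is.null(code)) {
      stop(kind, " requires event_type and code")
    }
    if (!event_type %in% EVENT_TYPES) {
      stop("unknown event_type '", event_type, "'")
    }
  }
  if (kind == "numeric_threshold") {
    if (is.null(op) || is.null(bound)) {
      stop("numeric_threshold requires op and bound")
    }
    if (!op %in% c("<", "<=", ">", ">=")) stop("op must be <, <=, > or >=")
  }
  if (kind == "age_range" && (is.null(lo) || is.null(hi))) {
    stop("age_range requires lo and hi")
  }
  if (kind == "gender_is" && is.null(gender)) {
    stop("gender_is requires gender")
  }
  structure(list(rule_id = rule_id, polarity = polarity, kind = kind,
                 event_type = event_type, code = code, op = op,
                 bound = bound, lo = lo, hi = hi, gender = gender),
            class = "tm_rule")
}

#' Evaluate one criterion rule on a record
#'
#' Pure predicate evaluation; exclusion polarity is NOT negated here.
#'
#' @param record A `tm_record`.
#' @param rule A `tm_rule`.
#' @return `TRUE` iff the predicate holds.
#' @export
evaluate_rule <- function(record, rule) {
  stopifnot(inherits(record, "tm_record"), inherits(rule, "tm_rule"))
  ev <- record$events
  switch(rule$kind,
    has_code = any(ev$event_type == rule$event_type & ev$code == rule$code),
    numeric_threshold = {
      vals <- ev$value[ev$event_type == rule$event_type &
                         ev$code == rule$code]
      vals <- vals[!is.na(vals)]
      if (!length(vals)) return(FALSE)
      cmp <- switch(rule$op, "<" = `<`, "<=" = `<=`,
                    ">" = `>`, ">=" = `>=`)
      any(cmp(vals, rule$bound))
    },
    age_range = record$age >= rule$lo && record$age <= rule$hi,
    gender_is = identical(record$gender, rule$gender)
  )
}

#' Binary rule-feature vector of a record
#'
#' @param record A `tm_record`.
#' @param rules Non-empty ordered list of `tm_rule`s.
#' @return 0/1 integer vector, one component per rule, in rule order.
#' @export
rule_feature_vector <- function(record, rules) {
  if (length(rules) == 0L) stop("the rule list must be non-empty")
  vapply(rules, function(r) as.integer(evaluate_rule(record, r)), integer(1))
}

rules_label <- function(features, rules) {
  pol <- vapply(rules, function(r) r$polarity, character(1))
  inc <- which(pol == "inclusion"); exc <- which(pol == "exclusion")
  as.integer(all(features[inc] == 1L) && all(features[exc] == 0L))
}

#' Fit and cross-validate a rule-feature baseline classifier
#'
#' Consumes only the binary rule features (never embeddings), preserving
#' the rule-based vs. representation-learning contrast. Uses the same
#' stratified folds and F1 metrics as [cross_validate()].
#'
#' @param features n x R binary feature matrix from
#'   [rule_feature_vector()].
#' @param labels Binary labels.
#' @param model `"logreg"`, `"svm"`, or `"random_forest"`.
#' @param seed Fold/model seed.
#' @param k_folds Number of folds.
#' @return List with `report` (a `tm_cv_report`) and `fit_full` (the model
#'   refitted on all data).
#' @export
fit_baseline <- function(features, labels, model = c("random_forest", "svm",
                                                     "logreg"),
                         seed = 1L, k_folds = 5L) {
  if (length(model) == 1L &&
      !model %in% c("random_forest", "svm", "logreg")) {
    stop("unknown baseline model '", model, "'")
  }
  model <- match.arg(model)
  features <- as.matrix(features)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  df_all <- as.data.frame(features)
  names(df_all) <- paste0("r", seq_len(ncol(features)))
  fit_one <- function(idx, fold_seed) {
    set.seed(fold_seed)
    dtr <- df_all[idx, , drop = FALSE]
    ytr <- labels[idx]
    if (model == "logreg") {
      suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                  data = cbind(dtr, y = ytr)))
    } else if (model == "svm") {
      e1071::svm(x = as.matrix(dtr), y = factor(ytr, levels = c(0, 1)))
    } else {
      randomForest::randomForest(x = dtr, y = factor(ytr, levels = c(0, 1)))
    }
  }
  predict_one <- function(fitted, idx) {
    dte <- df_all[idx, , drop = FALSE]
    if (model == "logreg") {
      p <- suppressWarnings(stats::predict(fitted, newdata = dte,
                                           type = "response"))
      as.integer(p >= 0.5)
    } else if (model == "svm") {
      as.integer(as.character(stats::predict(fitted, as.matrix(dte))))
    } else {
      as.integer(as.character(stats::predict(fitted, dte)))
    }
  }
  report <- cv_engine(labels, k = k_folds, seed = seed,
                      fit_fn = fit_one, predict_fn = predict_one,
                      config = list(model = model, k_folds = k_folds,
                                    seed = seed),
                      label = paste0("baseline_", model))
  list(report = report, fit_full = fit_one(seq_along(labels), seed))
}
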