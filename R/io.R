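# Serialization surfaces: JSONL corpora, the embedding cache, YAML
# configs, and CV-report JSON/CSV writers. Every artifact embeds the
# config and seed that produced it.

#' Write a pair corpus as JSONL
#'
#' One record per patient-trial pair:
#' `{pair_id, ehr_text, criteria: [{text, polarity}], label}` with labels
#' serialized as `"success"` / `"fail"`.
#'
#' @param corpus List of records, each a list with fields `pair_id`,
#'   `ehr_text`, `criteria` (list of `list(text, polarity)`), `label`
#'   (0/1).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(rec) {
    jsonlite::toJSON(list(
      pair_id = rec$pair_id,
      ehr_text = rec$ehr_text,
      criteria = lapply(rec$criteria, function(cr)
        list(text = cr$text, polarity = cr$polarity)),
      label = if (rec$label == 1) "success" else "fail"
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSONL pair corpus
#'
#' @param path JSONL file written by [write_corpus_jsonl()] (or any file
#'   in the same schema).
#' @return List of records with `label` mapped back to 1 (success) / 0
#'   (fail).
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) stop("corpus not found at ", path)
  lapply(readLines(path), function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    rec$label <- if (identical(rec$label, "success")) 1L else 0L
    rec
  })
}

#' Save an embedding cache
#'
#' Embedded pairs keyed by pair id with a granularity tag, written as a
#' single-archive `.rds` payload (a runtime artifact analogous to a
#' compressed array archive).
#'
#' @param pairs List of `tm_pair`s.
#' @param path Output path (`.rds`).
#' @param spec Optional generation spec recorded alongside the arrays.
#' @return Invisibly, `path`.
#' @export
save_embedding_cache <- function(pairs, path, spec = NULL) {
  g <- unique(vapply(pairs, function(p) p$granularity, character(1)))
  stopifnot(length(g) == 1L)
  payload <- list(
    granularity = g,
    pair_ids = vapply(pairs, function(p) p$pair_id, character(1)),
    labels = vapply(pairs, function(p) as.integer(p$label), integer(1)),
    ehr = lapply(pairs, function(p) p$ehr_rep),
    criteria = lapply(pairs, function(p) p$criteria_rep),
    spec = spec
  )
  saveRDS(payload, path, version = 2L)
  invisible(path)
}

#' Load an embedding cache
#'
#' @param path Path written by [save_embedding_cache()].
#' @return List of `tm_pair`s (plus the recorded spec in attribute
#'   `"spec"`).
#' @export
load_embedding_cache <- function(path) {
  if (!file.exists(path)) stop("embedding cache not found at ", path)
  payload <- readRDS(path)
  pairs <- lapply(seq_along(payload$pair_ids), function(i) {
    embedded_pair(payload$pair_ids[i], payload$granularity,
                  payload$ehr[[i]], payload$criteria[[i]],
                  payload$labels[i])
  })
  attr(pairs, "spec") <- payload$spec
  pairs
}

cv_report_to_list <- function(report) {
  list(
    schema = "trialmatch_cv_report_v1",
    label = report$label,
    seed = report$seed,
    mean_f1 = report$mean_f1,
    mean_f1_pos = report$mean_f1_pos,
    mean_f1_neg = report$mean_f1_neg,
    config = report$config[!vapply(report$config, is.function, logical(1))],
    folds = lapply(report$folds, function(f) {
      list(fold_index = f$fold_index, tp = f$tp, fp = f$fp, tn = f$tn,
           fn = f$fn, f1_overall = f$f1_overall, f1_pos = f$f1_pos,
           f1_neg = f$f1_neg, n_test = f$n_test, test_idx = f$test_idx,
           loss_history = f$history)
    })
  )
}

#' Write a CV report as JSON (and a per-fold CSV table)
#'
#' @param report A `tm_cv_report`.
#' @param path Output JSON path; the CSV table goes to `<path>.csv`.
#' @return Invisibly, `path`.
#' @export
write_cv_report <- function(report, path) {
  jsonlite::write_json(cv_report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  tab <- do.call(rbind, lapply(report$folds, function(f) {
    data.frame(fold = f$fold_index, tp = f$tp, fp = f$fp, tn = f$tn,
               fn = f$fn, f1_overall = f$f1_overall, f1_pos = f$f1_pos,
               f1_neg = f$f1_neg, n_test = f$n_test)
  }))
  utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' Read a CV report JSON back into a `tm_cv_report`
#'
#' @param path Path written by [write_cv_report()].
#' @return A `tm_cv_report`.
#' @export
read_cv_report <- function(path) {
  if (!file.exists(path)) stop("report not found at ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  folds <- lapply(x$folds, function(f) {
    list(fold_index = f$fold_index, tp = f$tp, fp = f$fp, tn = f$tn,
         fn = f$fn, f1_overall = f$f1_overall, f1_pos = f$f1_pos,
         f1_neg = f$f1_neg, n_test = f$n_test,
         test_idx = unlist(f$test_idx),
         history = unlist(f$loss_history))
  })
  structure(list(folds = folds, mean_f1 = x$mean_f1,
                 mean_f1_pos = x$mean_f1_pos, mean_f1_neg = x$mean_f1_neg,
                 config = x$config, seed = x$seed, label = x$label),
            class = "tm_cv_report")
}

#' Serialize an encoder configuration to YAML
#'
#' @param config An `encoder_config`.
#' @param path Output path; when `NULL`, the YAML string is returned.
#' @return The path (invisibly) or the YAML string.
#' @export
encoder_config_to_yaml <- function(config, path = NULL) {
  s <- yaml::as.yaml(unclass(config))
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Read an encoder configuration from YAML
#'
#' @param path YAML file (or a YAML string via `text`).
#' @param text Optional YAML string.
#' @return An `encoder_config`.
#' @export
encoder_config_from_yaml <- function(path = NULL, text = NULL) {
  x <- if (!is.null(text)) yaml::yaml.load(text) else
    yaml::read_yaml(path)
  do.call(encoder_config, x)
}

#' Serialize a rule list to YAML
#'
#' @param rules List of `tm_rule`s.
#' @param path Output path; `NULL` returns the string.
#' @return Path (invisibly) or YAML string.
#' @export
rules_to_yaml <- function(rules, path = NULL) {
  s <- yaml::as.yaml(lapply(rules, function(r)
    Filter(Negate(is.null), unclass(r))))
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Read a rule list from YAML
#'
#' @param path YAML file path (or `text`).
#' @param text Optional YAML string.
#' @return List of `tm_rule`s.
#' @export
rules_from_yaml <- function(path = NULL, text = NULL) {
  x <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  lapply(x, function(r) do.call(criterion_rule, r))
}
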