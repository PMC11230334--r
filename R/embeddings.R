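# Documents, embedding providers, and <EHR, Criteria> pair construction.
#
# Real deployments would plug a large-language-model backend in behind
# `embedding_provider()`; the default provider is a deterministic seeded
# pseudo-random generator keyed by a hash of the input text, so the whole
# pipeline runs offline and reproducibly.

#' Create a document
#'
#' A document is one text unit: an EHR narrative (or serialized structured
#' events) or a single eligibility-criterion statement, together with its
#' token list.
#'
#' @param doc_id Identifier string.
#' @param role Either `"ehr"` or `"criterion"`.
#' @param text Document text. Tokenized by whitespace when `tokens` is `NULL`.
#' @param tokens Optional explicit token character vector.
#' @return An object of class `tm_document`.
#' @export
document <- function(doc_id, role = c("ehr", "criterion"), text,
                     tokens = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(text), length(text) == 1L)
  if (is.null(tokens)) {
    tokens <- if (nzchar(trimws(text))) {
      strsplit(trimws(text), "\\s+")[[1]]
    } else {
      character(0)
    }
  }
  if (nzchar(trimws(text)) && length(tokens) == 0L) {
    stop("non-empty text must tokenize to at least one token")
  }
  structure(list(doc_id = doc_id, role = role, text = text, tokens = tokens),
            class = "tm_document")
}

#' Create a criteria set
#'
#' The ordered eligibility statements of one trial, each an inclusion or
#' exclusion criterion. Statement order is preserved.
#'
#' @param trial_id Trial identifier.
#' @param statements List of `tm_document` objects with role `"criterion"`.
#' @param polarity Character vector, one of `"inclusion"`/`"exclusion"` per
#'   statement.
#' @return An object of class `tm_criteria_set`.
#' @export
criteria_set <- function(trial_id, statements, polarity) {
  if (length(statements) < 1L) stop("a criteria set needs >= 1 statement")
  stopifnot(length(polarity) == length(statements),
            all(polarity %in% c("inclusion", "exclusion")))
  ok <- vapply(statements, function(s) {
    inherits(s, "tm_document") && s$role == "criterion"
  }, logical(1))
  if (!all(ok)) stop("all statements must be documents with role 'criterion'")
  structure(list(trial_id = trial_id, statements = statements,
                 polarity = polarity),
            class = "tm_criteria_set")
}

# djb2 string hash folded into [0, 2^31 - 2]; stable across platforms
text_hash <- function(text, salt = 0L) {
  bytes <- utf8ToInt(enc2utf8(text))
  h <- 5381
  m <- 2147483647
  for (b in bytes) h <- (h * 33 + b) %% m
  as.integer((h + salt) %% m)
}

# draw from a closure-local RNG stream without touching the global stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Create an embedding provider
#'
#' A provider maps text to a fixed-dimension vector. The built-in
#' `"synthetic"` provider derives each embedding from a hash of the input
#' text plus the provider seed, so identical text always yields an identical
#' vector and no model download is required. A custom backend (e.g. an LLM
#' embedding service) is supplied through `embed_fn`.
#'
#' @param name Provider name; `"synthetic"` for the built-in one.
#' @param dimension Embedding dimension D.
#' @param seed Integer seed mixed into the text hash (synthetic provider).
#' @param embed_fn Optional function `(text) -> numeric(dimension)` for a
#'   custom backend.
#' @param deterministic Whether the provider is deterministic.
#' @return An object of class `tm_provider`.
#' @export
embedding_provider <- function(name = "synthetic", dimension = 64L,
                               seed = 1L, embed_fn = NULL,
                               deterministic = TRUE) {
  stopifnot(dimension >= 1L)
  if (name == "synthetic") {
    embed_fn <- local({
      d <- dimension; s <- seed
      function(text) {
        with_local_seed(text_hash(text, salt = s),
                        stats::rnorm(d) / sqrt(d))
      }
    })
  } else if (is.null(embed_fn)) {
    stop("a non-synthetic provider requires embed_fn")
  }
  structure(list(name = name, dimension = as.integer(dimension),
                 seed = seed, embed_fn = embed_fn,
                 deterministic = deterministic),
            class = "tm_provider")
}

#' Embed a whole document as one vector
#'
#' The document-level ("coarse-grained") representation: the provider's
#' aggregated embedding of the full text.
#'
#' @param doc A `tm_document`.
#' @param provider A `tm_provider`.
#' @return Numeric vector of length `provider$dimension`.
#' @export
embed_document <- function(doc, provider) {
  stopifnot(inherits(doc, "tm_document"), inherits(provider, "tm_provider"))
  if (!nzchar(trimws(doc$text))) stop("cannot embed an empty document")
  v <- provider$embed_fn(doc$text)
  if (length(v) != provider$dimension) {
    stop("provider returned dimension ", length(v), ", expected ",
         provider$dimension)
  }
  if (!all(is.finite(v))) stop("provider returned non-finite values")
  as.numeric(v)
}

#' Embed a document token-by-token
#'
#' The token-level ("fine-grained") representation: one embedding row per
#' token, in token order.
#'
#' @inheritParams embed_document
#' @param max_tokens Sequence-length cap; longer documents are tail-truncated.
#' @return Matrix with `length(doc$tokens)` rows and D columns.
#' @export
embed_tokens <- function(doc, provider, max_tokens = 512L) {
  stopifnot(inherits(doc, "tm_document"), inherits(provider, "tm_provider"))
  toks <- doc$tokens
  if (length(toks) == 0L) stop("cannot embed a document with no tokens")
  if (length(toks) > max_tokens) toks <- toks[seq_len(max_tokens)]
  out <- t(vapply(toks, function(tk) {
    v <- provider$embed_fn(tk)
    if (length(v) != provider$dimension) {
      stop("provider returned dimension ", length(v), ", expected ",
           provider$dimension)
    }
    v
  }, numeric(provider$dimension)))
  rownames(out) <- NULL
  out
}

#' Mean-pool per-criterion embeddings
#'
#' Each criterion statement is embedded independently and the statement
#' vectors are mean-pooled to represent the whole criteria set at the
#' document level.
#'
#' @param statement_vectors List of equal-length numeric vectors.
#' @return The component-wise arithmetic mean vector.
#' @export
pool_criteria <- function(statement_vectors) {
  if (length(statement_vectors) == 0L) stop("cannot pool an empty list")
  d <- length(statement_vectors[[1]])
  if (!all(vapply(statement_vectors, length, integer(1)) == d)) {
    stop("statement vectors have ragged dimensions")
  }
  colMeans(do.call(rbind, statement_vectors))
}

#' Construct an embedded <EHR, Criteria> pair
#'
#' At coarse granularity the pair is two D-vectors: the EHR document
#' embedding and the mean-pooled per-statement criteria embedding. At fine
#' granularity it is two token-embedding matrices; the criteria statements
#' are concatenated in listed order (no separator token).
#'
#' @param ehr EHR `tm_document`.
#' @param criteria A `tm_criteria_set`.
#' @param provider A `tm_provider`.
#' @param granularity `"coarse"` or `"fine"`.
#' @param label Binary eligibility label (1 = success, 0 = fail).
#' @param pair_id Identifier; defaults to the EHR document id.
#' @param max_tokens Sequence-length cap for fine granularity.
#' @return An object of class `tm_pair` with `ehr_rep`, `criteria_rep`,
#'   `label`, `granularity`.
#' @export
build_pair <- function(ehr, criteria, provider,
                       granularity = c("coarse", "fine"), label = NA,
                       pair_id = ehr$doc_id, max_tokens = 512L) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(ehr, "tm_document"), inherits(criteria, "tm_criteria_set"))
  if (granularity == "coarse") {
    ehr_rep <- embed_document(ehr, provider)
    vecs <- lapply(criteria$statements, embed_document, provider = provider)
    criteria_rep <- pool_criteria(vecs)
  } else {
    ehr_rep <- embed_tokens(ehr, provider, max_tokens = max_tokens)
    mats <- lapply(criteria$statements, embed_tokens, provider = provider,
                   max_tokens = max_tokens)
    criteria_rep <- do.call(rbind, mats)
    if (nrow(criteria_rep) > max_tokens) {
      criteria_rep <- criteria_rep[seq_len(max_tokens), , drop = FALSE]
    }
  }
  embedded_pair(pair_id, granularity, ehr_rep, criteria_rep, label)
}

#' Assemble an embedded pair from pre-computed representations
#'
#' @param pair_id Identifier.
#' @param granularity `"coarse"` (vectors) or `"fine"` (token matrices).
#' @param ehr_rep,criteria_rep Numeric vector (coarse) or matrix (fine).
#' @param label 0 (fail), 1 (success), or `NA`.
#' @return An object of class `tm_pair`.
#' @export
embedded_pair <- function(pair_id, granularity, ehr_rep, criteria_rep,
                          label = NA) {
  if (granularity == "coarse") {
    ehr_rep <- as.numeric(ehr_rep); criteria_rep <- as.numeric(criteria_rep)
    if (length(ehr_rep) != length(criteria_rep)) {
      stop("EHR and criteria representations must share a dimension")
    }
  } else {
    stopifnot(is.matrix(ehr_rep), is.matrix(criteria_rep))
    if (ncol(ehr_rep) != ncol(criteria_rep)) {
      stop("EHR and criteria representations must share a dimension")
    }
    if (nrow(ehr_rep) < 1L || nrow(criteria_rep) < 1L) {
      stop("token matrices need >= 1 row")
    }
  }
  if (!all(is.finite(c(ehr_rep, criteria_rep)))) {
    stop("representations must be finite")
  }
  if (!is.na(label) && !label %in% c(0, 1)) stop("label must be 0, 1 or NA")
  label <- as.integer(label)
  structure(list(pair_id = pair_id, granularity = granularity,
                 ehr_rep = ehr_rep, criteria_rep = criteria_rep,
                 label = label),
            class = "tm_pair")
}
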