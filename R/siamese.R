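# The weight-sharing dual-encoder (Siamese) model and its early-fusion
# single-encoder counterpart.
#
# The Siamese model applies ONE encoder (a single parameter set — weight
# sharing is structural, not copied) to the EHR and criteria inputs
# separately, fuses the two learned representations, and classifies the
# fused vector with a 1-unit linear + sigmoid head. Under the contrastive
# objective the head is unused and eligibility is thresholded on the cosine
# similarity of the two representations.

FUSION_METHODS <- c("concat", "add", "multiply", "mean")

#' Fuse two encoded representations
#'
#' @param a,b Numeric vectors; equal length required for the element-wise
#'   methods.
#' @param method `"concat"` (length 2F), `"add"`, `"multiply"`, or `"mean"`
#'   (length F, component-wise).
#' @return The fused numeric vector.
#' @export
fuse <- function(a, b, method = c("concat", "add", "multiply", "mean")) {
  if (length(method) == 1L && !method %in% FUSION_METHODS) {
    stop("unknown fusion method '", method, "'")
  }
  method <- match.arg(method)
  if (method != "concat" && length(a) != length(b)) {
    stop("element-wise fusion requires equal lengths (", length(a), " vs ",
         length(b), ")")
  }
  switch(method,
         concat = c(a, b),
         add = a + b,
         multiply = a * b,
         mean = (a + b) / 2)
}

fuse_nodes <- function(a, b, method) {
  switch(method,
         concat = ad_concat_cols(a, b),
         add = ad_add(a, b),
         multiply = ad_mul(a, b),
         mean = ad_scale(ad_add(a, b), 0.5))
}

check_granularity <- function(encoder, granularity) {
  fam <- encoder$config$family
  if (granularity == "coarse" && fam != "mlp") {
    stop("sequence encoder '", fam, "' cannot consume coarse ",
         "(document-level) input; use family 'mlp'")
  }
  if (granularity == "fine" && fam == "mlp") {
    stop("the MLP encoder cannot consume fine-grained (token-level) ",
         "input; use a sequence encoder")
  }
  invisible(NULL)
}

#' Build a Siamese dual-encoder model
#'
#' @param encoder A `tm_encoder`; the single shared parameter set applied
#'   to both the EHR and the criteria branch.
#' @param fusion Fusion of the two encoded representations; `"concat"`
#'   (default, the strongest in practice), `"add"`, `"multiply"`, `"mean"`.
#' @param loss `"bce"`, `"wbce"`, or `"contrastive"`.
#' @param granularity `"coarse"` or `"fine"`; must match the encoder family.
#' @param threshold Decision threshold on the predicted probability
#'   (BCE/WBCE; ties resolve to positive).
#' @param margin Contrastive hinge level.
#' @param beta WBCE positive-class weight; if `NULL`, set from the training
#'   split's fail/success ratio at fit time.
#' @param seed Seed for head initialization.
#' @return A `tm_siamese` model.
#' @export
siamese_model <- function(encoder, fusion = "concat", loss = "wbce",
                          granularity = c("coarse", "fine"),
                          threshold = 0.5, margin = 1, beta = NULL,
                          seed = NULL) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(encoder, "tm_encoder"))
  if (!fusion %in% FUSION_METHODS) stop("unknown fusion method '", fusion, "'")
  if (!loss %in% c("bce", "wbce", "contrastive")) {
    stop("unknown loss '", loss, "'")
  }
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (margin <= 0) stop("margin must be positive")
  check_granularity(encoder, granularity)
  if (!is.null(seed)) set.seed(seed)
  fin <- if (fusion == "concat") 2L * encoder$output_dim else
    encoder$output_dim
  m <- structure(list(kind = "siamese", encoder = encoder, fusion = fusion,
                      loss = loss, granularity = granularity,
                      threshold = threshold, margin = margin, beta = beta,
                      head_W = ad_param(init_mat(fin, 1L)),
                      head_b = ad_param(matrix(0, 1, 1))),
                 class = "tm_siamese")
  m
}

#' Build the early-fusion single-encoder counterpart
#'
#' One encoder over the pre-fused input: the concatenated
#' `[EHR, criteria]` vector (coarse) or the EHR-then-criteria token
#' sequence (fine). The encoder's `input_dim` must be 2D for coarse input
#' and D for fine input.
#'
#' @inheritParams siamese_model
#' @return A `tm_single` model.
#' @export
single_encoder_model <- function(encoder, loss = "wbce",
                                 granularity = c("coarse", "fine"),
                                 threshold = 0.5, margin = 1, beta = NULL,
                                 seed = NULL) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(encoder, "tm_encoder"))
  if (!loss %in% c("bce", "wbce")) {
    stop("the single-encoder model supports 'bce' and 'wbce' (contrastive ",
         "needs two representations)")
  }
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  check_granularity(encoder, granularity)
  if (!is.null(seed)) set.seed(seed)
  structure(list(kind = "single", encoder = encoder, fusion = "early",
                 loss = loss, granularity = granularity,
                 threshold = threshold, margin = margin, beta = beta,
                 head_W = ad_param(init_mat(encoder$output_dim, 1L)),
                 head_b = ad_param(matrix(0, 1, 1))),
            class = "tm_single")
}

model_params <- function(model) {
  c(unname(model$encoder$params), list(model$head_W, model$head_b))
}

check_pair_granularity <- function(model, pairs) {
  g <- unique(vapply(pairs, function(p) p$granularity, character(1)))
  if (length(g) != 1L || g != model$granularity) {
    stop("pair granularity (", paste(g, collapse = "/"),
         ") does not match the model's (", model$granularity, ")")
  }
  invisible(NULL)
}

#' Build the early-fusion input of a pair
#'
#' Coarse: the length-2D `[EHR, criteria]` concatenation. Fine: the
#' `(d + n) x D` matrix of EHR tokens followed by criteria tokens.
#'
#' @param pair A `tm_pair`.
#' @return Numeric vector (coarse) or matrix (fine).
#' @export
early_fusion_input <- function(pair) {
  stopifnot(inherits(pair, "tm_pair"))
  if (pair$granularity == "coarse") {
    c(pair$ehr_rep, pair$criteria_rep)
  } else {
    rbind(pair$ehr_rep, pair$criteria_rep)
  }
}

# encode both branches of a batch of pairs on the tape; returns the two
# (B x F) representation nodes
siamese_branch_nodes <- function(model, pairs, train = FALSE) {
  check_pair_granularity(model, pairs)
  if (model$granularity == "coarse") {
    E <- do.call(rbind, lapply(pairs, function(p) p$ehr_rep))
    C <- do.call(rbind, lapply(pairs, function(p) p$criteria_rep))
    list(ehr = encoder_forward(model$encoder, E, train = train),
         crit = encoder_forward(model$encoder, C, train = train))
  } else {
    sbE <- seq_batch(lapply(pairs, function(p) p$ehr_rep))
    sbC <- seq_batch(lapply(pairs, function(p) p$criteria_rep))
    list(ehr = encoder_forward(model$encoder, sbE, train = train),
         crit = encoder_forward(model$encoder, sbC, train = train))
  }
}

# fused pre-head representation node for a batch of pairs
fused_nodes <- function(model, pairs, train = FALSE) {
  if (model$kind == "single") {
    if (model$granularity == "coarse") {
      X <- do.call(rbind, lapply(pairs, early_fusion_input))
      return(encoder_forward(model$encoder, X, train = train))
    }
    sb <- seq_batch(lapply(pairs, early_fusion_input))
    return(encoder_forward(model$encoder, sb, train = train))
  }
  br <- siamese_branch_nodes(model, pairs, train = train)
  fuse_nodes(br$ehr, br$crit, model$fusion)
}

# head logits node (B x 1) for BCE/WBCE models
logit_nodes <- function(model, pairs, train = FALSE) {
  fused <- fused_nodes(model, pairs, train = train)
  ad_add(ad_matmul(fused, model$head_W), model$head_b)
}

#' Predicted eligibility probability for pairs
#'
#' Runs the model in evaluation mode (deterministic). For contrastive
#' models use [predict_contrastive()].
#'
#' @param model A `tm_siamese` or `tm_single` model.
#' @param pairs A `tm_pair` or list of pairs.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
forward_pair <- function(model, pairs) {
  if (inherits(pairs, "tm_pair")) pairs <- list(pairs)
  ad_tape_reset()
  z <- node_value(logit_nodes(model, pairs, train = FALSE))
  as.vector(1 / (1 + exp(-z)))
}

#' Threshold a probability into a success/fail label
#'
#' @param p Probability in `[0, 1]`.
#' @param threshold Decision threshold in `[0, 1]`; ties (p equal to the
#'   threshold) resolve to the positive class.
#' @return Integer label(s) in {0, 1}.
#' @export
predict_label <- function(p, threshold = 0.5) {
  if (any(threshold < 0 | threshold > 1)) {
    stop("threshold must lie in [0, 1]")
  }
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  as.integer(p >= threshold)
}

#' Cosine similarities of the two encoded branches
#'
#' @param model A `tm_siamese` model.
#' @param pairs A `tm_pair` or list of pairs.
#' @return Numeric vector of cosine similarities in `[-1, 1]`.
#' @export
pair_similarity <- function(model, pairs) {
  if (inherits(pairs, "tm_pair")) pairs <- list(pairs)
  ad_tape_reset()
  if (model$kind != "siamese") {
    stop("similarity requires the dual-encoder (Siamese) model")
  }
  br <- siamese_branch_nodes(model, pairs, train = FALSE)
  as.vector(node_value(ad_cosine_rows(br$ehr, br$crit)))
}

#' Eligibility prediction for a contrastive-trained model
#'
#' Predicts success iff the cosine similarity between the two learned
#' representations reaches `sim_threshold` (default margin / 2).
#'
#' @param model A `tm_siamese` model with `loss = "contrastive"`.
#' @param pairs A `tm_pair` or list of pairs.
#' @param sim_threshold Similarity threshold.
#' @return Integer label(s) in {0, 1}.
#' @export
predict_contrastive <- function(model, pairs, sim_threshold = NULL) {
  if (model$loss != "contrastive") {
    stop("predict_contrastive requires a model trained with the ",
         "contrastive loss; this model uses '", model$loss, "'")
  }
  if (is.null(sim_threshold)) sim_threshold <- model$margin / 2
  d <- pair_similarity(model, pairs)
  as.integer(d >= sim_threshold)
}

# unified eval-mode label prediction used by the CV harness
model_predict <- function(model, pairs) {
  if (inherits(pairs, "tm_pair")) pairs <- list(pairs)
  if (model$loss == "contrastive") {
    predict_contrastive(model, pairs)
  } else {
    predict_label(forward_pair(model, pairs), model$threshold)
  }
}

#' @export
print.tm_siamese <- function(x, ...) {
  cat("<tm_siamese> encoder=", x$encoder$config$family, " fusion=", x$fusion,
      " loss=", x$loss, " granularity=", x$granularity, "\n", sep = "")
  invisible(x)
}

#' @export
print.tm_single <- function(x, ...) {
  cat("<tm_single> encoder=", x$encoder$config$family, " loss=", x$loss,
      " granularity=", x$granularity, "\n", sep = "")
  invisible(x)
}
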