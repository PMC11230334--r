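# Encoder architectures for the dual-encoder model.
#
# Ten families: mlp (coarse, document-level input) and nine sequence
# encoders (lstm, gru, bilstm, bigru, their self-attention variants, cnn,
# cnn_lstm) for token-level input. All run on the internal autodiff tape;
# each family maps its input to a fixed-length representation of
# `output_dim` components.

ENCODER_FAMILIES <- c("mlp", "lstm", "gru", "bilstm", "bigru",
                      "lstm_att", "gru_att", "bilstm_att", "bigru_att",
                      "cnn", "cnn_lstm")

#' Encoder configuration
#'
#' @param family One of `"mlp"`, `"lstm"`, `"gru"`, `"bilstm"`, `"bigru"`,
#'   `"lstm_att"`, `"gru_att"`, `"bilstm_att"`, `"bigru_att"`, `"cnn"`,
#'   `"cnn_lstm"`.
#' @param input_dim Embedding dimension D of the input vectors/token rows.
#' @param hidden_units Recurrent hidden size (default 50, one hidden layer).
#' @param num_hidden_layers MLP depth, 1--4.
#' @param projection_dim MLP output dimension (typical grid
#'   5/10/30/50/64/100; default 64).
#' @param dropout_rate In `[0, 1)`; defaults to 0.1 for the MLP and 0.5 for
#'   sequence encoders.
#' @param cnn_filters,kernel_size 1-d convolution width over the token axis
#'   (CNN families).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(family, input_dim, hidden_units = 50L,
                           num_hidden_layers = 1L, projection_dim = 64L,
                           dropout_rate = NULL, cnn_filters = 64L,
                           kernel_size = 3L) {
  if (!family %in% ENCODER_FAMILIES) {
    stop("unknown encoder family '", family, "'; known: ",
         paste(ENCODER_FAMILIES, collapse = ", "))
  }
  if (is.null(dropout_rate)) {
    dropout_rate <- if (family == "mlp") 0.1 else 0.5
  }
  stopifnot(input_dim >= 1L, hidden_units >= 1L, projection_dim >= 1L,
            num_hidden_layers >= 1L, num_hidden_layers <= 4L,
            dropout_rate >= 0, dropout_rate < 1,
            cnn_filters >= 1L, kernel_size >= 1L)
  structure(list(family = family, input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 num_hidden_layers = as.integer(num_hidden_layers),
                 projection_dim = as.integer(projection_dim),
                 dropout_rate = dropout_rate,
                 cnn_filters = as.integer(cnn_filters),
                 kernel_size = as.integer(kernel_size)),
            class = "encoder_config")
}

init_mat <- function(nr, nc, fan_in = nr) {
  k <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

bn_state_new <- function(n) {
  st <- new.env(parent = emptyenv())
  st$mean <- rep(0, n)
  st$var <- rep(1, n)
  st
}

recurrent_family <- function(family) {
  family %in% c("lstm", "gru", "bilstm", "bigru",
                "lstm_att", "gru_att", "bilstm_att", "bigru_att")
}

is_bidirectional <- function(family) family %in% c("bilstm", "bigru",
                                                   "bilstm_att", "bigru_att")
uses_attention <- function(family) grepl("_att$", family)
cell_kind <- function(family) if (grepl("gru", family)) "gru" else "lstm"

#' Build an encoder from its configuration
#'
#' Parameter initialization is drawn from the current RNG stream; call
#' `set.seed()` (or pass `seed`) for reproducible builds.
#'
#' @param config An `encoder_config`.
#' @param seed Optional integer seed applied before initialization.
#' @return A `tm_encoder` with fields `config`, `params` (named list),
#'   `output_dim`.
#' @export
build_encoder <- function(config, seed = NULL) {
  stopifnot(inherits(config, "encoder_config"))
  if (!is.null(seed)) set.seed(seed)
  D <- config$input_dim
  H <- config$hidden_units
  fam <- config$family
  params <- list()
  bn <- list()
  if (fam == "mlp") {
    prev <- D
    for (l in seq_len(config$num_hidden_layers)) {
      params[[paste0("W", l)]] <- ad_param(init_mat(prev, H))
      params[[paste0("b", l)]] <- ad_param(matrix(0, 1, H))
      params[[paste0("gamma", l)]] <- ad_param(matrix(1, 1, H))
      params[[paste0("beta", l)]] <- ad_param(matrix(0, 1, H))
      bn[[l]] <- bn_state_new(H)
      prev <- H
    }
    params$Wp <- ad_param(init_mat(prev, config$projection_dim))
    params$bp <- ad_param(matrix(0, 1, config$projection_dim))
    out_dim <- config$projection_dim
  } else if (recurrent_family(fam)) {
    ng <- if (cell_kind(fam) == "lstm") 4L else 3L
    dirs <- if (is_bidirectional(fam)) c("fw", "bw") else "fw"
    for (d in dirs) {
      params[[paste0("W_", d)]] <- ad_param(init_mat(D, ng * H, fan_in = H))
      params[[paste0("U_", d)]] <- ad_param(init_mat(H, ng * H, fan_in = H))
      params[[paste0("b_", d)]] <- ad_param(matrix(0, 1, ng * H))
    }
    out_dim <- if (is_bidirectional(fam)) 2L * H else H
    if (uses_attention(fam)) {
      params$att_v <- ad_param(init_mat(out_dim, 1L))
      params$att_b <- ad_param(matrix(0, 1, 1))
    }
  } else { # cnn / cnn_lstm
    K <- config$cnn_filters
    w <- config$kernel_size
    params$Wconv <- ad_param(init_mat(w * D, K, fan_in = w * D))
    params$bconv <- ad_param(matrix(0, 1, K))
    if (fam == "cnn_lstm") {
      params$W_fw <- ad_param(init_mat(K, 4L * H, fan_in = H))
      params$U_fw <- ad_param(init_mat(H, 4L * H, fan_in = H))
      params$b_fw <- ad_param(matrix(0, 1, 4L * H))
      out_dim <- H
    } else {
      out_dim <- K
    }
  }
  structure(list(config = config, params = params, bn = bn,
                 output_dim = as.integer(out_dim)),
            class = "tm_encoder")
}

# --- batched sequence container ---------------------------------------------
# A seq_batch packs variable-length token matrices into per-timestep
# (B x D) slices plus a (B x T) validity mask.

seq_batch <- function(mats) {
  stopifnot(length(mats) >= 1L)
  lens <- vapply(mats, nrow, integer(1))
  D <- ncol(mats[[1]])
  Tmax <- max(lens)
  B <- length(mats)
  steps <- vector("list", Tmax)
  for (t in seq_len(Tmax)) {
    xt <- matrix(0, B, D)
    for (i in seq_len(B)) if (lens[i] >= t) xt[i, ] <- mats[[i]][t, ]
    steps[[t]] <- xt
  }
  mask <- outer(lens, seq_len(Tmax), ">=") * 1
  list(steps = steps, mask = mask, lengths = lens, B = B, D = D, Tmax = Tmax)
}

# reverse each sequence within its valid length (for the backward direction)
seq_batch_reverse <- function(sb) {
  steps <- vector("list", sb$Tmax)
  for (t in seq_len(sb$Tmax)) steps[[t]] <- matrix(0, sb$B, sb$D)
  for (i in seq_len(sb$B)) {
    L <- sb$lengths[i]
    for (t in seq_len(L)) steps[[t]][i, ] <- sb$steps[[L - t + 1L]][i, ]
  }
  list(steps = steps, mask = sb$mask, lengths = sb$lengths,
       B = sb$B, D = sb$D, Tmax = sb$Tmax)
}

ad_col <- function(a, j) {
  av <- node_value(a)
  nc <- ncol(av)
  ad_node(av[, j, drop = FALSE], parents = list(a), backfn = function(go) {
    g <- matrix(0, nrow(av), nc)
    g[, j] <- go
    list(g)
  })
}

# run one recurrent direction over step inputs (list of B x D matrices,
# or conv-feature nodes for the CNN-LSTM hybrid) using the fused cell
# nodes; returns list(h_states = per-step hidden nodes or NULL, h_last)
run_rnn_direction <- function(kind, steps, mask, W, U, b, H,
                              collect_states = TRUE) {
  B <- nrow(node_value(steps[[1]]))
  Tn <- length(steps)
  hs <- if (collect_states) vector("list", Tn) else NULL
  if (kind == "lstm") {
    hc <- ad_const(matrix(0, B, 2L * H))
    for (t in seq_len(Tn)) {
      hc <- ad_lstm_step(steps[[t]], hc, W, U, b, mask[, t], H)
      if (collect_states) hs[[t]] <- ad_col_range(hc, 0L, H)
    }
    h_last <- if (collect_states) hs[[Tn]] else ad_col_range(hc, 0L, H)
  } else {
    h <- ad_const(matrix(0, B, H))
    for (t in seq_len(Tn)) {
      h <- ad_gru_step(steps[[t]], h, W, U, b, mask[, t], H)
      if (collect_states) hs[[t]] <- h
    }
    h_last <- h
  }
  list(h_states = hs, h_last = h_last)
}

# column block [offset+1, offset+n] of a node
ad_col_range <- function(a, offset, n) {
  av <- node_value(a)
  idx <- (offset + 1L):(offset + n)
  nc <- ncol(av)
  ad_node(av[, idx, drop = FALSE], parents = list(a), backfn = function(go) {
    g <- matrix(0, nrow(av), nc)
    g[, idx] <- go
    list(g)
  })
}

attention_pool_nodes <- function(h_states, mask, v, b) {
  scores <- lapply(h_states, function(h) ad_add(ad_matmul(h, v), b))
  S <- ad_stack_cols(scores)
  A <- ad_masked_softmax(S, mask)
  pooled <- NULL
  for (t in seq_along(h_states)) {
    term <- ad_colmul(h_states[[t]], ad_col(A, t))
    pooled <- if (is.null(pooled)) term else ad_add(pooled, term)
  }
  list(pooled = pooled, weights = node_value(A))
}

cnn_feature_nodes <- function(enc, sb, train) {
  w <- enc$config$kernel_size
  if (any(sb$lengths < w)) {
    stop("all sequences must have length >= kernel_size (", w, ")")
  }
  P <- sb$Tmax - w + 1L
  feats <- vector("list", P)
  for (p in seq_len(P)) {
    win <- do.call(cbind, sb$steps[p:(p + w - 1L)])
    feats[[p]] <- ad_relu(ad_add(ad_matmul(ad_const(win), enc$params$Wconv),
                                 enc$params$bconv))
  }
  pos_mask <- sb$mask[, (w:sb$Tmax), drop = FALSE] # valid iff t+w-1 <= len
  list(feats = feats, pos_mask = pos_mask,
       counts = pmax(sb$lengths - w + 1L, 1L))
}

# forward pass on the tape; input is a (B x D) matrix for mlp or a
# seq_batch for sequence families; returns a node of shape (B x output_dim)
encoder_forward <- function(enc, input, train = FALSE) {
  cfg <- enc$config
  fam <- cfg$family
  p <- enc$params
  if (fam == "mlp") {
    x <- if (is_node(input)) input else ad_const(input)
    for (l in seq_len(cfg$num_hidden_layers)) {
      x <- ad_add(ad_matmul(x, p[[paste0("W", l)]]), p[[paste0("b", l)]])
      x <- ad_batchnorm(x, p[[paste0("gamma", l)]], p[[paste0("beta", l)]],
                        enc$bn[[l]], train)
      x <- ad_relu(x)
      x <- ad_dropout(x, cfg$dropout_rate, train)
    }
    return(ad_add(ad_matmul(x, p$Wp), p$bp))
  }
  sb <- input
  if (!is.list(sb) || is.null(sb$steps)) {
    stop("sequence encoders require a token-level (fine-grained) input")
  }
  H <- cfg$hidden_units
  if (fam %in% c("cnn", "cnn_lstm")) {
    cf <- cnn_feature_nodes(enc, sb, train)
    if (fam == "cnn") {
      total <- NULL
      for (pi in seq_along(cf$feats)) {
        term <- ad_colmul(cf$feats[[pi]],
                          matrix(cf$pos_mask[, pi], ncol = 1L))
        total <- if (is.null(total)) term else ad_add(total, term)
      }
      pooled <- ad_colmul(total, matrix(1 / cf$counts, ncol = 1L))
      return(ad_dropout(pooled, cfg$dropout_rate, train))
    }
    res <- run_rnn_direction("lstm", cf$feats, cf$pos_mask,
                             p$W_fw, p$U_fw, p$b_fw, H,
                             collect_states = FALSE)
    return(ad_dropout(res$h_last, cfg$dropout_rate, train))
  }
  kind <- cell_kind(fam)
  att <- uses_attention(fam)
  fw <- run_rnn_direction(kind, sb$steps, sb$mask, p$W_fw, p$U_fw, p$b_fw,
                          H, collect_states = att)
  if (is_bidirectional(fam)) {
    rsb <- seq_batch_reverse(sb)
    bw <- run_rnn_direction(kind, rsb$steps, rsb$mask,
                            p$W_bw, p$U_bw, p$b_bw, H,
                            collect_states = att)
    if (uses_attention(fam)) {
      # align backward states to forward time before concatenation:
      # per-sequence position t pairs fw state t with bw state (L - t + 1)
      hs <- align_bi_states(fw$h_states, bw$h_states, sb$lengths)
      ap <- attention_pool_nodes(hs, sb$mask, p$att_v, p$att_b)
      enc_out <- ap$pooled
      attr_w <- ap$weights
    } else {
      enc_out <- ad_concat_cols(fw$h_last, bw$h_last)
      attr_w <- NULL
    }
  } else if (uses_attention(fam)) {
    ap <- attention_pool_nodes(fw$h_states, sb$mask, p$att_v, p$att_b)
    enc_out <- ap$pooled
    attr_w <- ap$weights
  } else {
    enc_out <- fw$h_last
    attr_w <- NULL
  }
  out <- ad_dropout(enc_out, cfg$dropout_rate, train)
  if (!is.null(attr_w)) attr(out, "attention") <- attr_w
  out
}

align_bi_states <- function(fw_states, bw_states, lengths) {
  Tmax <- length(fw_states)
  B <- nrow(node_value(fw_states[[1]]))
  out <- vector("list", Tmax)
  for (t in seq_len(Tmax)) {
    # bw state for forward position t lives at reversed position L - t + 1;
    # gather per-row via a selection matrix built from constants
    rows <- vector("list", Tmax)
    sel <- matrix(0, B, Tmax)
    for (i in seq_len(B)) {
      L <- lengths[i]
      if (t <= L) sel[i, L - t + 1L] <- 1
    }
    terms <- NULL
    for (tt in seq_len(Tmax)) {
      if (!any(sel[, tt] > 0)) next
      term <- ad_colmul(bw_states[[tt]], matrix(sel[, tt], ncol = 1L))
      terms <- if (is.null(terms)) term else ad_add(terms, term)
    }
    out[[t]] <- ad_concat_cols(fw_states[[t]], terms)
  }
  out
}

#' Encode one input to its fixed-length representation
#'
#' @param encoder A `tm_encoder`.
#' @param input Numeric vector of length D (mlp) or an L x D token matrix
#'   (sequence families).
#' @param train Training mode: enables dropout and batch-statistics
#'   normalization. Evaluation mode (default) is deterministic.
#' @return Numeric vector of length `encoder$output_dim`.
#' @export
encode <- function(encoder, input, train = FALSE) {
  stopifnot(inherits(encoder, "tm_encoder"))
  ad_tape_reset()
  if (encoder$config$family == "mlp") {
    if (is.matrix(input) && nrow(input) > 1L) {
      stop("the MLP encoder consumes one document-level vector, not a ",
           "token sequence; use a sequence encoder for fine-grained input")
    }
    v <- as.numeric(input)
    if (length(v) != encoder$config$input_dim) {
      stop("input dimension ", length(v), " does not match encoder D = ",
           encoder$config$input_dim)
    }
    node <- encoder_forward(encoder, matrix(v, 1L), train = train)
  } else {
    if (!is.matrix(input)) input <- matrix(input, nrow = 1L)
    if (nrow(input) < 1L) stop("empty sequence")
    if (ncol(input) != encoder$config$input_dim) {
      stop("input dimension ", ncol(input), " does not match encoder D = ",
           encoder$config$input_dim)
    }
    node <- encoder_forward(encoder, seq_batch(list(input)), train = train)
  }
  out <- as.numeric(node$value)
  if (!all(is.finite(out))) stop("encoder produced non-finite output")
  out
}

#' Self-attention pooling of hidden states
#'
#' Attention-weighted sum over positions: scores from a learned projection,
#' softmax-normalized so the weights are non-negative and sum to one.
#'
#' @param hidden_states L x H matrix of per-position hidden states.
#' @param v Scoring vector (length H); a random unit vector if omitted.
#' @return List with `pooled` (length-H vector) and `weights` (length L,
#'   summing to 1).
#' @export
self_attention_pool <- function(hidden_states, v = NULL) {
  stopifnot(is.matrix(hidden_states), nrow(hidden_states) >= 1L)
  if (is.null(v)) v <- rep(1 / sqrt(ncol(hidden_states)),
                           ncol(hidden_states))
  s <- as.vector(hidden_states %*% v)
  a <- exp(s - max(s)); a <- a / sum(a)
  list(pooled = as.vector(t(a) %*% hidden_states), weights = a)
}

#' 1-d convolution over the token axis with mean-pooling
#'
#' @param input L x D token-embedding matrix.
#' @param filters Matrix (kernel_size * D) x K, one column per filter; a
#'   random init if omitted.
#' @param kernel_size Window width w; requires L >= w.
#' @param n_filters K, used only when `filters` is omitted.
#' @return Length-K feature vector: per-position conv features mean-pooled
#'   over the L - w + 1 valid positions.
#' @export
cnn_extract <- function(input, filters = NULL, kernel_size = 3L,
                        n_filters = 64L) {
  stopifnot(is.matrix(input))
  L <- nrow(input); D <- ncol(input); w <- kernel_size
  if (L < w) {
    stop("sequence length ", L, " is below the minimum length ", w,
         " required by kernel_size")
  }
  if (is.null(filters)) filters <- init_mat(w * D, n_filters, fan_in = w * D)
  P <- L - w + 1L
  feats <- matrix(0, P, ncol(filters))
  for (p in seq_len(P)) {
    # token-major flattening matches the [X_p | X_{p+1} | ...] filter layout
    win <- as.vector(t(input[p:(p + w - 1L), , drop = FALSE]))
    feats[p, ] <- win %*% filters
  }
  colMeans(feats)
}

encoder_params <- function(enc) enc$params

#' @export
print.tm_encoder <- function(x, ...) {
  cat("<tm_encoder>", x$config$family, " D=", x$config$input_dim,
      " output_dim=", x$output_dim, "\n", sep = "")
  invisible(x)
}
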