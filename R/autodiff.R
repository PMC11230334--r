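# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every differentiable quantity is a "node": an environment holding the
# forward value, the parent nodes, and a backward closure mapping the
# incoming gradient to per-parent gradients. Non-parameter nodes are
# appended to a global tape at creation; creation order is a valid
# topological order, so the backward pass is a single reverse sweep over
# the tape. Model parameters live off-tape and accumulate gradients in
# their `grad` field until zeroed.
#
# The op set is deliberately small: exactly what the encoders, fusion ops
# and loss heads need. Losses are fused nodes (value + analytic gradient
# in one step) for numerical stability; everything is cross-checked
# against central finite differences in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$tape <- vector("list", 4096L)
.ad$tlen <- 0L

ad_tape_reset <- function() {
  if (.ad$tlen > 0L) {
    .ad$tape <- vector("list", max(4096L, length(.ad$tape)))
    .ad$tlen <- 0L
  }
  invisible(NULL)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_node <- function(value, parents = list(), backfn = NULL,
                    is_param = FALSE) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$backfn <- backfn
  n$is_param <- is_param
  n$grad <- NULL
  n$g <- NULL
  if (!is_param) {
    tl <- .ad$tlen + 1L
    if (tl > length(.ad$tape)) {
      .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
    }
    .ad$tape[[tl]] <- n
    .ad$tlen <- tl
    n$ti <- tl
  }
  n
}

#' @noRd
ad_param <- function(value) ad_node(as_mat(value), is_param = TRUE)

ad_const <- function(value) ad_node(as_mat(value))

is_node <- function(x) is.environment(x)

node_value <- function(x) if (is.environment(x)) x$value else as_mat(x)

# --- elementary ops ---------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- node_value(a); bv <- node_value(b)
  ad_node(av %*% bv, parents = list(a, b), backfn = function(go) {
    list(go %*% t(bv), crossprod(av, go))
  })
}

# add with row-broadcast: a (B x n) + b (1 x n) adds b to every row of a
ad_add <- function(a, b) {
  av <- node_value(a); bv <- node_value(b)
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    val <- sweep(av, 2L, bv[1L, ], "+")
    ad_node(val, parents = list(a, b), backfn = function(go) {
      list(go, matrix(colSums(go), nrow = 1L))
    })
  } else if (nrow(av) == 1L && nrow(bv) > 1L) {
    ad_add(b, a)
  } else {
    ad_node(av + bv, parents = list(a, b),
            backfn = function(go) list(go, go))
  }
}

ad_sub <- function(a, b) {
  av <- node_value(a); bv <- node_value(b)
  ad_node(av - bv, parents = list(a, b), backfn = function(go) {
    list(go, -go)
  })
}

# elementwise product, same shape (or one side a plain scalar)
ad_mul <- function(a, b) {
  av <- node_value(a); bv <- node_value(b)
  ad_node(av * bv, parents = list(a, b), backfn = function(go) {
    list(go * bv, go * av)
  })
}

ad_scale <- function(a, k) {
  av <- node_value(a)
  ad_node(av * k, parents = list(a), backfn = function(go) list(go * k))
}

# column-broadcast product: M (B x H) scaled per-row by c (B x 1)
ad_colmul <- function(m, c) {
  mv <- node_value(m); cv <- node_value(c)
  val <- mv * as.vector(cv)
  ad_node(val, parents = list(m, c), backfn = function(go) {
    list(go * as.vector(cv), matrix(rowSums(go * mv), ncol = 1L))
  })
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-node_value(a)))
  ad_node(s, parents = list(a), backfn = function(go) {
    list(go * s * (1 - s))
  })
}

ad_tanh <- function(a) {
  t <- tanh(node_value(a))
  ad_node(t, parents = list(a), backfn = function(go) {
    list(go * (1 - t * t))
  })
}

ad_relu <- function(a) {
  av <- node_value(a)
  mask <- av > 0
  ad_node(av * mask, parents = list(a), backfn = function(go) {
    list(go * mask)
  })
}

ad_concat_cols <- function(a, b) {
  av <- node_value(a); bv <- node_value(b)
  na <- ncol(av)
  ad_node(cbind(av, bv), parents = list(a, b), backfn = function(go) {
    list(go[, seq_len(na), drop = FALSE],
         go[, -seq_len(na), drop = FALSE])
  })
}

# stack a list of (B x 1) nodes into a (B x T) matrix
ad_stack_cols <- function(cols) {
  vals <- lapply(cols, node_value)
  val <- do.call(cbind, vals)
  ad_node(val, parents = cols, backfn = function(go) {
    lapply(seq_along(cols), function(j) go[, j, drop = FALSE])
  })
}

# inverted dropout; identity in eval mode
ad_dropout <- function(a, rate, train) {
  if (!train || rate <= 0) return(if (is_node(a)) a else ad_const(a))
  av <- node_value(a)
  keep <- matrix(stats::rbinom(length(av), 1L, 1 - rate),
                 nrow(av), ncol(av))
  scale <- keep / (1 - rate)
  ad_node(av * scale, parents = list(a), backfn = function(go) {
    list(go * scale)
  })
}

# batch normalization over the batch (row) dimension with running statistics
ad_batchnorm <- function(a, gamma, beta, state, train, momentum = 0.1,
                         eps = 1e-5) {
  av <- node_value(a)
  gv <- node_value(gamma); bv <- node_value(beta)
  if (train && nrow(av) > 1L) {
    mu <- colMeans(av)
    va <- colMeans(sweep(av, 2L, mu, "-")^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(av, 2L, mu, "-"), 2L, inv_sd, "*")
  val <- sweep(sweep(xhat, 2L, gv[1L, ], "*"), 2L, bv[1L, ], "+")
  use_batch <- train && nrow(av) > 1L
  ad_node(val, parents = list(a, gamma, beta), backfn = function(go) {
    dgamma <- matrix(colSums(go * xhat), nrow = 1L)
    dbeta <- matrix(colSums(go), nrow = 1L)
    dxhat <- sweep(go, 2L, gv[1L, ], "*")
    if (use_batch) {
      n <- nrow(av)
      t1 <- sweep(dxhat, 2L, colSums(dxhat) / n, "-")
      t2 <- sweep(xhat, 2L, colSums(dxhat * xhat) / n, "*")
      dx <- sweep(t1 - t2, 2L, inv_sd, "*")
    } else {
      dx <- sweep(dxhat, 2L, inv_sd, "*")
    }
    list(dx, dgamma, dbeta)
  })
}

# softmax over columns of S (B x T) restricted to mask == 1 positions
ad_masked_softmax <- function(s, mask) {
  sv <- node_value(s)
  z <- ifelse(mask > 0, sv, -Inf)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  a <- e / rowSums(e)
  ad_node(a, parents = list(s), backfn = function(go) {
    list(a * sweep(go, 1L, rowSums(go * a), "-"))
  })
}

# row-wise cosine similarity between A and B (both B x F) -> (B x 1)
ad_cosine_rows <- function(a, b) {
  av <- node_value(a); bv <- node_value(b)
  na <- sqrt(rowSums(av^2)); nb <- sqrt(rowSums(bv^2))
  if (any(na == 0) || any(nb == 0)) {
    stop("cosine similarity undefined for zero vectors (encoder collapse?)")
  }
  dot <- rowSums(av * bv)
  cs <- dot / (na * nb)
  ad_node(matrix(cs, ncol = 1L), parents = list(a, b),
          backfn = function(go) {
    g <- as.vector(go)
    da <- g * (bv / (na * nb) - (cs / na^2) * av)
    db <- g * (av / (na * nb) - (cs / nb^2) * bv)
    list(da, db)
  })
}

# --- fused loss heads -------------------------------------------------------

# binary cross-entropy from logits with optional positive-class weight
# beta; reduction "sum" or "mean"
ad_loss_bce_logits <- function(z, y, beta = 1, reduction = "mean") {
  zv <- as.vector(node_value(z))
  p <- 1 / (1 + exp(-zv))
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  li <- -(beta * y * log(pc) + (1 - y) * log(1 - pc))
  k <- if (reduction == "mean") 1 / length(y) else 1
  val <- sum(li) * k
  dz <- (beta * y * (p - 1) + (1 - y) * p) * k
  ad_node(matrix(val, 1L, 1L), parents = list(z), backfn = function(go) {
    list(matrix(as.vector(go) * dz, ncol = 1L))
  })
}

# contrastive loss from cosine similarities d (B x 1)
ad_loss_contrastive <- function(d, y, margin = 1, reduction = "mean") {
  dv <- as.vector(node_value(d))
  hinge <- pmax(0, margin - dv)
  li <- (1 - y) * dv^2 + y * hinge^2
  k <- if (reduction == "mean") 1 / length(y) else 1
  val <- sum(li) * k
  dd <- (2 * (1 - y) * dv - 2 * y * hinge) * k
  ad_node(matrix(val, 1L, 1L), parents = list(d), backfn = function(go) {
    list(matrix(as.vector(go) * dd, ncol = 1L))
  })
}

# --- backward pass ----------------------------------------------------------

# single reverse sweep over the tape from the loss node; parameter
# gradients accumulate in $grad, intermediate gradients travel in $g
ad_backward <- function(loss) {
  stopifnot(is.environment(loss), !is.null(loss$ti))
  tape <- .ad$tape
  loss$g <- matrix(1, nrow(loss$value), ncol(loss$value))
  for (i in loss$ti:1L) {
    n <- tape[[i]]
    if (is.null(n)) next
    go <- n$g
    if (is.null(go)) next
    n$g <- NULL
    if (is.null(n$backfn)) next
    pg <- n$backfn(go)
    ps <- n$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!is.environment(p)) next
      if (p$is_param) {
        p$grad <- if (is.null(p$grad)) pg[[j]] else p$grad + pg[[j]]
      } else {
        p$g <- if (is.null(p$g)) pg[[j]] else p$g + pg[[j]]
      }
    }
  }
  ad_tape_reset()
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# --- Adam optimizer ---------------------------------------------------------

adam_new <- function(params, lr = 0.005, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    mhat <- st$m[[i]] / (1 - b1^st$t)
    vhat <- st$v[[i]] / (1 - b2^st$t)
    p$value <- p$value - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  ad_zero_grad(st$params)
  invisible(NULL)
}

# --- fused recurrent cells --------------------------------------------------
# One tape node per timestep: forward computes the gated update, backward
# is the standard analytic cell backprop. The step input x is data (a
# plain matrix, no gradient) except in the CNN-LSTM hybrid, where the
# convolution features are nodes and receive gradients. The validity mask
# m (length-B 0/1) carries the previous state through padded positions.

# LSTM step over the combined state [h, c] (B x 2H)
ad_lstm_step <- function(x, hc_prev, W, U, b, m, H) {
  xv <- node_value(x); hcv <- node_value(hc_prev)
  Wv <- node_value(W); Uv <- node_value(U); bv <- node_value(b)
  h_prev <- hcv[, 1:H, drop = FALSE]
  c_prev <- hcv[, (H + 1L):(2L * H), drop = FALSE]
  a <- sweep(xv %*% Wv + h_prev %*% Uv, 2L, bv[1L, ], "+")
  ii <- 1:H; fi <- (H + 1L):(2L * H)
  gi <- (2L * H + 1L):(3L * H); oi <- (3L * H + 1L):(4L * H)
  i_g <- 1 / (1 + exp(-a[, ii, drop = FALSE]))
  f_g <- 1 / (1 + exp(-a[, fi, drop = FALSE]))
  g_g <- tanh(a[, gi, drop = FALSE])
  o_g <- 1 / (1 + exp(-a[, oi, drop = FALSE]))
  c_raw <- f_g * c_prev + i_g * g_g
  tc <- tanh(c_raw)
  h_new <- m * (o_g * tc) + (1 - m) * h_prev
  c_new <- m * c_raw + (1 - m) * c_prev
  x_is_node <- is.environment(x)
  parents <- list(hc_prev, W, U, b)
  if (x_is_node) parents <- c(parents, list(x))
  ad_node(cbind(h_new, c_new), parents = parents, backfn = function(go) {
    dh <- go[, 1:H, drop = FALSE]
    dc <- go[, (H + 1L):(2L * H), drop = FALSE]
    dh_raw <- m * dh
    dc_raw <- m * dc + dh_raw * o_g * (1 - tc * tc)
    dh_prev <- (1 - m) * dh
    dc_prev <- (1 - m) * dc + dc_raw * f_g
    da <- cbind(dc_raw * g_g * i_g * (1 - i_g),
                dc_raw * c_prev * f_g * (1 - f_g),
                dc_raw * i_g * (1 - g_g * g_g),
                dh_raw * tc * o_g * (1 - o_g))
    dh_prev <- dh_prev + da %*% t(Uv)
    out <- list(cbind(dh_prev, dc_prev),
                crossprod(xv, da),
                crossprod(h_prev, da),
                matrix(colSums(da), nrow = 1L))
    if (x_is_node) out <- c(out, list(da %*% t(Wv)))
    out
  })
}

# GRU step over h (B x H); gate blocks of W/U/b are [update z, reset r,
# candidate n], with the candidate using the reset-gated recurrent term
ad_gru_step <- function(x, h_prev, W, U, b, m, H) {
  xv <- node_value(x); hv <- node_value(h_prev)
  Wv <- node_value(W); Uv <- node_value(U); bv <- node_value(b)
  zi <- 1:H; ri <- (H + 1L):(2L * H); ni <- (2L * H + 1L):(3L * H)
  a3 <- xv %*% Wv
  u2 <- hv %*% Uv[, c(zi, ri), drop = FALSE]
  q <- hv %*% Uv[, ni, drop = FALSE]
  z_g <- 1 / (1 + exp(-(a3[, zi, drop = FALSE] +
                          u2[, 1:H, drop = FALSE] +
                          rep(bv[1L, zi], each = nrow(xv)))))
  r_g <- 1 / (1 + exp(-(a3[, ri, drop = FALSE] +
                          u2[, (H + 1L):(2L * H), drop = FALSE] +
                          rep(bv[1L, ri], each = nrow(xv)))))
  n_g <- tanh(a3[, ni, drop = FALSE] + r_g * q +
                rep(bv[1L, ni], each = nrow(xv)))
  h_new <- m * (z_g * hv + (1 - z_g) * n_g) + (1 - m) * hv
  x_is_node <- is.environment(x)
  parents <- list(h_prev, W, U, b)
  if (x_is_node) parents <- c(parents, list(x))
  ad_node(h_new, parents = parents, backfn = function(go) {
    dh_raw <- m * go
    dh_prev <- (1 - m) * go + dh_raw * z_g
    daz <- dh_raw * (hv - n_g) * z_g * (1 - z_g)
    dan <- dh_raw * (1 - z_g) * (1 - n_g * n_g)
    dar <- dan * q * r_g * (1 - r_g)
    dq <- dan * r_g
    dazr <- cbind(daz, dar)
    dh_prev <- dh_prev + dazr %*% t(Uv[, c(zi, ri), drop = FALSE]) +
      dq %*% t(Uv[, ni, drop = FALSE])
    da3 <- cbind(daz, dar, dan)
    out <- list(dh_prev,
                crossprod(xv, da3),
                cbind(crossprod(hv, dazr), crossprod(hv, dq)),
                matrix(colSums(da3), nrow = 1L))
    if (x_is_node) out <- c(out, list(da3 %*% t(Wv)))
    out
  })
}
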