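# Cluster analysis of the learned pair representations: extract the fused
# vectors right before the output layer, project to 2-D (PCA, or PCA
# followed by t-SNE), and export labelled scatter data.
#
# t-SNE is implemented here directly (exact pairwise affinities with
# per-point perplexity calibration, KL gradient descent with momentum and
# early exaggeration); at cohort sizes of a few hundred pairs the exact
# O(n^2) form is fast and has no extra dependencies.

#' Extract fused pre-output representations
#'
#' Row i is `fuse(encode(ehr_i), encode(criteria_i))` (or the encoder
#' output over the early-fused input for single-encoder models), computed
#' in evaluation mode with no sigmoid head applied.
#'
#' @param model A `tm_siamese` or `tm_single` model (trained or not; an
#'   untrained model is tagged `epoch = 0`).
#' @param pairs List of `tm_pair`s.
#' @param epoch Optional epoch tag; defaults to the trained epoch count or
#'   0 when the model has no training history.
#' @return Matrix (n x F') with attributes `labels` (per-pair) and
#'   `epoch`.
#' @export
extract_fused <- function(model, pairs, epoch = NULL) {
  if (inherits(pairs, "tm_pair")) pairs <- list(pairs)
  ad_tape_reset()
  fused <- node_value(fused_nodes(model, pairs, train = FALSE))
  rownames(fused) <- vapply(pairs, function(p) p$pair_id, character(1))
  if (is.null(epoch)) {
    epoch <- if (is.null(model$history)) 0L else model$history$epochs
  }
  attr(fused, "labels") <- vapply(pairs, function(p) p$label, numeric(1))
  attr(fused, "epoch") <- epoch
  fused
}

pca_2d <- function(x) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)
  rot <- pc$rotation
  # sign convention: the largest-magnitude loading of each component is
  # positive, so the projection is deterministic
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) {
      rot[, j] <- -rot[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  pc$x[, 1:2, drop = FALSE]
}

tsne_2d <- function(x, perplexity = 30, seed = 1L, max_iter = 400L) {
  n <- nrow(x)
  perplexity <- min(perplexity, (n - 1) / 3)
  d2 <- as.matrix(stats::dist(x))^2
  # per-point precision calibrated to the target perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2
        else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2
        else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_local_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    gains <- matrix(1, n, 2); inc <- matrix(0, n, 2)
    for (it in seq_len(max_iter)) {
      ex <- if (it <= 100) 4 else 1
      yd2 <- as.matrix(stats::dist(Y))^2
      num <- 1 / (1 + yd2); diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (ex * P - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      mom <- if (it <= 250) 0.5 else 0.8
      inc <- mom * inc - 200 * gains * grad
      Y <- Y + inc
      Y <- sweep(Y, 2L, colMeans(Y))
    }
    Y
  })
}

#' Project representations to two dimensions
#'
#' PCA is deterministic up to sign, fixed by making the largest-magnitude
#' loading of each component positive. `"tsne"` runs PCA to at most 50
#' dimensions first, then seeded t-SNE.
#'
#' @param x Representation matrix with >= 3 non-constant rows.
#' @param method `"pca"` or `"tsne"`.
#' @param seed Seed for t-SNE.
#' @param perplexity t-SNE perplexity (default 30, capped at (n-1)/3).
#' @return n x 2 coordinate matrix.
#' @export
reduce_2d <- function(x, method = c("pca", "tsne"), seed = 1L,
                      perplexity = 30) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 points")
  if (all(apply(x, 2L, stats::sd) == 0)) {
    stop("constant representation matrix cannot be projected")
  }
  if (method == "pca") {
    coords <- pca_2d(x)
  } else {
    if (ncol(x) > 50L) {
      pc <- stats::prcomp(x, center = TRUE, rank. = 50L)
      x <- pc$x
    }
    coords <- tsne_2d(x, perplexity = perplexity, seed = seed)
  }
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("x", "y")
  coords
}

#' Export a labelled 2-D scatter
#'
#' Always writes a CSV (`pair_id, x, y, label, epoch`); optionally a PNG
#' scatter colored by ground-truth label.
#'
#' @param coords n x 2 coordinate matrix.
#' @param labels Ground-truth labels, one per row.
#' @param path Output CSV path.
#' @param epoch Epoch tag recorded in the CSV.
#' @param png Also write `<path>.png`.
#' @return Invisibly, the data frame written.
#' @export
export_scatter <- function(coords, labels, path, epoch = NA, png = FALSE) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  if (nrow(coords) != length(labels)) {
    stop("coords and labels differ in length")
  }
  ids <- rownames(coords)
  if (is.null(ids)) ids <- sprintf("pair_%03d", seq_len(nrow(coords)))
  df <- data.frame(pair_id = ids, x = coords[, 1], y = coords[, 2],
                   label = labels, epoch = epoch)
  out <- df
  # full-precision text so a re-read reproduces the coordinates exactly
  out$x <- sprintf("%.17g", df$x)
  out$y <- sprintf("%.17g", df$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (png) {
    grDevices::png(paste0(path, ".png"), width = 640, height = 560)
    on.exit(grDevices::dev.off())
    graphics::plot(df$x, df$y, col = ifelse(df$label == 1, "#d95f02",
                                            "#1b9e77"),
                   pch = 19, xlab = "dim 1", ylab = "dim 2",
                   main = paste0("Fused pair representations (epoch ",
                                 epoch, ")"))
    graphics::legend("topright", legend = c("fail", "success"),
                     col = c("#1b9e77", "#d95f02"), pch = 19)
  }
  invisible(df)
}

#' 2-D distance between class centroids
#'
#' The qualitative cluster-separation summary: Euclidean distance between
#' the mean 2-D coordinates of the success and fail classes.
#'
#' @param coords n x 2 coordinates.
#' @param labels Binary labels.
#' @return Non-negative scalar.
#' @export
centroid_distance <- function(coords, labels) {
  stopifnot(nrow(coords) == length(labels))
  c1 <- colMeans(coords[labels == 1, , drop = FALSE])
  c0 <- colMeans(coords[labels == 0, , drop = FALSE])
  sqrt(sum((c1 - c0)^2))
}
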