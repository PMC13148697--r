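# Brute-force definitional oracles. These deliberately avoid the package's
# computational paths (ranks, cumulative sums): AUROC enumerates all
# positive-negative pairs, AUPRC walks the PR step function threshold by
# threshold, macro/micro AUROC reuse the pairwise oracle per class.

bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (x in pos) for (y in neg) total <- total + (x > y) + 0.5 * (x == y)
  total / (length(pos) * length(neg))
}

bf_auprc <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  recall_prev <- 0
  for (t in thresholds) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    recall <- tp / n_pos
    ap <- ap + (recall - recall_prev) * prec
    recall_prev <- recall
  }
  ap
}

bf_balacc <- function(true, predicted, n_classes) {
  recalls <- c()
  for (g in 0:(n_classes - 1)) {
    sel <- true == g
    if (!any(sel)) next
    recalls <- c(recalls, mean(predicted[sel] == g))
  }
  mean(recalls)
}

bf_macro_micro <- function(probs, labels) {
  G <- ncol(probs)
  per <- c()
  for (g in 0:(G - 1)) {
    y <- as.numeric(labels == g)
    if (length(unique(y)) < 2) next
    per <- c(per, bf_auroc(probs[, g + 1], y))
  }
  onehot <- as.numeric(outer(labels, 0:(G - 1), `==`))
  list(macro = mean(per), micro = bf_auroc(as.numeric(probs), onehot))
}

bf_youden <- function(scores, labels) {
  best_j <- -Inf
  best_t <- NA
  for (t in sort(unique(scores))) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

# Paired bootstrap of the AUROC difference: two-sided p from the bootstrap
# distribution's tail crossing of zero (oracle for the DeLong test).
bf_bootstrap_delong_p <- function(scores_a, scores_b, labels, n_boot = 20000L) {
  n <- length(labels)
  diffs <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    y <- labels[idx]
    if (length(unique(y)) < 2) {
      diffs[i] <- NA
      next
    }
    diffs[i] <- auroc(scores_a[idx], y) - auroc(scores_b[idx], y)
  }
  diffs <- diffs[!is.na(diffs)]
  m <- mean(diffs)
  s <- stats::sd(diffs)
  2 * stats::pnorm(-abs(m / s))
}

# Double-precision reference implementation of the network's forward loss,
# written directly from the architecture definition (nested loops, no
# im2col). Independent oracle for the C++ kernels: validates the weight
# layout, the stride-2 padding geometry, pooling, heads and loss — and its
# finite differences give reference gradients free of single-precision
# noise.
reference_network_loss <- function(params, x, ydiag, yprog, cw) {
  B <- dim(x)[3]
  conv_ref <- function(A, W, bias) {
    # A: H x W x C x B; W: Cout x (9*Cin); stride 2, pad 1
    H <- dim(A)[1]; Wd <- dim(A)[2]; Cin <- dim(A)[3]
    Ho <- (H + 1) %/% 2; Wo <- (Wd + 1) %/% 2
    Cout <- nrow(W)
    out <- array(0, c(Ho, Wo, Cout, B))
    for (b in seq_len(B)) for (oy in 0:(Ho - 1)) for (ox in 0:(Wo - 1)) {
      acc <- bias
      for (ky in 0:2) for (kx in 0:2) {
        iy <- 2 * oy + ky; ix <- 2 * ox + kx  # 1-based minus pad already
        if (iy < 1 || iy > H || ix < 1 || ix > Wd) next
        k <- ky * 3 + kx
        acc <- acc + W[, (k * Cin + 1):(k * Cin + Cin), drop = FALSE] %*%
          A[iy, ix, , b]
      }
      out[oy + 1, ox + 1, , b] <- pmax(acc, 0)
    }
    out
  }
  A <- array(x, c(dim(x)[1], dim(x)[2], 1, B))
  for (l in seq_along(params$conv_w)) {
    A <- conv_ref(A, params$conv_w[[l]], params$conv_b[[l]])
  }
  g <- apply(A, c(3, 4), mean)
  e <- pmax(params$emb_w %*% g + params$emb_b, 0)
  ld <- params$diag_w %*% e + params$diag_b
  P <- apply(ld, 2, function(v) { v <- exp(v - max(v)); v / sum(v) })
  pp <- 1 / (1 + exp(-(params$prog_w %*% e + params$prog_b)))
  loss_d <- 0; nd <- 0; loss_p <- 0; np <- 0
  for (b in seq_len(B)) {
    if (!is.na(ydiag[b])) {
      nd <- nd + 1
      loss_d <- loss_d - cw[ydiag[b] + 1] * log(P[ydiag[b] + 1, b])
    }
    if (!is.na(yprog[b])) {
      np <- np + 1
      loss_p <- loss_p - (yprog[b] * log(pp[b]) + (1 - yprog[b]) * log(1 - pp[b]))
    }
  }
  list(loss_diag = if (nd) loss_d / nd else NA_real_,
       loss_prog = if (np) loss_p / np else NA_real_,
       prob_diag = t(P), prob_prog = as.numeric(pp))
}

random_binary_instance <- function(n_max = 50L) {
  n <- sample(4:n_max, 1)
  scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
  labels <- rbinom(n, 1, 0.5)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  list(scores = scores, labels = labels, n = n)
}
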