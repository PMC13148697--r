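#' Two-headed convolutional backbone
#'
#' A deliberately small network that stands in for the full-scale
#' architectures used on real radiographs/MRI/mammograms: a stack of 3x3
#' stride-2 convolution + ReLU blocks, global average pooling, a ReLU
#' embedding layer, and two task heads sharing the trunk — a softmax
#' diagnosis head over the severity grades and a single-logit sigmoid
#' prognosis head. Small enough to train on one CPU, deep enough that
#' fine-tuning on the prognosis cohort alone exhibits catastrophic
#' forgetting of rare grades.
#'
#' @param conv_channels integer vector of output channels per conv block.
#' @param embedding_dim size of the shared embedding.
#' @param diagnosis_classes number of severity grades.
#' @param kernel_size convolution kernel side; only 3 is implemented.
#' @return an object of class `backbone_config`.
#' @export
backbone_config <- function(conv_channels = c(8L, 24L, 48L),
                            embedding_dim = 64L,
                            diagnosis_classes = 5L,
                            kernel_size = 3L) {
  stopifnot(length(conv_channels) >= 1L, all(conv_channels >= 1L),
            embedding_dim >= 1L, diagnosis_classes >= 2L)
  if (kernel_size != 3L) {
    stop("only 3x3 kernels are implemented", call. = FALSE)
  }
  structure(list(conv_channels = as.integer(conv_channels),
                 embedding_dim = as.integer(embedding_dim),
                 diagnosis_classes = as.integer(diagnosis_classes),
                 kernel_size = 3L,
                 pooling = "stride2-conv + global-average",
                 prognosis_outputs = 1L),
            class = "backbone_config")
}

# He-normal initialization of all parameters, drawn from the current RNG
# state (callers wrap this in a dedicated init stream for reproducibility).
init_network <- function(backbone) {
  ch <- c(1L, backbone$conv_channels)
  L <- length(backbone$conv_channels)
  conv_w <- vector("list", L)
  conv_b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- 9L * ch[l]
    conv_w[[l]] <- matrix(stats::rnorm(ch[l + 1L] * fan_in, 0, sqrt(2 / fan_in)),
                          nrow = ch[l + 1L])
    conv_b[[l]] <- numeric(ch[l + 1L])
  }
  clast <- ch[L + 1L]
  ed <- backbone$embedding_dim
  G <- backbone$diagnosis_classes
  list(conv_w = conv_w, conv_b = conv_b,
       emb_w = matrix(stats::rnorm(ed * clast, 0, sqrt(2 / clast)), nrow = ed),
       emb_b = numeric(ed),
       diag_w = matrix(stats::rnorm(G * ed, 0, sqrt(2 / ed)), nrow = G),
       diag_b = numeric(G),
       prog_w = matrix(stats::rnorm(ed, 0, sqrt(2 / ed)), nrow = 1L),
       prog_b = 0)
}

# Reinitialize the prognosis head only (used at the phase-1 -> phase-2
# transfer: trunk + diagnosis head are copied, the prognosis head is fresh).
reinit_prognosis_head <- function(params, backbone) {
  ed <- backbone$embedding_dim
  params$prog_w <- matrix(stats::rnorm(ed, 0, sqrt(2 / ed)), nrow = 1L)
  params$prog_b <- 0
  params
}

# Flatten/unflatten helpers so Adam state can live in plain numeric vectors.
flatten_params <- function(p) {
  unlist(list(p$conv_w, p$conv_b, p$emb_w, p$emb_b, p$diag_w, p$diag_b,
              p$prog_w, p$prog_b), use.names = FALSE)
}

unflatten_params <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0L
  take <- function(template) {
    n <- length(template)
    v <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(template)) matrix(v, nrow = nrow(template)) else v
  }
  out$conv_w <- lapply(skeleton$conv_w, take)
  out$conv_b <- lapply(skeleton$conv_b, take)
  out$emb_w <- take(skeleton$emb_w)
  out$emb_b <- take(skeleton$emb_b)
  out$diag_w <- take(skeleton$diag_w)
  out$diag_b <- take(skeleton$diag_b)
  out$prog_w <- take(skeleton$prog_w)
  out$prog_b <- take(skeleton$prog_b)
  out
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Cosine annealing from lr_max to lr_min, after a short linear warmup.
# The warmup matters most when fine-tuning from pretrained weights: without
# it the freshly initialized prognosis head's first gradients, taken at the
# peak learning rate, disturb the trunk before any replay can consolidate.
cosine_lr <- function(epoch, epochs, lr_max, lr_min = 0, warmup = 2L) {
  if (epochs <= 1L) return(lr_max)
  warmup <- min(warmup, epochs - 1L)
  if (epoch <= warmup) return(lr_max * epoch / (warmup + 1))
  span <- max(epochs - warmup - 1L, 1L)
  lr_min + 0.5 * (lr_max - lr_min) *
    (1 + cos(pi * (epoch - warmup - 1L) / span))
}

#' Inverse-frequency class weights
#'
#' Weights proportional to `1 / count`, renormalized so their mean over the
#' classes is 1 (classes absent from `labels` get the maximum observed
#' weight, with a warning).
#'
#' @param labels integer vector of 0-based class labels.
#' @param n_classes number of classes.
#' @return numeric vector of length `n_classes`.
#' @export
class_weights <- function(labels, n_classes) {
  counts <- tabulate(labels + 1L, nbins = n_classes)
  if (any(counts == 0L)) {
    warning("class(es) absent from training data: ",
            paste(which(counts == 0L) - 1L, collapse = ", "))
  }
  w <- ifelse(counts > 0L, 1 / pmax(counts, 1L), NA_real_)
  w[is.na(w)] <- max(w, na.rm = TRUE)
  w / mean(w)
}

# One forward/backward pass over a batch. x: H x W x B array; ydiag 0-based
# grades or NA; yprog 0/1 or NA.
network_batch <- function(params, x, ydiag, yprog, cw, want_grads = TRUE) {
  cnn_batch_cpp(x, params, as.integer(ydiag), as.numeric(yprog),
                as.numeric(cw), want_grads)
}

# Forward-only scoring in memory-bounded chunks.
network_predict <- function(params, x, chunk = 128L) {
  n <- dim(x)[3]
  G <- nrow(params$diag_w)
  prog <- numeric(n)
  diag <- matrix(NA_real_, n, G)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    res <- cnn_batch_cpp(x[, , s:e, drop = FALSE], params,
                         rep(NA_integer_, e - s + 1L),
                         rep(NA_real_, e - s + 1L),
                         rep(1, G), FALSE)
    prog[s:e] <- res$prob_prog
    diag[s:e, ] <- res$prob_diag
  }
  list(prognosis = prog, diagnosis = diag)
}

# Random flip / rotation / crop-zoom / shift augmentation; parameter draws
# come from the caller's current RNG state, geometry is applied in C++.
augment_batch <- function(x, spec = "flips+crops+rotations") {
  if (identical(spec, "none")) return(x)
  if (!identical(spec, "flips+crops+rotations")) {
    stop("unknown augmentation spec: ", spec, call. = FALSE)
  }
  b <- dim(x)[3]
  side <- dim(x)[1]
  augment_batch_cpp(x,
                    flip = stats::runif(b) < 0.5,
                    angle_deg = stats::runif(b, -10, 10),
                    zoom = rep(1 / 0.9, b),
                    dx = stats::runif(b, -0.05, 0.05) * side,
                    dy = stats::runif(b, -0.05, 0.05) * side)
}
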