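#' Training hyperparameters
#'
#' @param lr Adam peak learning rate (annealed to `lr_min` by a cosine
#'   schedule over the epochs).
#' @param betas Adam exponential-decay rates.
#' @param epochs number of epochs; an epoch is one pass over the regime's
#'   primary training set (the prognosis cohort for all prognosis-bearing
#'   regimes, with replay batches interleaved on top where applicable).
#' @param batch_size images per batch.
#' @param replay_probability probability that the next batch is a diagnosis
#'   "replay" batch rather than a prognosis batch (default 0.5, i.e. tasks
#'   sampled with equal probability).
#' @param weighted_ce use inverse-frequency class weights in the diagnosis
#'   cross-entropy.
#' @param augmentation `"none"` or `"flips+crops+rotations"` (horizontal
#'   flip p = 0.5, rotation up to +/-10 degrees, random crop to 90% with
#'   resize, small shifts).
#' @param checkpoint_criterion epoch-selection criterion:
#'   `"val_prognosis_auroc"`, `"val_diagnosis_balacc"` or
#'   `"val_total_loss"`.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param min_steps_per_epoch lower bound on optimizer steps per epoch; a
#'   training set smaller than `min_steps_per_epoch * batch_size` is
#'   recycled (reshuffled) within the epoch so that a 20-epoch run still
#'   performs a meaningful number of updates on desk-scale cohorts.
#' @param warmup_epochs linear learning-rate warmup length before the
#'   cosine decay begins.
#' @param replay_epoch_passes number of prognosis passes making up one
#'   replay-mode epoch. Replay training processes both cohorts, so its
#'   epoch is sized to the combined workload; replay batches are
#'   interleaved throughout, giving the diagnosis task roughly
#'   `replay_epoch_passes` matched passes of refresh per epoch.
#' @param lr_min cosine-annealing floor.
#' @param seed integer seed for initialization, data order, task sampling
#'   and augmentation (independent substreams are derived from it).
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 2e-3, betas = c(0.9, 0.999), epochs = 20L,
                         batch_size = 32L, replay_probability = 0.5,
                         weighted_ce = TRUE,
                         augmentation = "flips+crops+rotations",
                         checkpoint_criterion = "val_prognosis_auroc",
                         early_stop_patience = 10L,
                         min_steps_per_epoch = 4L,
                         replay_epoch_passes = 2L, warmup_epochs = 2L,
                         lr_min = 0, seed = 1L) {
  stopifnot(lr > 0, length(betas) == 2L, epochs >= 0L, batch_size >= 1L,
            replay_probability >= 0, replay_probability <= 1,
            augmentation %in% c("none", "flips+crops+rotations"),
            checkpoint_criterion %in% c("val_prognosis_auroc",
                                        "val_diagnosis_balacc",
                                        "val_total_loss"),
            early_stop_patience >= 1L)
  structure(list(lr = lr, betas = betas, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 replay_probability = replay_probability,
                 weighted_ce = isTRUE(weighted_ce),
                 augmentation = augmentation,
                 checkpoint_criterion = checkpoint_criterion,
                 early_stop_patience = as.integer(early_stop_patience),
                 min_steps_per_epoch = as.integer(min_steps_per_epoch),
                 replay_epoch_passes = as.integer(replay_epoch_passes),
                 warmup_epochs = as.integer(warmup_epochs),
                 lr_min = lr_min, seed = as.integer(seed)),
            class = "train_config")
}

#' Declarative description of a training regime
#'
#' The six regimes: `diagnosis_reference` (dedicated diagnosis model, also
#' the pretrained initialization for downstream strategies),
#' `prognosis_single_task` (either initialization), `single_cohort_mt`
#' (both heads, prognosis-cohort data only, random init),
#' `concurrent_mt` (both cohorts via batch sampling, random init),
#' `diag_pretrained_mt` (pretrained init, prognosis-cohort data only, no
#' replay) and `seq_replay` (pretrained init plus diagnosis replay).
#'
#' @param name one of the six regime names.
#' @param init `"random"` or `"diagnosis_pretrained"`; regimes whose
#'   definition fixes the initialization reject the other value.
#' @return an object of class `strategy_spec`.
#' @export
strategy_spec <- function(name, init = NULL) {
  names_ok <- c("diagnosis_reference", "prognosis_single_task",
                "single_cohort_mt", "concurrent_mt", "diag_pretrained_mt",
                "seq_replay")
  if (!name %in% names_ok) stop("unknown strategy: ", name, call. = FALSE)
  required <- switch(name,
    diagnosis_reference = "random",
    single_cohort_mt = "random",
    concurrent_mt = "random",
    diag_pretrained_mt = "diagnosis_pretrained",
    seq_replay = "diagnosis_pretrained",
    NULL)
  if (is.null(init)) init <- if (is.null(required)) "diagnosis_pretrained" else required
  stopifnot(init %in% c("random", "diagnosis_pretrained"))
  if (!is.null(required) && init != required) {
    stop(name, " requires init = ", required, call. = FALSE)
  }
  label <- if (name == "prognosis_single_task") paste(name, init, sep = ":") else name
  structure(list(name = name, init = init, label = label),
            class = "strategy_spec")
}

#' Sample the source cohort of the next batch
#'
#' A Bernoulli choice of the cohort from which the entire next batch is
#' drawn; every batch is single-task.
#'
#' @param p probability of a prognosis batch (so `1 - p` is the probability
#'   of a diagnosis replay batch).
#' @param n number of draws.
#' @param stream optional RNG substream.
#' @return character vector of `"prognosis"` / `"diagnosis"`.
#' @export
replay_batch_source <- function(p, n = 1L, stream = NULL) {
  stopifnot(p >= 0, p <= 1)
  draw <- function() ifelse(stats::runif(n) < p, "prognosis", "diagnosis")
  if (is.null(stream)) draw() else with_stream(stream, draw())
}

#' Extract a labelled dataset from a cohort bundle
#'
#' @param bundle a `cohort_bundle` with rendered images.
#' @param idx row indices into `bundle$scans`.
#' @return list with `x` (image array), `grade`, `prog` (progression label
#'   or `NA`), `scan_id`, `patient_id`, `n`.
#' @export
scan_dataset <- function(bundle, idx) {
  stopifnot(!is.null(bundle$images))
  list(x = bundle$images[, , idx, drop = FALSE],
       grade = bundle$scans$grade[idx],
       prog = bundle$scans$progression_label[idx],
       scan_id = bundle$scans$scan_id[idx],
       patient_id = bundle$scans$patient_id[idx],
       n = length(idx))
}

# Row indices of a patient set's scans; prognosis = TRUE keeps only scans
# carrying a progression label.
patient_scan_idx <- function(bundle, patients, prognosis = FALSE) {
  sel <- bundle$scans$patient_id %in% patients
  if (prognosis) sel <- sel & !is.na(bundle$scans$progression_label)
  which(sel)
}

#' Select the checkpoint epoch from a training log
#'
#' Arg-max (arg-min for loss criteria) of the criterion over the logged
#' epochs; ties break toward the earliest epoch; non-finite entries are
#' skipped with a warning. Epochs are numbered from 0.
#'
#' @param log training-log data frame with one row per epoch.
#' @param criterion name of the log column to optimize.
#' @return 0-based selected epoch.
#' @export
select_checkpoint <- function(log, criterion) {
  if (!is.data.frame(log) || nrow(log) == 0L) {
    stop("empty training log", call. = FALSE)
  }
  if (!criterion %in% names(log)) {
    stop("criterion not logged: ", criterion, call. = FALSE)
  }
  v <- log[[criterion]]
  if (grepl("loss", criterion)) v <- -v
  if (any(!is.finite(v))) {
    warning("non-finite criterion value(s) at epoch(s) ",
            paste(which(!is.finite(v)) - 1L, collapse = ", "), "; skipped")
    v[!is.finite(v)] <- -Inf
  }
  if (all(!is.finite(v))) {
    stop("criterion undefined at every epoch", call. = FALSE)
  }
  which.max(v) - 1L
}

# ---- core training engine ---------------------------------------------------

# Modes: "diag" (diagnosis-only pass over train_diag), "prog"
# (prognosis-only pass over train_prog), "both" (pass over train_prog, each
# batch contributes both its grade and its progression label), "replay"
# (pass over train_prog with diagnosis batches from train_diag interleaved
# by coin flips of probability cfg$replay_probability).
fit_network <- function(params, backbone, cfg, mode,
                        train_prog = NULL, train_diag = NULL,
                        val_prog = NULL, val_diag = NULL,
                        criterion = cfg$checkpoint_criterion) {
  stopifnot(mode %in% c("diag", "prog", "both", "replay"))
  order_stream <- rng_stream(derive_seed(cfg$seed, "order"))
  task_stream <- rng_stream(derive_seed(cfg$seed, "task"))
  aug_stream <- rng_stream(derive_seed(cfg$seed, "augment"))

  G <- backbone$diagnosis_classes
  grade_source <- switch(mode, diag = train_diag, both = train_prog,
                         replay = train_diag, prog = NULL)
  cw <- if (!is.null(grade_source) && cfg$weighted_ce) {
    class_weights(grade_source$grade, G)
  } else {
    rep(1, G)
  }

  # fall back to validation loss when the validation fold has one class
  if (criterion == "val_prognosis_auroc" && !is.null(val_prog) &&
      length(unique(val_prog$prog)) < 2L) {
    warning("single-class validation fold: checkpointing on validation loss")
    criterion <- "val_total_loss"
  }

  theta <- flatten_params(params)
  opt <- adam_state(length(theta))
  skeleton <- params
  best <- list(value = -Inf, epoch = NA_integer_, params = params)
  log <- NULL
  audit_diag <- character(0)
  audit_prog <- character(0)
  diag_cycle <- integer(0)  # cycling shuffled pool for replay batches

  next_diag_batch <- function() {
    if (length(diag_cycle) < cfg$batch_size) {
      diag_cycle <<- c(diag_cycle,
                       with_stream(order_stream, sample(train_diag$n)))
    }
    b <- diag_cycle[seq_len(min(cfg$batch_size, length(diag_cycle)))]
    diag_cycle <<- diag_cycle[-seq_along(b)]
    b
  }

  run_batch <- function(ds, idx, use_grade, use_prog, lr) {
    x <- ds$x[, , idx, drop = FALSE]
    if (cfg$augmentation != "none") {
      x <- with_stream(aug_stream, augment_batch(x, cfg$augmentation))
    }
    ydiag <- if (use_grade) ds$grade[idx] else rep(NA_integer_, length(idx))
    yprog <- if (use_prog) ds$prog[idx] else rep(NA_real_, length(idx))
    res <- network_batch(unflatten_params(theta, skeleton), x, ydiag, yprog, cw)
    gflat <- flatten_params(res$grads)
    st <- adam_step(theta, gflat, opt, lr, cfg$betas[1], cfg$betas[2])
    theta <<- st$theta
    opt <<- st$state
    if (use_grade) audit_diag <<- c(audit_diag, ds$scan_id[idx])
    if (use_prog) audit_prog <<- c(audit_prog, ds$scan_id[idx])
    c(diag = if (is.null(res$loss_diag)) NA_real_ else res$loss_diag,
      prog = if (is.null(res$loss_prog)) NA_real_ else res$loss_prog)
  }

  # one epoch's batch index list: a pass over the shuffled set, recycled
  # (with reshuffles) up to the configured minimum number of steps
  epoch_chunks <- function(n) {
    min_steps <- max(1L, cfg$min_steps_per_epoch)
    # with replay disabled the regime must reduce exactly to single-task
    # training, so the combined-workload epoch sizing only applies when
    # replay batches are actually drawn
    if (mode == "replay" && cfg$replay_probability > 0) {
      min_steps <- max(min_steps, max(1L, cfg$replay_epoch_passes) *
                                    ceiling(n / cfg$batch_size))
    }
    if (ceiling(n / cfg$batch_size) >= min_steps) {
      ord <- with_stream(order_stream, sample(n))
    } else {
      need <- min_steps * cfg$batch_size
      reps <- ceiling(need / n)
      ord <- with_stream(order_stream, unlist(
        lapply(seq_len(reps), function(i) sample(n))))[seq_len(need)]
    }
    split(ord, ceiling(seq_along(ord) / cfg$batch_size))
  }

  epochs_since_best <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch, cfg$epochs, cfg$lr, cfg$lr_min, cfg$warmup_epochs)
    primary <- if (mode == "diag") train_diag else train_prog
    chunks <- epoch_chunks(primary$n)
    losses <- list()
    for (ch in chunks) {
      if (mode == "replay") {
        while (replay_batch_source(1 - cfg$replay_probability, 1L,
                                   task_stream) == "diagnosis") {
          losses[[length(losses) + 1L]] <-
            run_batch(train_diag, next_diag_batch(), TRUE, FALSE, lr)
        }
      }
      losses[[length(losses) + 1L]] <- switch(mode,
        diag = run_batch(train_diag, ch, TRUE, FALSE, lr),
        prog = ,
        replay = run_batch(train_prog, ch, FALSE, TRUE, lr),
        both = run_batch(train_prog, ch, TRUE, TRUE, lr))
    }
    lm <- do.call(rbind, losses)
    cur <- unflatten_params(theta, skeleton)
    row <- data.frame(epoch = epoch - 1L, lr = lr,
                      train_loss_diag = mean(lm[, "diag"], na.rm = TRUE),
                      train_loss_prog = mean(lm[, "prog"], na.rm = TRUE))
    row$val_prognosis_auroc <- NA_real_
    row$val_diagnosis_balacc <- NA_real_
    row$val_total_loss <- NA_real_
    vloss <- 0
    if (!is.null(val_prog) && val_prog$n > 0L) {
      pv <- network_predict(cur, val_prog$x)
      if (length(unique(val_prog$prog)) >= 2L) {
        row$val_prognosis_auroc <- auroc(pv$prognosis, val_prog$prog)
      }
      pr <- pmin(pmax(pv$prognosis, 1e-12), 1 - 1e-12)
      vloss <- vloss - mean(val_prog$prog * log(pr) +
                              (1 - val_prog$prog) * log(1 - pr))
    }
    if (!is.null(val_diag) && val_diag$n > 0L) {
      dv <- network_predict(cur, val_diag$x)
      pred <- max.col(dv$diagnosis, ties.method = "first") - 1L
      cm <- confusion_matrix(val_diag$grade, pred, G)
      row$val_diagnosis_balacc <-
        suppressWarnings(balanced_accuracy(cm))
      pd <- pmax(dv$diagnosis[cbind(seq_len(val_diag$n),
                                    val_diag$grade + 1L)], 1e-12)
      vloss <- vloss - mean(cw[val_diag$grade + 1L] * log(pd))
    }
    row$val_total_loss <- vloss
    log <- rbind(log, row)
    crit_val <- row[[criterion]]
    if (grepl("loss", criterion)) crit_val <- -crit_val
    if (is.finite(crit_val) && crit_val > best$value) {
      best <- list(value = crit_val, epoch = epoch - 1L, params = cur)
      epochs_since_best <- 0L
    } else {
      epochs_since_best <- epochs_since_best + 1L
      if (epochs_since_best >= cfg$early_stop_patience) break
    }
  }

  selected <- if (is.null(log)) NA_integer_ else {
    suppressWarnings(select_checkpoint(log, criterion))
  }
  final <- unflatten_params(theta, skeleton)
  if (is.na(best$epoch)) best$params <- final
  structure(list(params = best$params, final_params = final,
                 backbone = backbone, config = cfg,
                 training_log = log, selected_epoch = selected,
                 criterion = criterion, class_weights = cw,
                 audit = list(diagnosis = unique(audit_diag),
                              prognosis = unique(audit_prog))),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model (", if (is.null(x$strategy)) "unlabelled" else
    x$strategy$label, "): ",
    if (is.null(x$training_log)) 0L else nrow(x$training_log),
    " epochs logged, checkpoint at epoch ", x$selected_epoch,
    " by ", x$criterion, "\n", sep = "")
  invisible(x)
}

#' Train the dedicated diagnosis reference model
#'
#' Phase-1 diagnosis pretraining on the leakage-safe pretraining cohort;
#' checkpoints on the best validation balanced accuracy. The result serves
#' both as the dedicated diagnosis comparator and as the pretrained
#' initialization of downstream strategies.
#'
#' @param pretrain_scans,val_scans datasets from [scan_dataset()] whose
#'   patients are disjoint.
#' @param cfg a [train_config()].
#' @param backbone a [backbone_config()].
#' @return a `trained_model`.
#' @export
train_diagnosis_reference <- function(pretrain_scans, val_scans, cfg,
                                      backbone = backbone_config()) {
  init <- with_stream(rng_stream(derive_seed(cfg$seed, "init")),
                      init_network(backbone))
  m <- fit_network(init, backbone, cfg, mode = "diag",
                   train_diag = pretrain_scans, val_diag = val_scans,
                   criterion = "val_diagnosis_balacc")
  m$strategy <- strategy_spec("diagnosis_reference")
  m
}

#' Train a single-task prognosis model
#'
#' The binary prognosis head is trained on the prognosis cohort;
#' checkpointing uses the best validation prognosis AUROC. The diagnosis
#' head stays attached but untrained — scoring it afterwards quantifies
#' forgetting. With `init = "diagnosis_pretrained"`, the trunk and
#' diagnosis head are copied from the supplied phase-1 model and the
#' prognosis head is freshly initialized.
#'
#' @param train_scans,val_scans prognosis-labelled datasets.
#' @param init `"random"` or `"diagnosis_pretrained"`.
#' @param cfg a [train_config()].
#' @param backbone a [backbone_config()].
#' @param phase1 the fold's phase-1 `trained_model` (required for
#'   pretrained init).
#' @return a `trained_model`.
#' @export
train_prognosis_single_task <- function(train_scans, val_scans, init, cfg,
                                        backbone = backbone_config(),
                                        phase1 = NULL) {
  init_stream <- rng_stream(derive_seed(cfg$seed, "init"))
  params <- strategy_init(init, backbone, phase1, init_stream)
  m <- fit_network(params, backbone, cfg, mode = "prog",
                   train_prog = train_scans, val_prog = val_scans,
                   criterion = "val_prognosis_auroc")
  m$strategy <- strategy_spec("prognosis_single_task", init)
  m
}

strategy_init <- function(init, backbone, phase1, init_stream) {
  if (init == "diagnosis_pretrained") {
    if (is.null(phase1)) {
      stop("diagnosis_pretrained init requires a phase-1 model", call. = FALSE)
    }
    # trunk + diagnosis head copied; prognosis head freshly initialized
    with_stream(init_stream, reinit_prognosis_head(phase1$params, backbone))
  } else {
    with_stream(init_stream, init_network(backbone))
  }
}

#' Train one of the four multitask regimes
#'
#' `single_cohort_mt`: both heads trained on the fold's prognosis-cohort
#' training scans only (each scan contributing both its grade and its
#' progression label), random init. `diag_pretrained_mt`: same data regime,
#' initialized from phase 1. `concurrent_mt`: prognosis batches with
#' diagnosis batches from the full pretraining cohort interleaved by the
#' replay sampler, random init. `seq_replay`: phase-1 init plus replay.
#' All regimes checkpoint on the highest validation prognosis AUROC.
#'
#' @param strategy a [strategy_spec()].
#' @param train_prog,val_prog prognosis-labelled datasets for the fold.
#' @param diag_pool diagnosis-cohort dataset (pretraining patients minus
#'   the fold's validation patients) used by replay-based regimes.
#' @param cfg a [train_config()].
#' @param backbone a [backbone_config()].
#' @param phase1 fold's phase-1 model where the init requires it.
#' @return a `trained_model`.
#' @export
train_multitask <- function(strategy, train_prog, val_prog, diag_pool = NULL,
                            cfg, backbone = backbone_config(),
                            phase1 = NULL) {
  stopifnot(inherits(strategy, "strategy_spec"))
  if (!strategy$name %in% c("single_cohort_mt", "concurrent_mt",
                            "diag_pretrained_mt", "seq_replay")) {
    stop("not a multitask strategy: ", strategy$name, call. = FALSE)
  }
  init_stream <- rng_stream(derive_seed(cfg$seed, "init"))
  params <- strategy_init(strategy$init, backbone, phase1, init_stream)
  mode <- if (strategy$name %in% c("concurrent_mt", "seq_replay")) "replay" else "both"
  if (mode == "replay" && is.null(diag_pool)) {
    stop(strategy$name, " requires a diagnosis replay pool", call. = FALSE)
  }
  m <- fit_network(params, backbone, cfg, mode = mode,
                   train_prog = train_prog, val_prog = val_prog,
                   train_diag = if (mode == "replay") diag_pool else NULL,
                   criterion = cfg$checkpoint_criterion)
  m$strategy <- strategy
  m
}

#' Score a dataset with a trained model's checkpoint
#'
#' @param model a `trained_model`.
#' @param dataset a dataset from [scan_dataset()].
#' @return data frame with `scan_id`, `prognosis_score` and one
#'   `grade_prob_<g>` column per grade.
#' @export
predict_scans <- function(model, dataset) {
  p <- network_predict(model$params, dataset$x)
  out <- data.frame(scan_id = dataset$scan_id,
                    prognosis_score = p$prognosis,
                    stringsAsFactors = FALSE)
  G <- ncol(p$diagnosis)
  for (g in seq_len(G)) out[[paste0("grade_prob_", g - 1L)]] <- p$diagnosis[, g]
  out
}
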