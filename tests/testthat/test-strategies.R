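test_that("strategy specs enforce the regime/init pairing", {
  expect_equal(strategy_spec("seq_replay")$init, "diagnosis_pretrained")
  expect_equal(strategy_spec("single_cohort_mt")$init, "random")
  expect_error(strategy_spec("seq_replay", "random"), "requires init")
  expect_error(strategy_spec("concurrent_mt", "diagnosis_pretrained"),
               "requires init")
  expect_error(strategy_spec("nonsense"), "unknown strategy")
  both <- lapply(c("random", "diagnosis_pretrained"),
                 function(i) strategy_spec("prognosis_single_task", i))
  expect_equal(vapply(both, `[[`, character(1), "label"),
               c("prognosis_single_task:random",
                 "prognosis_single_task:diagnosis_pretrained"))
})

test_that("replay batch source has the right degenerate and average behaviour", {
  expect_true(all(replay_batch_source(1, 50) == "prognosis"))
  expect_true(all(replay_batch_source(0, 50) == "diagnosis"))
  set.seed(33)
  draws <- replay_batch_source(0.5, 10000)
  frac_diag <- mean(draws == "diagnosis")
  expect_gte(frac_diag, 0.48)
  expect_lte(frac_diag, 0.52)
})

test_that("checkpoint selection follows the arg-max/tie/NaN rules", {
  log <- data.frame(epoch = 0:2, val_prognosis_auroc = c(0.6, 0.8, 0.7))
  expect_equal(select_checkpoint(log, "val_prognosis_auroc"), 1L)
  log$val_prognosis_auroc <- c(0.7, 0.7, 0.7)
  expect_equal(select_checkpoint(log, "val_prognosis_auroc"), 0L)
  log$val_prognosis_auroc <- c(0.6, 0.7, NaN)
  expect_warning(e <- select_checkpoint(log, "val_prognosis_auroc"),
                 "non-finite")
  expect_equal(e, 1L)
  log$val_prognosis_auroc <- rep(NaN, 3)
  expect_error(suppressWarnings(select_checkpoint(log, "val_prognosis_auroc")),
               "undefined at every epoch")
  expect_error(select_checkpoint(data.frame(), "x"), "empty")
  # loss criteria are minimized
  log2 <- data.frame(epoch = 0:2, val_total_loss = c(0.9, 0.3, 0.5))
  expect_equal(select_checkpoint(log2, "val_total_loss"), 1L)
})

test_that("inverse-frequency class weights match the hand formula", {
  labels <- c(rep(0L, 90), rep(1L, 10))
  w <- class_weights(labels, 2L)
  raw <- c(1 / 90, 1 / 10)
  expect_equal(w, raw / mean(raw))
  expect_equal(mean(w), 1)
  expect_warning(class_weights(c(0L, 0L), 3L), "absent")
})

test_that("diagnosis reference trains, logs and checkpoints", {
  fd <- tiny_fold_data()
  cfg <- fast_train_config(epochs = 1L)
  m <- suppressWarnings(
    train_diagnosis_reference(fd$diag_pool, fd$diag_val, cfg, tiny_backbone()))
  expect_s3_class(m, "trained_model")
  expect_equal(nrow(m$training_log), 1L)
  expect_equal(m$selected_epoch, 0L)
  expect_equal(m$criterion, "val_diagnosis_balacc")
  # audit records exactly the pretraining scans, no prognosis accesses
  expect_setequal(m$audit$diagnosis, fd$diag_pool$scan_id)
  expect_length(m$audit$prognosis, 0)
})

test_that("pretrained init copies the trunk bit-for-bit and zero-epoch runs are no-ops", {
  fd <- tiny_fold_data()
  cfg <- fast_train_config(epochs = 1L)
  phase1 <- suppressWarnings(
    train_diagnosis_reference(fd$diag_pool, fd$diag_val, cfg, tiny_backbone()))
  m0 <- suppressWarnings(train_prognosis_single_task(
    fd$prog_train, fd$prog_val, "diagnosis_pretrained",
    fast_train_config(epochs = 0L), tiny_backbone(), phase1))
  for (nm in c("conv_w", "conv_b", "emb_w", "emb_b", "diag_w", "diag_b")) {
    expect_identical(m0$params[[nm]], phase1$params[[nm]])
  }
  expect_true(is.na(m0$selected_epoch))
  # zero training steps: predictions equal those of the initialized network
  p0 <- predict_scans(m0, fd$prog_test)
  manual <- seqreplay:::network_predict(m0$params, fd$prog_test$x)
  expect_equal(p0$prognosis_score, manual$prognosis)
  expect_error(train_prognosis_single_task(
    fd$prog_train, fd$prog_val, "diagnosis_pretrained",
    fast_train_config(), tiny_backbone(), NULL), "phase-1")
})

test_that("seq_replay with zero replay probability reduces to single-task prognosis", {
  fd <- tiny_fold_data()
  cfg <- fast_train_config(epochs = 2L, replay_probability = 0)
  phase1 <- suppressWarnings(
    train_diagnosis_reference(fd$diag_pool, fd$diag_val,
                              fast_train_config(epochs = 1L), tiny_backbone()))
  m_replay <- suppressWarnings(train_multitask(
    strategy_spec("seq_replay"), fd$prog_train, fd$prog_val, fd$diag_pool,
    cfg, tiny_backbone(), phase1))
  m_single <- suppressWarnings(train_prognosis_single_task(
    fd$prog_train, fd$prog_val, "diagnosis_pretrained", cfg,
    tiny_backbone(), phase1))
  expect_equal(m_replay$params, m_single$params)
  p_r <- predict_scans(m_replay, fd$prog_test)
  p_s <- predict_scans(m_single, fd$prog_test)
  expect_equal(p_r$prognosis_score, p_s$prognosis_score)
  # and no diagnosis scans were replayed
  expect_length(m_replay$audit$diagnosis, 0)
})

test_that("single-cohort regimes touch only the fold's prognosis training scans", {
  fd <- tiny_fold_data()
  cfg <- fast_train_config(epochs = 2L)
  for (name in c("single_cohort_mt", "diag_pretrained_mt")) {
    phase1 <- if (name == "diag_pretrained_mt") {
      suppressWarnings(train_diagnosis_reference(
        fd$diag_pool, fd$diag_val, fast_train_config(epochs = 1L),
        tiny_backbone()))
    }
    m <- suppressWarnings(train_multitask(
      strategy_spec(name), fd$prog_train, fd$prog_val, NULL, cfg,
      tiny_backbone(), phase1))
    expect_setequal(m$audit$prognosis, fd$prog_train$scan_id)
    expect_true(all(m$audit$diagnosis %in% fd$prog_train$scan_id))
  }
})

test_that("replay regimes draw diagnosis batches from the pretraining pool only", {
  fd <- tiny_fold_data()
  cfg <- fast_train_config(epochs = 3L, replay_probability = 0.7)
  m <- suppressWarnings(train_multitask(
    strategy_spec("concurrent_mt"), fd$prog_train, fd$prog_val, fd$diag_pool,
    cfg, tiny_backbone()))
  expect_gt(length(m$audit$diagnosis), 0)
  expect_true(all(m$audit$diagnosis %in% fd$diag_pool$scan_id))
  expect_setequal(m$audit$prognosis, fd$prog_train$scan_id)
  expect_error(train_multitask(
    strategy_spec("seq_replay"), fd$prog_train, fd$prog_val, NULL, cfg,
    tiny_backbone(), m), "replay pool")
})

test_that("training is reproducible given identical configuration", {
  fd <- tiny_fold_data()
  cfg <- fast_train_config(epochs = 2L)
  m1 <- suppressWarnings(train_prognosis_single_task(
    fd$prog_train, fd$prog_val, "random", cfg, tiny_backbone()))
  m2 <- suppressWarnings(train_prognosis_single_task(
    fd$prog_train, fd$prog_val, "random", cfg, tiny_backbone()))
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$params, m2$params)
  cfg2 <- fast_train_config(epochs = 2L, seed = 99L)
  m3 <- suppressWarnings(train_prognosis_single_task(
    fd$prog_train, fd$prog_val, "random", cfg2, tiny_backbone()))
  expect_false(identical(m1$params, m3$params))
})

test_that("the C++ network agrees with the double-precision reference", {
  set.seed(14)
  bb <- backbone_config(conv_channels = c(3L, 4L), embedding_dim = 6L,
                        diagnosis_classes = 3L)
  p <- seqreplay:::init_network(bb)
  x <- array(runif(16 * 16 * 4), dim = c(16, 16, 4))
  yd <- c(0L, 2L, NA, 1L)
  yp <- c(1, NA, 0, 1)
  cw <- c(1.2, 0.8, 1.0)
  res <- seqreplay:::network_batch(p, x, yd, yp, cw)
  ref <- reference_network_loss(p, x, yd, yp, cw)
  # forward agreement: the C++ path runs in single precision
  expect_equal(res$loss_diag, ref$loss_diag, tolerance = 1e-5)
  expect_equal(res$loss_prog, ref$loss_prog, tolerance = 1e-5)
  expect_equal(res$prob_diag, ref$prob_diag, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(as.numeric(res$prob_prog), ref$prob_prog, tolerance = 1e-5)

  # analytic gradients vs double-precision finite differences of the
  # reference forward pass
  loss_of <- function(pp) {
    r <- reference_network_loss(pp, x, yd, yp, cw)
    r$loss_diag + r$loss_prog
  }
  th <- seqreplay:::flatten_params(p)
  g_an <- seqreplay:::flatten_params(res$grads)
  idx <- sample(length(th), 25)
  eps <- 1e-6
  for (i in idx) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    g_num <- (loss_of(seqreplay:::unflatten_params(tp, p)) -
                loss_of(seqreplay:::unflatten_params(tm, p))) / (2 * eps)
    expect_lt(abs(g_an[i] - g_num), 1e-3 + 0.01 * abs(g_num))
  }
})
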