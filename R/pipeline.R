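#' Experiment configuration
#'
#' Bundles the generator, backbone, training hyperparameters, fold count,
#' strategy list, replicate seeds and pre-registered DeLong comparisons
#' into one declarative object. The defaults are the frozen benchmark:
#' 600 patients, 64-px images, 5 folds, 20 epochs, 3 replicate seeds.
#'
#' @param generator a [generator_config()].
#' @param backbone a [backbone_config()]; its class count is forced to the
#'   generator's grade count.
#' @param train a [train_config()].
#' @param k_folds number of cross-validation folds.
#' @param strategies character vector of strategy labels (a
#'   `prognosis_single_task` label may carry `":random"` or
#'   `":diagnosis_pretrained"`).
#' @param seeds integer vector of experiment replicate seeds.
#' @param delong_pairs list of 2-element character vectors of strategy
#'   labels to compare with the DeLong test on fold-ensembled predictions.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              backbone = backbone_config(),
                              train = train_config(),
                              k_folds = 5L,
                              strategies = c(
                                "diagnosis_reference",
                                "prognosis_single_task:random",
                                "prognosis_single_task:diagnosis_pretrained",
                                "single_cohort_mt",
                                "concurrent_mt",
                                "diag_pretrained_mt",
                                "seq_replay"),
                              seeds = c(1L, 2L, 3L),
                              delong_pairs = list(
                                c("prognosis_single_task:diagnosis_pretrained",
                                  "prognosis_single_task:random"),
                                c("seq_replay",
                                  "prognosis_single_task:diagnosis_pretrained"),
                                c("seq_replay", "diag_pretrained_mt"))) {
  stopifnot(length(strategies) >= 1L, length(seeds) >= 1L, k_folds >= 2L)
  backbone$diagnosis_classes <- generator$n_grades
  specs <- lapply(strategies, as_strategy)
  labels <- vapply(specs, `[[`, character(1), "label")
  stopifnot(!anyDuplicated(labels))
  names(specs) <- labels
  delong_pairs <- Filter(function(p) all(p %in% labels), delong_pairs)
  structure(list(generator = generator, backbone = backbone, train = train,
                 k_folds = as.integer(k_folds), strategies = specs,
                 seeds = as.integer(seeds), delong_pairs = delong_pairs),
            class = "experiment_config")
}

as_strategy <- function(x) {
  if (inherits(x, "strategy_spec")) return(x)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) strategy_spec(parts[1]) else
    strategy_spec(parts[1], parts[2])
}

needs_phase1 <- function(specs) {
  any(vapply(specs, function(s)

    s$name == "diagnosis_reference" || s$init == "diagnosis_pretrained",
    logical(1)))
}

#' Run the full experiment
#'
#' For every replicate seed: generate the cohort, build the split plan,
#' train every requested strategy per fold with the fold-specific
#' pretraining holdout, collect test predictions, compute the metric
#' reports, DeLong comparisons, subgroup and forgetting analyses, and the
#' leakage audit. Per-stage seeds are derived deterministically from the
#' replicate seed, so two runs with the same configuration reproduce every
#' number exactly.
#'
#' @param config an [experiment_config()].
#' @param output_dir optional directory; when given, predictions, reports
#'   and logs are written under it.
#' @param quiet suppress progress messages.
#' @return an object of class `experiment_result`.
#' @export
run_experiment <- function(config, output_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(...)
  seeds_out <- list()
  for (seed in config$seeds) {
    say("seed ", seed, ": generating cohort")
    seeds_out[[as.character(seed)]] <- run_single_seed(config, seed, say)
  }
  result <- structure(list(config = config, seeds = seeds_out,
                           tables = NULL, audit = NULL),
                      class = "experiment_result")
  result$audit <- leakage_audit(result)
  result$tables <- build_report(result)
  if (!is.null(output_dir)) write_experiment(result, output_dir)
  result
}

run_single_seed <- function(config, seed, say = message) {
  gcfg <- config$generator
  gcfg$seed <- derive_seed(seed, "generator")
  bundle <- build_cohorts(gcfg)
  plan <- make_split_plan(bundle, config$k_folds, derive_seed(seed, "split"))
  specs <- config$strategies
  G <- config$backbone$diagnosis_classes

  preds_test <- list()   # prognosis-cohort test predictions
  preds_diag <- list()   # all test-patient scans (diagnosis evaluation)
  thresholds <- list()   # per strategy/fold Youden thresholds
  audit_rows <- list()
  logs <- list()

  # dedicated diagnosis-validation patients for phase-1 checkpointing,
  # carved from the patients that belong to the diagnosis cohort only (so
  # they sit in every fold's pretraining set and never in a prognosis
  # split); falls back to the fold's validation patients when the whole
  # population carries prognosis labels
  prog_patients <- unique(bundle$scans$patient_id[
    !is.na(bundle$scans$progression_label)])
  diag_only <- setdiff(unique(bundle$scans$patient_id), prog_patients)
  dval_patients <- if (length(diag_only) >= 10L) {
    with_stream(rng_stream(derive_seed(seed, "diagval")),
                sample(diag_only, max(5L, round(0.15 * length(diag_only)))))
  } else character(0)

  for (f in plan$folds) {
    fi <- f$fold_index
    say("  fold ", fi)
    prog_train <- scan_dataset(bundle, patient_scan_idx(bundle, f$train_patients, TRUE))
    prog_val <- scan_dataset(bundle, patient_scan_idx(bundle, f$val_patients, TRUE))
    prog_test <- scan_dataset(bundle, patient_scan_idx(bundle, f$test_patients, TRUE))
    dval_fold <- if (length(dval_patients)) dval_patients else f$val_patients
    # the fold's validation patients are also excluded from diagnosis
    # training (strictly more conservative than the test-only holdout), so
    # their graded scans join the held-out pool on which forgetting is
    # measured
    diag_pool <- scan_dataset(bundle, patient_scan_idx(
      bundle, setdiff(f$pretrain_diagnosis_patients,
                      union(dval_fold, f$val_patients))))
    diag_val <- scan_dataset(bundle, patient_scan_idx(bundle, dval_fold))
    diag_test <- scan_dataset(bundle, patient_scan_idx(
      bundle, union(f$test_patients, f$val_patients)))

    phase1 <- NULL
    if (needs_phase1(specs)) {
      cfg1 <- config$train
      cfg1$seed <- derive_seed(seed, paste0("train/diagnosis_reference/", fi))
      phase1 <- train_diagnosis_reference(diag_pool, diag_val, cfg1,
                                          config$backbone)
      phase1$fold_index <- fi
      if (!"diagnosis_reference" %in% names(specs)) {
        audit_rows[[length(audit_rows) + 1L]] <- data.frame(
          seed = seed, fold = fi, strategy = "diagnosis_reference",
          stage = "pretrain",
          diag_scans = I(list(phase1$audit$diagnosis)),
          prog_scans = I(list(phase1$audit$prognosis)),
          stringsAsFactors = FALSE)
      }
    }

    for (spec in specs) {
      label <- spec$label
      cfg <- config$train
      cfg$seed <- derive_seed(seed, paste0("train/", label, "/", fi))
      model <- if (spec$name == "diagnosis_reference") {
        phase1
      } else if (spec$name == "prognosis_single_task") {
        train_prognosis_single_task(prog_train, prog_val, spec$init, cfg,
                                    config$backbone, phase1)
      } else {
        train_multitask(spec, prog_train, prog_val, diag_pool, cfg,
                        config$backbone, phase1)
      }
      model$fold_index <- fi

      audit_rows[[length(audit_rows) + 1L]] <- data.frame(
        seed = seed, fold = fi, strategy = label,
        stage = "train",
        diag_scans = I(list(model$audit$diagnosis)),
        prog_scans = I(list(model$audit$prognosis)),
        stringsAsFactors = FALSE)
      lg <- model$training_log
      if (!is.null(lg)) {
        lg$seed <- seed; lg$fold <- fi; lg$strategy <- label
        logs[[length(logs) + 1L]] <- lg
      }

      if (spec$name != "diagnosis_reference" && prog_test$n > 0L) {
        pt <- predict_scans(model, prog_test)
        pt$fold_index <- fi
        pt$strategy <- label
        pt$label <- prog_test$prog
        preds_test[[paste(label, fi)]] <- pt
        if (prog_val$n > 0L && length(unique(prog_val$prog)) >= 2L) {
          pv <- predict_scans(model, prog_val)
          thresholds[[label]][[as.character(fi)]] <-
            youden_threshold(pv$prognosis_score, prog_val$prog)
        }
      }
      pd <- predict_scans(model, diag_test)
      pd$fold_index <- fi
      pd$strategy <- label
      pd$grade <- diag_test$grade
      preds_diag[[paste(label, fi)]] <- pd
    }
  }

  metrics <- compute_metric_reports(config, preds_test, preds_diag,
                                    thresholds, G)
  delong <- compute_delong(config, preds_test)
  forgetting <- compute_forgetting(config, preds_diag, G)
  subgroup <- compute_subgroups(config, preds_test, bundle)

  list(seed = seed,
       generator_seed = gcfg$seed,
       plan = plan,
       scans = bundle$scans[, c("scan_id", "patient_id", "visit_index",
                                "grade", "progression_label")],
       predictions_prognosis = do.call(rbind, unname(preds_test)),
       predictions_diagnosis = do.call(rbind, unname(preds_diag)),
       metrics = metrics, delong = delong, forgetting = forgetting,
       subgroup = subgroup,
       audit = audit_rows,
       training_logs = do.call(rbind, logs))
}

compute_metric_reports <- function(config, preds_test, preds_diag,
                                   thresholds, G) {
  out <- list()
  for (spec in config$strategies) {
    label <- spec$label
    rep <- list(strategy = label)
    # prognosis metrics per fold
    pt <- preds_test[grep(paste0("^", gsub("([:.|()^$*+?])", "\\\\\\1", label),
                                 " "), names(preds_test))]
    if (length(pt)) {
      fold_rows <- lapply(pt, function(df) {
        fi <- df$fold_index[1]
        th <- thresholds[[label]][[as.character(fi)]]
        ss <- if (!is.null(th)) {
          sens_spec_at_threshold(df$prognosis_score, df$label, th)
        } else list(sensitivity = NA_real_, specificity = NA_real_)
        ok <- length(unique(df$label)) >= 2L
        data.frame(fold = fi,
                   auroc = if (ok) auroc(df$prognosis_score, df$label) else NA,
                   auprc = if (any(df$label == 1)) auprc(df$prognosis_score, df$label) else NA,
                   sensitivity = ss$sensitivity,
                   specificity = ss$specificity,
                   threshold = if (is.null(th)) NA_real_ else th)
      })
      rep$prognosis_folds <- do.call(rbind, unname(fold_rows))
      pooled <- do.call(rbind, unname(pt))
      rep$prognosis_pooled <- pooled
      rep$ensembled_auroc <- auroc(pooled$prognosis_score, pooled$label)
    }
    # diagnosis metrics per fold
    pdl <- preds_diag[grep(paste0("^", gsub("([:.|()^$*+?])", "\\\\\\1", label),
                                  " "), names(preds_diag))]
    if (length(pdl)) {
      prob_cols <- paste0("grade_prob_", seq_len(G) - 1L)
      fold_rows <- lapply(pdl, function(df) {
        probs <- as.matrix(df[prob_cols])
        pred <- max.col(probs, ties.method = "first") - 1L
        cm <- confusion_matrix(df$grade, pred, G)
        mm <- suppressWarnings(macro_micro_auroc(probs, df$grade))
        data.frame(fold = df$fold_index[1],
                   balanced_accuracy = suppressWarnings(balanced_accuracy(cm)),
                   macro_auroc = mm$macro, micro_auroc = mm$micro)
      })
      rep$diagnosis_folds <- do.call(rbind, unname(fold_rows))
      pooled <- do.call(rbind, unname(pdl))
      probs <- as.matrix(pooled[prob_cols])
      pred <- max.col(probs, ties.method = "first") - 1L
      rep$confusion <- confusion_matrix(pooled$grade, pred, G)
      rep$pooled_balanced_accuracy <-
        suppressWarnings(balanced_accuracy(rep$confusion))
      support <- rowSums(rep$confusion)
      rep$per_class_recall <- ifelse(support > 0,
                                     diag(rep$confusion) / support, NA_real_)
    }
    out[[label]] <- rep
  }
  out
}

compute_delong <- function(config, preds_test) {
  if (!length(preds_test)) return(NULL)
  pooled <- do.call(rbind, unname(preds_test))
  rows <- lapply(config$delong_pairs, function(pair) {
    a <- pooled[pooled$strategy == pair[1], c("scan_id", "prognosis_score", "label")]
    b <- pooled[pooled$strategy == pair[2], c("scan_id", "prognosis_score", "label")]
    if (!nrow(a) || !nrow(b)) return(NULL)
    m <- merge(a, b, by = "scan_id", suffixes = c("_a", "_b"))
    dl <- delong_test(m$prognosis_score_a, m$prognosis_score_b, m$label_a)
    data.frame(strategy_a = pair[1], strategy_b = pair[2],
               auroc_a = dl$auroc_a, auroc_b = dl$auroc_b,
               z = dl$z, p = dl$p, n = dl$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

compute_forgetting <- function(config, preds_diag, G) {
  labels <- names(config$strategies)
  if (!"diagnosis_reference" %in% labels) return(NULL)
  pooled <- do.call(rbind, unname(preds_diag))
  prob_cols <- paste0("grade_prob_", seq_len(G) - 1L)
  ref <- pooled[pooled$strategy == "diagnosis_reference", ]
  ref <- ref[order(ref$scan_id, ref$fold_index), ]
  others <- setdiff(labels, "diagnosis_reference")
  strat_scores <- lapply(others, function(l) {
    df <- pooled[pooled$strategy == l, ]
    df <- df[order(df$scan_id, df$fold_index), ]
    stopifnot(identical(df$scan_id, ref$scan_id))
    as.matrix(df[prob_cols])
  })
  names(strat_scores) <- others
  suppressWarnings(forgetting_report(strat_scores, as.matrix(ref[prob_cols]),
                                     ref$grade))
}

compute_subgroups <- function(config, preds_test, bundle) {
  if (!length(preds_test)) return(NULL)
  pooled <- do.call(rbind, unname(preds_test))
  base_grade <- bundle$scans$grade[match(pooled$scan_id, bundle$scans$scan_id)]
  follow <- bundle$scans$followup_grade[match(pooled$scan_id, bundle$scans$scan_id)]
  sg <- assign_subgroup(base_grade, follow, config$generator$n_grades)
  rows <- lapply(unique(pooled$strategy), function(l) {
    sel <- pooled$strategy == l
    df <- suppressWarnings(subgroup_report(pooled$prognosis_score[sel],
                                           pooled$label[sel],
                                           sg$subgroup[sel]))
    if (!is.null(df) && nrow(df)) df$strategy <- l
    df
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' End-to-end patient-level leakage audit
#'
#' Replays every recorded data access of every training run and checks that
#' no scan of a fold's test patients was ever touched by that fold's
#' training or pretraining stage.
#'
#' @param result an `experiment_result`.
#' @return data frame with one row per (seed, fold, strategy) and a
#'   `violations` count; the audit passes iff all counts are zero.
#' @export
leakage_audit <- function(result) {
  rows <- list()
  for (sd in result$seeds) {
    scan_patient <- stats::setNames(sd$scans$patient_id, sd$scans$scan_id)
    for (i in seq_along(sd$audit)) {
      a <- sd$audit[[i]]
      f <- sd$plan$folds[[a$fold + 1L]]
      touched <- unique(c(a$diag_scans[[1]], a$prog_scans[[1]]))
      touched_patients <- unique(scan_patient[touched])
      rows[[length(rows) + 1L]] <- data.frame(
        seed = a$seed, fold = a$fold, strategy = a$strategy,
        n_scans_touched = length(touched),
        violations = sum(touched_patients %in% f$test_patients),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# ---- report -----------------------------------------------------------------

fmt_mean_sd <- function(values, digits = 3L) {
  v <- values[is.finite(values)]
  if (!length(v)) return("-")
  paste0(formatC(mean(v), digits = digits, format = "f"), " ± ",
         formatC(stats::sd(v), digits = digits, format = "f"))
}

# gather one prognosis metric's per-fold values across seeds for a strategy
gather_metric <- function(result, label, metric, task = "prognosis") {
  unlist(lapply(result$seeds, function(sd) {
    rep <- sd$metrics[[label]]
    df <- rep[[paste0(task, "_folds")]]
    if (is.null(df)) return(NULL)
    df[[metric]]
  }))
}

#' Build the three-table report
#'
#' Table 1 analog: initialization comparison for single-task prognosis.
#' Table 2 analog: prognosis metrics across multitask strategies.
#' Table 3 analog: diagnosis metrics (forgetting) across strategies against
#' the dedicated reference. Cells are `mean +/- sd` over all folds and
#' replicate seeds; the best value per row is marked with `*`. Machine
#' readable long-format tables accompany the formatted ones.
#'
#' @param result an `experiment_result`.
#' @return list with `init_comparison`, `prognosis_mt`, `diagnosis_mt`
#'   (formatted) and `long` (machine-readable).
#' @export
build_report <- function(result) {
  labels <- names(result$config$strategies)
  prog_labels <- setdiff(labels, "diagnosis_reference")
  prog_metrics <- c("auroc", "auprc", "sensitivity", "specificity")
  diag_metrics <- c("balanced_accuracy", "macro_auroc", "micro_auroc")

  long <- list()
  for (l in labels) {
    for (m in prog_metrics) {
      v <- gather_metric(result, l, m, "prognosis")
      if (length(v)) long[[length(long) + 1L]] <-
          data.frame(strategy = l, task = "prognosis", metric = m,
                     mean = mean(v[is.finite(v)]), sd = stats::sd(v[is.finite(v)]),
                     n_folds = sum(is.finite(v)), stringsAsFactors = FALSE)
    }
    for (m in diag_metrics) {
      v <- gather_metric(result, l, m, "diagnosis")
      if (length(v)) long[[length(long) + 1L]] <-
          data.frame(strategy = l, task = "diagnosis", metric = m,
                     mean = mean(v[is.finite(v)]), sd = stats::sd(v[is.finite(v)]),
                     n_folds = sum(is.finite(v)), stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, long)

  make_table <- function(cols, metrics, task) {
    cols <- intersect(cols, if (is.null(long)) character(0) else
      unique(long$strategy[long$task == task]))
    if (!length(cols)) return(NULL)
    tb <- data.frame(metric = metrics, stringsAsFactors = FALSE)
    means <- matrix(NA_real_, length(metrics), length(cols),
                    dimnames = list(metrics, cols))
    for (l in cols) {
      cells <- character(length(metrics))
      for (i in seq_along(metrics)) {
        v <- gather_metric(result, l, metrics[i], task)
        cells[i] <- fmt_mean_sd(v)
        vv <- v[is.finite(v)]
        if (length(vv)) means[i, l] <- mean(vv)
      }
      tb[[l]] <- cells
    }
    # best-per-metric marker = arg-max of the mean over columns
    for (i in seq_along(metrics)) {
      if (all(!is.finite(means[i, ]))) next
      best <- which.max(means[i, ])
      tb[i, 1L + best] <- paste0(tb[i, 1L + best], " *")
    }
    tb
  }

  init_cols <- intersect(c("prognosis_single_task:random",
                           "prognosis_single_task:diagnosis_pretrained"),
                         prog_labels)
  mt_cols <- intersect(c("prognosis_single_task:diagnosis_pretrained",
                         "single_cohort_mt", "concurrent_mt",
                         "diag_pretrained_mt", "seq_replay"), prog_labels)
  diag_cols <- intersect(c("diagnosis_reference", "single_cohort_mt",
                           "concurrent_mt", "diag_pretrained_mt",
                           "seq_replay",
                           "prognosis_single_task:diagnosis_pretrained",
                           "prognosis_single_task:random"), labels)
  missing <- setdiff(c(init_cols, mt_cols), labels)
  if (length(missing)) warning("strategies missing from report: ",
                               paste(missing, collapse = ", "))
  list(init_comparison = make_table(init_cols, prog_metrics, "prognosis"),
       prognosis_mt = make_table(mt_cols, prog_metrics, "prognosis"),
       diagnosis_mt = make_table(diag_cols, diag_metrics, "diagnosis"),
       long = long)
}

write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  yaml::write_yaml(experiment_config_to_list(cfg), file.path(dir, "config.yaml"), precision = 15L)
  for (nm in c("init_comparison", "prognosis_mt", "diagnosis_mt", "long")) {
    tb <- result$tables[[nm]]
    if (!is.null(tb)) utils::write.csv(tb, file.path(dir, paste0("table_", nm, ".csv")),
                                       row.names = FALSE)
  }
  utils::write.csv(result$audit, file.path(dir, "leakage_audit.csv"),
                   row.names = FALSE)
  for (sd in result$seeds) {
    sdir <- file.path(dir, paste0("seed_", sd$seed))
    dir.create(sdir, showWarnings = FALSE)
    if (!is.null(sd$predictions_prognosis)) {
      utils::write.csv(sd$predictions_prognosis,
                       file.path(sdir, "predictions_prognosis.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(sd$predictions_diagnosis,
                     file.path(sdir, "predictions_diagnosis.csv"),
                     row.names = FALSE)
    if (!is.null(sd$delong)) {
      utils::write.csv(sd$delong, file.path(sdir, "delong.csv"),
                       row.names = FALSE)
    }
    if (!is.null(sd$subgroup)) {
      utils::write.csv(sd$subgroup, file.path(sdir, "subgroup_auroc.csv"),
                       row.names = FALSE)
    }
    if (!is.null(sd$forgetting)) {
      for (l in names(sd$forgetting)) {
        base <- file.path(sdir, paste0("confusion_", gsub(":", "_", l)))
        cm <- sd$forgetting[[l]]$confusion
        utils::write.csv(cm, paste0(base, ".csv"))
        plot_confusion_png(cm, paste0(base, ".png"),
                           main = paste("diagnosis confusion:", l))
      }
    }
    if (!is.null(sd$training_logs)) {
      con <- file(file.path(sdir, "training_log.jsonl"), "w")
      for (i in seq_len(nrow(sd$training_logs))) {
        writeLines(jsonlite::toJSON(as.list(sd$training_logs[i, ]),
                                    auto_unbox = TRUE, digits = NA), con)
      }
      close(con)
    }
  }
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result:", length(x$seeds), "seed(s),",
      length(x$config$strategies), "strategies,",
      x$config$k_folds, "folds\n")
  if (!is.null(x$audit)) {
    cat("leakage audit violations:", sum(x$audit$violations), "\n")
  }
  for (nm in c("init_comparison", "prognosis_mt", "diagnosis_mt")) {
    tb <- x$tables[[nm]]
    if (is.null(tb)) next
    cat("\n--", nm, "--\n")
    print(tb, row.names = FALSE)
  }
  invisible(x)
}

# heatmap rendering of a confusion matrix (row-normalized shading, raw
# counts printed per cell)
plot_confusion_png <- function(cm, path, main = "confusion") {
  G <- nrow(cm)
  rs <- pmax(rowSums(cm), 1L)
  shade <- sweep(cm, 1, rs, "/")
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::image(seq_len(G), seq_len(G), t(shade[G:1, , drop = FALSE]),
                  col = grDevices::gray(seq(1, 0.2, length.out = 64)),
                  axes = FALSE, xlab = "predicted grade",
                  ylab = "true grade", main = main)
  graphics::axis(1, at = seq_len(G), labels = 0:(G - 1))
  graphics::axis(2, at = seq_len(G), labels = (G - 1):0)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    graphics::text(j, G + 1 - i, cm[i, j],
                   col = if (shade[i, j] > 0.5) "white" else "black")
  }
  graphics::box()
  invisible(path)
}

# ---- YAML config ------------------------------------------------------------

experiment_config_to_list <- function(config) {
  list(generator = unclass(config$generator),
       backbone = unclass(config$backbone)[c("conv_channels", "embedding_dim",
                                             "diagnosis_classes", "kernel_size")],
       train = unclass(config$train),
       k_folds = config$k_folds,
       strategies = unname(vapply(config$strategies, `[[`, character(1), "label")),
       seeds = config$seeds,
       delong_pairs = config$delong_pairs)
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_experiment_config()`: an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$generator)) args$generator <- do.call(generator_config, raw$generator)
  if (!is.null(raw$backbone)) args$backbone <- do.call(backbone_config, raw$backbone)
  if (!is.null(raw$train)) args$train <- do.call(train_config, raw$train)
  for (nm in c("k_folds", "strategies", "seeds")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$delong_pairs)) args$delong_pairs <- raw$delong_pairs
  do.call(experiment_config, args)
}

#' @rdname read_experiment_config
#' @param config an [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(experiment_config_to_list(config), path, precision = 15L)
  invisible(path)
}
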