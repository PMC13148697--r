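#' Patient-level k-fold split plan with pretraining holdout
#'
#' Prognosis-cohort patients are partitioned into `k` folds. For fold `i`:
#' the fold itself is the held-out test set, the next fold (cyclically) is
#' the validation set, and the remaining `k - 2` folds are the training
#' set. The diagnosis-pretraining set for fold `i` is every
#' diagnosis-cohort patient except that fold's test patients — the
#' leakage-safe "test set holdout", so prognosis models are always
#' evaluated on patients the entire pipeline, including pretraining, has
#' never seen. Patients, never scans, are the unit of assignment.
#'
#' @param bundle a `cohort_bundle`.
#' @param k number of folds (default 5).
#' @param seed integer seed for the patient shuffle.
#' @return an object of class `split_plan`: list with `folds` (each fold a
#'   list of `fold_index`, `test_patients`, `val_patients`,
#'   `train_patients`, `pretrain_diagnosis_patients`) and `seed`.
#' @export
make_split_plan <- function(bundle, k = 5L, seed = 1L) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  prog_patients <- sort(unique(
    bundle$scans$patient_id[!is.na(bundle$scans$progression_label)]))
  if (length(prog_patients) < k) {
    stop("fewer prognosis-cohort patients (", length(prog_patients),
         ") than folds (", k, ")", call. = FALSE)
  }
  all_patients <- unique(bundle$scans$patient_id)
  shuffled <- with_stream(rng_stream(seed), sample(prog_patients))
  fold_of <- rep(seq_len(k) - 1L, length.out = length(shuffled))
  folds <- lapply(seq_len(k) - 1L, function(i) {
    test <- shuffled[fold_of == i]
    val <- shuffled[fold_of == (i + 1L) %% k]
    train <- shuffled[!fold_of %in% c(i, (i + 1L) %% k)]
    list(fold_index = i,
         test_patients = test,
         val_patients = val,
         train_patients = train,
         pretrain_diagnosis_patients = setdiff(all_patients, test))
  })
  structure(list(folds = folds, k = as.integer(k), seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test_patients), integer(1))
  cat("split_plan:", x$k, "patient-level folds; test sizes",
      paste(sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Serialize / load a split plan
#'
#' One row per patient: `patient_id`, `fold_of_test` (empty for patients in
#' the diagnosis cohort only) and one `role_fold<i>` column per fold with
#' values `test`, `val`, `train` or `pretrain_only`.
#'
#' @param plan a `split_plan`.
#' @param path CSV file path.
#' @export
write_split_plan <- function(plan, path) {
  ids <- sort(unique(unlist(lapply(plan$folds, function(f)
    c(f$test_patients, f$pretrain_diagnosis_patients)))))
  df <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  df$fold_of_test <- NA_integer_
  for (f in plan$folds) df$fold_of_test[df$patient_id %in% f$test_patients] <- f$fold_index
  for (f in plan$folds) {
    role <- rep("pretrain_only", nrow(df))
    role[df$patient_id %in% f$train_patients] <- "train"
    role[df$patient_id %in% f$val_patients] <- "val"
    role[df$patient_id %in% f$test_patients] <- "test"
    df[[paste0("role_fold", f$fold_index)]] <- role
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_split_plan
#' @param seed seed recorded in the restored plan.
#' @export
read_split_plan <- function(path, seed = NA_integer_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  k <- sum(grepl("^role_fold", names(df)))
  folds <- lapply(seq_len(k) - 1L, function(i) {
    role <- df[[paste0("role_fold", i)]]
    list(fold_index = i,
         test_patients = df$patient_id[role == "test"],
         val_patients = df$patient_id[role == "val"],
         train_patients = df$patient_id[role == "train"],
         pretrain_diagnosis_patients = df$patient_id[role != "test"])
  })
  structure(list(folds = folds, k = as.integer(k), seed = as.integer(seed)),
            class = "split_plan")
}

#' Assign a scan to a clinical subgroup from its grade trajectory
#'
#' Baseline grade 0-1: the incidence stratum, with event = reaching grade 2
#' or above at follow-up. Baseline grade 2 to `n_grades - 2`: the
#' progression stratum, with event = any grade increase. Maximal baseline
#' grade: excluded. Grades are non-decreasing in this synthetic world, so a
#' follow-up grade below baseline is an input error.
#'
#' @param baseline_grade,followup_grade integer grades (vectorized).
#' @param n_grades number of grades.
#' @return data frame with columns `subgroup` (`"incidence"`,
#'   `"progression"` or `"excluded"`) and `event` (0/1, `NA` when excluded).
#' @export
assign_subgroup <- function(baseline_grade, followup_grade, n_grades = 5L) {
  stopifnot(length(baseline_grade) == length(followup_grade),
            all(baseline_grade >= 0 & baseline_grade <= n_grades - 1L),
            all(followup_grade >= 0 & followup_grade <= n_grades - 1L))
  if (any(followup_grade < baseline_grade)) {
    stop("follow-up grade below baseline: grades are non-decreasing",
         call. = FALSE)
  }
  subgroup <- ifelse(baseline_grade <= 1L, "incidence",
                     ifelse(baseline_grade <= n_grades - 2L, "progression",
                            "excluded"))
  event <- ifelse(subgroup == "incidence", as.integer(followup_grade >= 2L),
                  ifelse(subgroup == "progression",
                         as.integer(followup_grade > baseline_grade),
                         NA_integer_))
  data.frame(subgroup = subgroup, event = event, stringsAsFactors = FALSE)
}
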