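# Small cohort/training fixtures shared across test files; everything is
# generated in code at test time.

rng_stream_for_test <- function(seed) seqreplay:::rng_stream(seed)

tiny_generator_config <- function(...) {
  args <- list(n_patients = 40L, image_size = 32L,
               prognosis_cohort_fraction = 0.5, seed = 11L)
  args[names(list(...))] <- list(...)
  do.call(generator_config, args)
}

tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_cohorts(tiny_generator_config())
    cache
  }
})

fast_train_config <- function(...) {
  args <- list(epochs = 2L, batch_size = 16L, seed = 5L)
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}

tiny_backbone <- function() {
  backbone_config(conv_channels = c(4L, 8L), embedding_dim = 16L,
                  diagnosis_classes = 5L)
}

# fold datasets for the tiny bundle
tiny_fold_data <- function(bundle = tiny_bundle(), k = 3L, seed = 3L,
                           fold = 1L) {
  plan <- make_split_plan(bundle, k, seed)
  f <- plan$folds[[fold]]
  list(
    plan = plan, fold = f,
    prog_train = scan_dataset(bundle, seqreplay:::patient_scan_idx(
      bundle, f$train_patients, TRUE)),
    prog_val = scan_dataset(bundle, seqreplay:::patient_scan_idx(
      bundle, f$val_patients, TRUE)),
    prog_test = scan_dataset(bundle, seqreplay:::patient_scan_idx(
      bundle, f$test_patients, TRUE)),
    diag_pool = scan_dataset(bundle, seqreplay:::patient_scan_idx(
      bundle, setdiff(f$pretrain_diagnosis_patients, f$val_patients))),
    diag_val = scan_dataset(bundle, seqreplay:::patient_scan_idx(
      bundle, f$val_patients)))
}
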