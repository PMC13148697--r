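test_that("latent patients have the configured correlation structure", {
  cfg <- generator_config(n_patients = 10000L,
                          severity_progression_correlation = 0)
  set.seed(1)
  p0 <- sample_patients(cfg)
  expect_equal(nrow(p0), 10000L)
  expect_false(anyDuplicated(p0$patient_id) > 0)
  expect_lt(abs(cor(p0$severity, p0$progression_rate)), 0.03)

  cfg$severity_progression_correlation <- 0.6
  p6 <- sample_patients(cfg, rng_stream_for_test(99))
  expect_lt(abs(cor(p6$severity, p6$progression_rate) - 0.6), 0.03)

  cfg$severity_progression_correlation <- 1
  p1 <- sample_patients(cfg, rng_stream_for_test(7))
  expect_equal(p1$progression_rate, p1$severity)

  expect_error(generator_config(severity_progression_correlation = 1.5),
               "\\[-1, 1\\]")
})

test_that("grade assignment thresholds severity correctly", {
  cut <- c(-1, 0, 1, 2)
  expect_equal(assign_grade(-5, cut), 0L)
  expect_equal(assign_grade(5, cut), 4L)
  expect_equal(assign_grade(c(-1, 0, 0.5), cut), c(0L, 1L, 2L))  # strict
  expect_error(assign_grade(NaN, cut), "non-finite")
})

test_that("default cutpoints reproduce the target grade priors", {
  set.seed(2)
  s <- rnorm(10000)
  g <- assign_grade(s, generator_config()$grade_cutpoints)
  freq <- tabulate(g + 1L, 5) / 10000
  expect_true(all(abs(freq - c(0.35, 0.30, 0.20, 0.12, 0.03)) < 0.02))
})

test_that("progression outcomes follow the logistic model", {
  cfg <- generator_config(progression_intercept = -50,
                          progression_severity_coef = 0,
                          progression_rate_coef = 0)
  set.seed(3)
  r0 <- assign_progression(rnorm(500), rnorm(500), cfg)
  expect_true(all(r0$label == 0))
  expect_true(all(r0$probability < 1e-10))

  cfg2 <- generator_config(progression_intercept = 0,
                           progression_severity_coef = 0,
                           progression_rate_coef = 0)
  r5 <- assign_progression(rnorm(10000), rnorm(10000), cfg2)
  expect_lt(abs(mean(r5$label) - 0.5), 0.02)

  cfg3 <- generator_config(progression_severity_coef = 0,
                           progression_rate_coef = 1.5)
  pr <- rnorm(4000)
  r3 <- assign_progression(rnorm(4000), pr, cfg3)
  expect_gt(mean(r3$label[pr > 1]), mean(r3$label[pr < -1]))
})

test_that("image rendering is deterministic and monotone in severity", {
  cfg <- generator_config(pixel_noise_sd = 0)
  a <- render_image(0.5, 0.2, cfg, rng_stream_for_test(4))
  b <- render_image(0.5, 0.2, cfg, rng_stream_for_test(4))
  expect_identical(a, b)
  hi <- render_image(3, 0, cfg, rng_stream_for_test(5))
  lo <- render_image(-3, 0, cfg, rng_stream_for_test(5))
  expect_lt(measure_gap_width(hi), measure_gap_width(lo))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("texture ablation removes the progression-rate channel", {
  cfg <- generator_config(pixel_noise_sd = 0, texture_amplitude_coef = 0)
  a <- render_image(0.3, -2, cfg, rng_stream_for_test(6))
  b <- render_image(0.3, 2, cfg, rng_stream_for_test(6))
  expect_identical(a, b)
  cfg$texture_amplitude_coef <- 0.35
  a2 <- render_image(0.3, -2, cfg, rng_stream_for_test(6))
  b2 <- render_image(0.3, 2, cfg, rng_stream_for_test(6))
  expect_false(identical(a2, b2))
})

test_that("oversized bands are rejected", {
  cfg <- generator_config(image_size = 32L, gap_width_range = c(20, 30))
  expect_error(render_image(0, 0, cfg), "too small")
})

test_that("cohort construction applies the maximal-grade exclusion", {
  bundle <- tiny_bundle()
  sc <- bundle$scans
  # diagnosis cohort covers everything; prognosis is a labelled subset
  expect_true(all(which(!is.na(sc$progression_label)) %in% seq_len(nrow(sc))))
  # maximal-grade scans never carry progression labels
  expect_true(all(is.na(sc$progression_label[sc$grade == 4])))
  # each scan resolves to exactly one patient
  expect_true(all(sc$patient_id %in% bundle$patients$patient_id))
  # grade-4 scans of prognosis-cohort patients stay in the diagnosis cohort
  prog_pat <- bundle$patients$patient_id[bundle$patients$in_prognosis_cohort]
  g4 <- sc$grade == 4 & sc$patient_id %in% prog_pat
  if (any(g4)) expect_true(all(is.na(sc$progression_label[g4])))
})

test_that("full-fraction cohort without maximal grades has no exclusions", {
  cfg <- generator_config(n_patients = 20L, n_grades = 2L,
                          grade_cutpoints = 10,  # nobody reaches grade 1
                          prognosis_cohort_fraction = 1,
                          image_size = 32L, seed = 2L)
  b <- build_cohorts(cfg, render = FALSE)
  expect_true(all(!is.na(b$scans$progression_label)))
})

test_that("an all-maximal-grade cohort raises a generation error", {
  cfg <- generator_config(n_patients = 10L, n_grades = 2L,
                          grade_cutpoints = -10,  # everyone at grade 1
                          prognosis_cohort_fraction = 1,
                          image_size = 32L, seed = 2L)
  expect_error(build_cohorts(cfg, render = FALSE), "empty")
})

test_that("regeneration with the same seed is byte-identical", {
  cfg <- tiny_generator_config()
  d1 <- file.path(tempdir(), "cohortA")
  d2 <- file.path(tempdir(), "cohortB")
  write_cohort(build_cohorts(cfg), d1)
  write_cohort(build_cohorts(cfg), d2)
  expect_identical(readBin(file.path(d1, "cohort.csv"), "raw", 1e6),
                   readBin(file.path(d2, "cohort.csv"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "groundtruth.csv"), "raw", 1e6),
                   readBin(file.path(d2, "groundtruth.csv"), "raw", 1e6))
  # and a different seed is not
  cfg$seed <- cfg$seed + 1L
  d3 <- file.path(tempdir(), "cohortC")
  write_cohort(build_cohorts(cfg), d3)
  expect_false(identical(readBin(file.path(d1, "cohort.csv"), "raw", 1e6),
                         readBin(file.path(d3, "cohort.csv"), "raw", 1e6)))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("cohort round-trips through disk", {
  bundle <- tiny_bundle()
  d <- file.path(tempdir(), "cohortRT")
  write_cohort(bundle, d)
  back <- read_cohort(d)
  expect_equal(back$scans$scan_id, bundle$scans$scan_id)
  expect_equal(back$scans$grade, bundle$scans$grade)
  expect_equal(back$scans$progression_label, bundle$scans$progression_label)
  expect_equal(back$scans$followup_grade, bundle$scans$followup_grade)
  # PNG round-trip is 8-bit quantized
  expect_lt(max(abs(back$images - bundle$images)), 1 / 254)
  unlink(d, recursive = TRUE)
})

test_that("closed-form oracle AUROC behaves and matches simulation", {
  cfg0 <- generator_config(progression_severity_coef = 0,
                           progression_rate_coef = 0)
  expect_equal(oracle_auroc_closed_form(cfg0), 0.5)

  cfg <- generator_config()
  a1 <- oracle_auroc_closed_form(cfg)
  cfg10 <- cfg
  cfg10$progression_severity_coef <- cfg$progression_severity_coef * 10
  cfg10$progression_rate_coef <- cfg$progression_rate_coef * 10
  expect_gt(oracle_auroc_closed_form(cfg10), a1)

  set.seed(12)
  p <- sample_patients(generator_config(n_patients = 5000L))
  lab <- assign_progression(p$severity, p$progression_rate, cfg)$label
  eta <- cfg$progression_intercept +
    cfg$progression_severity_coef * p$severity +
    cfg$progression_rate_coef * p$progression_rate
  expect_lt(abs(a1 - auroc(eta, lab)), 0.02)

  # severity-only ceiling sits strictly below the full oracle
  expect_lt(oracle_auroc_closed_form(cfg, "severity_only"), a1)
})
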