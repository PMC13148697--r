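#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical skeleton of a paired
#' diagnosis/prognosis imaging study: a large cross-sectional cohort with an
#' ordinal severity grade per scan (imbalanced priors including a rare top
#' grade), and a small longitudinal subset, drawn from the same patient
#' population, with a binary progression-within-horizon outcome. Each
#' patient carries two correlated standard-normal latents: current severity
#' `s` and a progression rate `r` (correlation `rho`). Grades arise by
#' thresholding severity at `grade_cutpoints`; the progression outcome is
#' Bernoulli with logit `alpha + beta_s * s + beta_r * r`, so the prognostic
#' signal is correlated with — but not determined by — baseline severity.
#' Images carry severity through a joint-space-narrowing analog (gap width
#' between two bright bands) and a lesion-count analog, and carry the
#' progression rate exclusively through band-edge texture amplitude.
#'
#' @param n_patients number of patients.
#' @param scans_per_patient_range integer interval, scans drawn uniformly.
#' @param n_grades number of severity grades (default 5, grades 0-4).
#' @param grade_cutpoints ascending cutpoints on the severity scale; the
#'   default places the class priors at (0.35, 0.30, 0.20, 0.12, 0.03) —
#'   a rare top grade so forgetting of rare classes is observable.
#' @param severity_progression_correlation `rho` in `[-1, 1]`.
#' @param progression_intercept,progression_severity_coef,progression_rate_coef
#'   logistic-model coefficients `alpha`, `beta_s`, `beta_r`.
#' @param horizon_label free-text outcome horizon recorded in metadata.
#' @param image_size pixels per side (>= 32).
#' @param gap_width_range pixel interval `(min, max)`; gap width decreases
#'   monotonically with severity within this range.
#' @param lesion_count_rate Poisson rate scale of bright spots at maximal
#'   severity.
#' @param texture_amplitude_coef amplitude scale of the band-edge texture
#'   carrying the progression-rate signal; 0 ablates the prognosis-only
#'   channel entirely.
#' @param pixel_noise_sd additive Gaussian pixel noise sd (>= 0).
#' @param prognosis_cohort_fraction patient-level fraction contributing
#'   progression labels, in `(0, 1]`.
#' @param visit_drift severity drift per visit for progressing patients
#'   (multiplied by `max(r, 0)`), keeping grades non-decreasing over visits.
#' @param followup_visits horizon length, in visit units, used to derive the
#'   follow-up grade for subgroup assignment.
#' @param seed integer seed; the single source of all generator randomness.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 600L,
                             scans_per_patient_range = c(1L, 3L),
                             n_grades = 5L,
                             grade_cutpoints = stats::qnorm(c(0.35, 0.65, 0.85, 0.97)),
                             severity_progression_correlation = 0.6,
                             progression_intercept = -0.7,
                             progression_severity_coef = 0.6,
                             progression_rate_coef = 1.2,
                             horizon_label = "4y",
                             image_size = 64L,
                             gap_width_range = c(4L, 18L),
                             lesion_count_rate = 4,
                             texture_amplitude_coef = 0.25,
                             pixel_noise_sd = 0.05,
                             prognosis_cohort_fraction = 0.2,
                             visit_drift = 0.5,
                             followup_visits = 2L,
                             seed = 1L) {
  rho <- severity_progression_correlation
  if (!is.finite(rho) || abs(rho) > 1) {
    stop("severity_progression_correlation must be finite and in [-1, 1]",
         call. = FALSE)
  }
  stopifnot(n_patients >= 1L, n_grades >= 2L,
            length(grade_cutpoints) == n_grades - 1L,
            all(diff(grade_cutpoints) > 0),
            is.finite(progression_intercept),
            is.finite(progression_severity_coef),
            is.finite(progression_rate_coef),
            image_size >= 32L, pixel_noise_sd >= 0,
            length(scans_per_patient_range) == 2L,
            scans_per_patient_range[1] >= 1L,
            scans_per_patient_range[2] >= scans_per_patient_range[1],
            length(gap_width_range) == 2L,
            gap_width_range[1] >= 1, gap_width_range[2] > gap_width_range[1],
            visit_drift >= 0, followup_visits >= 1L)
  if (prognosis_cohort_fraction <= 0 || prognosis_cohort_fraction > 1) {
    stop("prognosis_cohort_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    scans_per_patient_range = as.integer(scans_per_patient_range),
    n_grades = as.integer(n_grades),
    grade_cutpoints = as.numeric(grade_cutpoints),
    severity_progression_correlation = rho,
    progression_intercept = progression_intercept,
    progression_severity_coef = progression_severity_coef,
    progression_rate_coef = progression_rate_coef,
    horizon_label = horizon_label,
    image_size = as.integer(image_size),
    gap_width_range = as.numeric(gap_width_range),
    lesion_count_rate = lesion_count_rate,
    texture_amplitude_coef = texture_amplitude_coef,
    pixel_noise_sd = pixel_noise_sd,
    prognosis_cohort_fraction = prognosis_cohort_fraction,
    visit_drift = visit_drift,
    followup_visits = as.integer(followup_visits),
    seed = as.integer(seed)), class = "generator_config")
}

#' Sample latent patients
#'
#' Severity is standard normal; the progression rate is
#' `rho * severity + sqrt(1 - rho^2) * z` with independent standard-normal
#' `z`, so the two latents are standard normal with correlation `rho`.
#'
#' @param config a `generator_config`.
#' @param stream optional RNG substream (defaults to the current RNG state).
#' @return data frame with `patient_id`, `severity`, `progression_rate`.
#' @export
sample_patients <- function(config, stream = NULL) {
  draw <- function() {
    n <- config$n_patients
    rho <- config$severity_progression_correlation
    s <- stats::rnorm(n)
    z <- stats::rnorm(n)
    data.frame(patient_id = sprintf("P%05d", seq_len(n)),
               severity = s,
               progression_rate = rho * s + sqrt(1 - rho^2) * z,
               stringsAsFactors = FALSE)
  }
  if (is.null(stream)) draw() else with_stream(stream, draw())
}

#' Threshold a severity value into an ordinal grade
#'
#' The grade is the number of cutpoints strictly below the severity.
#'
#' @param severity numeric severity value(s).
#' @param cutpoints ascending cutpoint vector.
#' @return integer grade(s) in `[0, length(cutpoints)]`.
#' @export
assign_grade <- function(severity, cutpoints) {
  if (any(!is.finite(severity))) stop("non-finite severity", call. = FALSE)
  stopifnot(all(diff(cutpoints) > 0))
  findInterval(severity, cutpoints, left.open = TRUE)
}

#' Draw a progression outcome from the latent logistic model
#'
#' @param severity,progression_rate patient latents (vectorized).
#' @param config a `generator_config`.
#' @param stream optional RNG substream.
#' @return list with `label` (0/1) and `probability` (the Bernoulli
#'   probability, retained as ground truth for calibration).
#' @export
assign_progression <- function(severity, progression_rate, config,
                               stream = NULL) {
  stopifnot(all(is.finite(severity)), all(is.finite(progression_rate)))
  eta <- config$progression_intercept +
    config$progression_severity_coef * severity +
    config$progression_rate_coef * progression_rate
  p <- stats::plogis(eta)
  draw <- function() as.integer(stats::runif(length(p)) < p)
  label <- if (is.null(stream)) draw() else with_stream(stream, draw())
  list(label = label, probability = p)
}

# Geometry shared by rendering and gap measurement.
band_geometry <- function(config, severity) {
  S <- config$image_size
  g <- config$gap_width_range
  gap <- as.integer(round(g[2] - (g[2] - g[1]) * stats::pnorm(severity)))
  thick <- max(3L, as.integer(round(S * 0.12)))
  centre <- S / 2
  top_band <- c(floor(centre - gap / 2) - thick, floor(centre - gap / 2) - 1L)
  bot_band <- c(ceiling(centre + gap / 2), ceiling(centre + gap / 2) + thick - 1L)
  if (top_band[1] < 1L || bot_band[2] > S) {
    stop("image_size too small to fit both bands at this gap width",
         call. = FALSE)
  }
  list(gap = gap, thick = thick, top = top_band, bottom = bot_band)
}

#' Render one synthetic scan
#'
#' The image holds three signals: (i) two horizontal bright bands whose gap
#' narrows monotonically with severity (joint-space-narrowing analog);
#' (ii) a Poisson count of small bright spots on the band edges with rate
#' increasing in severity (osteophyte analog); (iii) a sinusoidal band-edge
#' texture whose amplitude grows with the progression rate — the only
#' channel carrying prognosis-specific signal. Additive Gaussian pixel
#' noise is applied last and the image clipped to `[0, 1]`. The draw order
#' (lesion count, lesion positions, texture phase, noise) is fixed, so
#' ablating the texture coefficient leaves all other randomness unchanged.
#'
#' @inheritParams assign_progression
#' @return `image_size x image_size` numeric matrix in `[0, 1]`.
#' @export
render_image <- function(severity, progression_rate, config, stream = NULL) {
  draw <- function() {
    S <- config$image_size
    geo <- band_geometry(config, severity)
    img <- matrix(0.05, S, S)
    img[geo$top[1]:geo$top[2], ] <- 0.8
    img[geo$bottom[1]:geo$bottom[2], ] <- 0.8
    # lesions: bright 2x2 spots on the bands' inner edges
    n_lesions <- stats::rpois(1, config$lesion_count_rate * stats::pnorm(severity))
    if (n_lesions > 0) {
      xs <- sample.int(S - 1L, n_lesions, replace = TRUE)
      on_top <- stats::runif(n_lesions) < 0.5
      for (i in seq_len(n_lesions)) {
        row <- if (on_top[i]) geo$top[2] - 1L else geo$bottom[1]
        img[row:(row + 1L), xs[i]:(xs[i] + 1L)] <- 1
      }
    }
    # band texture: progression-rate signal only. A coarse (4-cycle)
    # random-phase intensity ripple along both bands; the large spatial
    # footprint keeps its energy detectable after augmentation, and the
    # amplitude ceiling keeps band pixels well above the gap-measurement
    # threshold.
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- config$texture_amplitude_coef * stats::pnorm(progression_rate)
    ripple <- amp * sin(2 * pi * 4 * seq_len(S) / S + phase)
    band_rows <- c(geo$top[1]:geo$top[2], geo$bottom[1]:geo$bottom[2])
    img[band_rows, ] <- img[band_rows, ] +
      matrix(ripple, length(band_rows), S, byrow = TRUE)
    if (config$pixel_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(S * S, 0, config$pixel_noise_sd), S, S)
    }
    pmin(pmax(img, 0), 1)
  }
  if (is.null(stream)) draw() else with_stream(stream, draw())
}

#' Measure the inter-band gap width of a rendered image
#'
#' Counts the dark rows between the two bands along the centre column;
#' used by calibration tests to verify the monotone severity -> gap map.
#'
#' @param img image matrix from [render_image()].
#' @return integer gap width in pixels.
#' @export
measure_gap_width <- function(img) {
  col <- img[, ncol(img) %/% 2]
  dark <- col < 0.45
  centre <- length(col) %/% 2
  lo <- centre
  while (lo > 1L && dark[lo - 1L]) lo <- lo - 1L
  hi <- centre
  while (hi < length(col) && dark[hi + 1L]) hi <- hi + 1L
  if (!dark[centre]) return(0L)
  hi - lo + 1L
}

#' Generate the paired diagnosis/prognosis cohorts
#'
#' All scans receive a grade (diagnosis cohort). A patient-level random
#' subset of approximately `prognosis_cohort_fraction * n_patients` patients
#' contributes progression labels; within that subset, scans with the
#' maximal grade are excluded from the prognosis cohort (the synthetic
#' analog of excluding end-stage disease at baseline). All randomness
#' derives from `config$seed`.
#'
#' @param config a `generator_config`.
#' @param render if `FALSE`, skip image rendering (metadata only; used by
#'   large statistical calibration checks).
#' @return a `cohort_bundle`: list with `scans` (metadata data frame),
#'   `patients` (ground-truth latents), `images` (`S x S x n_scans` array or
#'   `NULL`), and `config`.
#' @export
build_cohorts <- function(config, render = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  patient_stream <- rng_stream(derive_seed(config$seed, "patients"))
  scan_stream <- rng_stream(derive_seed(config$seed, "scans"))
  label_stream <- rng_stream(derive_seed(config$seed, "labels"))
  image_stream <- rng_stream(derive_seed(config$seed, "images"))

  patients <- sample_patients(config, patient_stream)
  pr <- assign_progression(patients$severity, patients$progression_rate,
                           config, label_stream)
  patients$event_probability <- pr$probability
  patients$progression_label <- pr$label

  n_prog <- max(1L, round(config$prognosis_cohort_fraction * config$n_patients))
  prog_patients <- with_stream(label_stream,
                               sample(patients$patient_id, n_prog))
  patients$in_prognosis_cohort <- patients$patient_id %in% prog_patients

  rng <- config$scans_per_patient_range
  n_scans <- with_stream(scan_stream, {
    if (rng[1] == rng[2]) rep(rng[1], nrow(patients))
    else sample(seq(rng[1], rng[2]), nrow(patients), replace = TRUE)
  })
  rows <- rep(seq_len(nrow(patients)), n_scans)
  visit <- unlist(lapply(n_scans, function(k) seq_len(k) - 1L))
  drift <- config$visit_drift * pmax(patients$progression_rate[rows], 0)
  sev_scan <- patients$severity[rows] + drift * visit
  sev_follow <- sev_scan + drift * config$followup_visits
  grade <- assign_grade(sev_scan, config$grade_cutpoints)
  followup_grade <- assign_grade(sev_follow, config$grade_cutpoints)

  scans <- data.frame(
    scan_id = sprintf("%s_V%d", patients$patient_id[rows], visit),
    patient_id = patients$patient_id[rows],
    visit_index = visit,
    grade = grade,
    progression_label = ifelse(
      patients$in_prognosis_cohort[rows] & grade < config$n_grades - 1L,
      patients$progression_label[rows], NA_integer_),
    stringsAsFactors = FALSE)
  scans$image_path <- file.path("images", paste0(scans$scan_id, ".png"))
  scans$followup_grade <- followup_grade

  if (!any(!is.na(scans$progression_label))) {
    stop("prognosis cohort is empty after maximal-grade exclusions; ",
         "increase prognosis_cohort_fraction or n_patients", call. = FALSE)
  }

  images <- NULL
  if (render) {
    S <- config$image_size
    images <- array(0, dim = c(S, S, nrow(scans)))
    for (i in seq_len(nrow(scans))) {
      images[, , i] <- render_image(sev_scan[i],
                                    patients$progression_rate[rows[i]],
                                    config, image_stream)
    }
  }
  structure(list(scans = scans, patients = patients, images = images,
                 config = config), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", nrow(x$scans), "scans from", nrow(x$patients),
      "patients;", sum(!is.na(x$scans$progression_label)),
      "prognosis-labelled scans (horizon", x$config$horizon_label, ")\n")
  invisible(x)
}

# Scan indices (rows of bundle$scans) in the prognosis cohort.
prognosis_scan_idx <- function(bundle) which(!is.na(bundle$scans$progression_label))

#' Write / read a cohort to disk
#'
#' Metadata goes to `cohort.csv` with exactly the columns `scan_id`,
#' `patient_id`, `visit_index`, `grade`, `progression_label` (empty when
#' absent), `image_path`; ground-truth latents (calibration only) go to
#' `groundtruth.csv`; images are 8-bit grayscale PNG under `images/`.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()`: the directory, invisibly. `read_cohort()`: a
#'   `cohort_bundle` (ground truth and config restored from disk).
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- bundle$scans[, c("scan_id", "patient_id", "visit_index", "grade",
                           "progression_label", "image_path")]
  utils::write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  gt <- bundle$patients[, c("patient_id", "severity", "progression_rate",
                            "event_probability")]
  utils::write.csv(gt, file.path(dir, "groundtruth.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(unclass(bundle$config),
                       file.path(dir, "generator_config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$images)) {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    for (i in seq_len(nrow(bundle$scans))) {
      png::writePNG(bundle$images[, , i],
                    file.path(dir, bundle$scans$image_path[i]))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "cohort.csv"),
                          stringsAsFactors = FALSE)
  meta$progression_label <- suppressWarnings(as.integer(meta$progression_label))
  cfg_list <- jsonlite::read_json(file.path(dir, "generator_config.json"),
                                  simplifyVector = TRUE)
  config <- do.call(generator_config, cfg_list[setdiff(names(cfg_list), NULL)])
  patients <- utils::read.csv(file.path(dir, "groundtruth.csv"),
                              stringsAsFactors = FALSE)
  patients$in_prognosis_cohort <- patients$patient_id %in%
    meta$patient_id[!is.na(meta$progression_label)]
  images <- NULL
  first <- file.path(dir, meta$image_path[1])
  if (file.exists(first)) {
    S <- config$image_size
    images <- array(0, dim = c(S, S, nrow(meta)))
    for (i in seq_len(nrow(meta))) {
      images[, , i] <- png::readPNG(file.path(dir, meta$image_path[i]))
    }
  }
  drift <- config$visit_drift *
    pmax(patients$progression_rate[match(meta$patient_id, patients$patient_id)], 0)
  sev <- patients$severity[match(meta$patient_id, patients$patient_id)] +
    drift * meta$visit_index
  meta$followup_grade <- assign_grade(sev + drift * config$followup_visits,
                                      config$grade_cutpoints)
  structure(list(scans = meta, patients = patients, images = images,
                 config = config), class = "cohort_bundle")
}

#' Closed-form AUROC of the generative (Bayes) score
#'
#' Under the latent model the optimal score for the progression label is
#' `eta = alpha + beta_s * s + beta_r * r`, which is normal with mean
#' `alpha` and variance `beta_s^2 + beta_r^2 + 2 rho beta_s beta_r`. The
#' AUROC of any score `t` with event probability `pi(t)` and density `w(t)`
#' is computed by 1-D numerical integration of the positive-class density
#' against the negative-class CDF. With `score = "severity_only"` the score
#' is the severity latent alone (its event probability integrates over
#' `r | s`), giving the ceiling attainable when the texture channel is
#' ablated.
#'
#' @param config a `generator_config`.
#' @param score `"full"` for the Bayes score, `"severity_only"` for the
#'   severity-ceiling variant.
#' @param grid_points integration grid resolution.
#' @return the AUROC as a single number.
#' @export
oracle_auroc_closed_form <- function(config, score = c("full", "severity_only"),
                                     grid_points = 4001L) {
  score <- match.arg(score)
  a <- config$progression_intercept
  bs <- config$progression_severity_coef
  br <- config$progression_rate_coef
  rho <- config$severity_progression_correlation
  if (score == "full") {
    v <- bs^2 + br^2 + 2 * rho * bs * br
    if (v <= 0) return(0.5)  # uninformative score
    sd_eta <- sqrt(v)
    t <- seq(a - 10 * sd_eta, a + 10 * sd_eta, length.out = grid_points)
    w <- stats::dnorm(t, a, sd_eta)
    pi_t <- stats::plogis(t)
  } else {
    # score = s; pi(s) = E_{r|s} plogis(a + bs*s + br*r), r|s ~ N(rho*s, 1-rho^2)
    gh <- gauss_hermite(40L)
    t <- seq(-10, 10, length.out = grid_points)
    w <- stats::dnorm(t)
    sd_r <- sqrt(max(1 - rho^2, 0))
    pi_t <- vapply(t, function(s) {
      r <- rho * s + sd_r * gh$nodes
      sum(gh$weights * stats::plogis(a + bs * s + br * r))
    }, numeric(1))
    if (bs + rho * br == 0 && (sd_r == 0 || br == 0)) return(0.5)
  }
  auroc_of_score_curve(t, w, pi_t)
}

# AUROC of a scalar score with density w(t) and event probability pi(t),
# by trapezoid integration of f1(t) * F0(t) (ties have measure zero).
auroc_of_score_curve <- function(t, w, pi_t) {
  dt <- diff(t)
  trap <- function(f) sum(dt * (f[-1] + f[-length(f)]) / 2)
  f1 <- w * pi_t
  f0 <- w * (1 - pi_t)
  p1 <- trap(f1)
  p0 <- trap(f0)
  # cumulative trapezoid of f0 up to each grid point
  F0 <- c(0, cumsum(dt * (f0[-1] + f0[-length(f0)]) / 2))
  trap(f1 * F0 / p0) / p1
}

# Gauss-Hermite nodes/weights transformed for N(0,1) expectations.
gauss_hermite <- function(n) {
  # Golub-Welsch via the symmetric tridiagonal Jacobi matrix
  i <- seq_len(n - 1)
  J <- diag(0, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values * sqrt(2)
  weights <- e$vectors[1, ]^2
  list(nodes = nodes, weights = weights)
}
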