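#' Synthetic cohort configuration
#'
#' Ranges and shape parameters for the synthetic malignant-glioma cohort.
#' Defaults emulate the published characteristics of such cohorts: ages
#' 11-92 (median ~64), symptom duration 27-3119 days, prescription doses
#' 30-80 Gy with 60 Gy the typical prescription, treatment durations
#' 19-80 days (median ~50), and DVH curves concentrated near the
#' prescription dose with patient-specific heterogeneity.
#'
#' @param n_patients Number of patients (>= 3).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @param age_range,symptom_range,dose_range,duration_range Clinical and
#'   treatment ranges (years / days / Gy / days).
#' @param dose_levels,dose_probs Discrete prescription-dose levels (Gy)
#'   and sampling weights; must lie inside `dose_range`.
#' @param homogeneity Dose-homogeneity factor of the generated DVH curves
#'   (larger = sharper fall-off near the prescription dose).
#' @param cold_spot_max Upper bound of the per-patient cold-spot volume
#'   fraction, drawn uniformly on `[0, cold_spot_max)`.
#' @param ctv_local_volume Median and log-sd of the lognormal CTV_local
#'   volume distribution (cm^3).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 35, seed = 1,
                          age_range = c(11, 92),
                          symptom_range = c(27, 3119),
                          dose_range = c(30, 80),
                          duration_range = c(19, 80),
                          dose_levels = c(30, 40, 50, 60, 70, 80),
                          dose_probs = c(0.06, 0.08, 0.10, 0.56, 0.12, 0.08),
                          homogeneity = 12,
                          cold_spot_max = 0.3,
                          ctv_local_volume = c(median = 60, sdlog = 0.55)) {
  for (r in list(age_range, symptom_range, dose_range, duration_range))
    if (length(r) != 2L || r[1] > r[2]) stop("invalid range: min > max")
  if (n_patients < 3L) stop("n_patients must be >= 3")
  if (length(dose_levels) != length(dose_probs))
    stop("dose_levels and dose_probs lengths differ")
  if (any(dose_levels < dose_range[1] | dose_levels > dose_range[2]))
    stop("dose_levels must lie inside dose_range")
  if (cold_spot_max < 0 || cold_spot_max >= 1)
    stop("cold_spot_max must be in [0, 1)")
  structure(as.list(environment()), class = "cohort_config")
}

#' Ground-truth survival model of the synthetic cohort
#'
#' Survival (days) is generated as
#' `intercept + sum_j coef_j * z_j + dose_response + duration_effect *
#' (duration - 50) + noise`, floored at 1 day. The `z_j` are features
#' standardized by fixed reference scales (so each patient's noise-free
#' survival is an exact function of that patient's features alone). The
#' dose response rises linearly at `slope` days/Gy above 30 Gy up to a
#' per-patient plateau dose and declines at `decline` days/Gy beyond it
#' (escalation past tolerance harms); the plateau is
#' `plateau + spread * (2 * cold_fraction / cold_spot_max - 1)`, i.e.
#' patients whose target is underdosed (larger cold-spot fraction,
#' visible in their DVH) benefit from escalation up to a higher dose.
#'
#' @param intercept Baseline survival in days.
#' @param coefficients Named vector: effect sizes in days per standardized
#'   unit (names ending in `_abnormal` etc. denote 0/1 indicators of a
#'   categorical level, taken with unit scale). The default truth is
#'   sparse (five nonzero coefficients) and mixes clinical signal (age,
#'   mental status, symptom duration) with DVH signal loading on two
#'   distinct mechanisms: target volume and coverage (near-minimum dose
#'   D98, which reflects cold spots), so that every coefficient is
#'   identifiable from the generated features.
#' @param dose_response List with `plateau` (Gy), `slope` (days/Gy),
#'   `spread` (Gy, half-range of the per-patient plateau modifier) and
#'   `decline` (days/Gy beyond the plateau, representing toxicity of
#'   escalation past tolerance). Note that when prescription dose is
#'   swept in a what-if simulation, dose-linked DVH features in
#'   `coefficients` (such as D98) rescale with it and add their own
#'   slope on top of `dose_response`; the default `decline` is chosen
#'   large enough that the *total* response still has an interior
#'   per-patient optimum (see [true_whatif_survival()]).
#' @param duration_effect Days of survival per day of treatment duration
#'   (centered at 50 days).
#' @param noise_sd Gaussian noise standard deviation in days; 0 makes
#'   survival a deterministic function of the features.
#' @param reference_scales Named list of `c(center, scale)` pairs used to
#'   standardize numeric features in the truth.
#' @return Object of class `ground_truth_model` with a `k_true` element
#'   (number of nonzero coefficients).
#' @export
ground_truth_model <- function(
    intercept = 400,
    coefficients = c(age = -80, mental_status_abnormal = -120,
                     symptom_duration = 50, target_volume_cc = -90,
                     PTVlocal_D98pct = 70),
    dose_response = list(plateau = 65, slope = 5, spread = 8, decline = 8),
    duration_effect = -2,
    noise_sd = 100,
    reference_scales = list(
      age = c(62, 17), symptom_duration = c(173, 260),
      target_volume_cc = c(95, 57), PTVlocal_D98pct = c(44, 9.6)
    )) {
  coefficients <- coefficients[coefficients != 0]
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(intercept = intercept, coefficients = coefficients,
                 dose_response = dose_response,
                 duration_effect = duration_effect, noise_sd = noise_sd,
                 reference_scales = reference_scales,
                 k_true = length(coefficients)),
            class = "ground_truth_model")
}

truth_feature_value <- function(truth, name, feature_row) {
  # indicator coefficients are written "<feature>_<level>"
  if (name %in% colnames(feature_row) || name %in% names(feature_row)) {
    v <- as.numeric(feature_row[[name]])
    rs <- truth$reference_scales[[name]]
    if (is.null(rs)) rs <- c(0, 1)
    return((v - rs[1]) / rs[2])
  }
  for (f in names(clinical_levels())) {
    pref <- paste0(f, "_")
    if (startsWith(name, pref)) {
      lev <- substring(name, nchar(pref) + 1L)
      return(as.numeric(as.character(feature_row[[f]]) == lev))
    }
  }
  stop("ground-truth coefficient refers to unknown feature: ", name)
}

#' Per-patient dose response and noise-free survival of the ground truth
#'
#' @param truth A [ground_truth_model()].
#' @param feature_row One patient's candidate-feature row (data.frame or
#'   named list) as produced by [build_feature_matrix()].
#' @param dose Prescription dose in Gy.
#' @param duration Treatment duration in days.
#' @param plateau Patient's plateau dose in Gy (see
#'   [true_plateau()]).
#' @return Noise-free survival in days (not floored).
#' @export
true_survival <- function(truth, feature_row, dose, duration, plateau) {
  dr <- truth$dose_response
  resp <- dr$slope * (pmin(dose, plateau) - 30) -
    dr$decline * pmax(0, dose - plateau)
  lin <- 0
  for (nm in names(truth$coefficients))
    lin <- lin + truth$coefficients[[nm]] *
      truth_feature_value(truth, nm, feature_row)
  truth$intercept + lin + resp + truth$duration_effect * (duration - 50)
}

#' @rdname true_survival
#' @param cold_fraction Patient's cold-spot volume fraction.
#' @param cold_spot_max Upper bound of cold-spot fractions in the cohort
#'   configuration.
#' @export
true_plateau <- function(truth, cold_fraction, cold_spot_max = 0.3) {
  dr <- truth$dose_response
  if (cold_spot_max <= 0) return(dr$plateau)
  dr$plateau + dr$spread * (2 * cold_fraction / cold_spot_max - 1)
}

#' Ground-truth survival under a what-if dose change
#'
#' The generator's own answer to the what-if question: rescale the
#' patient's DVH curves to `new_dose`, re-extract the DVH features, and
#' evaluate the noise-free truth. This is the reference curve a trained
#' model's [dose_duration_surface()] is compared against; it includes
#' both the explicit dose-response term and the contribution of
#' dose-linked DVH features in the truth's coefficients.
#'
#' @param truth A [ground_truth_model()].
#' @param cohort_row The patient's cohort row (treatment fields).
#' @param curves The patient's [dvh_curve()]s.
#' @param feature_row The patient's candidate-feature row.
#' @param new_dose Prescription dose to evaluate (Gy).
#' @param duration Treatment duration (days); defaults to the actual.
#' @param plateau The patient's plateau dose (from `truth_detail`).
#' @return Noise-free survival in days.
#' @export
true_whatif_survival <- function(truth, cohort_row, curves, feature_row,
                                 new_dose, duration = NULL, plateau) {
  if (is.null(duration)) duration <- cohort_row$treatment_duration_days
  scaled <- lapply(curves, rescale_curve,
                   old_dose = cohort_row$prescription_dose_gy,
                   new_dose = new_dose)
  feats <- extract_feature_set(scaled, treatment = list(
    gamma_knife = cohort_row$gamma_knife,
    target_volume_cc = cohort_row$target_volume_cc,
    prescription_dose_gy = new_dose,
    n_fractions = cohort_row$n_fractions,
    treatment_duration_days = duration))
  newrow <- feature_row
  for (nm in intersect(names(feats), colnames(newrow)))
    newrow[[nm]] <- feats[[nm]]
  true_survival(truth, newrow, new_dose, duration, plateau)
}

#' @rdname true_whatif_survival
#' @param doses Dose grid over which to locate the optimum.
#' @return `true_optimal_dose`: the smallest grid dose maximizing the
#'   ground-truth what-if survival.
#' @export
true_optimal_dose <- function(truth, cohort_row, curves, feature_row,
                              doses = seq(30, 80, by = 5),
                              duration = NULL, plateau) {
  v <- vapply(doses, function(d)
    true_whatif_survival(truth, cohort_row, curves, feature_row, d,
                         duration, plateau), numeric(1))
  doses[which.max(v)]
}

#' Generate one synthetic cumulative DVH curve
#'
#' The curve is a smooth logistic sigmoid in dose, centred near the
#' prescription, truncated to reach exactly zero at ~1.12 x prescription,
#' optionally mixed with a cold-spot component (a fraction of the volume
#' whose coverage falls off around 75% of the prescription and vanishes
#' by 85%). `homogeneity = Inf` yields the uniform-irradiation step
#' limit.
#'
#' @param prescription_dose Prescription dose in Gy (> 0).
#' @param homogeneity Sharpness of the fall-off (unitless, > 0); the
#'   sigmoid width is `prescription_dose / (8 * homogeneity)`.
#' @param cold_spot_fraction Volume fraction in `[0, 1)` belonging to the
#'   underdosed component.
#' @param total_volume Structure volume in cm^3.
#' @param structure Structure label.
#' @param seed Optional integer seed for the small random jitter of the
#'   sigmoid centre; `NULL` leaves the RNG stream untouched and centres
#'   the curve exactly on the prescription.
#' @param jitter Relative jitter half-width of the sigmoid centre.
#' @return A [dvh_curve()].
#' @export
generate_dvh_curve <- function(prescription_dose, homogeneity = 12,
                               cold_spot_fraction = 0, total_volume = 100,
                               structure = "PTV_local", seed = NULL,
                               jitter = 0.02) {
  if (prescription_dose <= 0) stop("prescription dose must be positive")
  if (cold_spot_fraction < 0 || cold_spot_fraction >= 1)
    stop("cold_spot_fraction must be in [0, 1)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    d50 <- prescription_dose * (1 + stats::runif(1, -jitter, jitter))
  } else d50 <- prescription_dose
  rx <- prescription_dose
  dmax <- 1.12 * rx
  w <- if (is.finite(homogeneity)) rx / (8 * homogeneity) else rx * 1e-9
  comp <- function(d, centre, width, upper) {
    s <- stats::plogis(-(d - centre) / width)
    s0 <- stats::plogis(centre / width)
    su <- stats::plogis(-(upper - centre) / width)
    out <- (s - su) / (s0 - su)
    out[d >= upper] <- 0
    pmax(pmin(out, 1), 0)
  }
  # base grid refined around the sigmoid centres so sharp fall-offs
  # (large homogeneity, up to the uniform-irradiation step limit) are
  # represented faithfully by the piecewise-linear curve
  refine <- function(centre, width)
    centre + width * c(-40, -16, -8, -4, -2, -1, 0, 1, 2, 4, 8, 16, 40)
  dose <- c(seq(0, dmax, length.out = 97L), refine(d50, w))
  if (cold_spot_fraction > 0) dose <- c(dose, refine(0.75 * rx, w))
  dose <- sort(unique(dose[dose >= 0 & dose <= dmax]))
  dose <- dose[c(TRUE, diff(dose) > 1e-12)]
  if (dose[1] != 0) dose <- c(0, dose)
  main <- comp(dose, d50, w, dmax)
  v <- if (cold_spot_fraction > 0) {
    cold <- comp(dose, 0.75 * rx, w, 0.85 * rx)
    100 * ((1 - cold_spot_fraction) * main + cold_spot_fraction * cold)
  } else 100 * main
  v <- rev(cummax(rev(v)))  # guard monotonicity against fp wiggle
  v[1] <- 100
  dvh_curve(dose, v, total_volume = total_volume, structure = structure)
}

sample_clipped <- function(n, gen, lo, hi) pmin(pmax(gen(n), lo), hi)

#' Generate a seeded synthetic cohort
#'
#' Draws clinical and treatment covariates from the configured marginal
#' distributions, builds four target-structure DVH curves per patient,
#' extracts the full candidate feature set and generates survival times
#' from the ground-truth model plus Gaussian noise, floored at 1 day.
#' All patients are uncensored (followed until death). The same
#' configuration and seed reproduce the cohort bit for bit.
#'
#' @param config A [cohort_config()].
#' @param truth A [ground_truth_model()].
#' @return Object of class `rs_cohort`: list with `cohort` (data.frame of
#'   clinical/treatment fields and `survival_days`), `dvh` (per patient:
#'   named list of [dvh_curve()]s), `features` (candidate feature
#'   data.frame from [build_feature_matrix()]), and `truth_detail`
#'   (per-patient cold-spot fraction, plateau dose = per-patient optimal
#'   prescription, and noise-free survival).
#' @export
generate_cohort <- function(config = cohort_config(),
                            truth = ground_truth_model()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(truth, "ground_truth_model"))
  set.seed(config$seed)
  n <- config$n_patients
  lv <- clinical_levels()

  age <- round(sample_clipped(n, function(n) stats::rnorm(n, 62, 18),
                              config$age_range[1], config$age_range[2]))
  sex <- sample(lv$sex, n, TRUE, prob = c(12, 23))
  histology <- sample(lv$histology, n, TRUE, prob = c(2, 3, 30))
  mental_status <- sample(lv$mental_status, n, TRUE, prob = c(19, 16))
  chemotherapy <- sample(lv$chemotherapy, n, TRUE, prob = c(0.1, 0.9))
  tumor_location <- sample(lv$tumor_location, n, TRUE,
                           prob = c(17, 10, 1, 7))
  surgical_resection <- sample(lv$surgical_resection, n, TRUE,
                               prob = c(0.4, 0.35, 0.25))
  symptom_duration <- round(sample_clipped(
    n, function(n) stats::rlnorm(n, log(93), 1.1),
    config$symptom_range[1], config$symptom_range[2]))

  dose <- sample(config$dose_levels, n, TRUE, prob = config$dose_probs)
  n_fractions <- round(dose / 2)
  duration <- round(sample_clipped(
    n, function(n) n_fractions * 1.4 + stats::rnorm(n, 7, 6),
    config$duration_range[1], config$duration_range[2]))
  gamma_knife <- stats::rbinom(n, 1, 0.15)

  ctv_local <- stats::rlnorm(n, log(config$ctv_local_volume[["median"]]),
                             config$ctv_local_volume[["sdlog"]])
  ptv_local <- ctv_local * stats::runif(n, 1.25, 1.45)
  ctv_extend <- ctv_local * stats::runif(n, 1.6, 2.6)
  ptv_extend <- ctv_extend * stats::runif(n, 1.25, 1.45)
  volumes <- list(PTV_local = ptv_local, CTV_local = ctv_local,
                  PTV_extend = ptv_extend, CTV_extend = ctv_extend)

  cold <- stats::runif(n, 0, config$cold_spot_max)
  homog <- config$homogeneity * exp(stats::rnorm(n, 0, 0.15))
  curve_seeds <- sample.int(2^30, n)

  cohort <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = age, sex = sex, histology = histology,
    mental_status = mental_status, chemotherapy = chemotherapy,
    tumor_location = tumor_location,
    surgical_resection = surgical_resection,
    symptom_duration = symptom_duration,
    prescription_dose_gy = dose, n_fractions = n_fractions,
    treatment_duration_days = duration, gamma_knife = gamma_knife,
    target_volume_cc = ptv_local,
    stringsAsFactors = FALSE
  )

  dvh <- lapply(seq_len(n), function(i) {
    out <- lapply(dvh_structures(), function(st)
      generate_dvh_curve(dose[i], homogeneity = homog[i],
                         cold_spot_fraction = cold[i],
                         total_volume = volumes[[st]][i], structure = st,
                         seed = curve_seeds[i] +
                           match(st, dvh_structures())))
    names(out) <- dvh_structures()
    out
  })
  names(dvh) <- cohort$patient_id

  features <- build_feature_matrix(cohort, dvh)
  plateau <- true_plateau(truth, cold, config$cold_spot_max)
  noiseless <- vapply(seq_len(n), function(i)
    true_survival(truth, features[i, , drop = FALSE], dose[i], duration[i],
                  plateau[i]), numeric(1))
  noise <- if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd) else 0
  cohort$survival_days <- pmax(noiseless + noise, 1)

  structure(list(
    cohort = cohort, dvh = dvh, features = features,
    truth_detail = data.frame(patient_id = cohort$patient_id,
                              cold_fraction = cold, plateau_dose = plateau,
                              survival_noiseless = noiseless),
    config = config, truth = truth
  ), class = "rs_cohort")
}

#' @export
print.rs_cohort <- function(x, ...) {
  cat(sprintf(
    "<rs_cohort> %d patients (seed %d), median survival %.0f days\n",
    nrow(x$cohort), x$config$seed, stats::median(x$cohort$survival_days)))
  invisible(x)
}

#' Feature-recovery benchmark dataset
#'
#' Builds the standard benchmark for feature-selection recovery: a
#' synthetic cohort reduced to `n_candidates` candidate features
#' containing every informative feature of the ground truth plus
#' distractors. Because the DVH inventory contains near-collinear
#' duplicates of the informative features by construction (structure
#' volumes track the target volume, coverage features track each other),
#' distractors are sampled only among features whose absolute
#' correlation with every informative feature is below `max_abs_cor`;
#' without this identifiability cap, a proxy subset can match the truth's
#' fit and "recovery" of the named features is undefined.
#'
#' @param n_patients Cohort size.
#' @param n_candidates Total number of candidate features.
#' @param seed Cohort and sampling seed.
#' @param truth Ground-truth model (its nonzero coefficients define the
#'   informative features).
#' @param max_abs_cor Identifiability cap on distractor correlation; if
#'   the cohort at hand yields too few candidates under the cap, it is
#'   relaxed in steps of 0.05 (never beyond 0.9).
#' @return List with `dataset` (an [rs_dataset()]), `informative`
#'   (character vector of the candidate features carrying the truth's
#'   nonzero coefficients) and `cohort` (the underlying `rs_cohort`).
#' @export
make_recovery_dataset <- function(n_patients = 60, n_candidates = 50,
                                  seed = 1, truth = ground_truth_model(),
                                  max_abs_cor = 0.6) {
  co <- generate_cohort(cohort_config(n_patients = n_patients,
                                      seed = seed), truth)
  ds <- as_rs_dataset(co)
  # map coefficient names (possibly "<feature>_<level>" indicators) to
  # candidate columns
  informative <- vapply(names(truth$coefficients), function(nm) {
    if (nm %in% colnames(ds$x)) return(nm)
    for (f in names(clinical_levels()))
      if (startsWith(nm, paste0(f, "_"))) return(f)
    stop("cannot map truth coefficient ", nm, " to a candidate feature")
  }, character(1))
  informative <- unique(unname(informative))
  num <- vapply(ds$x, is.numeric, logical(1))
  Xn <- as.matrix(ds$x[, num, drop = FALSE])
  sds <- apply(Xn, 2, stats::sd)
  inf_num <- intersect(informative, colnames(Xn))
  r <- abs(stats::cor(Xn[, sds > 0, drop = FALSE],
                      Xn[, inf_num, drop = FALSE]))
  n_extra <- n_candidates - length(informative)
  cap <- max_abs_cor
  repeat {
    pool_num <- rownames(r)[apply(r, 1, max) < cap]
    pool <- c(setdiff(names(clinical_levels()), informative),
              setdiff(pool_num, informative))
    pool <- setdiff(pool, informative)
    if (length(pool) >= n_extra || cap > 0.9) break
    cap <- cap + 0.05
  }
  if (n_extra > length(pool))
    stop("not enough decorrelated distractors available")
  set.seed(seed + 10000L)
  cand <- sample(c(informative, sample(pool, n_extra)))
  list(dataset = rs_dataset(ds$x[, cand, drop = FALSE], ds$y,
                            ds$patient_id),
       informative = informative, cohort = co)
}

#' Dataset view of a synthetic cohort
#'
#' @param cohort An `rs_cohort` from [generate_cohort()].
#' @return An [rs_dataset()] of candidate features and survival days.
#' @export
as_rs_dataset <- function(cohort) {
  stopifnot(inherits(cohort, "rs_cohort"))
  rs_dataset(cohort$features, cohort$cohort$survival_days,
             cohort$cohort$patient_id)
}
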