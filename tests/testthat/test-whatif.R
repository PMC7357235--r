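# shared setup: a small noise-free cohort and a combined-features model
whatif_setup <- function(n = 40, seed = 13) {
  truth <- ground_truth_model(noise_sd = 0)
  co <- generate_cohort(cohort_config(n_patients = n, seed = seed), truth)
  ds <- as_rs_dataset(co)
  feats <- c("age", "mental_status", "symptom_duration",
             "target_volume_cc", "PTVlocal_D98pct",
             "prescription_dose_gy", "treatment_duration_days", "bed_gy")
  model <- svr_train(ds, feats, svr_params(1000, 5, 0.02))
  list(co = co, ds = ds, model = model)
}

test_that("dose change at the actual dose reproduces the ordinary prediction bit for bit", {
  s <- whatif_setup()
  for (i in c(1, 7, 20)) {
    row <- s$co$cohort[i, ]
    pid <- row$patient_id
    ordinary <- predict(s$model, s$co$features[i, , drop = FALSE])
    sim <- simulate_dose_change(row, s$co$features[i, , drop = FALSE],
                                s$co$dvh[[pid]], s$model,
                                new_dose = row$prescription_dose_gy)
    expect_identical(sim, ordinary)
  }
})

test_that("simulated features equal manual rescale-and-reextract", {
  s <- whatif_setup(n = 20)
  i <- 4
  row <- s$co$cohort[i, ]
  pid <- row$patient_id
  new_dose <- 72
  # manual oracle: rescale raw curves, re-extract, overwrite selected
  scaled <- lapply(s$co$dvh[[pid]], rescale_curve,
                   old_dose = row$prescription_dose_gy,
                   new_dose = new_dose)
  manual <- extract_feature_set(scaled, list(
    gamma_knife = row$gamma_knife,
    target_volume_cc = row$target_volume_cc,
    prescription_dose_gy = new_dose,
    n_fractions = row$n_fractions,
    treatment_duration_days = row$treatment_duration_days))
  newrow <- s$co$features[i, , drop = FALSE]
  for (nm in intersect(s$model$features, names(manual)))
    newrow[[nm]] <- manual[[nm]]
  expect_equal(simulate_dose_change(row, s$co$features[i, , drop = FALSE],
                                    s$co$dvh[[pid]], s$model, new_dose),
               predict(s$model, newrow))
  expect_error(simulate_dose_change(row, s$co$features[i, , drop = FALSE],
                                    s$co$dvh[[pid]], s$model, -10),
               "positive")
})

test_that("surfaces have full grids, commute with cell order, and collapse to identity", {
  s <- whatif_setup(n = 20)
  i <- 2
  row <- s$co$cohort[i, ]
  frow <- s$co$features[i, , drop = FALSE]
  curves <- s$co$dvh[[row$patient_id]]
  surf <- dose_duration_surface(row, frow, curves, s$model,
                                doses = c(40, 50, 60, 70),
                                durations = c(30, 50, 70))
  expect_equal(nrow(surf), 12)
  expect_true(all(is.finite(surf$predicted_days)))
  # pure function of inputs: reversed grids give the same cell values
  surf2 <- dose_duration_surface(row, frow, curves, s$model,
                                 doses = rev(c(40, 50, 60, 70)),
                                 durations = rev(c(30, 50, 70)))
  m1 <- surf[order(surf$dose_gy, surf$duration_days), "predicted_days"]
  m2 <- surf2[order(surf2$dose_gy, surf2$duration_days),
              "predicted_days"]
  expect_identical(m1, m2)
  # 1x1 grid at the actual treatment equals the ordinary prediction
  one <- dose_duration_surface(row, frow, curves, s$model,
                               doses = row$prescription_dose_gy,
                               durations = row$treatment_duration_days)
  expect_identical(one$predicted_days, predict(s$model, frow))
  expect_true(one$actual)
  expect_error(dose_duration_surface(row, frow, curves, s$model,
                                     doses = c(60, 95)), "95")
})

test_that("predicted dose response rises to a plateau under a saturating truth", {
  # truth whose coefficients carry no dose-linked DVH feature and whose
  # dose response has no decline: the true what-if response is
  # non-decreasing then exactly flat for every patient
  truth <- ground_truth_model(
    coefficients = c(age = -80, mental_status_abnormal = -120,
                     target_volume_cc = -90),
    noise_sd = 0,
    dose_response = list(plateau = 60, slope = 5, spread = 0,
                         decline = 0))
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 21), truth)
  ds <- as_rs_dataset(co)
  feats <- c("age", "mental_status", "target_volume_cc",
             "prescription_dose_gy", "treatment_duration_days")
  model <- svr_train(ds, feats, svr_params(1000, 5, 0.02))
  doses <- seq(30, 80, by = 10)
  i <- which(co$cohort$prescription_dose_gy == 60)[1]
  row <- co$cohort[i, ]
  surf <- dose_duration_surface(row, co$features[i, , drop = FALSE],
                                co$dvh[[row$patient_id]], model,
                                doses = doses,
                                durations = row$treatment_duration_days)
  pred <- surf$predicted_days
  truthvals <- vapply(doses, function(d)
    true_whatif_survival(truth, row, co$dvh[[row$patient_id]],
                         co$features[i, , drop = FALSE], d,
                         row$treatment_duration_days, 60), numeric(1))
  # the generator's own sweep is monotone then flat
  expect_true(all(diff(truthvals) >= -1e-9))
  expect_equal(truthvals[6], truthvals[4], tolerance = 1e-9)
  # the model recovers the rising section and stays comparatively flat
  # beyond the plateau, within model error
  rise <- truthvals[4] - truthvals[1]
  expect_gt(pred[4] - pred[1], 0.3 * rise)
  expect_lt(abs(pred[6] - pred[4]), 0.35 * rise)
})

test_that("patients with different plateau modifiers have different optimal doses", {
  truth <- ground_truth_model(noise_sd = 0)
  co <- generate_cohort(cohort_config(n_patients = 80, seed = 31), truth)
  ds <- as_rs_dataset(co)
  feats <- c("age", "mental_status", "symptom_duration",
             "target_volume_cc", "PTVlocal_D98pct", "PTVlocal_V55pct",
             "prescription_dose_gy", "treatment_duration_days")
  model <- svr_train(ds, feats, svr_params(1000, 5, 0.02))
  det <- co$truth_detail
  lo <- which.min(det$plateau_dose)
  hi <- which.max(det$plateau_dose)
  # the generator's per-patient optima differ...
  opt <- vapply(c(lo, hi), function(i) {
    row <- co$cohort[i, ]
    true_optimal_dose(truth, row, co$dvh[[row$patient_id]],
                      co$features[i, , drop = FALSE],
                      plateau = det$plateau_dose[i])
  }, numeric(1))
  expect_lt(opt[1], opt[2])
  # ...and so do the model's argmax doses
  am <- vapply(c(lo, hi), function(i) {
    row <- co$cohort[i, ]
    surf <- dose_duration_surface(row, co$features[i, , drop = FALSE],
                                  co$dvh[[row$patient_id]], model,
                                  doses = seq(30, 80, by = 5),
                                  durations =
                                    row$treatment_duration_days)
    argmax_dose(surf)
  }, numeric(1))
  expect_false(am[1] == am[2])
})
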