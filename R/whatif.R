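#' Predicted survival under a changed prescription dose
#'
#' Three-step what-if simulation for one patient: (1) set the
#' prescription-dose feature to `new_dose`; (2) rescale the four DVH
#' curves by `new_dose / actual dose` and recompute the DVH features
#' (including BED at the new dose, same fractionation); (3) predict with
#' the trained model. Only the features the model selected reach the
#' prediction, so unselected features are untouched. At the patient's
#' actual dose the transform is the identity and the ordinary prediction
#' is reproduced bit for bit.
#'
#' @param cohort_row One row of the cohort table (treatment fields are
#'   read from it).
#' @param feature_row The patient's candidate-feature row from
#'   [build_feature_matrix()].
#' @param curves Named list of the patient's [dvh_curve()]s.
#' @param model A trained `rs_model` (combined features).
#' @param new_dose New prescription dose in Gy (> 0).
#' @param new_duration Optional treatment duration override in days.
#' @param alpha_beta Alpha/beta ratio for the BED recomputation.
#' @return Predicted survival in days.
#' @export
simulate_dose_change <- function(cohort_row, feature_row, curves, model,
                                 new_dose, new_duration = NULL,
                                 alpha_beta = 10) {
  if (new_dose <= 0) stop("prescription dose must be positive")
  stopifnot(inherits(model, "rs_model"))
  old_dose <- cohort_row$prescription_dose_gy
  newrow <- feature_row
  scaled <- lapply(curves, rescale_curve, old_dose = old_dose,
                   new_dose = new_dose)
  feats <- extract_feature_set(
    scaled,
    treatment = list(
      gamma_knife = cohort_row$gamma_knife,
      target_volume_cc = cohort_row$target_volume_cc,
      prescription_dose_gy = new_dose,
      n_fractions = cohort_row$n_fractions,
      treatment_duration_days = if (is.null(new_duration))
        cohort_row$treatment_duration_days else new_duration
    ),
    alpha_beta = alpha_beta
  )
  recompute <- intersect(model$features, names(feats))
  for (nm in recompute) newrow[[nm]] <- feats[[nm]]
  predict(model, newrow)
}

#' Predicted-survival surface over dose and duration
#'
#' Evaluates [simulate_dose_change()] over a grid of prescription doses
#' and treatment durations for one patient. The surface is a pure
#' function of its inputs; the cell at the patient's actual dose and
#' duration equals the model's ordinary prediction.
#'
#' @inheritParams simulate_dose_change
#' @param doses Dose grid in Gy.
#' @param durations Duration grid in days.
#' @param dose_bounds,duration_bounds Allowed sweep ranges; defaults are
#'   the observed cohort ranges (30-80 Gy, 19-80 days) so the RBF model
#'   is not evaluated far outside its support.
#' @return Object of class `rs_whatif`: long data.frame with
#'   `patient_id`, `dose_gy`, `duration_days`, `predicted_days` and
#'   `actual` (TRUE at the patient's actual dose/duration cell when on
#'   the grid).
#' @export
dose_duration_surface <- function(cohort_row, feature_row, curves, model,
                                  doses, durations = NULL,
                                  dose_bounds = c(30, 80),
                                  duration_bounds = c(19, 80),
                                  alpha_beta = 10) {
  if (length(doses) < 1L) stop("empty dose grid")
  if (is.null(durations)) durations <- cohort_row$treatment_duration_days
  bad_d <- doses[doses < dose_bounds[1] | doses > dose_bounds[2]]
  bad_t <- durations[durations < duration_bounds[1] |
                     durations > duration_bounds[2]]
  if (length(bad_d) || length(bad_t))
    stop("grid values outside configured bounds: ",
         paste(c(bad_d, bad_t), collapse = ", "))
  grid <- expand.grid(dose_gy = doses, duration_days = durations,
                      KEEP.OUT.ATTRS = FALSE)
  pred <- vapply(seq_len(nrow(grid)), function(i)
    simulate_dose_change(cohort_row, feature_row, curves, model,
                         new_dose = grid$dose_gy[i],
                         new_duration = grid$duration_days[i],
                         alpha_beta = alpha_beta),
    numeric(1))
  out <- data.frame(patient_id = cohort_row$patient_id, grid,
                    predicted_days = pred,
                    actual = grid$dose_gy == cohort_row$prescription_dose_gy &
                      grid$duration_days ==
                        cohort_row$treatment_duration_days)
  class(out) <- c("rs_whatif", "data.frame")
  out
}

#' @param x An `rs_whatif` surface.
#' @param ... Passed to the underlying plot call.
#' @rdname dose_duration_surface
#' @export
plot.rs_whatif <- function(x, ...) {
  doses <- sort(unique(x$dose_gy))
  durs <- sort(unique(x$duration_days))
  if (length(durs) == 1L) {
    graphics::plot(x$dose_gy, x$predicted_days, type = "b",
                   xlab = "prescription dose (Gy)",
                   ylab = "predicted survival (days)", ...)
    if (any(x$actual))
      graphics::points(x$dose_gy[x$actual], x$predicted_days[x$actual],
                       pch = 19, cex = 1.4)
  } else {
    z <- matrix(x$predicted_days[order(x$duration_days, x$dose_gy)],
                nrow = length(doses))
    graphics::image(doses, durs, z, xlab = "prescription dose (Gy)",
                    ylab = "treatment duration (days)", ...)
    graphics::contour(doses, durs, z, add = TRUE)
  }
  invisible(x)
}

#' Dose maximizing the predicted survival of one patient
#'
#' Convenience accessor: the smallest grid dose attaining the maximum
#' predicted survival of a what-if surface (at a fixed duration).
#'
#' @param surface An `rs_whatif` surface.
#' @param duration Duration at which to read the dose sweep; defaults to
#'   the first duration in the surface.
#' @return Dose in Gy.
#' @export
argmax_dose <- function(surface, duration = NULL) {
  stopifnot(inherits(surface, "rs_whatif"))
  if (is.null(duration)) duration <- surface$duration_days[1]
  sl <- surface[surface$duration_days == duration, ]
  sl$dose_gy[which.max(sl$predicted_days)]
}
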