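#' Candidate feature inventory
#'
#' The fixed, documented inventory of candidate predictors. Clinical
#' features describe the patient at presentation; the DVH group contains
#' the treatment-level scalars (gamma-knife boost flag, target volume,
#' prescription dose, treatment duration, BED) and, for each of the four
#' target structures, D_X in both referents (X in %: 98, 95..50 by 5, 2;
#' X in cm^3 on the same grid), V_X in both referents (X Gy: 80..5 by 5)
#' and the max/min/mean dose.
#'
#' @return A data.frame with columns `name`, `group` (`"clinical"` or
#'   `"dvh"`), `type` (`"numeric"` or `"categorical"`) and `units`.
#' @export
feature_inventory <- function() {
  clin <- data.frame(
    name = c("age", "sex", "histology", "mental_status", "chemotherapy",
             "tumor_location", "surgical_resection", "symptom_duration"),
    group = "clinical",
    type = c("numeric", "categorical", "categorical", "categorical",
             "categorical", "categorical", "categorical", "numeric"),
    units = c("years", "", "", "", "", "", "", "days"),
    stringsAsFactors = FALSE
  )
  scalars <- data.frame(
    name = c("gamma_knife", "target_volume_cc", "prescription_dose_gy",
             "treatment_duration_days", "bed_gy"),
    group = "dvh", type = "numeric",
    units = c("0/1", "cm^3", "Gy", "days", "Gy"),
    stringsAsFactors = FALSE
  )
  per_structure <- function(st) {
    pre <- structure_prefix(st)
    nm <- c(paste0(pre, "_D", dx_grid(), "pct"),
            paste0(pre, "_D", dx_grid(), "cc"),
            paste0(pre, "_V", vx_grid(), "pct"),
            paste0(pre, "_V", vx_grid(), "cc"),
            paste0(pre, c("_Dmax", "_Dmin", "_Dmean")))
    un <- c(rep("Gy", 2 * length(dx_grid())),
            rep("%", length(vx_grid())), rep("cm^3", length(vx_grid())),
            rep("Gy", 3))
    data.frame(name = nm, group = "dvh", type = "numeric", units = un,
               stringsAsFactors = FALSE)
  }
  rbind(clin, scalars,
        do.call(rbind, lapply(dvh_structures(), per_structure)))
}

structure_prefix <- function(st) gsub("_", "", st, fixed = TRUE)

#' @rdname feature_inventory
#' @export
dx_grid <- function() c(98, seq(95, 50, by = -5), 2)

#' @rdname feature_inventory
#' @export
vx_grid <- function() seq(80, 5, by = -5)

#' Categorical levels of the clinical schema
#'
#' Declared levels for each categorical clinical feature. Levels are part
#' of the data schema (not statistics learned from data), so one-hot
#' encodings are stable across cross-validation folds.
#' @return Named list of character vectors.
#' @export
clinical_levels <- function() {
  list(
    sex = c("female", "male"),
    histology = c("oligodendroglioma", "anaplastic_astrocytoma",
                  "glioblastoma"),
    mental_status = c("normal", "abnormal"),
    chemotherapy = c("no", "yes"),
    tumor_location = c("frontal", "temporal", "parietal", "other"),
    surgical_resection = c("gross_total", "subtotal", "biopsy")
  )
}

#' Extract the DVH feature set for one patient
#'
#' Computes every DVH-group feature of [feature_inventory()] from the
#' patient's four structure curves and treatment scalars. For the cm^3
#' referent of D_X, thresholds exceeding the structure volume are clamped
#' to the total volume (the dose covering the entire structure).
#'
#' @param curves Named list of [dvh_curve()]s, one per structure in
#'   `dvh_structures()`.
#' @param treatment List (or 1-row data.frame) with elements `gamma_knife`
#'   (0/1), `target_volume_cc`, `prescription_dose_gy`, `n_fractions`,
#'   `treatment_duration_days`.
#' @param alpha_beta Alpha/beta ratio for the BED feature (Gy).
#' @return Named numeric vector, in the fixed inventory order.
#' @export
extract_feature_set <- function(curves, treatment, alpha_beta = 10) {
  missing <- setdiff(dvh_structures(), names(curves))
  if (length(missing))
    stop("missing DVH structure(s): ", paste(missing, collapse = ", "))
  out <- c(
    gamma_knife = as.numeric(treatment$gamma_knife),
    target_volume_cc = as.numeric(treatment$target_volume_cc),
    prescription_dose_gy = as.numeric(treatment$prescription_dose_gy),
    treatment_duration_days = as.numeric(treatment$treatment_duration_days),
    bed_gy = compute_bed(treatment$prescription_dose_gy,
                         treatment$n_fractions, alpha_beta)
  )
  for (st in dvh_structures()) {
    cv <- curves[[st]]
    if (!inherits(cv, "dvh_curve")) stop("curve for ", st, " is not a dvh_curve")
    pre <- structure_prefix(st)
    dpct <- vapply(dx_grid(), function(x) dose_at_volume(cv, x, "percent"),
                   numeric(1))
    dcc <- vapply(pmin(dx_grid(), cv$total_volume),
                  function(x) dose_at_volume(cv, x, "cc"), numeric(1))
    vpct <- vapply(vx_grid(), function(x) volume_at_dose(cv, x, "percent"),
                   numeric(1))
    vcc <- vapply(vx_grid(), function(x) volume_at_dose(cv, x, "cc"),
                  numeric(1))
    sm <- summary_doses(cv)
    vals <- c(dpct, dcc, vpct, vcc, sm[["max"]], sm[["min"]], sm[["mean"]])
    names(vals) <- c(paste0(pre, "_D", dx_grid(), "pct"),
                     paste0(pre, "_D", dx_grid(), "cc"),
                     paste0(pre, "_V", vx_grid(), "pct"),
                     paste0(pre, "_V", vx_grid(), "cc"),
                     paste0(pre, c("_Dmax", "_Dmin", "_Dmean")))
    out <- c(out, vals)
  }
  out
}

#' Build the full candidate feature matrix for a cohort
#'
#' Combines the clinical columns of the cohort table with the extracted
#' DVH features of every patient, in the fixed inventory order.
#'
#' @param cohort Cohort data.frame as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @param dvh Named list (by patient id) of per-structure curve lists.
#' @param alpha_beta Alpha/beta ratio for the BED feature (Gy).
#' @return A data.frame of candidate features (factors for categorical
#'   clinical features, numeric otherwise), row names = patient ids.
#' @export
build_feature_matrix <- function(cohort, dvh, alpha_beta = 10) {
  inv <- feature_inventory()
  lv <- clinical_levels()
  clin_names <- inv$name[inv$group == "clinical"]
  clin <- cohort[, clin_names, drop = FALSE]
  for (nm in names(lv)) clin[[nm]] <- factor(clin[[nm]], levels = lv[[nm]])
  dvh_rows <- t(vapply(seq_len(nrow(cohort)), function(i) {
    pid <- as.character(cohort$patient_id[i])
    extract_feature_set(
      dvh[[pid]],
      treatment = list(
        gamma_knife = cohort$gamma_knife[i],
        target_volume_cc = cohort$target_volume_cc[i],
        prescription_dose_gy = cohort$prescription_dose_gy[i],
        n_fractions = cohort$n_fractions[i],
        treatment_duration_days = cohort$treatment_duration_days[i]
      ),
      alpha_beta = alpha_beta
    )
  }, numeric(sum(inv$group == "dvh"))))
  out <- cbind(clin, as.data.frame(dvh_rows))
  rownames(out) <- as.character(cohort$patient_id)
  stopifnot(identical(colnames(out), inv$name))
  out
}

#' Bundle a feature matrix and survival outcome for modelling
#'
#' @param x Candidate feature data.frame (see [build_feature_matrix()]).
#' @param y Observed survival times in days.
#' @param patient_id Optional patient identifiers.
#' @return An object of class `rs_dataset`.
#' @export
rs_dataset <- function(x, y, patient_id = NULL) {
  stopifnot(is.data.frame(x), nrow(x) == length(y))
  if (any(!is.finite(y))) stop("survival times must be finite")
  if (is.null(patient_id)) patient_id <- rownames(x)
  if (is.null(patient_id)) patient_id <- as.character(seq_len(nrow(x)))
  structure(list(x = x, y = as.numeric(y),
                 patient_id = as.character(patient_id)),
            class = "rs_dataset")
}

#' @export
print.rs_dataset <- function(x, ...) {
  cat(sprintf("<rs_dataset> %d patients, %d candidate features\n",
              length(x$y), ncol(x$x)))
  invisible(x)
}
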