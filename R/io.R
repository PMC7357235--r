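#' Write / read a cohort table
#'
#' The cohort CSV has one header row and one row per patient with the
#' columns of [generate_cohort()]'s `cohort` element (clinical fields,
#' treatment fields, `survival_days`). `read_cohort` validates the
#' schema and reports offending rows.
#'
#' @param cohort Cohort data.frame.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   validated data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

cohort_columns <- function() {
  c("patient_id", "age", "sex", "histology", "mental_status",
    "chemotherapy", "tumor_location", "surgical_resection",
    "symptom_duration", "prescription_dose_gy", "n_fractions",
    "treatment_duration_days", "gamma_knife", "target_volume_cc",
    "survival_days")
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns(), colnames(df))
  if (length(missing))
    stop("cohort file lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(is.na(df$survival_days))
  if (length(bad))
    stop("missing survival time for patient(s): ",
         paste(df$patient_id[bad], collapse = ", "))
  lv <- clinical_levels()
  for (nm in names(lv)) {
    off <- which(!df[[nm]] %in% lv[[nm]])
    if (length(off))
      stop("invalid level in '", nm, "' at row(s) ",
           paste(off, collapse = ", "))
  }
  df
}

#' Write / read DVH curves
#'
#' Each patient-structure curve is one CSV with columns `dose_gy`,
#' `volume_pct`, `volume_cc`, named `<patient>_<structure>.csv` in
#' `dir`. `read_dvh` re-validates the curve invariants and cites the
#' offending row on failure.
#'
#' @param dvh Named list (patient id) of named lists (structure) of
#'   [dvh_curve()]s.
#' @param dir Directory for the CSV files.
#' @return `write_dvh` returns `dir` invisibly; `read_dvh` the nested
#'   curve list.
#' @export
write_dvh <- function(dvh, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (pid in names(dvh)) for (st in names(dvh[[pid]])) {
    cv <- dvh[[pid]][[st]]
    utils::write.csv(
      data.frame(dose_gy = cv$dose, volume_pct = cv$volume_pct,
                 volume_cc = cv$volume_cc),
      file.path(dir, paste0(pid, "_", st, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_dvh
#' @export
read_dvh <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  out <- list()
  for (f in files) {
    base <- sub("\\.csv$", "", basename(f))
    st <- dvh_structures()[vapply(dvh_structures(), function(s)
      endsWith(base, s), logical(1))]
    if (length(st) != 1L) stop("cannot parse structure from file ", f)
    pid <- sub(paste0("_", st, "$"), "", base)
    df <- utils::read.csv(f)
    inc <- which(diff(df$volume_pct) > 1e-9)
    if (length(inc))
      stop("non-monotone volume in ", basename(f), " at row ",
           inc[1] + 1L)
    tv <- if (df$volume_pct[1] > 0) df$volume_cc[1] / df$volume_pct[1] * 100
          else stop("zero volume at dose 0 in ", basename(f))
    out[[pid]][[st]] <- dvh_curve(df$dose_gy, df$volume_pct,
                                  total_volume = tv, structure = st)
  }
  out
}

#' Write a model-comparison report
#'
#' JSON report (summary statistics, Wilcoxon and log-rank results, AUC)
#' plus CSV tables of the per-patient cross-validation results and the
#' Kaplan-Meier step curves.
#'
#' @param comparison An `rs_model_comparison`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(comparison, dir) {
  stopifnot(inherits(comparison, "rs_model_comparison"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  doc <- list(
    summary = comparison$summary,
    wilcoxon = lapply(comparison$wilcoxon, function(w)
      w[c("statistic", "p_value", "method")]),
    logrank = comparison$logrank,
    median_split_auc = comparison$auc
  )
  jsonlite::write_json(doc, file.path(dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (g in names(comparison$cv))
    utils::write.csv(comparison$cv[[g]],
                     file.path(dir, paste0("loocv_", g, ".csv")),
                     row.names = FALSE)
  for (k in names(comparison$km))
    utils::write.csv(comparison$km[[k]],
                     file.path(dir, paste0("km_", k, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

stage_seed <- function(seed, stage) {
  # documented fan-out: global seed + fixed offset per stage
  offsets <- c(generate = 0L, extract = 101L, select = 211L,
               evaluate = 307L, optimize = 401L)
  as.integer(seed) + offsets[[stage]]
}

#' Run the full analysis pipeline
#'
#' Orders the stages of the analysis: `generate` a synthetic cohort (or
#' load one), `extract` the candidate feature matrix, `select` features
#' and SVR parameters per feature group with the GA, `evaluate` the
#' three models, and `optimize` (what-if dose/duration surfaces for each
#' patient). Every stage writes its artifacts under `out_dir` together
#' with a manifest recording the seed and configuration; rerunning with
#' the same configuration and seed reproduces the outputs.
#'
#' @param out_dir Output directory.
#' @param stages Subset of
#'   `c("generate", "extract", "select", "evaluate", "optimize")`.
#' @param seed Global seed; per-stage seeds are derived by fixed
#'   offsets.
#' @param n_patients Cohort size for the generate stage.
#' @param truth Ground-truth model for the generate stage.
#' @param ga_profile GA budget profile (see [ga_config()]).
#' @param doses,durations What-if grids for the optimize stage.
#' @return Invisibly, a list with the objects produced by the executed
#'   stages.
#' @export
run_pipeline <- function(out_dir, stages = c("generate", "extract",
                                             "select", "evaluate",
                                             "optimize"),
                         seed = 1L, n_patients = 35,
                         truth = ground_truth_model(),
                         ga_profile = "ci",
                         doses = seq(30, 80, by = 10),
                         durations = c(30, 50, 70)) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  state <- list()

  if ("generate" %in% stages) {
    cfg <- cohort_config(n_patients = n_patients,
                         seed = stage_seed(seed, "generate"))
    state$cohort <- generate_cohort(cfg, truth)
    write_cohort(state$cohort$cohort, file.path(out_dir, "cohort.csv"))
    write_dvh(state$cohort$dvh, file.path(out_dir, "dvh"))
    jsonlite::write_json(
      list(seed = seed, n_patients = n_patients,
           truth = list(intercept = truth$intercept,
                        coefficients = as.list(truth$coefficients),
                        noise_sd = truth$noise_sd)),
      file.path(out_dir, "generate_manifest.json"),
      auto_unbox = TRUE, digits = NA)
  }

  if ("extract" %in% stages) {
    if (is.null(state$cohort)) {
      cohort <- read_cohort(file.path(out_dir, "cohort.csv"))
      dvh <- read_dvh(file.path(out_dir, "dvh"))
      state$features <- build_feature_matrix(cohort, dvh)
      state$dataset <- rs_dataset(state$features, cohort$survival_days,
                                  cohort$patient_id)
      state$raw <- list(cohort = cohort, dvh = dvh)
    } else {
      state$features <- state$cohort$features
      state$dataset <- as_rs_dataset(state$cohort)
      state$raw <- list(cohort = state$cohort$cohort,
                        dvh = state$cohort$dvh)
    }
    utils::write.csv(
      cbind(patient_id = rownames(state$features), state$features),
      file.path(out_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(feature_inventory(),
                         file.path(out_dir, "feature_inventory.json"),
                         dataframe = "rows")
  }

  inv <- feature_inventory()
  groups <- list(clinical = inv$name[inv$group == "clinical"],
                 dvh = inv$name[inv$group == "dvh"],
                 combined = inv$name)

  if ("select" %in% stages) {
    if (is.null(state$dataset))
      stop("select requires extract outputs; run the extract stage first")
    state$ga <- lapply(names(groups), function(g) {
      cfg <- ga_config(n_features = length(groups[[g]]),
                       profile = ga_profile,
                       seed = stage_seed(seed, "select") +
                         match(g, names(groups)))
      res <- ga_select(state$dataset, cfg, subset = groups[[g]])
      write_ga_manifest(res, file.path(out_dir,
                                       paste0("ga_", g, ".json")))
      res
    })
    names(state$ga) <- names(groups)
  }

  if ("evaluate" %in% stages) {
    if (is.null(state$ga))
      stop("evaluate requires select outputs; run the select stage first")
    selections <- lapply(names(groups), function(g) list(
      mask = intersect(state$ga[[g]]$best_features, groups[[g]]),
      params = state$ga[[g]]$best_record$params))
    names(selections) <- names(groups)
    state$comparison <- compare_feature_groups(state$dataset, selections)
    write_report(state$comparison, out_dir)
  }

  if ("optimize" %in% stages) {
    if (is.null(state$ga))
      stop("optimize requires select outputs; run the select stage first")
    model <- svr_train(state$dataset, state$ga$combined$best_features,
                       state$ga$combined$best_record$params)
    surfaces <- lapply(seq_len(nrow(state$raw$cohort)), function(i) {
      pid <- state$raw$cohort$patient_id[i]
      dose_duration_surface(state$raw$cohort[i, ],
                            state$features[i, , drop = FALSE],
                            state$raw$dvh[[pid]], model,
                            doses = doses, durations = durations)
    })
    state$surfaces <- do.call(rbind, surfaces)
    utils::write.csv(state$surfaces,
                     file.path(out_dir, "whatif_surfaces.csv"),
                     row.names = FALSE)
  }

  invisible(state)
}
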