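#' Leave-one-out cross-validated survival predictions
#'
#' For each patient, fits the SVR on the remaining n - 1 patients and
#' predicts the held-out one. The one-hot encoding map comes from the
#' declared feature schema; standardization statistics are re-estimated
#' inside every training fold, so no information leaks from the held-out
#' row. The residual error is the absolute difference between actual and
#' predicted survival.
#'
#' @param dataset An [rs_dataset()] with n >= 3.
#' @param mask Logical vector over `colnames(dataset$x)`, or a character
#'   vector of feature names.
#' @param params An [svr_params()].
#' @param group Optional label (`"clinical"`, `"dvh"`, `"combined"`, ...)
#'   attached to the result.
#' @param warm_start If `TRUE`, each fold's dual solver is seeded with
#'   the full-data solution (with the held-out point's coefficients
#'   removed), which cuts solver iterations by an order of magnitude.
#'   Fold models are refit to the same KKT tolerance either way, so
#'   predictions agree with the cold-start path to solver precision;
#'   the default keeps cold, independent per-fold fits.
#' @return Object of class `rs_cv`: data.frame with `patient_id`,
#'   `actual`, `predicted` and `residual` (days), one row per patient.
#' @export
loocv_predict <- function(dataset, mask, params, group = NA_character_,
                          warm_start = FALSE) {
  stopifnot(inherits(dataset, "rs_dataset"))
  n <- length(dataset$y)
  if (n < 3L) stop("LOOCV needs at least 3 patients")
  features <- if (is.character(mask)) mask else colnames(dataset$x)[mask]
  if (length(features) < 1L) stop("mask selects no features")
  if (!all(features %in% colnames(dataset$x)))
    stop("unknown feature(s): ",
         paste(setdiff(features, colnames(dataset$x)), collapse = ", "))
  # encode once (schema-level); standardize per fold below
  Xraw <- encode_columns(dataset$x,
                         list(features = features, levels = list()),
                         learn = TRUE)
  attr(Xraw, "transform") <- NULL
  y <- dataset$y
  predicted <- numeric(n)
  if (warm_start) {
    storage.mode(Xraw) <- "double"
    tol <- 1e-5 * (1 + max(abs(y)))
    res <- .smo_loocv(Xraw, y, params$C, params$epsilon, params$gamma,
                      tol, 500000L)
    if (!res$converged)
      stop("LOOCV fold ", res$fold, " failed: solver did not converge")
    predicted <- res$predicted
    out <- data.frame(patient_id = dataset$patient_id, actual = y,
                      predicted = predicted,
                      residual = abs(y - predicted))
    attr(out, "group") <- group
    attr(out, "features") <- features
    class(out) <- c("rs_cv", "data.frame")
    return(out)
  }
  for (i in seq_len(n)) {
    Xtr <- Xraw[-i, , drop = FALSE]
    ctr <- colMeans(Xtr)
    sc <- sqrt(pmax(colMeans(Xtr^2) - ctr^2, 0))
    sc[!is.finite(sc) | sc < 1e-12] <- 1
    Xs <- sweep(sweep(Xtr, 2L, ctr, "-"), 2L, sc, "/")
    fit <- tryCatch(
      fit_svr(Xs, y[-i], params),
      error = function(e) stop("LOOCV fold ", i, " failed: ",
                               conditionMessage(e), call. = FALSE))
    xnew <- (Xraw[i, ] - ctr) / sc
    predicted[i] <- predict(fit, matrix(xnew, nrow = 1L))
  }
  out <- data.frame(patient_id = dataset$patient_id, actual = y,
                    predicted = predicted,
                    residual = abs(y - predicted))
  attr(out, "group") <- group
  attr(out, "features") <- features
  class(out) <- c("rs_cv", "data.frame")
  out
}

#' Mean and standard deviation of LOOCV residual errors
#'
#' The mean residual error is the performance index of a model; the
#' standard deviation uses the n - 1 denominator. A single residual is
#' reported with sd 0 and `degenerate = TRUE`.
#'
#' @param cv An `rs_cv` from [loocv_predict()], or a numeric vector of
#'   residuals.
#' @return List with `mean`, `sd`, `n`, `degenerate`.
#' @export
summarize_residuals <- function(cv) {
  r <- if (inherits(cv, "rs_cv")) cv$residual else as.numeric(cv)
  if (length(r) == 0L) stop("no residuals to summarize")
  degenerate <- length(r) == 1L
  list(mean = mean(r), sd = if (degenerate) 0 else stats::sd(r),
       n = length(r), degenerate = degenerate)
}

# exact null distribution of the positive rank sum W+ for (possibly
# tied, mid-ranked) absolute ranks; ranks are doubled so sums are
# integers.  Returns counts over 0:T with T = sum(2*ranks).
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total + 1L - r)]
    f <- g
  }
  f
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences equal to zero are dropped (their count is flagged); tied
#' absolute differences receive mid-ranks. For `m <= exact_max` nonzero
#' pairs the p-value is exact, computed from the full null distribution
#' of the rank sum (equivalent to enumerating all `2^m` sign patterns);
#' beyond that a normal approximation with tie correction and continuity
#' correction is used. The reported statistic is the smaller of the
#' positive and negative rank sums.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of the
#'   location of `a - b`).
#' @param exact_max Largest number of nonzero pairs for which the exact
#'   distribution is enumerated.
#' @return List with `statistic` (min rank sum), `w_plus`, `p_value`,
#'   `method`, `n_zero` (dropped pairs) and `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(a, b,
                                 alternative = c("two.sided", "less",
                                                 "greater"),
                                 exact_max = 25L) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b) || length(a) < 1L)
    stop("paired samples of equal length >= 1 required")
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L)
    return(list(statistic = 0, w_plus = 0, p_value = 1,
                method = "degenerate", n_zero = length(a),
                all_zero = TRUE))
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  w_minus <- sum(rk[d < 0])
  total <- m * (m + 1) / 2
  if (m <= exact_max) {
    counts <- signed_rank_counts(as.integer(round(2 * rk)))
    denom <- 2^m
    cum <- cumsum(counts)
    p_le <- function(w) cum[min(length(cum), floor(round(2 * w)) + 1L)] / denom
    p_ge <- function(w) {
      idx <- ceiling(round(2 * w)) + 1L
      if (idx > length(counts)) 0 else sum(counts[idx:length(counts)]) / denom
    }
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le(w_plus), p_ge(w_plus))),
                greater = p_ge(w_plus),
                less = p_le(w_plus))
    method <- "exact"
  } else {
    mu <- total / 2
    tie_tab <- table(rk)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5
    z_g <- (w_plus - mu - cc) / sqrt(sigma2)
    z_l <- (w_plus - mu + cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(stats::pnorm(z_l),
                                           stats::pnorm(z_g,
                                                        lower.tail = FALSE))),
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l))
    method <- "normal approximation"
  }
  list(statistic = min(w_plus, w_minus), w_plus = w_plus, p_value = p,
       method = method, n_zero = length(a) - m, all_zero = FALSE)
}

#' Kaplan-Meier product-limit survival curve
#'
#' Thin wrapper over [survival::survfit()] returning the step function
#' as a table. With no censoring the estimate equals the empirical
#' survival function.
#'
#' @param times Positive survival times in days.
#' @param events Event indicators (1 = death observed); defaults to all
#'   observed, matching a cohort followed until death.
#' @return Object of class `rs_km`: data.frame with `time`, `n_risk`,
#'   `n_event`, `survival`.
#' @export
kaplan_meier <- function(times, events = rep(1, length(times))) {
  if (any(times <= 0)) stop("survival times must be positive")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "none")
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, survival = sf$surv)
  class(out) <- c("rs_km", "data.frame")
  out
}

#' @param x An `rs_km` object.
#' @param ... Passed to [graphics::plot()].
#' @rdname kaplan_meier
#' @export
plot.rs_km <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$survival)),
                 do.points = FALSE, verticals = FALSE,
                 xlab = "days", ylab = "survival fraction",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Two-sample log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with 1 degree of
#' freedom, via [survival::survdiff()].
#'
#' @param times_a,times_b Positive survival times of the two groups.
#' @param events_a,events_b Event indicators (default: all observed).
#' @return List with `statistic` (chi-square), `p_value`, `df`.
#' @export
logrank_test <- function(times_a, times_b,
                         events_a = rep(1, length(times_a)),
                         events_b = rep(1, length(times_b))) {
  if (any(c(times_a, times_b) <= 0))
    stop("survival times must be positive")
  if (sum(events_a) == 0 || sum(events_b) == 0)
    stop("degenerate comparison: a group has no observed events")
  df <- data.frame(
    time = c(times_a, times_b), event = c(events_a, events_b),
    group = rep(c("A", "B"), c(length(times_a), length(times_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Median-split classification AUC of a survival regressor
#'
#' Binarizes the actual survival at its median (values equal to the
#' median go to the lower class) and scores the predicted survival as a
#' ranking of the two classes: the area under the ROC curve computed by
#' the rank (Mann-Whitney) formula, with tied predictions counted 1/2.
#'
#' @param actual Observed survival times (days), n >= 4.
#' @param predicted Predicted survival times (days).
#' @return AUC in [0, 1].
#' @export
median_split_auc <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 4L)
    stop("need paired vectors of length >= 4")
  labels <- actual > stats::median(actual)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("median split produced a single class")
  r <- rank(predicted)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare clinical-only, DVH-only and combined feature models
#'
#' Runs leave-one-out cross-validation for each feature-group selection,
#' summarizes residual errors, tests the combined model's residuals
#' against each single-group model with the paired Wilcoxon signed-rank
#' test, compares the actual survival with the combined model's
#' predictions by Kaplan-Meier curves and the log-rank test (predictions
#' treated as a fully-observed sample), and reports the median-split
#' classification AUC of the combined model.
#'
#' @param dataset An [rs_dataset()].
#' @param selections Named list with elements `clinical`, `dvh`,
#'   `combined`, each a list with `mask` (logical or character) and
#'   `params` ([svr_params()]), e.g. from [ga_select()] runs restricted
#'   to each group.
#' @return Object of class `rs_model_comparison`: `summary` (data.frame
#'   group/mean/sd), `cv` (list of `rs_cv`), `wilcoxon` (combined vs
#'   each), `km` (list of `rs_km` for actual and predicted), `logrank`,
#'   `auc`.
#' @export
compare_feature_groups <- function(dataset, selections) {
  need <- c("clinical", "dvh", "combined")
  if (!all(need %in% names(selections)))
    stop("selections must contain: ", paste(need, collapse = ", "))
  cv <- lapply(need, function(g)
    loocv_predict(dataset, selections[[g]]$mask, selections[[g]]$params,
                  group = g))
  names(cv) <- need
  summ <- do.call(rbind, lapply(need, function(g) {
    s <- summarize_residuals(cv[[g]])
    data.frame(group = g, mean_residual = s$mean, sd_residual = s$sd,
               n = s$n)
  }))
  wil <- list(
    combined_vs_clinical = wilcoxon_signed_rank(cv$combined$residual,
                                                cv$clinical$residual),
    combined_vs_dvh = wilcoxon_signed_rank(cv$combined$residual,
                                           cv$dvh$residual)
  )
  pred <- pmax(cv$combined$predicted, 1)  # KM needs positive times
  km <- list(actual = kaplan_meier(cv$combined$actual),
             predicted = kaplan_meier(pred))
  lr <- logrank_test(cv$combined$actual, pred)
  auc <- median_split_auc(cv$combined$actual, cv$combined$predicted)
  structure(list(summary = summ, cv = cv, wilcoxon = wil, km = km,
                 logrank = lr, auc = auc),
            class = "rs_model_comparison")
}

#' @export
print.rs_model_comparison <- function(x, ...) {
  cat("<rs_model_comparison>\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s mean residual %.1f +/- %.1f days (n = %d)\n",
                s$group[i], s$mean_residual[i], s$sd_residual[i], s$n[i]))
  cat(sprintf("  Wilcoxon combined vs clinical: p = %.4g\n",
              x$wilcoxon$combined_vs_clinical$p_value))
  cat(sprintf("  Wilcoxon combined vs DVH:      p = %.4g\n",
              x$wilcoxon$combined_vs_dvh$p_value))
  cat(sprintf("  Log-rank actual vs predicted:  chi2 = %.3f, p = %.3f\n",
              x$logrank$statistic, x$logrank$p_value))
  cat(sprintf("  Median-split AUC: %.3f\n", x$auc))
  invisible(x)
}
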