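#' SVR hyperparameters
#'
#' @param C Regularization weight (> 0): trade-off between flatness and
#'   training error.
#' @param epsilon Half-width of the insensitive zone in days (>= 0):
#'   residuals smaller than `epsilon` carry no loss.
#' @param gamma RBF kernel amplitude (> 0), per squared standardized
#'   feature unit.
#' @return An object of class `svr_params`.
#' @export
svr_params <- function(C, epsilon, gamma) {
  if (!is.finite(C) || C <= 0) stop("C must be positive")
  if (!is.finite(epsilon) || epsilon < 0) stop("epsilon must be >= 0")
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive")
  structure(list(C = C, epsilon = epsilon, gamma = gamma),
            class = "svr_params")
}

#' @export
print.svr_params <- function(x, ...) {
  cat(sprintf("<svr_params> C = %.4g, epsilon = %.4g days, gamma = %.4g\n",
              x$C, x$epsilon, x$gamma))
  invisible(x)
}

#' Encode and standardize a feature subset
#'
#' Builds a numeric design matrix from the selected candidate features:
#' categorical features are one-hot encoded (binary features become a
#' single 0/1 indicator of the second declared level), numeric features
#' are z-scored. Standardization statistics (mean and population standard
#' deviation) come from the supplied data only, so refitting the
#' transform inside each cross-validation fold avoids leakage; constant
#' columns get a unit scale and map to zero.
#'
#' @param data Data.frame of candidate features.
#' @param features Character vector of selected feature names (>= 1).
#' @param transform Optional transform record from a previous call; when
#'   supplied, its encoding and statistics are applied to `data` instead
#'   of being re-estimated.
#' @return List with `X` (numeric matrix) and `transform` (encoding map
#'   plus `centers` and `scales`).
#' @export
encode_and_standardize <- function(data, features, transform = NULL) {
  if (is.null(transform)) {
    if (length(features) < 1L) stop("at least one feature must be selected")
    if (!all(features %in% colnames(data)))
      stop("unknown feature(s): ",
           paste(setdiff(features, colnames(data)), collapse = ", "))
    transform <- list(features = features, levels = list(),
                      centers = NULL, scales = NULL)
    X <- encode_columns(data, transform, learn = TRUE)
    transform <- attr(X, "transform")
    ctr <- colMeans(X)
    sc <- sqrt(pmax(colMeans(X^2) - ctr^2, 0))   # population sd
    sc[!is.finite(sc) | sc < 1e-12] <- 1
    transform$centers <- ctr
    transform$scales <- sc
  } else {
    X <- encode_columns(data, transform, learn = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, transform$centers, "-"), 2L,
              transform$scales, "/")
  attr(Xs, "transform") <- NULL
  list(X = Xs, transform = transform)
}

encode_columns <- function(data, transform, learn) {
  cols <- list()
  for (f in transform$features) {
    v <- data[[f]]
    if (is.factor(v) || is.character(v)) {
      if (learn) {
        lev <- if (is.factor(v)) levels(v) else sort(unique(as.character(v)))
        transform$levels[[f]] <- lev
      } else lev <- transform$levels[[f]]
      vc <- as.character(v)
      if (any(!vc %in% lev))
        stop("unseen category in feature '", f, "': ",
             paste(unique(setdiff(vc, lev)), collapse = ", "))
      if (length(lev) == 2L) {
        cols[[f]] <- as.numeric(vc == lev[2L])
      } else {
        for (l in lev) cols[[paste0(f, "=", l)]] <- as.numeric(vc == l)
      }
    } else {
      if (any(is.na(v))) stop("missing values in feature '", f, "'")
      cols[[f]] <- as.numeric(v)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  attr(X, "transform") <- transform
  X
}

#' Fit an epsilon-insensitive RBF support vector regression
#'
#' Solves the standard eps-SVR dual with an in-package SMO solver
#' (maximal-violating-pair working set selection). The bias is the mean
#' of the Karush-Kuhn-Tucker estimate over free support vectors; when no
#' support vector is free the midpoint of the feasible interval is used.
#'
#' @param X Numeric design matrix (rows = observations), already encoded
#'   and standardized (see [encode_and_standardize()]).
#' @param y Numeric targets (survival days).
#' @param params An [svr_params()] object.
#' @param tol Solver stopping tolerance on the KKT violation; defaults to
#'   `1e-5 * (1 + max(abs(y)))` so it scales with the target units.
#' @param max_iter Iteration cap; exceeding it raises a convergence error.
#' @return Object of class `rs_svr` with elements `X`, `beta` (support
#'   coefficients alpha - alpha*), `bias`, `params`.
#' @export
fit_svr <- function(X, y, params, tol = NULL, max_iter = 500000L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 1L) stop("need at least one training row")
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  stopifnot(inherits(params, "svr_params"))
  if (is.null(tol)) tol <- 1e-5 * (1 + max(abs(y)))
  fit <- .smo_fit(X, y, params$C, params$epsilon, params$gamma, tol,
                  as.integer(max_iter))
  if (!fit$converged)
    stop("SVR solver did not converge within ", max_iter, " iterations")
  structure(list(X = X, beta = fit$beta, bias = fit$bias, params = params,
                 iterations = fit$iterations),
            class = "rs_svr")
}

#' @export
predict.rs_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != ncol(object$X))
    stop("newdata has ", ncol(newdata), " columns, model expects ",
         ncol(object$X))
  as.numeric(.rbf_predict(object$X, object$beta, object$bias,
                          object$params$gamma, newdata))
}

#' Train a survival SVR on named candidate features
#'
#' High-level wrapper: encodes and standardizes the selected features,
#' fits the SVR, and returns a self-contained model that can predict from
#' raw feature rows. This is the model object consumed by the what-if
#' simulation.
#'
#' @param dataset An [rs_dataset()].
#' @param features Character vector of selected candidate feature names.
#' @param params An [svr_params()].
#' @param ... Passed to [fit_svr()].
#' @return Object of class `rs_model` holding the transform record, the
#'   fitted SVR and the selected feature names.
#' @export
svr_train <- function(dataset, features, params, ...) {
  stopifnot(inherits(dataset, "rs_dataset"))
  enc <- encode_and_standardize(dataset$x, features)
  fit <- fit_svr(enc$X, dataset$y, params, ...)
  structure(list(transform = enc$transform, fit = fit,
                 features = features, params = params),
            class = "rs_model")
}

#' @export
predict.rs_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop("missing feature(s) in newdata: ", paste(missing, collapse = ", "))
  enc <- encode_and_standardize(newdata, transform = object$transform)
  predict(object$fit, enc$X)
}

#' @export
print.rs_model <- function(x, ...) {
  cat(sprintf("<rs_model> eps-SVR on %d features (C = %.4g, eps = %.4g, gamma = %.4g)\n",
              length(x$features), x$params$C, x$params$epsilon,
              x$params$gamma))
  invisible(x)
}

#' Serialize / restore an rs_model as JSON
#'
#' @param model An `rs_model`.
#' @param path File path for the JSON document.
#' @return `write_model` returns `path` invisibly; `read_model` returns
#'   the restored `rs_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "rs_model"))
  doc <- list(
    features = model$features,
    params = unclass(model$params),
    transform = model$transform,
    X = model$fit$X, beta = model$fit$beta, bias = model$fit$bias
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- svr_params(doc$params$C, doc$params$epsilon, doc$params$gamma)
  tr <- doc$transform
  tr$centers <- unlist(tr$centers)
  tr$scales <- unlist(tr$scales)
  fit <- structure(list(X = as.matrix(doc$X), beta = as.numeric(doc$beta),
                        bias = as.numeric(doc$bias), params = params),
                   class = "rs_svr")
  structure(list(transform = tr, fit = fit, features = doc$features,
                 params = params),
            class = "rs_model")
}
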