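#' Genetic-algorithm configuration
#'
#' The chromosome is a bitstring with three fixed-width parameter
#' segments (C, epsilon, gamma, decoded log-uniformly onto their ranges)
#' followed by one mask bit per candidate feature. The study-faithful
#' profile uses a population of 500 evolved for 1000 generations with
#' crossover rate 0.8 and mutation rate 0.3; the `"ci"` profile is a
#' reduced budget (population 30, 40 generations) for smoke runs.
#'
#' @param n_features Number of candidate features (mask length).
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate Probability a selected pair is recombined by
#'   uniform crossover.
#' @param mutation_rate Expected number of bit flips per individual; each
#'   bit flips independently with probability
#'   `mutation_rate / chromosome length`.
#' @param bits Named integer vector of segment widths for C, epsilon and
#'   gamma.
#' @param ranges Named list of `c(lo, hi)` decoding ranges: C is
#'   unitless, epsilon in days, gamma per squared standardized unit.
#' @param tournament_size Tournament selection size.
#' @param elitism Number of best individuals copied unchanged.
#' @param init_mask_prob Probability a mask bit starts at 1; the sparse
#'   default matches the parsimony pressure of the AIC fitness.
#' @param seed Integer seed for the run.
#' @param profile `"paper"` (500 x 1000) or `"ci"` (30 x 40); explicit
#'   `population_size`/`generations` arguments override the profile.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(n_features, population_size = NULL,
                      generations = NULL, crossover_rate = 0.8,
                      mutation_rate = 0.3,
                      bits = c(C = 12L, epsilon = 12L, gamma = 12L),
                      ranges = list(C = c(2^-5, 2^15),
                                    epsilon = c(1e-2, 1e2),
                                    gamma = c(2^-15, 2^3)),
                      tournament_size = 2L, elitism = 1L,
                      init_mask_prob = 0.15, seed = 1L,
                      profile = c("paper", "ci")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper") c(500L, 1000L) else c(30L, 40L)
  if (is.null(population_size)) population_size <- defaults[1]
  if (is.null(generations)) generations <- defaults[2]
  if (population_size < 2L) stop("population_size must be >= 2")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0)
    stop("rates must be valid probabilities / budgets")
  if (n_features < 1L) stop("need at least one candidate feature")
  stopifnot(all(c("C", "epsilon", "gamma") %in% names(bits)),
            all(c("C", "epsilon", "gamma") %in% names(ranges)))
  for (r in ranges) if (r[1] <= 0 || r[1] > r[2]) stop("invalid range")
  structure(list(
    n_features = as.integer(n_features),
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    crossover_rate = crossover_rate, mutation_rate = mutation_rate,
    bits = bits, ranges = ranges,
    tournament_size = as.integer(tournament_size),
    elitism = as.integer(elitism), init_mask_prob = init_mask_prob,
    seed = as.integer(seed), profile = profile,
    length = sum(bits) + as.integer(n_features)
  ), class = "ga_config")
}

segment_index <- function(config) {
  b <- config$bits
  list(C = seq_len(b[["C"]]),
       epsilon = b[["C"]] + seq_len(b[["epsilon"]]),
       gamma = b[["C"]] + b[["epsilon"]] + seq_len(b[["gamma"]]),
       mask = sum(b) + seq_len(config$n_features))
}

decode_segment <- function(bits, range) {
  b <- length(bits)
  v <- sum(bits * 2^((b - 1):0))
  lo <- range[1]; hi <- range[2]
  lo * (hi / lo)^(v / (2^b - 1))
}

#' Decode a chromosome into SVR parameters and a feature mask
#'
#' Each parameter segment is read as an unsigned integer `v` of `b` bits
#' and mapped log-uniformly onto its range:
#' `param = lo * (hi/lo)^(v / (2^b - 1))`. Mask bits pass through. An
#' all-zero mask is repaired by activating one random bit (so every
#' decoded individual selects at least one feature).
#'
#' @param chrom Integer 0/1 vector of length `config$length`.
#' @param config A [ga_config()].
#' @return List with `params` ([svr_params()]) and `mask` (logical).
#' @export
decode_chromosome <- function(chrom, config) {
  if (length(chrom) != config$length)
    stop("chromosome length ", length(chrom), " != ", config$length)
  idx <- segment_index(config)
  params <- svr_params(
    C = decode_segment(chrom[idx$C], config$ranges$C),
    epsilon = decode_segment(chrom[idx$epsilon], config$ranges$epsilon),
    gamma = decode_segment(chrom[idx$gamma], config$ranges$gamma)
  )
  mask <- chrom[idx$mask] == 1L
  list(params = params, mask = mask)
}

repair_chromosome <- function(chrom, config) {
  idx <- segment_index(config)
  if (!any(chrom[idx$mask] == 1L)) {
    pick <- if (config$n_features == 1L) 1L
            else sample.int(config$n_features, 1L)
    chrom[idx$mask[pick]] <- 1L
  }
  chrom
}

random_chromosome <- function(config) {
  idx <- segment_index(config)
  chrom <- integer(config$length)
  nb <- sum(config$bits)
  chrom[seq_len(nb)] <- sample(0:1, nb, TRUE)
  chrom[idx$mask] <- stats::rbinom(config$n_features, 1L,
                                   config$init_mask_prob)
  repair_chromosome(chrom, config)
}

#' AIC of a residual vector
#'
#' The Gaussian-residual Akaike information criterion used as the GA
#' fitness: `n * log(RSS / n) + 2 * (k + 1)`, with `RSS` the sum of
#' squared residuals, `n` their number and `k` the number of selected
#' features (the `+ 1` counts the residual variance). `RSS` is clamped
#' below at `1e-12` so a perfect fit stays finite.
#'
#' @param residuals Numeric residual vector (days).
#' @param k Number of model features.
#' @return The AIC (unitless; smaller is better).
#' @examples
#' aic_score(rep(1, 4), k = 2)   # 4 log(1) + 2 * 3 = 6
#' @export
aic_score <- function(residuals, k) {
  n <- length(residuals)
  rss <- max(sum(residuals^2), 1e-12)
  n * log(rss / n) + 2 * (k + 1)
}

#' GA fitness: AIC of the leave-one-out residuals
#'
#' Decodes the chromosome, runs leave-one-out cross-validation with the
#' selected features and parameters, and scores
#' `AIC = n * log(RSS / n) + 2 * (k + 1)` with `RSS` the sum of squared
#' LOOCV residuals and `k` the number of selected features (the +1
#' counts the noise variance). Smaller is fitter; a simple model with few
#' features is favoured. `RSS` is clamped below at `1e-12` so a perfect
#' fit stays finite; a solver failure on any fold yields an infinite
#' (worst) fitness rather than an error, so the GA is total.
#'
#' @param chrom Chromosome bit vector.
#' @param dataset An [rs_dataset()] (n >= 3).
#' @param config A [ga_config()].
#' @return List of class `fitness_record`: `aic`, `n`, `k`, `rss`,
#'   `params`, `mask`, `failed`.
#' @export
ga_fitness <- function(chrom, dataset, config) {
  stopifnot(inherits(dataset, "rs_dataset"))
  n <- length(dataset$y)
  if (n < 3L) stop("dataset must have at least 3 rows")
  dec <- decode_chromosome(chrom, config)
  k <- sum(dec$mask)
  rec <- tryCatch({
    cv <- loocv_predict(dataset, dec$mask, dec$params, warm_start = TRUE)
    list(aic = aic_score(cv$residual, k),
         rss = max(sum(cv$residual^2), 1e-12), failed = FALSE)
  }, error = function(e) list(aic = Inf, rss = Inf, failed = TRUE))
  structure(list(aic = rec$aic, n = n, k = k, rss = rec$rss,
                 params = dec$params, mask = dec$mask,
                 failed = rec$failed),
            class = "fitness_record")
}

tournament_pick <- function(fitness, size) {
  cand <- sample.int(length(fitness), size, replace = TRUE)
  cand[which.min(fitness[cand])]
}

#' One GA generation: selection, crossover, mutation, elitism
#'
#' Tournament selection (size `config$tournament_size`) draws parents;
#' each pair undergoes uniform crossover with probability
#' `crossover_rate`; every bit then flips with probability
#' `mutation_rate / length`; empty masks are repaired; the
#' `elitism` best individuals survive unchanged. Population size is
#' constant.
#'
#' @param population List of chromosomes.
#' @param fitness Numeric vector of their AIC values.
#' @param config A [ga_config()].
#' @return List of chromosomes of the same length.
#' @export
genetic_step <- function(population, fitness, config) {
  np <- length(population)
  ord <- order(fitness)
  nxt <- vector("list", np)
  nelite <- min(config$elitism, np)
  for (e in seq_len(nelite)) nxt[[e]] <- population[[ord[e]]]
  pbit <- min(config$mutation_rate / config$length, 1)
  i <- nelite + 1L
  while (i <= np) {
    p1 <- population[[tournament_pick(fitness, config$tournament_size)]]
    p2 <- population[[tournament_pick(fitness, config$tournament_size)]]
    if (stats::runif(1) < config$crossover_rate) {
      swap <- stats::runif(config$length) < 0.5
      tmp <- p1[swap]
      p1[swap] <- p2[swap]
      p2[swap] <- tmp
    }
    for (child in list(p1, p2)) {
      if (i > np) break
      flip <- stats::runif(config$length) < pbit
      child[flip] <- 1L - child[flip]
      nxt[[i]] <- repair_chromosome(child, config)
      i <- i + 1L
    }
  }
  nxt
}

#' Simultaneous GA selection of features and SVR parameters
#'
#' Evolves a population of chromosomes encoding (C, epsilon, gamma) and
#' the feature mask, scored by [ga_fitness()] (AIC on leave-one-out
#' residuals), for `config$generations` generations. Fitness values are
#' cached by chromosome, so unchanged individuals are not re-evaluated.
#' With one-individual elitism the best-so-far fitness is non-increasing
#' across generations. Seeded and reproducible.
#'
#' @param dataset An [rs_dataset()].
#' @param config A [ga_config()]; `config$n_features` must equal
#'   `ncol(dataset$x)` (or the number of candidate columns in `subset`).
#' @param subset Optional character vector restricting the candidate
#'   features to a group (e.g. clinical-only); the mask then ranges over
#'   this subset.
#' @return List of class `ga_result`: `best_chromosome`, `best_record`
#'   (a `fitness_record`), `best_features` (selected names), `trace`
#'   (data.frame of per-generation best and best-so-far AIC), `config`,
#'   `evaluations` (number of distinct chromosomes scored).
#' @export
ga_select <- function(dataset, config, subset = NULL) {
  stopifnot(inherits(dataset, "rs_dataset"))
  data <- dataset
  if (!is.null(subset)) {
    if (!all(subset %in% colnames(dataset$x)))
      stop("unknown features in subset")
    data <- rs_dataset(dataset$x[, subset, drop = FALSE], dataset$y,
                       dataset$patient_id)
  }
  if (config$n_features != ncol(data$x))
    stop("config$n_features (", config$n_features,
         ") != number of candidate features (", ncol(data$x), ")")
  set.seed(config$seed)

  cache <- new.env(parent = emptyenv())
  nevals <- 0L
  eval_one <- function(chrom) {
    key <- paste(chrom, collapse = "")
    rec <- cache[[key]]
    if (is.null(rec)) {
      rec <- ga_fitness(chrom, data, config)
      cache[[key]] <- rec
      nevals <<- nevals + 1L
    }
    rec
  }

  population <- replicate(config$population_size,
                          random_chromosome(config), simplify = FALSE)
  best_rec <- NULL
  best_chrom <- NULL
  trace <- data.frame(generation = integer(), best_aic = numeric(),
                      best_so_far = numeric())
  for (gen in seq_len(config$generations)) {
    records <- lapply(population, eval_one)
    fitness <- vapply(records, function(r) r$aic, numeric(1))
    ib <- which.min(fitness)
    if (is.null(best_rec) || fitness[ib] < best_rec$aic) {
      best_rec <- records[[ib]]
      best_chrom <- population[[ib]]
    }
    trace <- rbind(trace, data.frame(generation = gen,
                                     best_aic = fitness[ib],
                                     best_so_far = best_rec$aic))
    if (gen < config$generations)
      population <- genetic_step(population, fitness, config)
  }
  structure(list(
    best_chromosome = best_chrom, best_record = best_rec,
    best_features = colnames(data$x)[best_rec$mask],
    trace = trace, config = config, evaluations = nevals
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result> best AIC %.3f with %d features after %d generations (%d evaluations)\n",
    x$best_record$aic, x$best_record$k, nrow(x$trace), x$evaluations))
  cat("  features:", paste(utils::head(x$best_features, 8), collapse = ", "),
      if (length(x$best_features) > 8) "...\n" else "\n")
  invisible(x)
}

#' Write a GA run manifest
#'
#' Records the configuration, seed, best chromosome, decoded parameters,
#' selected feature names and the fitness trace as JSON (the trace also
#' as CSV next to it).
#'
#' @param result A `ga_result`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_ga_manifest <- function(result, path) {
  stopifnot(inherits(result, "ga_result"))
  cfg <- result$config
  doc <- list(
    seed = cfg$seed, population_size = cfg$population_size,
    generations = cfg$generations, crossover_rate = cfg$crossover_rate,
    mutation_rate = cfg$mutation_rate, bits = as.list(cfg$bits),
    ranges = cfg$ranges,
    best_chromosome = paste(result$best_chromosome, collapse = ""),
    params = unclass(result$best_record$params),
    aic = result$best_record$aic,
    selected_features = result$best_features
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$trace, sub("\\.json$", "_trace.csv", path),
                   row.names = FALSE)
  invisible(path)
}
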