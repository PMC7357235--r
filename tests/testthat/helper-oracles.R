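# Independent oracles used across the test files.  Each is written
# directly from the defining formulas, not from the package's code paths.

# Brute-force eps-SVR dual solved as a box-constrained QP in the 2n
# variables (alpha, alpha*) with kernlab's interior-point solver; a tiny
# ridge keeps the (singular) dual Hessian numerically positive definite.
# The bias uses the KKT estimate averaged over free support vectors,
# falling back to the feasible-interval midpoint (the documented model
# convention).
qp_svr_oracle <- function(X, y, C, eps, gamma) {
  n <- nrow(X)
  K <- exp(-gamma * as.matrix(stats::dist(X))^2)
  cc <- c(eps - y, eps + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), nrow = 1)
  a <- NULL
  for (ridge in c(1e-10, 1e-8, 1e-7)) {
    H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(ridge, 2 * n)
    a <- tryCatch({
      sv <- kernlab::ipop(c = cc, H = H, A = A, b = 0,
                          l = rep(0, 2 * n), u = rep(C, 2 * n), r = 0,
                          sigf = 7, maxiter = 300)
      kernlab::primal(sv)
    }, error = function(e) NULL)
    if (!is.null(a)) break
  }
  if (is.null(a)) stop("QP oracle failed on this instance")
  beta <- a[1:n] - a[(n + 1):(2 * n)]
  u <- as.numeric(K %*% beta)
  # bias by direct 1-D primal minimization: b minimizes the summed
  # eps-insensitive loss of the residuals r - b; the argmin interval's
  # midpoint matches the model's KKT-midpoint convention and is robust
  # to the interior-point solver's fuzzy bound activity
  r <- y - u
  knots <- sort(c(r - eps, r + eps))
  loss <- vapply(knots, function(b) sum(pmax(abs(r - b) - eps, 0)),
                 numeric(1))
  minl <- min(loss)
  bias <- mean(range(knots[loss <= minl + 1e-10 * (1 + minl)]))
  list(beta = beta, bias = bias,
       predict = function(Xnew) {
         Kn <- matrix(0, nrow(Xnew), n)
         for (i in seq_len(nrow(Xnew)))
           for (j in seq_len(n))
             Kn[i, j] <- exp(-gamma * sum((Xnew[i, ] - X[j, ])^2))
         as.numeric(Kn %*% beta + bias)
       })
}

# Exact Wilcoxon signed-rank p-value by full enumeration of the 2^m sign
# patterns (mid-ranks for ties, zeros dropped by the caller).
wilcoxon_enum_oracle <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  m <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.numeric(signs %*% rk)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# AUC by brute-force concordant-pair counting (ties count 1/2).
auc_pair_oracle <- function(labels, scores) {
  pos <- which(labels)
  neg <- which(!labels)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# Hand-written leave-one-out loop around the public fit/predict API,
# standardizing each training fold with the population-sd convention.
loocv_loop_oracle <- function(dataset, features, params) {
  X <- radsurv:::encode_columns(dataset$x,
                                list(features = features, levels = list()),
                                learn = TRUE)
  attr(X, "transform") <- NULL
  n <- length(dataset$y)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ctr <- colMeans(Xtr)
    sc <- sqrt(pmax(colMeans(Xtr^2) - ctr^2, 0))
    sc[!is.finite(sc) | sc < 1e-12] <- 1
    Xs <- sweep(sweep(Xtr, 2L, ctr, "-"), 2L, sc, "/")
    fit <- fit_svr(Xs, dataset$y[-i], params)
    pred[i] <- predict(fit, matrix((X[i, ] - ctr) / sc, nrow = 1))
  }
  pred
}

# Product-limit estimator computed directly from the risk table.
km_hand_oracle <- function(times) {
  ut <- sort(unique(times))
  s <- 1
  out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    n_risk <- sum(times >= ut[k])
    n_event <- sum(times == ut[k])
    s <- s * (1 - n_event / n_risk)
    out[k] <- s
  }
  data.frame(time = ut, survival = out)
}

# Two-group log-rank chi-square from the hand-tabulated O-E risk table.
logrank_hand_oracle <- function(ta, tb) {
  times <- sort(unique(c(ta, tb)))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    n1 <- sum(ta >= t); n2 <- sum(tb >= t); n <- n1 + n2
    d1 <- sum(ta == t); d2 <- sum(tb == t); d <- d1 + d2
    if (n < 1 || d == 0) next
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
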