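# Analytic DVH fixtures.

# V(d) = 100 * (1 - d/80) on [0, 80] Gy: closed-form inversions
# D_x = 80 * (1 - x/100), V_x = 100 * (1 - x/80), mean = 40 Gy.
linear_curve <- function(total_volume = 200) {
  dvh_curve(c(0, 80), c(100, 0), total_volume = total_volume,
            structure = "PTV_local")
}

# Uniform irradiation at `dose` Gy: a step curve (sharp linear drop of
# width `delta`).
step_curve <- function(dose = 60, total_volume = 100, delta = 1e-9,
                       structure = "PTV_local") {
  dvh_curve(c(0, dose, dose + delta), c(100, 100, 0),
            total_volume = total_volume, structure = structure)
}

# Two-level curve: 100% of the volume gets >= lo Gy, `frac` of it gets
# >= hi Gy.
two_step_curve <- function(lo = 40, hi = 60, frac = 50,
                           total_volume = 100, delta = 1e-9) {
  dvh_curve(c(0, lo, lo + delta, hi, hi + delta),
            c(100, 100, frac, frac, 0),
            total_volume = total_volume, structure = "PTV_local")
}

# Uniform curves for all four structures (used by feature extraction
# tests).
uniform_structure_set <- function(dose = 60, volume = 100) {
  out <- lapply(dvh_structures(), function(st)
    step_curve(dose, total_volume = volume, structure = st))
  names(out) <- dvh_structures()
  out
}

toy_treatment <- function(dose = 60, n_fractions = 30, duration = 42,
                          volume = 100) {
  list(gamma_knife = 0, target_volume_cc = volume,
       prescription_dose_gy = dose, n_fractions = n_fractions,
       treatment_duration_days = duration)
}

# Small deterministic regression datasets for SVR tests.
toy_xy <- function(n = 5, p = 1, seed = 1, noise = 0.2) {
  set.seed(seed)
  X <- matrix(stats::runif(n * p, -2, 2), n, p)
  y <- sin(X[, 1]) + if (noise > 0) stats::rnorm(n, 0, noise) else 0
  list(X = X, y = y)
}
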