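#' Cumulative dose-volume histogram curve
#'
#' Container for one structure's cumulative DVH: for each dose level `d`,
#' the percentage of the structure volume receiving at least `d` Gy.
#' Absolute volumes (cm^3) are derived from `total_volume`.
#'
#' @param dose Numeric vector of dose levels (Gy), strictly increasing,
#'   starting at 0.
#' @param volume_pct Numeric vector of relative volumes (%), non-increasing,
#'   with `volume_pct[1] == 100`.
#' @param total_volume Structure volume in cm^3 (positive scalar).
#' @param structure Structure label, one of `dvh_structures()`.
#' @return An object of class `dvh_curve`: a list with elements `dose`,
#'   `volume_pct`, `volume_cc`, `total_volume` and `structure`.
#' @examples
#' cv <- dvh_curve(c(0, 40, 80), c(100, 50, 0), total_volume = 120,
#'                 structure = "PTV_local")
#' dose_at_volume(cv, 50)
#' @export
dvh_curve <- function(dose, volume_pct, total_volume,
                      structure = "PTV_local") {
  dose <- as.numeric(dose)
  volume_pct <- as.numeric(volume_pct)
  if (length(dose) < 2L || length(dose) != length(volume_pct))
    stop("'dose' and 'volume_pct' must have equal length >= 2")
  if (dose[1] != 0)
    stop("DVH curve must start at dose 0")
  if (any(diff(dose) <= 0))
    stop("doses must be strictly increasing")
  if (any(diff(volume_pct) > 1e-9))
    stop("volume_pct must be non-increasing")
  if (abs(volume_pct[1] - 100) > 1e-9)
    stop("volume_pct at dose 0 must be 100")
  if (any(volume_pct < -1e-9))
    stop("volume_pct must be non-negative")
  if (!is.numeric(total_volume) || length(total_volume) != 1L ||
      total_volume <= 0)
    stop("'total_volume' must be a positive scalar (cm^3)")
  structure <- match.arg(structure, dvh_structures())
  structure(
    list(dose = dose, volume_pct = pmax(volume_pct, 0),
         volume_cc = pmax(volume_pct, 0) / 100 * total_volume,
         total_volume = total_volume, structure = structure),
    class = "dvh_curve"
  )
}

#' Target structures carried by a treatment plan
#'
#' The four radiotherapy target volumes for which DVH features are
#' extracted: local and extended clinical/planning target volumes.
#' @return Character vector of structure labels.
#' @export
dvh_structures <- function() {
  c("PTV_local", "CTV_local", "PTV_extend", "CTV_extend")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %d points, %.1f cm^3, dose 0-%.1f Gy\n",
              x$structure, length(x$dose), x$total_volume, max(x$dose)))
  invisible(x)
}

as_pct <- function(curve, x, referent) {
  referent <- match.arg(referent, c("percent", "cc"))
  if (referent == "cc") x / curve$total_volume * 100 else x
}

#' Dose covering a given volume (D_X)
#'
#' Smallest dose `d` such that the volume receiving at least `d` Gy is no
#' larger than `x`, under linear interpolation of the cumulative curve.
#' This is the conventional D_X metric: the minimum dose delivered to the
#' hottest `x` % (or cm^3) of the structure.
#'
#' @param curve A [dvh_curve()].
#' @param x Volume threshold, in % of the structure (`referent = "percent"`)
#'   or cm^3 (`referent = "cc"`).
#' @param referent Unit of `x`.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(curve, x, referent = c("percent", "cc")) {
  stopifnot(inherits(curve, "dvh_curve"))
  referent <- match.arg(referent)
  xp <- as_pct(curve, x, referent)
  if (xp <= 0 || xp > 100 + 1e-9)
    stop("volume threshold must be in (0, total volume]")
  v <- curve$volume_pct
  d <- curve$dose
  if (xp >= v[1]) return(d[1])
  i <- which(v <= xp + 1e-12)[1]
  if (is.na(i))
    stop("curve does not fall to the requested volume; it is truncated")
  # segment (i-1, i) crosses xp; smallest qualifying dose
  v0 <- v[i - 1L]; v1 <- v[i]
  if (v0 <= v1 + 1e-15) return(d[i])
  d[i - 1L] + (v0 - xp) / (v0 - v1) * (d[i] - d[i - 1L])
}

#' Volume receiving a given dose (V_X)
#'
#' Linearly interpolated cumulative volume at dose `x` Gy; 0 beyond the
#' last tabulated dose.
#'
#' @inheritParams dose_at_volume
#' @param x Dose threshold in Gy (non-negative).
#' @param referent Unit of the returned volume.
#' @return Volume in % or cm^3.
#' @export
volume_at_dose <- function(curve, x, referent = c("percent", "cc")) {
  stopifnot(inherits(curve, "dvh_curve"))
  referent <- match.arg(referent)
  if (x < 0) stop("dose must be non-negative")
  v <- if (x > max(curve$dose)) 0
       else stats::approx(curve$dose, curve$volume_pct, xout = x,
                          method = "linear", ties = "ordered")$y
  if (referent == "cc") v / 100 * curve$total_volume else v
}

#' Maximum, minimum and mean dose of a DVH curve
#'
#' `max` is the highest dose received by any positive volume (where the
#' cumulative curve reaches zero); `min` is the dose received by the whole
#' structure (where the curve first drops below 100%); `mean` is the
#' volume-weighted mean dose, integrated from the piecewise-linear
#' cumulative curve.
#'
#' @inheritParams dose_at_volume
#' @return Named numeric vector `c(max =, min =, mean =)` in Gy.
#' @export
summary_doses <- function(curve) {
  stopifnot(inherits(curve, "dvh_curve"))
  d <- curve$dose
  v <- curve$volume_pct
  n <- length(d)
  # max: dose where volume reaches 0 (interpolated); last dose if truncated
  dmax <- if (v[n] > 1e-12) d[n] else {
    i <- which(v <= 1e-12)[1]
    if (i == 1L) d[1] else {
      v0 <- v[i - 1L]; v1 <- v[i]
      if (v0 <= v1 + 1e-15) d[i]
      else d[i - 1L] + v0 / (v0 - v1) * (d[i] - d[i - 1L])
    }
  }
  # min: largest dose still covering 100% of the volume
  below <- which(v < 100 - 1e-9)
  dmin <- if (length(below) == 0L) d[n] else {
    i <- below[1]
    if (i == 1L) d[1] else {
      v0 <- v[i - 1L]; v1 <- v[i]
      # crossing of 100% on the segment (exact when v0 == 100)
      d[i - 1L] + (v0 - 100) / (v0 - v1) * (d[i] - d[i - 1L])
    }
  }
  # mean = (1/100) * integral of V(d) dd  (trapezoid; exact for the
  # piecewise-linear curve); a truncated tail adds a point mass at d[n]
  dmean <- sum((v[-n] + v[-1]) / 2 * diff(d)) / 100
  if (v[n] > 1e-12) dmean <- dmean + d[n] * v[n] / 100
  c(max = dmax, min = dmin, mean = dmean)
}

#' Biologically effective dose (linear-quadratic model)
#'
#' `BED = D * (1 + d / (alpha/beta))` with total dose `D` and dose per
#' fraction `d = D / n`. No time/repopulation correction is applied;
#' treatment duration enters the feature set as its own scalar.
#'
#' @param total_dose Total physical dose in Gy.
#' @param n_fractions Number of fractions.
#' @param alpha_beta Tissue alpha/beta ratio in Gy (default 10, tumor).
#' @return BED in Gy; always `>= total_dose`.
#' @examples
#' compute_bed(60, 30)  # 72 Gy
#' @export
compute_bed <- function(total_dose, n_fractions, alpha_beta = 10) {
  if (any(total_dose <= 0) || any(n_fractions <= 0))
    stop("total dose and fraction number must be positive")
  if (any(alpha_beta <= 0)) stop("alpha/beta must be positive")
  total_dose * (1 + (total_dose / n_fractions) / alpha_beta)
}

#' Rescale a DVH curve to a new prescription dose
#'
#' Multiplies the dose axis by `new_dose / old_dose`, leaving volumes
#' unchanged: the plan shape is assumed to scale uniformly with the
#' prescription. Hence `D_X` scales by the same factor and
#' `V_X(x)` becomes `V(x / s)`. Identity (bit-for-bit) when the doses
#' are equal.
#'
#' @inheritParams dose_at_volume
#' @param old_dose,new_dose Old and new prescription doses in Gy.
#' @return A [dvh_curve()] with the scaled dose axis.
#' @export
rescale_curve <- function(curve, old_dose, new_dose) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (old_dose <= 0 || new_dose <= 0)
    stop("prescription doses must be positive")
  if (new_dose == old_dose) return(curve)
  s <- new_dose / old_dose
  out <- curve
  out$dose <- curve$dose * s
  out
}
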