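#' Isotope-dilution quantification and culture-derived rates
#'
#' Metabolite amounts are quantified by spiking a known amount of
#' unlabeled internal standard into the labeled sample and measuring the
#' heavy fraction of the mixture. Conservation of labeled material on
#' mixing gives
#' \deqn{(n + n_{std})\, x^{mix} = n x + n_{std} x^{std}}
#' which is solved for the unknown amount n. Concentrations in spent
#' medium versus baseline medium (incubated without cells) give net
#' uptake/release rates, normalized by the time-integral of exponentially
#' growing cell counts.
#'
#' @name quantify
NULL

#' Internal standard spike
#'
#' @param metabolite metabolite name.
#' @param n_std amount of unlabeled standard added (fmol).
#' @param x_std heavy fraction of the standard, in `[0, 0.5)`. An
#'   unlabeled standard fits x = 0 exactly in the mixture-model basis
#'   (natural abundance is already part of the unlabeled reference MID).
#' @return object of class `standard_spike`.
#' @export
standard_spike <- function(metabolite, n_std, x_std = 0) {
  if (!is.finite(n_std) || n_std <= 0) stop("invalid-argument: n_std must be > 0")
  if (!is.finite(x_std) || x_std < 0 || x_std >= 0.5) {
    stop("invalid-argument: x_std must be in [0, 0.5)")
  }
  structure(list(metabolite = metabolite, n_std = n_std, x_std = x_std),
            class = "standard_spike")
}

#' Solve the isotope-dilution mass balance for the analyte amount
#'
#' Default variant `"mass_balance"` inverts
#' `x_mix = (n x + n_std x_std) / (n + n_std)`, giving
#' `n = n_std (x_std - x_mix) / (x_mix - x)`. Variant `"as_printed"`
#' reproduces the alternative form with a factor 1/2 on the mixing side,
#' `(n + n_std) x_mix = (n x + n_std x_std) / 2`; it is provided for
#' comparison only and is not the default because it does not conserve
#' labeled amounts on mixing.
#'
#' @param x_mix measured heavy fraction of the spiked mixture.
#' @param x heavy fraction of the analyte in the sample.
#' @param spike a [standard_spike()].
#' @param variant `"mass_balance"` (default) or `"as_printed"`.
#' @param x_mix_sd optional sd of `x_mix`; when given, the sd of n is
#'   propagated by the delta method and returned as attribute `"sd"`.
#' @return estimated amount n (same units as `n_std`), with attribute
#'   `"sd"` when `x_mix_sd` is supplied.
#' @export
isotope_dilution_amount <- function(x_mix, x, spike,
                                    variant = c("mass_balance", "as_printed"),
                                    x_mix_sd = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(spike, "standard_spike"))
  n_std <- spike$n_std
  x_std <- spike$x_std
  if (!all(is.finite(c(x_mix, x)))) stop("invalid-argument: non-finite input")
  if (x == x_std) stop("unidentifiable: analyte and standard have equal heavy fraction")
  lo <- min(x, x_std); hi <- max(x, x_std)
  if (x_mix < lo - 1e-12 || x_mix > hi + 1e-12) {
    stop(sprintf(
      "inconsistent-measurement: x_mix = %.4g outside [%.4g, %.4g] spanned by analyte and standard",
      x_mix, lo, hi))
  }
  if (variant == "mass_balance") {
    if (abs(x_mix - x) < 1e-14) {
      stop("inconsistent-measurement: x_mix equals analyte heavy fraction (infinite amount)")
    }
    n <- n_std * (x_std - x_mix) / (x_mix - x)
    deriv <- n_std * (x - x_std) / (x_mix - x)^2
  } else {
    denom <- x_mix - x / 2
    if (abs(denom) < 1e-14) {
      stop("inconsistent-measurement: degenerate denominator in as_printed variant")
    }
    n <- n_std * (x_std / 2 - x_mix) / denom
    deriv <- n_std * (x - x_std) / 2 / denom^2
  }
  if (!is.null(x_mix_sd)) attr(n, "sd") <- abs(deriv) * x_mix_sd
  n
}

#' Spherical cell volume from mean diameter
#'
#' @param mean_diameter_um mean cell diameter in micrometers.
#' @param cytosol_fraction fraction of the spherical volume treated as
#'   cytosol (default 1: whole-cell volume as proxy).
#' @return volume per cell in femtoliters.
#' @export
cell_volume_fl <- function(mean_diameter_um, cytosol_fraction = 1) {
  if (!is.finite(mean_diameter_um) || mean_diameter_um <= 0) {
    stop("invalid-argument: diameter must be > 0")
  }
  (pi / 6) * mean_diameter_um^3 * cytosol_fraction
}

#' Convert an extract amount to intracellular concentration
#'
#' The total cytosol volume of the extracted cells is estimated from the
#' mean cell diameter (spheres), so
#' `conc = n / (cell_count * v_cell)`.
#'
#' @param n_fmol amount in the extract, femtomoles.
#' @param cell_count number of cells extracted.
#' @param mean_diameter_um mean cell diameter (micrometers).
#' @param cytosol_fraction see [cell_volume_fl()].
#' @return concentration in micromolar.
#' @export
intracellular_concentration <- function(n_fmol, cell_count, mean_diameter_um,
                                        cytosol_fraction = 1) {
  if (!is.finite(cell_count) || cell_count <= 0) {
    stop("invalid-argument: cell_count must be > 0")
  }
  if (n_fmol < 0) stop("invalid-argument: amount must be >= 0")
  v_fl <- cell_volume_fl(mean_diameter_um, cytosol_fraction)
  # fmol / fL = mol / L; scale to uM
  n_fmol / (cell_count * v_fl) * 1e6
}

#' Time-integral of exponentially growing cell counts (cell-hours)
#'
#' With counts n0 at time 0 and n1 after `elapsed` hours and exponential
#' growth in between, the integral of N(t) is `(n1 - n0) / mu` with
#' `mu = log(n1/n0) / elapsed`. Alternatives: the endpoint count times
#' elapsed, or the arithmetic mean count times elapsed.
#'
#' @param n0,n1 cell counts at start and end.
#' @param elapsed duration in hours.
#' @param method `"exponential"` (default), `"endpoint"`, or `"mean"`.
#' @return cell-hours.
#' @export
cell_hours <- function(n0, n1, elapsed,
                       method = c("exponential", "endpoint", "mean")) {
  method <- match.arg(method)
  if (!all(is.finite(c(n0, n1, elapsed))) || n0 <= 0 || n1 <= 0 || elapsed <= 0) {
    stop("invalid-argument: counts and elapsed must be > 0")
  }
  switch(method,
    exponential = {
      mu <- log(n1 / n0) / elapsed
      if (abs(mu) < 1e-12) n0 * elapsed else (n1 - n0) / mu
    },
    endpoint = n1 * elapsed,
    mean = (n0 + n1) / 2 * elapsed
  )
}

#' Net uptake/release rate from medium concentrations
#'
#' Computed by subtracting the concentration in baseline medium
#' (incubated without cells) from the spent-medium concentration.
#' Positive values are release, negative uptake.
#'
#' @param baseline_conc_uM,spent_conc_uM concentrations in micromolar.
#' @param medium_volume_ml culture medium volume, mL.
#' @param cell_hours time-integral of cell counts (see [cell_hours()]).
#' @param conc_sd_uM optional sd of each concentration (length-2 or
#'   scalar); propagated into attribute `"sd"` of the result.
#' @return rate in fmol/cell/h (attribute `"sd"` when sds given).
#' @export
uptake_release_rate <- function(baseline_conc_uM, spent_conc_uM,
                                medium_volume_ml, cell_hours,
                                conc_sd_uM = NULL) {
  if (!is.finite(cell_hours) || cell_hours <= 0) {
    stop("invalid-argument: cell_hours must be > 0")
  }
  # uM * mL = nmol = 1e6 fmol
  rate <- (spent_conc_uM - baseline_conc_uM) * medium_volume_ml * 1e6 / cell_hours
  if (!is.null(conc_sd_uM)) {
    sds <- rep_len(conc_sd_uM, 2L)
    attr(rate, "sd") <- sqrt(sum(sds^2)) * medium_volume_ml * 1e6 / cell_hours
  }
  rate
}

#' Doubling time and growth rate assuming exponential growth
#'
#' @param n0,n1 initial and final cell counts.
#' @param elapsed elapsed time in hours.
#' @return list with `doubling_time` (h), `growth_rate` (1/h) and
#'   `shrinking` flag. Equal counts give an infinite doubling time with a
#'   warning; a declining culture gives a negative doubling time, flagged.
#' @export
doubling_time <- function(n0, n1, elapsed) {
  if (!all(is.finite(c(n0, n1, elapsed))) || n0 <= 0 || n1 <= 0 || elapsed <= 0) {
    stop("invalid-argument: counts and elapsed must be > 0")
  }
  mu <- log(n1 / n0) / elapsed
  if (n1 == n0) {
    warning("counts unchanged: doubling time is infinite")
    return(list(doubling_time = Inf, growth_rate = 0, shrinking = FALSE))
  }
  list(doubling_time = log(2) / mu, growth_rate = mu, shrinking = n1 < n0)
}

#' Fit a growth rate to a count time series
#'
#' Log-linear least squares on counts versus time; robust to
#' multiplicative (lognormal) noise.
#'
#' @param counts positive cell counts.
#' @param times_h times in hours (same length).
#' @return list with `growth_rate` (1/h) and `doubling_time` (h).
#' @export
fit_growth_rate <- function(counts, times_h) {
  if (length(counts) != length(times_h) || length(counts) < 2) {
    stop("invalid-argument: need matched counts and times, length >= 2")
  }
  if (any(counts <= 0)) stop("invalid-argument: counts must be > 0")
  fit <- stats::lm(log(counts) ~ times_h)
  mu <- unname(stats::coef(fit)[2])
  list(growth_rate = mu, doubling_time = log(2) / mu)
}
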