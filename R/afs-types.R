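#' Force curve from a dynamic force-spectroscopy retraction
#'
#' A single retraction trace: tip-substrate separation against cantilever
#' force, plus the acquisition metadata needed to turn a retraction velocity
#' into a loading rate.
#'
#' @param separation Numeric vector of tip-substrate distances (nm).
#' @param force Numeric vector of cantilever forces (pN), same length as
#'   `separation`. Pulling forces are positive.
#' @param retraction_velocity Cantilever retraction velocity (nm/s), > 0.
#' @param k_syst Spring constant of the entire system (pN/nm), > 0. The
#'   loading rate applied to the bond is `retraction_velocity * k_syst`.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(separation, force, retraction_velocity, k_syst) {
  if (!is.numeric(separation) || !is.numeric(force)) {
    stop("`separation` and `force` must be numeric", call. = FALSE)
  }
  if (length(separation) != length(force) || length(separation) < 2L) {
    stop("`separation` and `force` must have equal length >= 2", call. = FALSE)
  }
  check_positive(retraction_velocity, "retraction_velocity")
  check_positive(k_syst, "k_syst")
  structure(
    list(separation = as.numeric(separation), force = as.numeric(force),
         retraction_velocity = retraction_velocity, k_syst = k_syst),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "<force_curve> %d points, v = %g nm/s, k_syst = %g pN/nm (r = %g pN/s)\n",
    length(x$force), x$retraction_velocity, x$k_syst,
    x$retraction_velocity * x$k_syst))
  invisible(x)
}

#' Bell-Evans kinetic parameters
#'
#' Dissociation rate and barrier width governing the loading-rate dependence
#' of the most probable unbinding force.
#'
#' @param k_off Dissociation rate at zero force (1/s), > 0.
#' @param x_beta Width of the energy barrier along the pulling direction
#'   (nm), > 0.
#' @param temperature Absolute temperature (K).
#' @param se_k_off,se_x_beta Optional standard errors.
#' @return An object of class `bell_evans_params`.
#' @export
bell_evans_params <- function(k_off, x_beta, temperature = 298,
                              se_k_off = NA_real_, se_x_beta = NA_real_) {
  check_positive(k_off, "k_off")
  check_positive(x_beta, "x_beta")
  check_positive(temperature, "temperature")
  structure(
    list(k_off = k_off, x_beta = x_beta, temperature = temperature,
         se_k_off = se_k_off, se_x_beta = se_x_beta),
    class = "bell_evans_params"
  )
}

#' @export
print.bell_evans_params <- function(x, ...) {
  fmt <- function(v, se) {
    if (is.finite(se)) sprintf("%.3g +/- %.2g", v, se) else sprintf("%.3g", v)
  }
  cat("<bell_evans_params>\n")
  cat("  k_off  :", fmt(x$k_off, x$se_k_off), "1/s\n")
  cat("  x_beta :", fmt(x$x_beta, x$se_x_beta), "nm\n")
  cat("  T      :", x$temperature, "K\n")
  invisible(x)
}

#' Single unbinding event extracted from a force curve
#'
#' @param rupture_force Unbinding force from the jump extension (pN), > 0.
#' @param loading_rate Loading rate of the acquisition (pN/s), > 0.
#' @param is_specific Logical: did the pre-jump rise carry the nonlinear
#'   polymer-linker stretching signature at a separation consistent with the
#'   linker contour length?
#' @param rupture_separation Tip-substrate separation at the jump (nm).
#' @return An object of class `unbinding_event`.
#' @export
unbinding_event <- function(rupture_force, loading_rate, is_specific,
                            rupture_separation) {
  check_positive(rupture_force, "rupture_force")
  check_positive(loading_rate, "loading_rate")
  stopifnot(is.logical(is_specific), length(is_specific) == 1L)
  structure(
    list(rupture_force = rupture_force, loading_rate = loading_rate,
         is_specific = is_specific, rupture_separation = rupture_separation),
    class = "unbinding_event"
  )
}

#' Histogram of unbinding forces
#'
#' @param bin_edges Strictly increasing bin edges (pN).
#' @param counts Non-negative integer counts, one per bin.
#' @return An object of class `force_histogram` with fields `bin_edges`,
#'   `counts` and `n_total` (= `sum(counts)`).
#' @export
force_histogram <- function(bin_edges, counts) {
  if (any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  }
  if (length(bin_edges) != length(counts) + 1L) {
    stop("length(bin_edges) must equal length(counts) + 1", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  structure(
    list(bin_edges = as.numeric(bin_edges), counts = as.integer(counts),
         n_total = as.integer(sum(counts))),
    class = "force_histogram"
  )
}

#' Extended freely-jointed-chain linker description
#'
#' Parameters of the polymer tether (e.g. a 3 kDa PEG linker) whose nonlinear
#' stretching signature marks specific unbinding events.
#'
#' @param contour_length Contour length (nm); default 21 nm for 3 kDa PEG.
#' @param kuhn_length Kuhn segment length (nm); default 0.7 nm.
#' @param temperature Absolute temperature (K).
#' @return An object of class `linker_params`.
#' @export
linker_params <- function(contour_length = 21, kuhn_length = 0.7,
                          temperature = 298) {
  check_positive(contour_length, "contour_length")
  check_positive(kuhn_length, "kuhn_length")
  check_positive(temperature, "temperature")
  structure(
    list(contour_length = contour_length, kuhn_length = kuhn_length,
         temperature = temperature),
    class = "linker_params"
  )
}

#' Freely-jointed-chain extension at a given force
#'
#' Langevin-function extension of a freely jointed chain pulled with force
#' `force`: `x = L_c (coth(u) - 1/u)` with `u = F b / k_B T`.
#'
#' @param force Force (pN), vectorised; non-positive forces give extension 0.
#' @param linker A [linker_params()] object.
#' @return Extension (nm).
#' @export
fjc_extension <- function(force, linker = linker_params()) {
  kbt <- thermal_energy(linker$temperature)
  u <- force * linker$kuhn_length / kbt
  x <- ifelse(u > 0, linker$contour_length * (1 / tanh(u) - 1 / u), 0)
  # 1/tanh(u) - 1/u -> u/3 as u -> 0; guard numeric noise at tiny u
  small <- u > 0 & u < 1e-6
  x[small] <- linker$contour_length * u[small] / 3
  x
}

#' Freely-jointed-chain force at a given extension
#'
#' Numerical inverse of [fjc_extension()]: the entropic restoring force of the
#' linker at extension `extension`. Diverges as the extension approaches the
#' contour length; extensions >= 99.9% of the contour length return `Inf`.
#'
#' @param extension Extension (nm), vectorised.
#' @param linker A [linker_params()] object.
#' @return Force (pN).
#' @export
fjc_force <- function(extension, linker = linker_params()) {
  kbt <- thermal_energy(linker$temperature)
  f_grid <- exp(seq(log(1e-4), log(5e4), length.out = 2048))
  x_grid <- fjc_extension(f_grid, linker)
  out <- numeric(length(extension))
  out[extension <= 0] <- 0
  hi <- extension >= 0.999 * linker$contour_length
  out[hi] <- Inf
  mid <- !hi & extension > 0
  if (any(mid)) {
    out[mid] <- stats::approx(x_grid, f_grid, xout = extension[mid],
                              rule = 2)$y
  }
  out
}
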