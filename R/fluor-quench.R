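#' Steady-state emission spectrum
#'
#' @param wavelengths Strictly increasing wavelengths (nm).
#' @param intensities Non-negative signal/reference corrected intensities,
#'   same length.
#' @param absorbance_ex Optical density at the excitation wavelength.
#' @param absorbance_em Optical density at the monitored emission wavelength.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities,
                              absorbance_ex = NA_real_,
                              absorbance_em = NA_real_) {
  if (length(wavelengths) != length(intensities)) {
    stop("`wavelengths` and `intensities` must have equal length",
         call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  }
  if (any(intensities < 0)) stop("`intensities` must be >= 0", call. = FALSE)
  structure(
    list(wavelengths = as.numeric(wavelengths),
         intensities = as.numeric(intensities),
         absorbance_ex = absorbance_ex, absorbance_em = absorbance_em),
    class = "emission_spectrum"
  )
}

#' Inner-filter correction of an emission spectrum
#'
#' Optically dense samples reabsorb excitation and emission light; the
#' standard half-path correction multiplies intensities by
#' `10^((A_ex + A_em)/2)`. Applied only when the excitation-wavelength
#' absorbance exceeds the threshold (default 0.15 OD); below it the spectrum
#' is returned unchanged.
#'
#' @param spectrum An [emission_spectrum()] with absorbances populated.
#' @param threshold Absorbance above which the correction applies (OD).
#' @return The corrected spectrum; the multiplicative factor applied is
#'   stored in attribute `correction_factor` (1 when not applied).
#' @export
inner_filter_correct <- function(spectrum, threshold = 0.15) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  a_ex <- spectrum$absorbance_ex
  if (is.na(a_ex)) {
    stop("excitation absorbance missing; cannot assess inner-filter need",
         call. = FALSE)
  }
  factor <- 1
  if (a_ex > threshold) {
    a_em <- spectrum$absorbance_em
    if (is.na(a_em)) {
      stop("emission absorbance missing but A_ex exceeds the inner-filter ",
           "threshold", call. = FALSE)
    }
    factor <- 10^((a_ex + a_em) / 2)
    spectrum$intensities <- spectrum$intensities * factor
  }
  attr(spectrum, "correction_factor") <- factor
  spectrum
}

#' Subtract a buffer blank (e.g. Raman band) from a spectrum
#'
#' Pointwise subtraction on an identical wavelength grid, clipped at zero;
#' channels where the blank exceeded the signal are flagged.
#'
#' @param spectrum,buffer_spectrum [emission_spectrum()] objects on the same
#'   wavelength grid.
#' @return The blank-subtracted spectrum, with attribute `clipped` (logical:
#'   any channel clipped at zero).
#' @export
subtract_blank <- function(spectrum, buffer_spectrum) {
  stopifnot(inherits(spectrum, "emission_spectrum"),
            inherits(buffer_spectrum, "emission_spectrum"))
  if (!isTRUE(all.equal(spectrum$wavelengths, buffer_spectrum$wavelengths))) {
    stop("wavelength grids differ between spectrum and blank", call. = FALSE)
  }
  diffs <- spectrum$intensities - buffer_spectrum$intensities
  clipped <- any(diffs < 0)
  spectrum$intensities <- pmax(diffs, 0)
  attr(spectrum, "clipped") <- clipped
  spectrum
}

# peak wavelength by quadratic interpolation through the maximum and its
# neighbours; interior maximum required
.peak_wavelength <- function(spectrum) {
  y <- spectrum$intensities
  x <- spectrum$wavelengths
  if (diff(range(y)) <= 0) {
    stop("flat spectrum: emission peak undefined", call. = FALSE)
  }
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(x[i])
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (denom == 0) return(x[i])
  delta <- 0.5 * (y0 - y2) / denom
  x[i] + delta * (x[i + 1L] - x[i])
}

#' Maximum pairwise shift of the emission peak across spectra
#'
#' Locates each peak by quadratic interpolation around the maximum and
#' reports the largest pairwise difference in peak wavelength. Used to check
#' that a quencher leaves the fluorophore's environment unperturbed (no
#' significant shift).
#'
#' @param spectra List of at least two [emission_spectrum()] objects.
#' @return Maximum peak shift (nm).
#' @export
peak_shift <- function(spectra) {
  if (length(spectra) < 2L) stop("need at least 2 spectra", call. = FALSE)
  peaks <- vapply(spectra, .peak_wavelength, numeric(1))
  max(peaks) - min(peaks)
}

#' Stern-Volmer fit of a quenching titration
#'
#' Linear Stern-Volmer analysis F0/F = 1 + K_SV [Q]. F0 is the measured
#' zero-quencher intensity (required in the input), not a fitted intercept;
#' the fitted intercept is retained as a quality check and should lie within
#' 1 +/- 0.05. Weighted by propagated intensity-ratio variances when
#' replicate standard deviations are supplied.
#'
#' @param titration Data frame with columns `quencher_conc` (M),
#'   `intensity` (corrected counts at the monitored wavelength) and
#'   optionally `sd`. Must contain a zero-concentration point and at least 3
#'   concentrations.
#' @return A list of class `stern_volmer_fit` with `K_SV`, `se_K_SV`,
#'   `intercept`, `r_squared`, `k_q` (NA until a lifetime is supplied to
#'   [bimolecular_quenching_constant()]), `anti_quenching` flag and the
#'   underlying `lm` fit.
#' @export
stern_volmer_fit <- function(titration) {
  stopifnot(is.data.frame(titration),
            all(c("quencher_conc", "intensity") %in% names(titration)))
  if (any(titration$quencher_conc < 0)) {
    stop("quencher concentrations must be >= 0", call. = FALSE)
  }
  if (any(titration$intensity <= 0)) {
    stop("intensities must be > 0", call. = FALSE)
  }
  zero <- titration$quencher_conc == 0
  if (!any(zero)) {
    stop("titration must include a zero-quencher point (defines F0)",
         call. = FALSE)
  }
  if (length(unique(titration$quencher_conc)) < 3L) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  f0 <- mean(titration$intensity[zero])
  q <- titration$quencher_conc
  ratio <- f0 / titration$intensity

  w <- NULL
  if ("sd" %in% names(titration) && all(is.finite(titration$sd))) {
    sd0 <- mean(titration$sd[zero])
    var_ratio <- ratio^2 * ((sd0 / f0)^2 + (titration$sd /
                                              titration$intensity)^2)
    if (all(var_ratio > 0)) w <- 1 / var_ratio
  }
  fit <- stats::lm(ratio ~ q, weights = w)
  cf <- stats::coef(fit)
  slope <- unname(cf[2L])
  # summary/vcov warn on an exactly collinear (noise-free) fit; harmless here
  sm <- suppressWarnings(summary(fit))
  structure(
    list(K_SV = slope,
         se_K_SV = unname(suppressWarnings(sqrt(stats::vcov(fit)[2L, 2L]))),
         intercept = unname(cf[1L]),
         r_squared = sm$r.squared,
         k_q = NA_real_,
         anti_quenching = slope < 0,
         fit = fit),
    class = "stern_volmer_fit"
  )
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat(sprintf(
    "<stern_volmer_fit> K_SV = %.4g +/- %.2g 1/M, intercept = %.3f, R2 = %.4f\n",
    x$K_SV, x$se_K_SV, x$intercept, x$r_squared))
  if (x$anti_quenching) cat("  warning: negative slope (anti-quenching)\n")
  invisible(x)
}

#' Bimolecular quenching constant
#'
#' k_q = K_SV / tau_q, the collision-rate constant implied by a Stern-Volmer
#' constant if quenching were purely dynamic. Values orders of magnitude
#' above the diffusion limit (~1e10 1/(M s)) rule dynamic quenching out.
#'
#' @param K_SV Stern-Volmer constant (1/M), or a [stern_volmer_fit()].
#' @param tau_q Unquenched fluorophore lifetime (s), > 0.
#' @return k_q (1/(M s)); when given a fit object, the fit is returned with
#'   its `k_q` field populated.
#' @export
bimolecular_quenching_constant <- function(K_SV, tau_q) {
  check_positive(tau_q, "tau_q")
  if (inherits(K_SV, "stern_volmer_fit")) {
    K_SV$k_q <- K_SV$K_SV / tau_q
    return(K_SV)
  }
  K_SV / tau_q
}

#' Classify quenching as static, dynamic or ambiguous
#'
#' Static (ground-state complex) quenching leaves the fluorescence lifetime
#' unchanged while the intensity drops, and implies an apparent k_q far above
#' the diffusion-controlled limit. Classification rule: static iff
#' `k_q >= 100 * diffusion_limit` and the lifetime deviation is below the
#' threshold; dynamic iff `k_q <= diffusion_limit` and the lifetime deviation
#' is at or above the threshold (lifetimes track F0/F); ambiguous otherwise.
#'
#' @param k_q Bimolecular quenching constant (1/(M s)).
#' @param lifetime_deviation_pct Percent deviation of the lifetime in the
#'   presence of the quencher from the unquenched lifetime.
#' @param diffusion_limit Diffusion-controlled rate (1/(M s)), default 1e10.
#' @param deviation_threshold Percent lifetime deviation separating
#'   "unchanged" from "tracking" (default 4).
#' @return One of `"static"`, `"dynamic"`, `"ambiguous"`.
#' @export
classify_quenching <- function(k_q, lifetime_deviation_pct,
                               diffusion_limit = 1e10,
                               deviation_threshold = 4) {
  stopifnot(k_q >= 0, lifetime_deviation_pct >= 0)
  if (k_q >= 100 * diffusion_limit &&
      lifetime_deviation_pct < deviation_threshold) {
    "static"
  } else if (k_q <= diffusion_limit &&
             lifetime_deviation_pct >= deviation_threshold) {
    "dynamic"
  } else {
    "ambiguous"
  }
}

#' Titration design over the informative Stern-Volmer range
#'
#' Concentration grid from `0.05 / K_SV` to `2 / K_SV` (plus the zero point),
#' spanning F0/F from 1.05 to 3.
#'
#' @param K_SV Anticipated Stern-Volmer constant (1/M).
#' @param n Number of nonzero concentrations.
#' @return Numeric vector of concentrations (M), starting at 0.
#' @export
design_titration <- function(K_SV, n = 10) {
  check_positive(K_SV, "K_SV")
  c(0, seq(0.05 / K_SV, 2 / K_SV, length.out = n))
}
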