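#' Most probable unbinding force under the Bell-Evans model
#'
#' The Bell-Evans model predicts that the most probable rupture force of a
#' single bond loaded at constant rate r grows linearly with ln(r):
#' \deqn{F^* = \frac{k_B T}{x_\beta}\,
#'   \ln\!\frac{r\, x_\beta}{k_{off}\, k_B T}}
#'
#' @param loading_rate Loading rate r (pN/s), > 0; vectorised.
#' @param params A [bell_evans_params()] object.
#' @return Most probable unbinding force (pN). May be negative for very low
#'   loading rates, where no force peak exists; physical interpretation is
#'   left to the caller.
#' @examples
#' p <- bell_evans_params(k_off = 0.44, x_beta = 0.73)
#' bell_evans_force(4600, p)  # ~42 pN at 4.6 nN/s
#' @export
bell_evans_force <- function(loading_rate, params) {
  stopifnot(inherits(params, "bell_evans_params"))
  if (!is.numeric(loading_rate) || any(!is.finite(loading_rate)) ||
      any(loading_rate <= 0)) {
    stop("`loading_rate` must be positive and finite (pN/s)", call. = FALSE)
  }
  kbt <- thermal_energy(params$temperature)
  (kbt / params$x_beta) *
    log(loading_rate * params$x_beta / (params$k_off * kbt))
}

#' Analytic distribution of first-rupture forces
#'
#' Probability density of the rupture force for a single bond whose force-
#' dependent off-rate follows Bell kinetics and which is loaded at a constant
#' rate. With `b = x_beta / (k_B T)`:
#' \deqn{p(F) = \frac{k_{off}}{r} e^{bF}
#'   \exp\!\left[-\frac{k_{off}}{r b}\left(e^{bF}-1\right)\right]}
#' The density integrates to one over F in [0, Inf) and its mode, when
#' positive, equals [bell_evans_force()].
#'
#' @param force Rupture force (pN), >= 0; vectorised.
#' @param loading_rate Loading rate (pN/s), > 0.
#' @param params A [bell_evans_params()] object.
#' @return Probability density (1/pN).
#' @export
rupture_force_pdf <- function(force, loading_rate, params) {
  stopifnot(inherits(params, "bell_evans_params"))
  check_positive(loading_rate, "loading_rate")
  if (any(force < 0)) stop("`force` must be >= 0", call. = FALSE)
  kbt <- thermal_energy(params$temperature)
  b <- params$x_beta / kbt
  # evaluated on the log scale so the survival factor tames the exp overflow
  logp <- log(params$k_off / loading_rate) + b * force -
    (params$k_off / (loading_rate * b)) * expm1(b * force)
  exp(logp)
}

#' Sample rupture forces from the Bell-kinetics distribution
#'
#' Exact inverse-transform sampling of [rupture_force_pdf()]: the survival
#' function S(F) = exp(-(k_off/(r b)) (exp(bF) - 1)) inverts in closed form.
#'
#' @param loading_rate Loading rate (pN/s), > 0.
#' @param params A [bell_evans_params()] object.
#' @param n Number of samples, >= 1.
#' @param seed Integer seed; sampling is reproducible for a fixed seed.
#' @return Numeric vector of n i.i.d. rupture forces (pN).
#' @export
sample_rupture_forces <- function(loading_rate, params, n, seed) {
  stopifnot(inherits(params, "bell_evans_params"))
  check_positive(loading_rate, "loading_rate")
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  kbt <- thermal_energy(params$temperature)
  b <- params$x_beta / kbt
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u <- stats::runif(n)
  log1p(-(loading_rate * b / params$k_off) * log(u)) / b
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Detect and classify the unbinding event in a retraction curve
#'
#' Locates the largest force drop along the retraction, then decides whether
#' the event is a specific unbinding: the pre-jump force rise must be better
#' explained (lower residual sum of squares) by the nonlinear freely-jointed-
#' chain stretching of the tether than by a straight line, and the rupture
#' separation must fall inside a window set by the linker contour length
#' (default 0.25 to 1.05 contour lengths), which excludes nonspecific
#' adhesion jumping off at near-zero separation.
#'
#' @param curve A [force_curve()].
#' @param jump_threshold Minimum force drop between consecutive samples that
#'   counts as a rupture (pN).
#' @param linker A [linker_params()] describing the tether.
#' @param separation_window Length-2 multiplier of the contour length giving
#'   the admissible rupture-separation window.
#' @return An [unbinding_event()] or `NULL` when no jump exceeds the
#'   threshold.
#' @export
detect_unbinding_event <- function(curve, jump_threshold = 15,
                                   linker = linker_params(),
                                   separation_window = c(0.25, 1.05)) {
  stopifnot(inherits(curve, "force_curve"))
  f <- curve$force
  s <- curve$separation
  drops <- f[-length(f)] - f[-1L]
  j <- which.max(drops)
  if (length(j) == 0L || drops[j] < jump_threshold) return(NULL)

  rupture_force <- drops[j]          # jump extension
  rupture_sep <- s[j]
  loading_rate <- curve$retraction_velocity * curve$k_syst

  # pre-jump rise: from the last point at <= 10% of the rupture force up to j
  start <- which(f[seq_len(j)] <= 0.1 * f[j])
  start <- if (length(start)) max(start) else 1L
  idx <- start:j
  is_specific <- FALSE
  if (length(idx) >= 5L) {
    sseg <- s[idx]
    fseg <- f[idx]
    rss_lin <- sum(stats::lm.fit(cbind(1, sseg), fseg)$residuals^2)
    rss_fjc <- .fjc_rss(sseg, fseg, linker)
    window <- separation_window * linker$contour_length
    is_specific <- is.finite(rss_fjc) && rss_fjc < rss_lin &&
      rupture_sep >= window[1] && rupture_sep <= window[2]
  }
  unbinding_event(rupture_force = rupture_force, loading_rate = loading_rate,
                  is_specific = is_specific,
                  rupture_separation = rupture_sep)
}

# best residual sum of squares of an FJC force-extension fit with free
# contour length (0.3-2x the nominal value)
.fjc_rss <- function(sseg, fseg, linker) {
  obj <- function(lc) {
    lk <- linker_params(lc, linker$kuhn_length, linker$temperature)
    pred <- fjc_force(sseg, lk)
    pred[!is.finite(pred)] <- 1e6
    sum((fseg - pred)^2)
  }
  opt <- stats::optimize(obj, interval = linker$contour_length * c(0.3, 2))
  opt$objective
}

#' Cast specific unbinding forces into a histogram
#'
#' Only events flagged `is_specific` are counted; the event count is
#' conserved (`sum(counts) == n_total` = number of specific events).
#'
#' @param events List of [unbinding_event()] objects, at least one specific.
#' @param bin_width Histogram bin width (pN), default 10.
#' @return A [force_histogram()].
#' @export
build_force_histogram <- function(events, bin_width = 10) {
  if (length(events) == 0L) stop("no events supplied", call. = FALSE)
  forces <- vapply(events, function(e) {
    if (isTRUE(e$is_specific)) e$rupture_force else NA_real_
  }, numeric(1))
  forces <- forces[!is.na(forces)]
  if (length(forces) == 0L) {
    stop("no specific events to histogram", call. = FALSE)
  }
  lo <- floor(min(forces) / bin_width) * bin_width
  hi <- ceiling(max(forces) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (max(forces) >= edges[length(edges)]) {
    edges <- c(edges, edges[length(edges)] + bin_width)
  }
  counts <- graphics::hist(forces, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  force_histogram(edges, counts)
}

#' Fit a single Gaussian to the main peak of a force histogram
#'
#' Nonlinear least-squares fit of `A exp(-(F - F*)^2 / (2 sigma^2))` to the
#' bin centres and counts; the fitted mean is reported as the most probable
#' unbinding force. The start point is the largest-amplitude bin, so
#' secondary peaks are ignored.
#'
#' @param hist A [force_histogram()] with at least 4 nonzero bins.
#' @return A list of class `gaussian_peak_fit` with `f_star`, `sigma`,
#'   `amplitude` and `fit_ok`.
#' @export
fit_gaussian_peak <- function(hist) {
  stopifnot(inherits(hist, "force_histogram"))
  centers <- (hist$bin_edges[-1L] + hist$bin_edges[-length(hist$bin_edges)]) / 2
  counts <- hist$counts
  if (sum(counts > 0) < 4L) {
    stop("need at least 4 nonzero bins for a Gaussian peak fit",
         call. = FALSE)
  }
  i0 <- which.max(counts)
  start <- list(
    A = max(counts),
    mu = centers[i0],
    sigma = max(diff(hist$bin_edges)[1], stats::sd(rep(centers, counts)))
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ A * exp(-(centers - mu)^2 / (2 * sigma^2)),
      start = start,
      lower = c(A = 0, mu = min(centers), sigma = 1e-3),
      upper = c(A = Inf, mu = max(centers), sigma = diff(range(centers)) + 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(f_star = NA_real_, sigma = NA_real_,
                          amplitude = NA_real_, fit_ok = FALSE,
                          message = conditionMessage(fit)),
                     class = "gaussian_peak_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(f_star = unname(cf["mu"]), sigma = unname(abs(cf["sigma"])),
                 amplitude = unname(cf["A"]), fit_ok = TRUE,
                 message = NULL),
            class = "gaussian_peak_fit")
}

#' @export
print.gaussian_peak_fit <- function(x, ...) {
  cat(sprintf("<gaussian_peak_fit> F* = %.3g pN, sigma = %.3g pN (ok: %s)\n",
              x$f_star, x$sigma, x$fit_ok))
  invisible(x)
}

#' Fit the Bell-Evans model to most probable forces across loading rates
#'
#' Weighted linear regression of F* on ln(r). The slope equals
#' `k_B T / x_beta` and the intercept `(k_B T / x_beta) ln(x_beta /
#' (k_off k_B T))`, from which the barrier width and the zero-force
#' dissociation rate are recovered. Standard errors are propagated from the
#' regression covariance by the delta method; the confidence interval for
#' k_off is formed on the log scale.
#'
#' @param points Data frame with columns `loading_rate` (pN/s), `f_star`
#'   (pN) and optionally `se` (pN). At least 3 distinct loading rates.
#' @param temperature Absolute temperature (K).
#' @param conf_level Confidence level for the reported k_off interval.
#' @return A [bell_evans_params()] object with standard errors, plus
#'   attributes `ci_k_off` (confidence interval) and `fit` (the `lm`).
#' @export
fit_bell_evans <- function(points, temperature = 298, conf_level = 0.95) {
  stopifnot(is.data.frame(points),
            all(c("loading_rate", "f_star") %in% names(points)))
  if (length(unique(points$loading_rate)) < 3L) {
    stop("need at least 3 distinct loading rates", call. = FALSE)
  }
  if (any(points$loading_rate <= 0)) {
    stop("loading rates must be positive", call. = FALSE)
  }
  kbt <- thermal_energy(temperature)
  lr <- log(points$loading_rate)
  w <- if ("se" %in% names(points) && all(is.finite(points$se)) &&
           all(points$se > 0)) 1 / points$se^2 else NULL
  fit <- stats::lm(points$f_star ~ lr, weights = w)
  cf <- stats::coef(fit)
  slope <- unname(cf[2L])
  intercept <- unname(cf[1L])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-positive slope of F* vs ln(r): no single-barrier Bell-Evans ",
         "interpretation", call. = FALSE)
  }
  x_beta <- kbt / slope
  # intercept = slope * ln(x_beta / (k_off kbt)) => k_off = exp(-c/s) / slope
  k_off <- exp(-intercept / slope) / slope

  # vcov warns on an exactly collinear (noise-free) fit; harmless here
  V <- suppressWarnings(stats::vcov(fit))  # order: (Intercept), lr
  # delta method; x_beta = kbt/s, log k_off = -c/s - log s
  d_xb <- c(0, -kbt / slope^2)
  se_x_beta <- sqrt(drop(t(d_xb) %*% V %*% d_xb))
  d_logk <- c(-1 / slope, intercept / slope^2 - 1 / slope)
  se_logk <- sqrt(drop(t(d_logk) %*% V %*% d_logk))
  se_k_off <- k_off * se_logk
  # t quantile: the residual variance behind vcov is estimated on few points
  z <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  ci_k_off <- k_off * exp(c(-1, 1) * z * se_logk)

  out <- bell_evans_params(k_off = k_off, x_beta = x_beta,
                           temperature = temperature,
                           se_k_off = se_k_off, se_x_beta = se_x_beta)
  attr(out, "ci_k_off") <- ci_k_off
  attr(out, "fit") <- fit
  out
}

#' Affinity constant and complex lifetime from the dissociation rate
#'
#' `K_A = k_on / k_off` and `tau = 1 / k_off`. The association rate is not
#' derivable from force spectroscopy alone and is supplied by the user.
#'
#' @param k_on Association rate (1/(M s)), > 0.
#' @param params A [bell_evans_params()] object.
#' @return A list of class `kinetics_summary` with `k_on`, `k_off`, `K_A`
#'   (1/M) and `lifetime_tau` (s).
#' @export
affinity_constant <- function(k_on, params) {
  stopifnot(inherits(params, "bell_evans_params"))
  check_positive(k_on, "k_on")
  structure(
    list(k_on = k_on, k_off = params$k_off, K_A = k_on / params$k_off,
         lifetime_tau = 1 / params$k_off),
    class = "kinetics_summary"
  )
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf("<kinetics_summary> K_A = %.3g 1/M (k_on = %.3g, k_off = %.3g),",
              x$K_A, x$k_on, x$k_off),
      sprintf("tau = %.3g s\n", x$lifetime_tau))
  invisible(x)
}

#' Specific-event fractions with and without blocking
#'
#' Fraction of events flagged specific over the total, for a free and a
#' receptor-blocked acquisition; a marked reduction upon blocking supports
#' the specificity of the interaction.
#'
#' @param events_free,events_blocked Nonempty lists of [unbinding_event()].
#' @return Named numeric vector `c(fraction_free =, fraction_blocked =)`.
#' @export
blocking_comparison <- function(events_free, events_blocked) {
  frac <- function(events, lab) {
    if (length(events) == 0L) {
      stop(sprintf("empty event list (%s)", lab), call. = FALSE)
    }
    mean(vapply(events, function(e) isTRUE(e$is_specific), logical(1)))
  }
  c(fraction_free = frac(events_free, "free"),
    fraction_blocked = frac(events_blocked, "blocked"))
}
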