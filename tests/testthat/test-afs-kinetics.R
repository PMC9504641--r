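test_that("most probable force follows the logarithmic loading-rate law", {
  p <- bell_evans_params(k_off = 0.44, x_beta = 0.73, temperature = 298)
  kbt <- thermal_energy(298)

  # at r = k_off kbt / x_beta the log argument is 1 and the force vanishes
  r0 <- p$k_off * kbt / p$x_beta
  expect_equal(bell_evans_force(r0, p), 0, tolerance = 1e-12)

  # frozen from independent arithmetic: (kbt/xb) ln(r xb / (k_off kbt))
  expect_equal(bell_evans_force(4600, p), 42.41635, tolerance = 1e-5)

  # doubling the rate adds exactly (kbt/xb) ln 2
  expect_equal(bell_evans_force(9200, p) - bell_evans_force(4600, p),
               (kbt / p$x_beta) * log(2), tolerance = 1e-12)

  expect_error(bell_evans_force(-1, p), "positive")
  expect_error(bell_evans_params(k_off = -0.1, x_beta = 0.7), "positive")
})

test_that("rupture-force density normalises, peaks at the Bell-Evans force and
          starts at k_off/r", {
  p <- bell_evans_params(0.44, 0.73)
  for (r in c(500, 4600, 42000)) {
    q <- stats::integrate(function(f) rupture_force_pdf(f, r, p), 0, Inf,
                          rel.tol = 1e-9)
    expect_lt(abs(q$value - 1), 1e-6)

    grid <- seq(0, 150, by = 0.001)
    mode_grid <- grid[which.max(rupture_force_pdf(grid, r, p))]
    expect_equal(mode_grid, bell_evans_force(r, p), tolerance = 0.1)

    expect_equal(rupture_force_pdf(0, r, p), p$k_off / r, tolerance = 1e-12)
  }
  expect_error(rupture_force_pdf(-5, 4600, p), ">= 0")
})

test_that("rupture-force sampling is deterministic and matches the analytic law", {
  p <- bell_evans_params(0.44, 0.73)
  x1 <- sample_rupture_forces(4600, p, 1e4, seed = 42)
  x2 <- sample_rupture_forces(4600, p, 1e4, seed = 42)
  expect_identical(x1, x2)

  # analytic CDF from the closed-form survival function
  kbt <- thermal_energy(298)
  b <- p$x_beta / kbt
  cdf <- function(q) 1 - exp(-(p$k_off / (4600 * b)) * expm1(b * q))
  ks <- suppressWarnings(stats::ks.test(x1, cdf))
  expect_gt(ks$p.value, 0.01)

  # histogram peak of a large sample sits at the analytic mode
  x <- sample_rupture_forces(4600, p, 1e5, seed = 7)
  h <- graphics::hist(x, breaks = seq(0, ceiling(max(x) / 2) * 2, by = 2),
                      plot = FALSE)
  peak <- h$mids[which.max(h$counts)]
  expect_lt(abs(peak - bell_evans_force(4600, p)), 4)  # two bin widths
})

test_that("event detection recovers rupture forces and separates specific from
          nonspecific curves", {
  cfg <- synth_config(force_noise_sd = 1e-9, nonspecific_fraction = 0)
  fc <- gen_force_curves(cfg, n_curves = 10, seed = 5)
  for (i in seq_along(fc$curves)) {
    ev <- detect_unbinding_event(fc$curves[[i]], jump_threshold = 5)
    expect_false(is.null(ev))
    expect_true(ev$is_specific)
    expect_lt(abs(ev$rupture_force - fc$truth$rupture_force[i]), 1)
    expect_equal(ev$loading_rate,
                 fc$curves[[i]]$retraction_velocity * fc$curves[[i]]$k_syst)
  }

  # flat noise, no rupture
  set.seed(1)
  flat <- force_curve(seq(0, 25, by = 0.05),
                      rnorm(501, 0, 2), retraction_velocity = 460,
                      k_syst = 10)
  expect_null(detect_unbinding_event(flat, jump_threshold = 15))

  # linear adhesion jumping at near-zero separation is nonspecific
  cfg_ns <- synth_config(nonspecific_fraction = 1)
  fcn <- gen_force_curves(cfg_ns, n_curves = 8, seed = 9)
  for (cu in fcn$curves) {
    ev <- detect_unbinding_event(cu)
    expect_false(is.null(ev))
    expect_false(ev$is_specific)
  }
})

test_that("force histograms bin specific events only and conserve counts", {
  ev <- lapply(rep(40, 10), make_event)
  h <- build_force_histogram(ev, bin_width = 10)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(max(h$counts), 10L)

  ev2 <- lapply(c(20, 45, 48, 90), make_event)
  h2 <- build_force_histogram(ev2, bin_width = 10)
  expect_equal(h2$bin_edges[1], 20)
  centers <- (h2$bin_edges[-1] + h2$bin_edges[-length(h2$bin_edges)]) / 2
  expect_equal(h2$counts[centers == 25], 1L)
  expect_equal(h2$counts[centers == 45], 2L)
  expect_equal(h2$counts[centers == 95], 1L)
  expect_equal(h2$n_total, 4L)

  # nonspecific events are excluded but present events are conserved
  mixed <- c(ev2, list(make_event(60, specific = FALSE)))
  h3 <- build_force_histogram(mixed)
  expect_equal(h3$n_total, 4L)
  expect_equal(sum(h3$counts), h3$n_total)

  expect_error(build_force_histogram(list()), "no events")
  expect_error(
    build_force_histogram(list(make_event(40, specific = FALSE))),
    "no specific")
})

test_that("Gaussian peak fitting finds the most probable force", {
  # symmetric synthetic histogram centred at 50 pN
  edges <- seq(0, 100, by = 10)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- round(100 * exp(-(centers - 50)^2 / (2 * 15^2)))
  g <- fit_gaussian_peak(force_histogram(edges, counts))
  expect_true(g$fit_ok)
  expect_lt(abs(g$f_star - 50), 10)

  # histogram of 1e5 Bell-kinetics samples: peak within 10% of analytic mode
  p <- bell_evans_params(0.44, 0.73)
  x <- sample_rupture_forces(4600, p, 1e5, seed = 21)
  h <- build_force_histogram(lapply(x, make_event), bin_width = 5)
  gf <- fit_gaussian_peak(h)
  expect_true(gf$fit_ok)
  expect_lt(abs(gf$f_star - bell_evans_force(4600, p)) /
              bell_evans_force(4600, p), 0.10)

  # too few populated bins is an error
  expect_error(fit_gaussian_peak(force_histogram(seq(0, 40, 10),
                                                 c(0, 5, 3, 0))),
               "4 nonzero bins")
})

test_that("Bell-Evans regression inverts the forward model exactly", {
  rates <- c(1, 3.1, 10, 31, 100) * 1000
  for (k_off in c(0.1, 0.44, 2)) {
    for (x_beta in c(0.3, 0.73, 1.2)) {
      truth <- bell_evans_params(k_off, x_beta)
      pts <- data.frame(loading_rate = rates,
                        f_star = bell_evans_force(rates, truth))
      fit <- fit_bell_evans(pts)
      expect_equal(fit$k_off, k_off, tolerance = 1e-6)
      expect_equal(fit$x_beta, x_beta, tolerance = 1e-6)
    }
  }

  # decreasing forces (negative slope) has no barrier interpretation
  bad <- data.frame(loading_rate = rates, f_star = seq(50, 10, length.out = 5))
  expect_error(fit_bell_evans(bad), "slope")
  expect_error(fit_bell_evans(data.frame(loading_rate = c(1, 2),
                                         f_star = c(10, 20))),
               "3 distinct")
})

test_that("recovered dissociation-rate confidence intervals cover the truth", {
  study <- bell_evans_recovery_study()
  coverage <- mean(study$ci_lo <= 0.44 & 0.44 <= study$ci_hi)
  expect_gte(coverage, 0.90)
})

test_that("affinity constant and lifetime follow from the dissociation rate", {
  p <- bell_evans_params(0.44, 0.73)
  ks <- affinity_constant(1.0e4, p)
  expect_equal(signif(ks$K_A, 2), 2.3e4)
  expect_equal(ks$lifetime_tau, 1 / 0.44, tolerance = 1e-12)

  p1 <- bell_evans_params(0.5, 0.7)
  expect_equal(affinity_constant(0.5, p1)$K_A, 1)
  expect_error(affinity_constant(-1, p), "positive")
})

test_that("blocking comparison reports specific fractions per condition", {
  free <- c(lapply(rep(40, 45), make_event),
            lapply(rep(40, 55), make_event, specific = FALSE))
  blocked <- c(lapply(rep(40, 20), make_event),
               lapply(rep(40, 80), make_event, specific = FALSE))
  fr <- blocking_comparison(free, blocked)
  expect_equal(unname(fr), c(0.45, 0.20))
  expect_equal(unname(blocking_comparison(free, free)[1]),
               unname(blocking_comparison(free, free)[2]))
  all_spec <- lapply(rep(30, 5), make_event)
  expect_equal(unname(blocking_comparison(all_spec, all_spec)[1]), 1)
  expect_error(blocking_comparison(list(), free), "empty")
})
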