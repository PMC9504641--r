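# Replicate simulation studies shared between property tests and the
# acceptance suite. Each study runs once per test session and is cached.

.study_cache <- new.env(parent = emptyenv())

.cached_study <- function(key, fn) {
  if (!exists(key, envir = .study_cache, inherits = FALSE)) {
    assign(key, fn(), envir = .study_cache)
  }
  get(key, envir = .study_cache, inherits = FALSE)
}

# Bell-Evans parameter recovery: most probable forces at five loading rates,
# perturbed by 5% multiplicative Gaussian noise, refitted; 200 replicates.
bell_evans_recovery_study <- function(n_rep = 200) {
  .cached_study("bell_evans", function() {
    truth <- bell_evans_params(k_off = 0.44, x_beta = 0.73,
                               temperature = 298)
    rates <- synth_config()$loading_rates
    f_true <- bell_evans_force(rates, truth)
    rows <- lapply(seq_len(n_rep), function(rep) {
      set.seed(5000 + rep)
      f_obs <- f_true * (1 + stats::rnorm(length(rates), 0, 0.05))
      fit <- fit_bell_evans(data.frame(loading_rate = rates, f_star = f_obs,
                                       se = 0.05 * f_true))
      ci <- attr(fit, "ci_k_off")
      data.frame(k_off = fit$k_off, x_beta = fit$x_beta,
                 ci_lo = ci[1], ci_hi = ci[2])
    })
    do.call(rbind, rows)
  })
}

# Stern-Volmer recovery at the default titration design (11 concentrations,
# 5 replicates, 2% multiplicative noise); 200 replicates.
stern_volmer_recovery_study <- function(n_rep = 200) {
  .cached_study("stern_volmer", function() {
    cfg <- synth_config()
    vapply(seq_len(n_rep), function(rep) {
      g <- gen_titration(cfg, scenario = "static", seed = 7000 + rep)
      stern_volmer_fit(g$titration)$K_SV
    }, numeric(1))
  })
}

# TCSPC reconvolution recovery at a bi-exponential decay (1.5 and 6.5 ns,
# amplitude ratio 1:2, 1e6 photons, Gaussian IRF of 1 ns FWHM); the
# synthetic IRF carries no timing jitter, so the shift is held at zero.
tcspc_recovery_study <- function(n_rep = 200) {
  .cached_study("tcspc", function() {
    cfg <- synth_config()
    times <- seq(0, by = cfg$channel_width_ns,
                 length.out = cfg$n_channels)
    sigma <- cfg$irf_fwhm_ns / (2 * sqrt(2 * log(2)))
    shape <- exp(-(times - cfg$irf_t0_ns)^2 / (2 * sigma^2))
    irf <- instrument_response(times, round(1e5 * shape / max(shape)))
    rows <- lapply(seq_len(n_rep), function(rep) {
      d <- simulate_decay(c(1, 2), c(1.5, 6.5), a0 = 0.03, irf = irf,
                          total_counts = 1e6, seed = 9000 + rep)
      f <- fit_multiexp_reconvolution(d, irf, n_components = 2,
                                      fit_shift = FALSE)
      data.frame(tau1 = f$lifetimes[1], tau2 = f$lifetimes[2],
                 chi2 = f$chi2_reduced)
    })
    do.call(rbind, rows)
  })
}

# Static/dynamic quenching classification over noisy labelled scenarios.
# The static scenario is the default titration; the dynamic scenario uses a
# diffusion-limited collisional quencher (k_q = 1e9 1/(M s), i.e.
# K_SV = k_q * tau0) probed over its own informative concentration range.
quenching_classification_study <- function(n_rep = 200) {
  .cached_study("quenching", function() {
    cfg_static <- synth_config()
    tau0_s <- 5.38e-9
    ksv_dyn <- 1e9 * tau0_s
    cfg_dyn <- synth_config(K_SV = ksv_dyn,
                            conc_grid = design_titration(ksv_dyn))
    classify_one <- function(cfg, scenario, seed) {
      g <- gen_titration(cfg, scenario = scenario, seed = seed)
      sv <- stern_volmer_fit(g$titration)
      tau <- g$lifetimes$tau_ns
      dev <- lifetime_deviation(tau[1], tau[length(tau)])
      kq <- bimolecular_quenching_constant(max(sv$K_SV, 0), tau0_s)
      classify_quenching(kq, dev)
    }
    static_calls <- vapply(seq_len(n_rep), function(rep) {
      classify_one(cfg_static, "static", 11000 + rep)
    }, character(1))
    dynamic_calls <- vapply(seq_len(n_rep), function(rep) {
      classify_one(cfg_dyn, "dynamic", 13000 + rep)
    }, character(1))
    list(static = static_calls, dynamic = dynamic_calls)
  })
}

# small constructors used across test files
make_event <- function(force, rate = 4600, specific = TRUE, sep = 15) {
  unbinding_event(force, rate, specific, sep)
}

make_gaussian_irf <- function(channel_width = 0.05, n_channels = 1024,
                              fwhm = 1, t0 = 2) {
  times <- seq(0, by = channel_width, length.out = n_channels)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  shape <- exp(-(times - t0)^2 / (2 * sigma^2))
  instrument_response(times, round(1e5 * shape / max(shape)))
}
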