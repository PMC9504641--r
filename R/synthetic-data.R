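#' Configuration for the synthetic-data generators
#'
#' One bundle of ground-truth parameters for every measurement modality the
#' pipeline consumes. Defaults put the generators in the regime the analysis
#' is designed for: a transient protein-RNA complex with k_off ~ 0.4 1/s, a
#' barrier width under a nanometre, an association constant of a few 1e4 1/M
#' probed by tryptophan quenching, nanosecond donor lifetimes, and a
#' donor-acceptor separation near 4 nm.
#'
#' @param seed Default integer seed used by generators when none is given.
#' @param k_off True dissociation rate (1/s).
#' @param x_beta True barrier width (nm).
#' @param temperature Temperature (K).
#' @param loading_rates Loading rates (pN/s) of the force-spectroscopy
#'   acquisitions; default five rates from retraction velocities 50-4200
#'   nm/s with a 10 pN/nm system spring constant.
#' @param k_syst System spring constant (pN/nm).
#' @param contour_length,kuhn_length Linker (PEG) contour and Kuhn lengths
#'   (nm).
#' @param nonspecific_fraction Fraction of event-bearing curves that are
#'   nonspecific adhesion (free scenario).
#' @param blocked_specific_fraction Specific fraction after receptor
#'   blocking.
#' @param force_noise_sd Additive Gaussian force noise (pN).
#' @param K_SV True Stern-Volmer constant (1/M).
#' @param conc_grid Quencher concentrations (M), including 0.
#' @param intensity_noise_pct Multiplicative intensity noise, percent.
#' @param n_replicates Replicates per titration point.
#' @param tau_components_ns,tau_amplitudes Donor decay components; the
#'   amplitude-weighted mean is 5.38 ns.
#' @param irf_fwhm_ns,irf_t0_ns Gaussian IRF width and position (ns).
#' @param channel_width_ns,n_channels TCSPC binning (default 1024 channels
#'   of 0.05 ns).
#' @param total_counts Photon budget per decay.
#' @param background_frac Background fraction of the photon budget.
#' @param r0_nm Foerster radius used by synthetic FRET scenarios (chosen at
#'   3.9 nm so efficiencies sit near 0.5, where the distance inversion is
#'   best conditioned; a synthetic choice, not a measured one).
#' @param dda_nm Prescribed donor-acceptor distance (nm).
#' @param traj_mean_nm,traj_sd_nm Trajectory distance level and fluctuation.
#' @param traj_t_ns,traj_dt_ns Trajectory window and sampling step (ns).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         k_off = 0.44, x_beta = 0.73, temperature = 298,
                         loading_rates = 10 * exp(seq(log(50), log(4200),
                                                      length.out = 5)),
                         k_syst = 10,
                         contour_length = 21, kuhn_length = 0.7,
                         nonspecific_fraction = 0.55,
                         blocked_specific_fraction = 0.20,
                         force_noise_sd = 3,
                         K_SV = 2.6e4,
                         conc_grid = c(0, 1.5, 2.5, 5, 7.5, 10, 15, 20, 25,
                                       35, 50) * 1e-6,
                         intensity_noise_pct = 2,
                         n_replicates = 5,
                         tau_components_ns = c(1.5, 6.5),
                         tau_amplitudes = c(0.224, 0.776),
                         irf_fwhm_ns = 1, irf_t0_ns = 2,
                         channel_width_ns = 0.05, n_channels = 1024,
                         total_counts = 1e6, background_frac = 0.01,
                         r0_nm = 3.9, dda_nm = 3.9,
                         traj_mean_nm = 3.8, traj_sd_nm = 0.1,
                         traj_t_ns = 10, traj_dt_ns = 0.1) {
  cfg <- as.list(environment())
  stopifnot(cfg$nonspecific_fraction >= 0, cfg$nonspecific_fraction <= 1,
            cfg$blocked_specific_fraction >= 0,
            cfg$blocked_specific_fraction <= 1)
  structure(cfg, class = "synth_config")
}

#' Generate synthetic force-spectroscopy retraction curves
#'
#' Specific curves follow the freely-jointed-chain stretching of the tether
#' up to a rupture force drawn from the analytic Bell-kinetics distribution
#' at the curve's loading rate, then drop to the baseline; nonspecific
#' curves are linear adhesion ramps jumping off at near-zero separation;
#' additive Gaussian force noise throughout. A ground-truth table labels
#' every curve.
#'
#' @param config A [synth_config()].
#' @param n_curves Number of curves.
#' @param scenario `"free"` or `"blocked"`; blocking suppresses the specific
#'   fraction to `blocked_specific_fraction`.
#' @param loading_rate Single loading rate (pN/s) for the whole batch;
#'   default cycles through `config$loading_rates`.
#' @param seed Integer seed.
#' @return List with `curves` (list of [force_curve()]) and `truth`
#'   (data frame: `curve`, `kind`, `loading_rate`, `rupture_force`).
#' @export
gen_force_curves <- function(config = synth_config(), n_curves = 100,
                             scenario = c("free", "blocked"),
                             loading_rate = NULL, seed = config$seed) {
  scenario <- match.arg(scenario)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p_spec <- switch(scenario,
                   free = 1 - config$nonspecific_fraction,
                   blocked = config$blocked_specific_fraction)
  params <- bell_evans_params(config$k_off, config$x_beta,
                              config$temperature)
  linker <- linker_params(config$contour_length, config$kuhn_length,
                          config$temperature)
  kbt <- thermal_energy(config$temperature)
  b <- config$x_beta / kbt
  rates <- if (is.null(loading_rate)) {
    rep_len(config$loading_rates, n_curves)
  } else rep(loading_rate, n_curves)
  sep_grid <- seq(0, 25, by = 0.05)
  kinds <- ifelse(stats::runif(n_curves) < p_spec, "specific", "nonspecific")
  curves <- vector("list", n_curves)
  f_rupt <- rep(NA_real_, n_curves)
  for (i in seq_len(n_curves)) {
    r <- rates[i]
    if (kinds[i] == "specific") {
      u <- stats::runif(1)
      fr <- log1p(-(r * b / config$k_off) * log(u)) / b
      f_rupt[i] <- fr
      sep_r <- fjc_extension(fr, linker)
      # include the exact rupture point so the jump carries the full force
      sep <- sort(unique(c(sep_grid, sep_r)))
      f <- fjc_force(sep, linker)
      f[sep > sep_r | !is.finite(f)] <- 0
    } else {
      sep_r <- stats::runif(1, 0.5, 3)
      fa <- stats::runif(1, 30, 80)
      f_rupt[i] <- fa
      sep <- sort(unique(c(sep_grid, sep_r)))
      f <- ifelse(sep <= sep_r, fa * sep / sep_r, 0)
    }
    f <- f + stats::rnorm(length(sep), 0, config$force_noise_sd)
    curves[[i]] <- force_curve(sep, f, retraction_velocity = r /
                                 config$k_syst,
                               k_syst = config$k_syst)
  }
  list(curves = curves,
       truth = data.frame(curve = seq_len(n_curves), kind = kinds,
                          loading_rate = rates, rupture_force = f_rupt))
}

#' Generate a synthetic quenching titration
#'
#' Static scenario: intensities follow `F = F0 / (1 + K_SV Q)` with
#' multiplicative Gaussian noise over replicates while lifetimes stay at the
#' unquenched value; dynamic scenario: lifetimes additionally track
#' `tau0 / (1 + K_SV Q)`.
#'
#' @param config A [synth_config()].
#' @param scenario `"static"` or `"dynamic"`.
#' @param seed Integer seed.
#' @return List with `titration` (data frame `quencher_conc`, `intensity`,
#'   `sd`), `lifetimes` (data frame `quencher_conc`, `tau_ns`) and `truth`.
#' @export
gen_titration <- function(config = synth_config(),
                          scenario = c("static", "dynamic"),
                          seed = config$seed) {
  scenario <- match.arg(scenario)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  q <- config$conc_grid
  f0 <- 1e6
  tau0 <- mean_lifetime(config$tau_amplitudes, config$tau_components_ns)
  f_true <- f0 / (1 + config$K_SV * q)
  noise <- config$intensity_noise_pct / 100
  reps <- matrix(stats::rnorm(length(q) * config$n_replicates, 1, noise),
                 nrow = length(q))
  obs <- reps * f_true
  tau <- if (scenario == "static") rep(tau0, length(q)) else
    tau0 / (1 + config$K_SV * q)
  tau <- tau * stats::rnorm(length(q), 1, noise / 4)
  list(
    titration = data.frame(quencher_conc = q,
                           intensity = rowMeans(obs),
                           sd = apply(obs, 1, stats::sd)),
    lifetimes = data.frame(quencher_conc = q, tau_ns = tau),
    truth = list(K_SV = config$K_SV, F0 = f0, tau0_ns = tau0,
                 scenario = scenario)
  )
}

#' Generate a synthetic TCSPC decay and its instrument response
#'
#' The IRF is a Gaussian pulse on the configured channel grid. The donor
#' scenario uses the configured decay components; the FRET scenario scales
#' every component lifetime by `1 - E` with `E = R0^6 / (R0^6 + D^6)` at the
#' prescribed donor-acceptor distance (the rate relation of
#' distance-dependent energy transfer), so the amplitude-weighted mean obeys
#' the donor-lifetime-variation relation exactly.
#'
#' @param config A [synth_config()].
#' @param scenario `"donor"` (no acceptor) or `"fret"`.
#' @param dda_nm Prescribed distance for the FRET scenario (defaults to
#'   `config$dda_nm`).
#' @param seed Integer seed.
#' @return List with `decay` ([decay_histogram()]), `irf`
#'   ([instrument_response()]) and `truth` (components, E, distances).
#' @export
gen_tcspc <- function(config = synth_config(),
                      scenario = c("donor", "fret"),
                      dda_nm = config$dda_nm, seed = config$seed) {
  scenario <- match.arg(scenario)
  times <- seq(0, by = config$channel_width_ns,
               length.out = config$n_channels)
  sigma <- config$irf_fwhm_ns / (2 * sqrt(2 * log(2)))
  irf_shape <- exp(-(times - config$irf_t0_ns)^2 / (2 * sigma^2))
  irf <- instrument_response(times, round(1e5 * irf_shape /
                                            max(irf_shape)))
  e <- 0
  tau <- config$tau_components_ns
  if (scenario == "fret") {
    e <- config$r0_nm^6 / (config$r0_nm^6 + dda_nm^6)
    tau <- tau * (1 - e)
  }
  amp <- config$tau_amplitudes
  a0 <- config$background_frac * sum(amp)
  decay <- simulate_decay(amp, tau, a0, irf,
                          total_counts = config$total_counts, seed = seed)
  list(decay = decay, irf = irf,
       truth = list(amplitudes = amp, lifetimes_ns = tau,
                    mean_lifetime_ns = mean_lifetime(amp, tau),
                    E = e, dda_nm = if (scenario == "fret") dda_nm else NA,
                    r0_nm = config$r0_nm, scenario = scenario))
}

# idealised indole-ring coordinates (Angstrom, planar), recentred so the
# nine-ring-atom centroid is exactly the origin
.indole_template <- function() {
  m <- rbind(
    CG  = c( 0.000, 0.000, 0),
    CD1 = c( 1.093, 0.784, 0),
    NE1 = c( 0.870, 2.125, 0),
    CE2 = c(-0.483, 2.250, 0),
    CD2 = c(-1.014, 0.961, 0),
    CE3 = c(-2.382, 0.640, 0),
    CZ3 = c(-3.222, 1.728, 0),
    CH2 = c(-2.705, 3.028, 0),
    CZ2 = c(-1.349, 3.329, 0)
  )
  sweep(m, 2, colMeans(m))
}

#' Generate a toy donor-acceptor complex at a prescribed distance
#'
#' Minimal structure with a complete tryptophan indole ring (chain A,
#' residue number of choice) whose ring centroid sits exactly at the origin,
#' and a minimal RNA 5' terminus (chain B) whose phosphorus atom sits
#' exactly `dda_nm` away along x, so [model_dda()] returns the prescribed
#' distance to machine precision. Serialisable to PDB with
#' [write_structure()].
#'
#' @param dda_nm Prescribed donor-acceptor distance (nm), > 0.
#' @param trp_residue_number Residue number for the tryptophan.
#' @param rna_chain Chain id for the RNA fragment.
#' @param model_id Rank label.
#' @return A [structure_model()].
#' @export
gen_toy_complex <- function(dda_nm = 4.0, trp_residue_number = 214,
                            rna_chain = "B", model_id = 1L) {
  check_positive(dda_nm, "dda_nm")
  ring <- .indole_template()
  trp <- data.frame(
    elety = rownames(ring), resid = "TRP", resno = trp_residue_number,
    chain = "A", x = ring[, 1], y = ring[, 2], z = ring[, 3],
    elesy = substr(rownames(ring), 1, 1), stringsAsFactors = FALSE
  )
  # anchor atoms of the Trp backbone (outside the ring), for realism
  extra <- data.frame(
    elety = c("CB", "CA"), resid = "TRP", resno = trp_residue_number,
    chain = "A", x = c(0.8, 1.5), y = c(-1.3, -2.5), z = c(0.4, 0.2),
    elesy = "C", stringsAsFactors = FALSE
  )
  px <- dda_nm * 10
  rna <- data.frame(
    elety = c("P", "OP1", "OP2", "O5'", "C5'"),
    resid = "U", resno = 1L, chain = rna_chain,
    x = px + c(0, 0.9, -0.6, 0.3, 1.0),
    y = c(0, 1.1, 1.2, -1.3, -2.0),
    z = c(0, 0.2, -0.9, 0.6, 0.1),
    elesy = c("P", "O", "O", "O", "C"), stringsAsFactors = FALSE
  )
  rna$x[1] <- px; rna$y[1] <- 0; rna$z[1] <- 0
  structure_model(rbind(trp, extra, rna), model_id = model_id)
}

#' Generate a synthetic trajectory of donor-acceptor distances
#'
#' Gaussian fluctuations about a base level, with optional step changes
#' ("jumps") to new levels at configured times, over a window sampled like a
#' short MD run (default 10 ns at 0.1 ns).
#'
#' @param config A [synth_config()].
#' @param jumps Optional data frame with columns `time_ns` and `level_nm`:
#'   from each `time_ns` on, the mean level becomes `level_nm`.
#' @param seed Integer seed.
#' @return List with `times` (ns), `distances` (nm) and `truth`.
#' @export
gen_trajectory_distances <- function(config = synth_config(), jumps = NULL,
                                     seed = config$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  times <- seq(0, config$traj_t_ns, by = config$traj_dt_ns)
  level <- rep(config$traj_mean_nm, length(times))
  if (!is.null(jumps)) {
    stopifnot(all(c("time_ns", "level_nm") %in% names(jumps)))
    for (k in seq_len(nrow(jumps))) {
      level[times >= jumps$time_ns[k]] <- jumps$level_nm[k]
    }
  }
  distances <- level + stats::rnorm(length(times), 0, config$traj_sd_nm)
  list(times = times, distances = distances,
       truth = list(levels = level, mean_nm = config$traj_mean_nm,
                    sd_nm = config$traj_sd_nm,
                    n_jumps = if (is.null(jumps)) 0L else nrow(jumps)))
}
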