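# fretforce

Characterisation of biomolecular complexes — here a serum-albumin/microRNA
pair is the motivating system — rarely rests on one technique. `fretforce`
implements, as one tested R pipeline, the four analyses that such a study
chains together:

1. **Single-molecule unbinding kinetics** (dynamic force spectroscopy).
   Rupture events are extracted from retraction curves by their polymer-linker
   stretching signature, binned per loading rate, and the most probable
   unbinding force F\* is fitted across loading rates with the Bell–Evans
   model

   F\* = (k_B T / x_β) · ln( r·x_β / (k_off·k_B T) ),

   yielding the dissociation rate `k_off`, the barrier width `x_β`, the
   complex lifetime τ = 1/k_off and, with a user-supplied `k_on`, the
   affinity constant K_A = k_on/k_off.

2. **Steady-state fluorescence quenching.** Inner-filter and blank
   corrections, the Stern–Volmer fit F₀/F = 1 + K_SV·[Q], the bimolecular
   quenching constant k_q = K_SV/τ_q, and a static-vs-dynamic classification
   based on k_q relative to the diffusion limit and on lifetime invariance.

3. **Time-resolved fluorescence (TCSPC) and FRET.** Multi-exponential
   reconvolution fitting of photon-count decays against a measured
   instrument response (Poisson weights, fitted sub-channel timing shift),
   amplitude-weighted mean lifetimes τ = Σaᵢτᵢ/Σaᵢ, the donor-lifetime FRET
   efficiency E = 1 − ⟨τ_DA⟩/⟨τ_D⟩ and the distance inversion
   D_DA = R₀·((1−E)/E)^(1/6).

4. **Structure screening and binding free energy.** Donor–acceptor
   distances measured on candidate complex structures (tryptophan indole-ring
   centroid to nucleic-acid 5′ end), RMSD grouping of docking poses,
   selection of models consistent with the experimental FRET distance, a
   Shrake–Rupley solvent-accessible surface area primitive with the linear
   nonpolar-solvation model γ·SASA + β, and MM-PBSA-style composition
   ΔG_B = ΔG_nonpol,solv + ΔE_MM + (−TΔS) + ΔG_pol,solv.

A synthetic-data module (`gen_force_curves`, `gen_titration`, `gen_tcspc`,
`gen_toy_complex`, `gen_trajectory_distances`) emulates every input modality
with known ground truth, so the whole chain runs and validates without an
instrument.

## Worked example

```r
library(fretforce)
cfg <- synth_config(seed = 7)   # ground truth: k_off 0.44 1/s, x_beta 0.73 nm,
                                # K_SV 2.6e4 1/M, tau_D 5.38 ns, D_DA 3.9 nm

## 1. unbinding kinetics from synthetic force curves
pts <- do.call(rbind, lapply(cfg$loading_rates, function(r) {
  batch <- gen_force_curves(cfg, n_curves = 600, loading_rate = r,
                            seed = 7 + round(r))
  events <- Filter(Negate(is.null),
                   lapply(batch$curves, detect_unbinding_event))
  specific <- Filter(function(e) e$is_specific, events)
  peak <- fit_gaussian_peak(build_force_histogram(specific, bin_width = 5))
  data.frame(loading_rate = r, f_star = peak$f_star,
             se = peak$sigma / sqrt(length(specific)))
}))
be <- fit_bell_evans(pts)
be
#> <bell_evans_params>
#>   k_off  : 0.506 +/- 0.12 1/s
#>   x_beta : 0.756 +/- 0.028 nm
#>   T      : 298 K
affinity_constant(k_on = 1.0e4, be)
#> <kinetics_summary> K_A = 1.98e+04 1/M (k_on = 1e+04, k_off = 0.506), tau = 1.98 s
```

The fitted rate and barrier width recover the generator truth (0.44 s⁻¹,
0.73 nm) within their standard errors; the affinity lands at the expected
~2×10⁴ M⁻¹ scale.

```r
## 2. Stern-Volmer quenching
tit <- gen_titration(cfg, scenario = "static", seed = 7)
sv <- bimolecular_quenching_constant(stern_volmer_fit(tit$titration),
                                     tau_q = 5.38e-9)
sv
#> <stern_volmer_fit> K_SV = 2.654e+04 +/- 3.4e+02 1/M, intercept = 1.018, R2 = 0.9986
classify_quenching(sv$k_q,
                   lifetime_deviation(tit$lifetimes$tau_ns[1],
                                      tail(tit$lifetimes$tau_ns, 1)))
#> [1] "static"
```

K_SV ≈ 2.65×10⁴ M⁻¹ against a true 2.6×10⁴; k_q ≈ 4.9×10¹² M⁻¹s⁻¹ is far
above the ~10¹⁰ diffusion limit while lifetimes stay flat, so the quenching
is classified static (a ground-state complex, making K_SV an affinity
constant).

```r
## 3. FRET distance from TCSPC decays
donor <- gen_tcspc(cfg, scenario = "donor", seed = 7)
da    <- gen_tcspc(cfg, scenario = "fret", seed = 8)
tau_d  <- mean_lifetime(fit_multiexp_reconvolution(donor$decay, donor$irf, 2))
tau_da <- mean_lifetime(fit_multiexp_reconvolution(da$decay, da$irf, 2))
E <- fret_efficiency(tau_da, tau_d)
fret_distance(E, R0 = cfg$r0_nm)
#> tau_D = 5.347 ns, tau_DA = 2.694 ns, E = 0.496, D_DA = 3.91 nm
```

```r
## 4. screening candidate structures against the measured distance
models <- lapply(c(2.5, 3.8, 4.0, 4.2, 5.6),
                 function(d) gen_toy_complex(d, model_id = round(10 * d)))
filter_by_fret(models,
               distance_constraint(d_exp = 3.9, sd = 0.2, dye_offset = 0.1),
               trp_residue_number = 214, rna_chain = "B")
#>   model_id dda_nm  pass
#> 1       25    2.5 FALSE
#> 2       38    3.8  TRUE
#> 3       40    4.0  TRUE
#> 4       42    4.2  TRUE
#> 5       56    5.6 FALSE
compose_binding_energy(deltas = list(g_nonpol_solv = -30, e_mm = -198,
                                     minus_t_delta_s = 878,
                                     g_pol_solv = -1600))
#> <energy_terms> (kJ/mol)
#>   dG_nonpol,solv =      -30
#>   dE_MM          =     -198
#>   -T dS          =      878
#>   dG_pol,solv    =    -1600
#>   dG_B           =     -950
```

Only the three candidates within 0.2 nm of the dye-offset-corrected
experimental distance (3.9 + 0.1 nm) survive the screen; the energy
composition sums per-term MM-PBSA deltas into the binding free energy.

See `vignettes/pipeline-methods.Rmd` for the models, assumptions, parameter
choices and limitations.

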