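#' Bondi-type van der Waals radii
#'
#' Element radii (Angstrom) used for the solvent-accessible surface area.
#'
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
    "F" = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.40)
}

# quasi-uniform points on the unit sphere (golden-section spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area by Shrake-Rupley sampling
#'
#' Each atom's van der Waals sphere is inflated by the probe radius and
#' covered with quasi-uniform test points (golden-section spiral); points
#' falling inside any other atom's inflated sphere are occluded, and the
#' accessible area is the exposed fraction of each sphere. A point lying
#' exactly on another atom's inflated sphere is occluded only by lower-index
#' atoms, so exactly duplicated atoms contribute their surface once.
#'
#' @param model A [structure_model()].
#' @param probe_radius Solvent probe radius (Angstrom), default 1.4.
#' @param n_points Test points per atom, default 960.
#' @param radii Named element-radius table (Angstrom); default [vdw_radii()].
#' @return Total solvent-accessible surface area (nm^2); per-atom areas
#'   (nm^2) in attribute `per_atom`.
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960,
                 radii = vdw_radii()) {
  stopifnot(inherits(model, "structure_model"))
  check_positive(probe_radius, "probe_radius")
  if (n_points < 10) stop("`n_points` must be >= 10", call. = FALSE)
  a <- model$atoms
  el <- toupper(trimws(a$elesy))
  unknown <- !(el %in% names(radii))
  if (any(unknown)) {
    k <- which(unknown)[1L]
    stop(sprintf(
      "no van der Waals radius for element '%s' (atom %s, residue %s %s)",
      el[k], trimws(a$elety[k]), a$resid[k], a$resno[k]), call. = FALSE)
  }
  r <- unname(radii[el]) + probe_radius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n_atoms <- nrow(xyz)
  pts <- .sphere_points(n_points)
  tol <- 1e-6
  per_atom <- numeric(n_atoms)
  d2mat <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n_atoms)) {
    neigh <- which(d2mat[i, ] < (r[i] + r)^2 & seq_len(n_atoms) != i)
    test <- sweep(pts * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in neigh) {
      if (!any(exposed)) break
      d2 <- rowSums(sweep(test, 2, xyz[j, ], "-")^2)
      occ <- d2 < r[j]^2 - tol | (abs(d2 - r[j]^2) <= tol & j < i)
      exposed <- exposed & !occ
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(exposed) / n_points / 100  # A^2->nm^2
  }
  structure(sum(per_atom), per_atom = per_atom)
}

#' Nonpolar solvation free energy from SASA
#'
#' Linear surface-area model `G = gamma * SASA + beta`, with
#' gamma = 2.27 kJ/(mol nm^2) and beta = 3.84 kJ/mol by default.
#'
#' @param sasa_nm2 Solvent-accessible surface area (nm^2), >= 0.
#' @param gamma Surface-tension coefficient (kJ/(mol nm^2)).
#' @param beta Offset (kJ/mol).
#' @return Nonpolar solvation free energy (kJ/mol).
#' @export
nonpolar_solvation <- function(sasa_nm2, gamma = 2.27, beta = 3.84) {
  if (any(sasa_nm2 < 0)) stop("`sasa_nm2` must be >= 0", call. = FALSE)
  gamma * as.numeric(sasa_nm2) + beta
}

.energy_fields <- c("g_nonpol_solv", "e_mm", "minus_t_delta_s", "g_pol_solv")

#' MM-PBSA energy decomposition
#'
#' The four components of the free energy
#' `G = E_MM - T S + G_polar,solv + G_nonpolar,solv` (all kJ/mol), with the
#' total `g_b` formed as their sum.
#'
#' @param g_nonpol_solv Nonpolar solvation term (kJ/mol).
#' @param e_mm Molecular-mechanics internal energy, electrostatic plus van
#'   der Waals (kJ/mol).
#' @param minus_t_delta_s Entropic term -T*S (kJ/mol).
#' @param g_pol_solv Polar (electrostatic) solvation term (kJ/mol).
#' @return An object of class `energy_terms` with the four terms and `g_b`.
#' @export
energy_terms <- function(g_nonpol_solv, e_mm, minus_t_delta_s, g_pol_solv) {
  vals <- c(g_nonpol_solv = g_nonpol_solv, e_mm = e_mm,
            minus_t_delta_s = minus_t_delta_s, g_pol_solv = g_pol_solv)
  if (any(!is.finite(vals))) {
    stop("all energy terms must be finite (kJ/mol)", call. = FALSE)
  }
  structure(as.list(c(vals, g_b = sum(vals))), class = "energy_terms")
}

#' @export
print.energy_terms <- function(x, ...) {
  cat("<energy_terms> (kJ/mol)\n")
  cat(sprintf("  dG_nonpol,solv = %8.4g\n", x$g_nonpol_solv))
  cat(sprintf("  dE_MM          = %8.4g\n", x$e_mm))
  cat(sprintf("  -T dS          = %8.4g\n", x$minus_t_delta_s))
  cat(sprintf("  dG_pol,solv    = %8.4g\n", x$g_pol_solv))
  cat(sprintf("  dG_B           = %8.4g\n", x$g_b))
  invisible(x)
}

#' Compose the MM-PBSA binding free energy
#'
#' `dG_B = G(complex) - G(receptor) - G(ligand)`, formed either from the
#' absolute per-species decompositions (each an [energy_terms()] or a named
#' list of the four terms) or directly from per-term deltas (table style).
#' Both routes are algebraically identical: deltas are formed per term and
#' summed.
#'
#' @param complex_terms,receptor_terms,ligand_terms Per-species terms; give
#'   all three, or none when `deltas` is supplied.
#' @param deltas Named list/vector with `g_nonpol_solv`, `e_mm`,
#'   `minus_t_delta_s`, `g_pol_solv` already as complex-minus-parts deltas.
#' @return An [energy_terms()] holding the deltas and total `g_b` (kJ/mol).
#' @export
compose_binding_energy <- function(complex_terms = NULL,
                                   receptor_terms = NULL,
                                   ligand_terms = NULL,
                                   deltas = NULL) {
  pick <- function(x, what) {
    x <- as.list(x)
    missing <- setdiff(.energy_fields, names(x))
    if (length(missing) > 0) {
      stop(what, " is missing energy term(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    vapply(.energy_fields, function(f) as.numeric(x[[f]]), numeric(1))
  }
  if (!is.null(deltas)) {
    d <- pick(deltas, "`deltas`")
  } else {
    if (is.null(complex_terms) || is.null(receptor_terms) ||
        is.null(ligand_terms)) {
      stop("supply either `deltas` or all of complex/receptor/ligand terms",
           call. = FALSE)
    }
    d <- pick(complex_terms, "`complex_terms`") -
      pick(receptor_terms, "`receptor_terms`") -
      pick(ligand_terms, "`ligand_terms`")
  }
  energy_terms(d[["g_nonpol_solv"]], d[["e_mm"]], d[["minus_t_delta_s"]],
               d[["g_pol_solv"]])
}

#' Mean, spread and jump count of a trajectory distance series
#'
#' Summarises the temporal evolution of a donor-acceptor distance along a
#' simulation: overall mean and standard deviation, plus a count of level
#' shifts ("jumps", local re-organisation of the ligand). A jump is a
#' successive difference exceeding `threshold_mult` times the median
#' absolute successive difference whose new level persists for at least
#' `min_persist` samples (windowed means on both sides must differ by more
#' than the threshold).
#'
#' @param times Sample times (ns).
#' @param distances Distances (nm), > 0, same length, >= 10 samples.
#' @param threshold_mult Multiplier of the median absolute successive
#'   difference (default 3).
#' @param min_persist Minimum persistence in samples (default 10).
#' @return A list with `mean`, `sd`, `n_jumps` and `jump_times`.
#' @export
distance_series_stats <- function(times, distances, threshold_mult = 3,
                                  min_persist = 10) {
  if (length(times) != length(distances)) {
    stop("`times` and `distances` must have equal length", call. = FALSE)
  }
  n <- length(distances)
  if (n < 10L) stop("need at least 10 samples", call. = FALSE)
  if (any(distances <= 0)) stop("distances must be > 0", call. = FALSE)
  d <- diff(distances)
  thr <- threshold_mult * stats::median(abs(d))
  cand <- which(abs(d) > thr & thr > 0)
  jumps <- integer(0)
  for (k in cand) {
    lo <- max(1L, k - min_persist + 1L)
    hi <- min(n, k + min_persist)
    if (k - lo + 1L < 3L || hi - k < 3L) next
    pre <- mean(distances[lo:k])
    post <- mean(distances[(k + 1L):hi])
    if (abs(post - pre) > thr) jumps <- c(jumps, k)
  }
  # merge candidates within one persistence window into a single jump
  if (length(jumps) > 1L) {
    keep <- c(TRUE, diff(jumps) >= min_persist)
    jumps <- jumps[keep]
  }
  list(mean = mean(distances), sd = stats::sd(distances),
       n_jumps = length(jumps), jump_times = times[jumps])
}
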