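#' Structure model (atom table) for complex screening
#'
#' A light container for one candidate complex structure: an atom table in
#' PDB conventions (coordinates in Angstrom) plus a rank label. Reported
#' distances are in nm throughout the screening interface.
#'
#' @param atoms Data frame with columns `elety` (atom name), `resid`
#'   (residue name), `resno` (residue number), `chain`, `x`, `y`, `z`
#'   (Angstrom) and optionally `elesy` (element symbol).
#' @param model_id Rank label (e.g. docking rank), default 1.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  need <- c("elety", "resid", "resno", "chain", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms))) {
    stop("`atoms` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  if (!"elesy" %in% names(atoms)) {
    atoms$elesy <- .element_from_name(atoms$elety)
  }
  structure(list(atoms = atoms, model_id = model_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> model %s: %d atoms, chains %s\n",
              format(x$model_id), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

# element symbol guessed from a PDB atom name (first alphabetic character,
# with two-letter halogens/metals left to the explicit element column)
.element_from_name <- function(elety) {
  sub("^[0-9']*([A-Za-z]).*$", "\\1", toupper(trimws(elety)))
}

#' Read candidate structures from a PDB file
#'
#' Parses ATOM/HETATM records via bio3d after a line-level validation pass
#' that reports malformed coordinate fields with their line number.
#' Multi-MODEL files yield a list of [structure_model()] objects, one per
#' MODEL block, ranked in file order.
#'
#' @param path Path to a PDB file.
#' @return A single `structure_model`, or a list of them for multi-MODEL
#'   files.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed PDB record at line %d: truncated before the ",
                   i), "coordinate fields", call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop(sprintf("malformed coordinate field at line %d of %s", i, path),
           call. = FALSE)
    }
  }
  if (!any(rec)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  build <- function(k) {
    co <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    atoms <- data.frame(
      elety = at$elety, resid = at$resid, resno = at$resno,
      chain = at$chain, x = co[, 1], y = co[, 2], z = co[, 3],
      elesy = ifelse(is.na(at$elesy) | at$elesy == "",
                     .element_from_name(at$elety), toupper(at$elesy)),
      stringsAsFactors = FALSE
    )
    structure_model(atoms, model_id = k)
  }
  if (n_models == 1L) build(1L) else lapply(seq_len(n_models), build)
}

#' Write a structure model to a PDB file
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = a$chain, elesy = a$elesy)
  invisible(path)
}

# indole ring atom names of tryptophan
.trp_ring_atoms <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
                     "CH2")

#' FRET donor site: centre of the tryptophan indole ring
#'
#' Unweighted centroid of the nine side-chain ring atoms (CG, CD1, CD2, NE1,
#' CE2, CE3, CZ2, CZ3, CH2) of the specified tryptophan residue.
#'
#' @param model A [structure_model()].
#' @param trp_residue_number Residue number of the tryptophan (e.g. 214 for
#'   the single tryptophan of human serum albumin).
#' @return Numeric length-3 point (nm).
#' @export
donor_site <- function(model, trp_residue_number = 214) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  ring <- a[a$resno == trp_residue_number &
              trimws(a$elety) %in% .trp_ring_atoms, , drop = FALSE]
  missing <- setdiff(.trp_ring_atoms, trimws(ring$elety))
  if (length(missing) > 0) {
    stop("tryptophan ", trp_residue_number, " is missing indole ring atoms: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  colMeans(as.matrix(ring[, c("x", "y", "z")])) / 10
}

#' FRET acceptor site: 5' end of the nucleic-acid chain
#'
#' Position of the 5'-terminal residue's phosphorus atom, falling back to
#' O5' when the terminal residue carries no phosphate (common for the first
#' nucleotide), where an acceptor dye would be conjugated.
#'
#' @param model A [structure_model()].
#' @param rna_chain Chain identifier of the nucleic acid.
#' @return Numeric length-3 point (nm).
#' @export
acceptor_site <- function(model, rna_chain) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  nuc <- a[!is.na(a$chain) & a$chain == rna_chain, , drop = FALSE]
  if (nrow(nuc) == 0L) {
    stop("chain '", rna_chain, "' not present in the model", call. = FALSE)
  }
  first <- nuc[nuc$resno == min(nuc$resno), , drop = FALSE]
  hit <- first[trimws(first$elety) == "P", , drop = FALSE]
  if (nrow(hit) == 0L) {
    hit <- first[trimws(first$elety) == "O5'", , drop = FALSE]
  }
  if (nrow(hit) == 0L) {
    stop("5'-terminal residue of chain '", rna_chain,
         "' has neither P nor O5'", call. = FALSE)
  }
  as.numeric(hit[1L, c("x", "y", "z")]) / 10
}

#' Donor-acceptor distance of a candidate complex model
#'
#' Euclidean distance between the tryptophan indole-ring centre
#' ([donor_site()]) and the nucleic-acid 5' end ([acceptor_site()]), in nm.
#'
#' @inheritParams donor_site
#' @inheritParams acceptor_site
#' @return Distance (nm).
#' @export
model_dda <- function(model, trp_residue_number = 214, rna_chain) {
  d <- donor_site(model, trp_residue_number)
  a <- acceptor_site(model, rna_chain)
  sqrt(sum((d - a)^2))
}

#' Group docking poses by all-atom RMSD
#'
#' Single-linkage grouping of models whose pairwise all-atom RMSD falls
#' below the cutoff. The RMSD is computed without superposition, since
#' docked poses share the fixed receptor frame; set `superpose = TRUE` to
#' least-squares fit each pair first. The representative of each group is
#' its lowest-rank member.
#'
#' @param models List of [structure_model()] with identical atom counts and
#'   ordering.
#' @param cutoff RMSD grouping cutoff (nm), default 0.1.
#' @param superpose Superpose each pair before the RMSD (default FALSE).
#' @return A list with `membership` (group index per model),
#'   `representatives` (indices into `models`, one per group, lowest rank
#'   first) and `rmsd` (pairwise matrix, nm).
#' @export
group_models_by_rmsd <- function(models, cutoff = 0.1, superpose = FALSE) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "structure_model")))
  counts <- vapply(models, function(m) nrow(m$atoms), integer(1))
  if (length(unique(counts)) != 1L) {
    stop("models differ in atom count: no atom correspondence", call. = FALSE)
  }
  xyz <- lapply(models, function(m) as.matrix(m$atoms[, c("x", "y", "z")]))
  n <- length(models)
  rmsd <- matrix(0, n, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        a <- xyz[[i]]; b <- xyz[[j]]
        if (superpose) {
          fit <- bio3d::fit.xyz(fixed = as.numeric(t(a)),
                                mobile = as.numeric(t(b)))
          b <- matrix(fit, ncol = 3, byrow = TRUE)
        }
        rmsd[i, j] <- rmsd[j, i] <- sqrt(mean(rowSums((a - b)^2))) / 10
      }
    }
  }
  membership <- if (n == 1L) 1L else {
    hc <- stats::hclust(stats::as.dist(rmsd), method = "single")
    stats::cutree(hc, h = cutoff)
  }
  ranks <- vapply(models, function(m) as.numeric(m$model_id), numeric(1))
  reps <- vapply(sort(unique(membership)), function(g) {
    members <- which(membership == g)
    members[which.min(ranks[members])]
  }, integer(1))
  reps <- reps[order(ranks[reps])]
  list(membership = membership, representatives = reps, rmsd = rmsd)
}

#' Experimental FRET distance constraint
#'
#' @param d_exp Experimental donor-acceptor distance (nm), > 0.
#' @param sd Its uncertainty (nm), > 0; used as the half-width of the
#'   acceptance window.
#' @param dye_offset Extra distance contributed by the dye linker at the 5'
#'   end (nm), added to `d_exp` before comparison. Default 0.1.
#' @return An object of class `distance_constraint`.
#' @export
distance_constraint <- function(d_exp, sd, dye_offset = 0.1) {
  check_positive(d_exp, "d_exp")
  check_positive(sd, "sd")
  check_positive(dye_offset, "dye_offset")
  structure(list(d_exp = d_exp, sd = sd, dye_offset = dye_offset),
            class = "distance_constraint")
}

#' Screen candidate models against the FRET distance constraint
#'
#' A model passes when its donor-acceptor distance lies within `sd` of
#' `d_exp + dye_offset`.
#'
#' @param models List of [structure_model()].
#' @param constraint A [distance_constraint()].
#' @inheritParams model_dda
#' @return Data frame with `model_id`, `dda_nm` and `pass`; the selected
#'   models are attached as attribute `selected`.
#' @export
filter_by_fret <- function(models, constraint, trp_residue_number = 214,
                           rna_chain) {
  stopifnot(inherits(constraint, "distance_constraint"))
  dda <- vapply(models, model_dda, numeric(1),
                trp_residue_number = trp_residue_number,
                rna_chain = rna_chain)
  target <- constraint$d_exp + constraint$dye_offset
  # tolerance keeps models exactly on the window edge inside it
  pass <- abs(dda - target) <= constraint$sd + 1e-9
  out <- data.frame(
    model_id = vapply(models, function(m) as.integer(m$model_id), integer(1)),
    dda_nm = dda, pass = pass
  )
  attr(out, "selected") <- models[pass]
  out
}
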