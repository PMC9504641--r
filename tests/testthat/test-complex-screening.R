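# fixed-column PDB ATOM line
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     element = substr(trimws(name), 1, 1)) {
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resn, chain, resno, x, y, z, element)
}

test_that("PDB reading returns exact coordinates and honours MODEL blocks", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, " N  ", "GLY", "A", 1, 1.5, 2.25, -3.125),
    pdb_line(2, " CA ", "GLY", "A", 1, 0.001, -0.002, 0.003),
    pdb_line(3, " C  ", "GLY", "A", 1, 10, 20, 30),
    "END"), f)
  m <- read_structure(f)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$atoms$x, c(1.5, 0.001, 10))
  expect_equal(m$atoms$y, c(2.25, -0.002, 20))
  expect_equal(m$atoms$z, c(-3.125, 0.003, 30))

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdb_line(1, " CA ", "GLY", "A", 1, 0, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, " CA ", "GLY", "A", 1, 5, 0, 0),
    "ENDMDL",
    "END"), f2)
  ms <- read_structure(f2)
  expect_length(ms, 2L)
  expect_equal(ms[[2]]$atoms$x, 5)

  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, " CA ", "GLY", "A", 1, 0, 0, 0),
               substr(pdb_line(2, " C  ", "GLY", "A", 1, 1, 1, 1), 1, 40)),
             f3)
  expect_error(read_structure(f3), "line 2")
})

test_that("donor site is the indole ring centroid and transforms rigidly", {
  m <- gen_toy_complex(4.0)
  expect_equal(donor_site(m, 214), c(x = 0, y = 0, z = 0), tolerance = 1e-12)

  # translation equivariance (Angstrom in, nm out)
  m2 <- m
  m2$atoms$x <- m2$atoms$x + 1
  m2$atoms$y <- m2$atoms$y + 2
  m2$atoms$z <- m2$atoms$z + 3
  expect_equal(donor_site(m2, 214), c(x = 0.1, y = 0.2, z = 0.3),
               tolerance = 1e-12)

  m3 <- m
  m3$atoms <- m3$atoms[trimws(m3$atoms$elety) != "NE1", ]
  expect_error(donor_site(m3, 214), "NE1")
})

test_that("acceptor site is the 5' phosphate with an O5' fallback", {
  m <- gen_toy_complex(4.0)
  expect_equal(acceptor_site(m, "B"), c(40, 0, 0) / 10, tolerance = 1e-12)

  # drop the phosphate group: falls back to O5'
  m2 <- m
  keep <- !(m2$atoms$chain == "B" &
              trimws(m2$atoms$elety) %in% c("P", "OP1", "OP2"))
  m2$atoms <- m2$atoms[keep, ]
  o5 <- m2$atoms[m2$atoms$chain == "B" & trimws(m2$atoms$elety) == "O5'", ]
  expect_equal(acceptor_site(m2, "B"),
               as.numeric(o5[1, c("x", "y", "z")]) / 10)

  protein_only <- m
  protein_only$atoms <- protein_only$atoms[protein_only$atoms$chain == "A", ]
  expect_error(acceptor_site(protein_only, "B"), "not present")
})

test_that("model donor-acceptor distance is exact and isometry invariant", {
  m <- gen_toy_complex(4.0)
  expect_equal(model_dda(m, 214, "B"), 4.0, tolerance = 1e-9)

  # random rigid rotation + translation leaves the distance unchanged
  set.seed(31)
  th <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- rz %*% rx
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m2 <- m
  m2$atoms$x <- xyz[, 1] + 7
  m2$atoms$y <- xyz[, 2] - 3
  m2$atoms$z <- xyz[, 3] + 11
  expect_equal(model_dda(m2, 214, "B"), 4.0, tolerance = 1e-9)
})

test_that("RMSD grouping partitions models with lowest-rank representatives", {
  mA <- gen_toy_complex(4.0, model_id = 1)
  mB <- gen_toy_complex(4.0, model_id = 2)
  gr0 <- group_models_by_rmsd(list(mA, mB), cutoff = 0.1)
  expect_equal(unname(gr0$membership), c(1L, 1L))
  expect_equal(gr0$rmsd[1, 2], 0)
  expect_equal(gr0$representatives, 1L)

  # 0.05 nm uniform displacement stays inside a 0.1 nm cutoff
  mC <- mA
  mC$atoms$x <- mC$atoms$x + 0.5
  mC$model_id <- 3
  mD <- gen_toy_complex(5.0, model_id = 4)  # well outside
  gr <- group_models_by_rmsd(list(mA, mC, mD), cutoff = 0.1)
  expect_equal(gr$membership[1], gr$membership[2])
  expect_false(gr$membership[1] == gr$membership[3])
  expect_equal(gr$rmsd[1, 2], 0.05, tolerance = 1e-9)

  # partition: every model in exactly one group; one representative each
  expect_length(gr$membership, 3L)
  expect_equal(sort(unique(gr$membership)), seq_along(gr$representatives))

  bad <- mA
  bad$atoms <- bad$atoms[-1, ]
  expect_error(group_models_by_rmsd(list(mA, bad)), "atom count")
})

test_that("FRET screening passes exactly the distances inside the offset
          window", {
  mods <- lapply(c(2.5, 3.8, 4.0, 4.2, 5.6),
                 function(d) gen_toy_complex(d, model_id = round(10 * d)))
  cons <- distance_constraint(d_exp = 3.9, sd = 0.2, dye_offset = 0.1)
  res <- filter_by_fret(mods, cons, 214, "B")
  expect_equal(res$pass, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_length(attr(res, "selected"), 3L)

  wide <- distance_constraint(3.9, sd = 100, dye_offset = 0.1)
  expect_true(all(filter_by_fret(mods, wide, 214, "B")$pass))
})

test_that("Shrake-Rupley surface area matches sphere oracles", {
  atom <- function(x, el = "C") {
    data.frame(elety = el, resid = "LIG", resno = seq_along(x), chain = "A",
               x = x, y = 0, z = 0, elesy = el)
  }
  r <- unname(vdw_radii()["C"]) + 1.4

  # isolated sphere: closed form, < 1% error
  s1 <- sasa(structure_model(atom(0)))
  expect_equal(as.numeric(s1), 4 * pi * r^2 / 100, tolerance = 0.01)

  # far-separated atoms: additivity
  s2 <- sasa(structure_model(atom(c(0, 50))))
  expect_equal(as.numeric(s2), 2 * 4 * pi * r^2 / 100, tolerance = 0.01)

  # fully coincident duplicates count one surface
  s3 <- sasa(structure_model(atom(c(0, 0))))
  expect_equal(as.numeric(s3), 4 * pi * r^2 / 100, tolerance = 0.01)

  # two overlapping spheres: analytic spherical-cap oracle
  d <- 2.0
  cap_h <- r - d / 2                       # equal radii
  exact <- 2 * (4 * pi * r^2 - 2 * pi * r * cap_h) / 100
  s4 <- sasa(structure_model(atom(c(0, d))), n_points = 960)
  expect_equal(as.numeric(s4), exact, tolerance = 0.01)
  # denser sampling gets closer to the oracle
  s4d <- sasa(structure_model(atom(c(0, d))), n_points = 7680)
  expect_lte(abs(as.numeric(s4d) - exact), abs(as.numeric(s4) - exact) + 1e-9)

  xe <- structure_model(atom(0, el = "XX"))
  expect_error(sasa(xe), "XX")
})

test_that("nonpolar solvation is linear in surface area", {
  expect_equal(nonpolar_solvation(0), 3.84)
  expect_equal(nonpolar_solvation(10), 2.27 * 10 + 3.84)
  expect_equal(nonpolar_solvation(10, gamma = 0), 3.84)
})

test_that("binding free energy composes identically from deltas and from
          per-species terms", {
  z <- compose_binding_energy(deltas = list(g_nonpol_solv = 0, e_mm = 0,
                                            minus_t_delta_s = 0,
                                            g_pol_solv = 0))
  expect_equal(z$g_b, 0)

  set.seed(5)
  cx <- as.list(stats::setNames(rnorm(4, 0, 100),
                                c("g_nonpol_solv", "e_mm",
                                  "minus_t_delta_s", "g_pol_solv")))
  rc <- lapply(cx, function(v) v + rnorm(1, 0, 50))
  lg <- lapply(cx, function(v) v + rnorm(1, 0, 50))
  via_species <- compose_binding_energy(cx, rc, lg)
  deltas <- mapply(function(a, b, d) a - b - d, cx, rc, lg,
                   SIMPLIFY = FALSE)
  via_deltas <- compose_binding_energy(deltas = deltas)
  expect_equal(via_species$g_b, via_deltas$g_b, tolerance = 1e-12)

  expect_error(compose_binding_energy(deltas = list(e_mm = 1)),
               "g_nonpol_solv")
  expect_error(compose_binding_energy(complex_terms = cx), "supply either")
})

test_that("distance-series statistics report mean, spread and persistent
          jumps", {
  const <- rep(3.8, 100)
  st <- distance_series_stats(seq(0, 9.9, 0.1), const)
  expect_equal(st$mean, 3.8)
  expect_equal(st$sd, 0)
  expect_equal(st$n_jumps, 0L)

  # one persistent step against fast fluctuations
  tr <- gen_trajectory_distances(synth_config(traj_sd_nm = 0.05),
                                 jumps = data.frame(time_ns = 5,
                                                    level_nm = 4.1),
                                 seed = 9)
  st2 <- distance_series_stats(tr$times, tr$distances)
  expect_equal(st2$n_jumps, 1L)
  expect_gt(st2$mean, 3.8)
  expect_lt(st2$mean, 4.1)

  expect_error(distance_series_stats(1:5, rep(1, 5)), "10 samples")
})
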