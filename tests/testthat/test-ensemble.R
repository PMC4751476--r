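test_that("backbone dihedrals recover construction and match the atan2 oracle", {
  n <- 8
  set.seed(21)
  phi <- c(NA, runif(n - 1, -160, -40))
  psi <- c(runif(n - 1, -80, 170), NA)
  cf <- build_backbone(paste(rep("A", n), collapse = ""), phi, psi)
  dh <- backbone_dihedrals(cf)
  expect_lt(max(abs(dh$phi[1, -1] - phi[-1])), 0.5)
  expect_lt(max(abs(dh$psi[1, -n] - psi[-n])), 0.5)

  # ideal trans extended chain
  ext <- build_backbone("AAAAA", rep(180, 5), rep(180, 5))
  dhe <- backbone_dihedrals(ext)
  expect_lt(max(abs(abs(dhe$phi[1, -1]) - 180)), 0.5)

  # planar cis four points -> 0
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)

  # arbitrary quadruples match the independent projection oracle
  for (s in 1:25) {
    set.seed(s)
    p <- lapply(1:4, function(i) rnorm(3, sd = 3))
    expect_equal(dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]]),
                 oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-9)
  }
})

test_that("Karplus closed forms and analytic bounds hold", {
  p <- karplus_parameters()
  mk_series <- function(phi) {
    structure(list(phi = matrix(phi, 1), psi = matrix(NA_real_, 1, length(phi)),
                   resno = seq_along(phi)), class = "dihedral_series")
  }
  # phi at the offset: cosine of zero
  j <- jcoupling_profile(mk_series(c(p$offset, p$offset)), p)
  expect_equal(j$value, rep(p$A + p$B + p$C, 2))
  # phi at offset + 90: cosine of 90
  j90 <- jcoupling_profile(mk_series(p$offset + 90), p)
  expect_equal(j90$value, p$C)
  # phi = -60 with offset 60: cos(-120) = -1/2
  jm <- jcoupling_profile(mk_series(-60), p)
  expect_equal(jm$value, 0.25 * p$A - 0.5 * p$B + p$C)

  # every ensemble-averaged J lies inside the closed-form range
  rng <- karplus_range(p)
  set.seed(3)
  ser <- mk_series(runif(30, -180, 180))
  ser$phi <- matrix(runif(300, -180, 180), 10, 30)
  jj <- jcoupling_profile(ser, p)
  expect_true(all(jj$value >= rng[1] - 1e-12 & jj$value <= rng[2] + 1e-12))
})

test_that("secondary shifts follow the coil-minus-observed convention", {
  coil <- observable_table(1:4, c(56, 56, 45.1, 58), nucleus = "CA")
  obs <- observable_table(1:4, c(56, 54, 45.1, 58), nucleus = "CA")
  d <- secondary_shift(obs, coil)
  expect_equal(d$value, c(0, 2, 0, 0))
  # flip gives the other literature convention
  expect_equal(secondary_shift(obs, coil, flip = TRUE)$value, c(0, -2, 0, 0))
  # residue absent from the reference stays missing
  coil3 <- observable_table(c(1, 2, 4), c(56, 56, 58), nucleus = "CA")
  d3 <- secondary_shift(obs, coil3)
  expect_equal(sum(is.na(d3$value)), 1)
  expect_true(is.na(d3$value[d3$residue == 3]))
  # nucleus mismatch is a validation error
  cb <- observable_table(1:4, c(19, 19, 19, 19), nucleus = "CB")
  expect_error(secondary_shift(obs, cb), "mismatch")
})

test_that("pearson matches the textbook formula and flags degeneracy", {
  x <- observable_table(1:3, c(1, 2, 3))
  expect_equal(pearson(x, x), 1)
  y <- observable_table(1:3, c(-1, -2, -3))
  expect_equal(pearson(x, y), -1)
  z <- observable_table(1:3, c(1, 2, 4))
  xv <- c(1, 2, 3); zv <- c(1, 2, 4)
  manual <- sum((xv - mean(xv)) * (zv - mean(zv))) /
    sqrt(sum((xv - mean(xv))^2) * sum((zv - mean(zv))^2))
  expect_equal(pearson(x, z), manual)
  expect_error(pearson(x, observable_table(1:3, c(2, 2, 2))), "variance")
  expect_error(pearson(observable_table(1:2, 1:2), observable_table(1:2, 2:3)),
               "3 shared")
})

test_that("secondary-structure assignment follows the documented regions", {
  mk <- function(phi, psi) structure(
    list(phi = matrix(phi, 1), psi = matrix(psi, 1), resno = seq_along(phi)),
    class = "dihedral_series")
  expect_true(all(assign_secondary_structure(mk(rep(-60, 6), rep(-45, 6))) == "H"))
  expect_true(all(assign_secondary_structure(mk(rep(-120, 4), rep(130, 4))) == "E"))
  # external assigner letters are grouped H/G/I -> H and E/B -> E
  expect_identical(as.vector(map_ss_classes(c("G", "I", "B"))), c("H", "H", "E"))
  expect_identical(as.vector(map_ss_classes(c("T", "C", "X"))), c("T", "C", "C"))
})

test_that("ss propensities average classes over frames and ignore frame order", {
  cls <- rbind(c("H", "E"), c("C", "E"))
  p <- ss_propensity(cls)
  expect_equal(p$H, c(50, 0))
  expect_equal(p$E, c(0, 100))
  expect_true(all(p$H + p$E + p$T <= 100 + 1e-12))
  # identical frames give 0/100
  p2 <- ss_propensity(rbind(c("H", "T"), c("H", "T")))
  expect_equal(p2$H, c(100, 0)); expect_equal(p2$T, c(0, 100))
  # frame order is irrelevant
  expect_equal(ss_propensity(cls[2:1, ]), p)
})

test_that("kabsch_rmsd is zero on self, rigid-invariant and matches oracles", {
  a <- random_conformer(10, seed = 31)
  expect_equal(kabsch_rmsd(a, a, "all"), 0, tolerance = 1e-12)
  R <- random_rotation(32)
  b <- a
  b$xyz <- a$xyz %*% t(R) + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  expect_lt(kabsch_rmsd(a, b, "all"), 1e-6)
  # symmetry
  set.seed(33); c2 <- a; c2$xyz <- a$xyz + matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(a, c2, "all"), kabsch_rmsd(c2, a, "all"),
               tolerance = 1e-12)
  # 4-point toys vs the grid-search oracle (oracle in angstrom)
  for (s in 1:3) {
    set.seed(s)
    A <- matrix(rnorm(12, sd = 2), 4, 3)
    B <- matrix(rnorm(12, sd = 2), 4, 3)
    ca <- conformer(A, data.frame(elety = "CA", resno = 1:4, resid = "ALA", chain = "A"))
    cb <- conformer(B, data.frame(elety = "CA", resno = 1:4, resid = "ALA", chain = "A"))
    expect_equal(kabsch_rmsd(ca, cb, "all") * 10, oracle_grid_rmsd(A, B, step = 4),
                 tolerance = 1e-2)
  }
  # independent library cross-check
  a2 <- random_conformer(12, seed = 35)
  b2 <- random_conformer(12, seed = 36)
  ref <- bio3d::rmsd(as.numeric(t(a2$xyz)), as.numeric(t(b2$xyz)),
                     fit = TRUE) / 10
  expect_equal(kabsch_rmsd(a2, b2, "all"), ref, tolerance = 1e-4)
  expect_error(kabsch_rmsd(random_conformer(2, 1), random_conformer(2, 1)))
})

test_that("radius of gyration closed forms", {
  mk <- function(xyz) conformer(xyz, data.frame(
    elety = "CA", resno = seq_len(nrow(xyz)), resid = "ALA", chain = "A"))
  expect_equal(radius_of_gyration(mk(matrix(c(1, 2, 3), 1))), 0)
  # two equal masses 1 nm apart -> 0.5 nm
  expect_equal(radius_of_gyration(mk(rbind(c(0, 0, 0), c(10, 0, 0)))), 0.5)
  # four equal masses at square corners, side 2 nm -> sqrt(2) nm
  sq <- rbind(c(0, 0, 0), c(20, 0, 0), c(20, 20, 0), c(0, 20, 0))
  expect_equal(radius_of_gyration(mk(sq)), sqrt(2))
})

test_that("free-energy surface obeys the Boltzmann closed form", {
  fes <- oligoring:::fes_from_counts(matrix(c(5, 5, 0, 1), 2, 2), T = 300)
  F <- fes$F
  # equal counts -> equal F
  expect_equal(F[1, 1], F[2, 1])
  # empty bin masked
  expect_true(is.na(F[1, 2]))
  # global minimum shifted to zero
  expect_equal(min(F, na.rm = TRUE), 0)
  # count ratio e:1 -> delta F = kT
  fes_e <- oligoring:::fes_from_counts(matrix(c(exp(1), 1), 1, 2), T = 300)
  expect_equal(diff(fes_e$F[1, ]), 0.0019872 * 300, tolerance = 1e-9)
  expect_equal(0.0019872 * 300, 0.59616)  # 0.596 kcal/mol at 300 K
  # scaling all counts leaves every delta F unchanged
  c1 <- matrix(c(4, 9, 2, 7), 2, 2)
  f1 <- oligoring:::fes_from_counts(c1, T = 300)$F
  f2 <- oligoring:::fes_from_counts(17 * c1, T = 300)$F
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("free_energy_surface bins frames and errors on empty input", {
  ens <- sample_ensemble(two_state_config(n_frames = 40, seed = 8))
  ref <- get_conformer(ens, 1)
  fes <- free_energy_surface(ens, ref, rmsd_breaks = 6, rg_breaks = 6)
  expect_equal(sum(fes$counts), 40)
  expect_equal(min(fes$F, na.rm = TRUE), 0)
  expect_true(all(is.na(fes$F[fes$counts == 0])))
})

test_that("gromos clustering matches the exhaustive reference on random ensembles", {
  # trivial cases
  cf <- random_conformer(8, seed = 41)
  same <- ensemble(list(cf, cf, cf))
  cs <- gromos_cluster(same, 0.2, selection = "all")
  expect_equal(length(cs$clusters), 1)
  expect_equal(sort(cs$clusters[[1]]), 1:3)
  # two tight groups of very different shape (superposition-invariant split)
  far <- random_conformer(8, seed = 42, spread = 20)
  two <- ensemble(list(cf, cf, far, far, far))
  cs2 <- gromos_cluster(two, 0.2, selection = "all")
  expect_equal(length(cs2$clusters), 2)
  expect_equal(lengths(cs2$clusters), c(3, 2))
  # random 15-frame ensembles vs the reference implementation
  for (s in 1:5) {
    base <- random_conformer(10, seed = 50 + s)
    set.seed(60 + s)
    frames <- lapply(1:15, function(i) {
      cf2 <- base
      cf2$xyz <- cf2$xyz + matrix(rnorm(30, sd = runif(1, 0.2, 2)), 10, 3)
      cf2
    })
    ens <- ensemble(frames)
    D <- oligoring:::rmsd_matrix(ens, "all")
    got <- gromos_cluster(ens, 0.15, selection = "all")
    ref <- oracle_gromos(D, 0.15)
    expect_identical(canonical_partition(got$clusters),
                     canonical_partition(ref$clusters))
    expect_identical(got$centers, ref$centers)
  }
  expect_error(gromos_cluster(same, 0), "positive")
})

test_that("minimal side-chain distances match brute force and exclude backbone", {
  # two single-atom side chains 4.4 A apart -> 0.44 nm
  atom <- data.frame(
    elety = c("N", "CA", "C", "CB", "N", "CA", "C", "CB"),
    resno = c(1, 1, 1, 1, 2, 2, 2, 2), resid = "ALA", chain = "A")
  xyz <- rbind(c(0, 5, 0), c(0, 6, 0), c(0, 7, 0), c(0, 0, 0),
               c(9, 5, 0), c(9, 6, 0), c(9, 7, 0), c(4.4, 0, 0))
  cf <- conformer(xyz, atom)
  expect_equal(min_sidechain_distance(cf, 1, 2), 0.44)
  expect_equal(min_sidechain_distance(cf, 1, 1), 0)
  expect_error(min_sidechain_distance(cf, 1, 9), "not found")
  # multi-atom toy equals exhaustive pairwise minimum
  set.seed(71)
  atom2 <- data.frame(
    elety = c("N", "CA", "C", "CB", "CG", "N", "CA", "C", "CB", "CG", "CD"),
    resno = c(rep(1, 5), rep(2, 6)), resid = c(rep("GLU", 5), rep("LYS", 6)),
    chain = "A")
  xyz2 <- matrix(rnorm(33, sd = 4), 11, 3)
  cf2 <- conformer(xyz2, atom2)
  sideA <- xyz2[4:5, , drop = FALSE]; sideB <- xyz2[9:11, , drop = FALSE]
  brute <- min(sqrt(outer(rowSums(sideA^2), rowSums(sideB^2), "+") -
                      2 * sideA %*% t(sideB))) / 10
  expect_equal(min_sidechain_distance(cf2, 1, 2), brute, tolerance = 1e-9)
})
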