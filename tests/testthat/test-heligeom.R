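test_that("transform extraction recovers identity, known transforms and noise floor", {
  p1 <- random_conformer(20, seed = 111)
  expect_lt(max(abs(transform_from_dimer(p1, p1)$R - diag(3))), 1e-9)

  R <- random_rotation(112); tv <- c(4, -7, 2)
  p2 <- p1; p2$xyz <- p1$xyz %*% t(R) + matrix(tv, 20, 3, byrow = TRUE)
  tr <- transform_from_dimer(p1, p2)
  expect_lt(max(abs(tr$R - R)), 1e-6)
  expect_lt(max(abs(tr$t - tv)), 1e-6)

  # noisy copy: residual equals the grid-search oracle minimum
  set.seed(113)
  small1 <- random_conformer(4, seed = 114, spread = 3)
  small2 <- small1
  small2$xyz <- small1$xyz %*% t(random_rotation(115)) +
    matrix(rnorm(12, sd = 0.1), 4, 3)
  fit <- transform_from_dimer(small1, small2)
  expect_equal(attr(fit, "rmsd"), oracle_grid_rmsd(small1$xyz, small2$xyz, step = 4),
               tolerance = 1e-2)
})

test_that("screw decomposition closed forms: axis-aligned and offset-axis cases", {
  # 90 deg about z with 2 A rise
  tr <- rigid_transform(rotation_matrix(c(0, 0, 1), 90), c(0, 0, 2))
  s <- screw_from_transform(tr)
  expect_equal(s$theta, 90, tolerance = 1e-9)
  expect_equal(abs(s$rise), 2, tolerance = 1e-9)
  d <- helical_descriptors(s)
  expect_equal(d$n, 4, tolerance = 1e-9)
  expect_equal(d$pitch, 0.8, tolerance = 1e-9)

  # 72 deg about an axis through (10, 0, 0), zero rise: pure cyclic
  R72 <- rotation_matrix(c(0, 0, 1), 72)
  p0 <- c(10, 0, 0)
  tr2 <- rigid_transform(R72, as.numeric((diag(3) - R72) %*% p0))
  s2 <- screw_from_transform(tr2)
  expect_equal(s2$axis_point[1], 10, tolerance = 1e-8)
  expect_equal(abs(s2$rise), 0, tolerance = 1e-9)
  d2 <- helical_descriptors(s2)
  expect_equal(d2$n, 5, tolerance = 1e-9)
  expect_equal(d2$pitch, 0, tolerance = 1e-9)

  # theta = 180 -> n = 2
  tr3 <- rigid_transform(rotation_matrix(c(0, 1, 0), 180), c(0, 3, 0))
  expect_equal(helical_descriptors(screw_from_transform(tr3))$n, 2,
               tolerance = 1e-6)

  # near-zero rotation flagged degenerate, not numbers
  s4 <- screw_from_transform(rigid_transform(diag(3), c(1, 2, 3)))
  expect_true(s4$degenerate)
  expect_error(helical_descriptors(s4), "degenerate")
})

test_that("screw decomposition round trips random transforms on test points", {
  set.seed(121)
  for (s in 1:20) {
    R <- random_rotation(130 + s)
    tv <- rnorm(3, sd = 5)
    tr <- rigid_transform(R, tv)
    sp <- screw_from_transform(tr)
    if (sp$degenerate) next
    back <- screw_to_transform(sp)
    pts <- matrix(rnorm(30, sd = 10), 10, 3)
    expect_lt(max(abs(apply_transform(tr, pts) - apply_transform(back, pts))),
              1e-6)
  }
})

test_that("helical descriptors reproduce the selected-assembly round trip", {
  # theta = 69.2308 deg, rise = 2.1154 A: 5.2 protomers/turn, 1.1 nm pitch
  s <- screw_params(c(0, 0, 0), c(0, 0, 1), 69.2308, 2.1154)
  d <- helical_descriptors(s)
  expect_equal(round(d$n, 1), 5.2)
  expect_equal(round(d$pitch, 1), 1.1)
  expect_equal(helical_descriptors(screw_params(c(0, 0, 0), c(0, 0, 1), 72, 0))$n, 5)
})

test_that("descriptors are invariant to global motion and protomer order", {
  prot <- random_conformer(15, seed = 141)
  s <- screw_params(c(3, -2, 0), vunit(c(1, 2, 2)), 65, 1.7)
  dim <- make_ideal_dimer(prot, s)
  tr <- transform_from_dimer(dim$protomer1, dim$protomer2)
  d0 <- helical_descriptors(screw_from_transform(tr))
  # global rigid motion of the whole dimer
  g <- rigid_transform(random_rotation(142), c(9, 9, -4))
  q1 <- dim$protomer1; q1$xyz <- apply_transform(g, q1$xyz)
  q2 <- dim$protomer2; q2$xyz <- apply_transform(g, q2$xyz)
  dg <- helical_descriptors(screw_from_transform(transform_from_dimer(q1, q2)))
  expect_equal(dg$n, d0$n, tolerance = 1e-8)
  expect_equal(dg$pitch, d0$pitch, tolerance = 1e-8)
  # reversing protomer order: same n and pitch, axis flipped
  sr <- screw_from_transform(transform_from_dimer(dim$protomer2, dim$protomer1))
  dr <- helical_descriptors(sr)
  expect_equal(dr$n, d0$n, tolerance = 1e-8)
  expect_equal(dr$pitch, d0$pitch, tolerance = 1e-8)
  s0 <- screw_from_transform(tr)
  # positive-theta convention: reversal flips the axis direction, so the
  # world axial displacement changes sign while handedness is preserved
  expect_equal(sr$axis_dir, -s0$axis_dir, tolerance = 1e-6)
  expect_equal(sr$rise * sr$axis_dir, -s0$rise * s0$axis_dir, tolerance = 1e-6)
  d0h <- helical_descriptors(s0); drh <- helical_descriptors(sr)
  expect_identical(drh$handedness, d0h$handedness)
})

test_that("extend_helix reproduces the dimer, keeps interfaces congruent and closes rings", {
  prot <- build_backbone("KLVFF", rep(-120, 5), rep(130, 5))
  s <- screw_params(c(14, 0, 0), c(0, 0, 1), 72, 0)
  tr <- screw_to_transform(s)
  asm <- extend_helix(prot, tr, 5)
  # N = 2 reproduces the input dimer exactly
  dim2 <- extend_helix(prot, tr, 2)
  ideal <- make_ideal_dimer(prot, s)
  expect_lt(max(abs(dim2$conformer$xyz -
                      rbind(ideal$protomer1$xyz, ideal$protomer2$xyz))), 1e-9)
  # consecutive-pair transform extracted from the output equals the input
  pA <- get_protomer(asm, 2); pB <- get_protomer(asm, 3)
  pA$atom$chain <- "A"; pB$atom$chain <- "A"
  tr_out <- transform_from_dimer(pA, pB)
  expect_lt(max(abs(tr_out$R - tr$R)), 1e-8)
  expect_lt(max(abs(tr_out$t - tr$t)), 1e-6)
  # group closure: protomer 5 -> protomer 1 under one more application
  p5 <- get_protomer(asm, 5)
  expect_lt(max(abs(apply_transform(tr, p5$xyz) - get_protomer(asm, 1)$xyz)),
            1e-8)
  expect_error(extend_helix(prot, tr, 1))
})

test_that("candidate filtering applies the inclusive-n strict-pitch rules", {
  crit <- selection_criteria(5, 6, 2)
  mk <- function(n, pitch_nm) {
    theta <- 360 / n
    rise <- pitch_nm * 10 / n
    screw_params(c(0, 0, 0), c(0, 0, 1), theta, rise)
  }
  cases <- expand.grid(n = c(4.9, 5.0, 5.2, 6.0, 6.1),
                       P = c(1.1, 1.9, 2.0, 2.5))
  screws <- mapply(mk, cases$n, cases$P, SIMPLIFY = FALSE)
  res <- filter_candidates(screws, crit)
  expected <- cases$n >= 5 & cases$n <= 6 & cases$P < 2
  expect_equal(res$pass, expected)
  expect_equal(res$n, cases$n, tolerance = 1e-9)
  expect_equal(res$pitch, cases$P, tolerance = 1e-9)
  # the selected assembly's parameters pass the printed criteria
  sel <- screw_params(c(0, 0, 0), c(0, 0, 1), 69.2308, 2.1154)
  expect_true(filter_candidates(list(sel), crit)$pass)
  # failure reasons name the violated rule
  expect_match(res$reason[abs(cases$n - 4.9) < 1e-9 & cases$P == 1.1], "below")
  expect_match(res$reason[abs(cases$n - 5.2) < 1e-9 & cases$P == 2.5], "pitch")
})

test_that("orientation filter compares marker radius to the protomer mean", {
  # protomer with last-residue CA pulled toward the future axis
  mkprot <- function(marker_r) {
    xyz <- rbind(c(20, 0, 0), c(21, 1, 3), c(22, -1, 6), c(marker_r, 0, 9))
    conformer(xyz, data.frame(elety = "CA", resno = 1:4, resid = "ALA",
                              chain = "A"))
  }
  tr <- screw_to_transform(screw_params(c(0, 0, 0), c(0, 0, 1), 72, 0))
  inward <- extend_helix(mkprot(2), tr, 5)
  expect_true(orientation_filter(inward, 4))
  outward <- extend_helix(mkprot(45), tr, 5)
  expect_false(orientation_filter(outward, 4))
  # marker exactly at the mean radius fails the strict inequality
  flat <- rbind(c(10, 0, 0), c(10, 0, 3), c(10, 0, 6), c(10, 0, 9))
  even <- extend_helix(conformer(flat, data.frame(elety = "CA", resno = 1:4,
                                                  resid = "ALA", chain = "A")),
                       tr, 5)
  expect_false(orientation_filter(even, 4))
})
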