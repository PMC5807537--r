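test_that("a convex body yields no cavities and small structures warn", {
  expect_warning(cv <- detect_cavities(
    structure_from_atoms(atom_row("A", 1, "ALA", "CB", "C", 0, 0, 0))),
    "too small")
  expect_length(cv, 0)
  ball <- ball_fixture()
  expect_length(detect_cavities(ball, grid_spacing = 1.0), 0)
})

test_that("the cup fixture yields one dominant cavity at the pocket centre", {
  cup <- cup_fixture()
  cav <- detect_cavities(cup, grid_spacing = 0.8, min_atoms = 30)
  expect_gte(length(cav), 1)
  main <- cav[[1]] # sorted by depth
  # pocket centre is on the cup axis below the rim
  expect_lt(sqrt(sum(main$centroid[1:2]^2)), 2 * 0.8)
  expect_lt(main$centroid[3], 0)
  expect_gt(main$depth, 0)
  # lining atoms lie within mouth_radius + depth of the centroid (with
  # the probe reach making contact possible at that range)
  lin <- as.matrix(cup$atoms[main$lining_atoms, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(lin, 2, main$centroid)^2))
  expect_true(all(d <= main$mouth_radius + main$depth + 4.5))
})

test_that("cavity points agree with a brute-force flood-fill oracle", {
  cup <- cup_fixture()
  gs <- 1.0
  cav <- detect_cavities(cup, grid_spacing = gs, min_atoms = 30,
                         min_points = 1)
  got <- do.call(rbind, lapply(cav, function(cv) cv$points))
  want <- oracle_cavity_points(cup, gs, probe_reach = 4.5)
  expect_equal(nrow(got), nrow(want))
  key <- function(m) sort(apply(round(m, 6), 1, paste, collapse = ","))
  expect_equal(key(got), key(want))
})

test_that("probe scoring vanishes at range and matches hand-summed terms", {
  rec <- structure_from_atoms(
    atom_row("A", 10, "GLU", c("CD", "OE1"), c("C", "O"),
             c(0, 0), c(0, 0), c(0, 1.25)))
  far <- probe_pose("S", rigid_transform(translation = c(50, 0, 0)))
  sc_far <- score_probe(rec, far)
  expect_equal(sc_far$delta_g, 0)
  expect_equal(unname(sc_far$components), c(0, 0, 0))

  # 9 A away: outside the solvation shell (8 A) but inside the
  # interaction cutoff, so vdW + electrostatics only, checked against an
  # explicit hand computation from the parameter tables
  pose <- probe_pose("S", rigid_transform(translation = c(9, 0, 0)))
  sc <- score_probe(rec, pose)
  pxyz <- rbind(c(9, 0, 0), c(9 + 1.43 * cos(pi / 3),
                              1.43 * sin(pi / 3), 0))
  rxyz <- rbind(c(0, 0, 0), c(0, 0, 1.25))
  q_p <- c(0, -0.30); q_r <- c(0, -0.50)
  rmin_p <- c(1.90, 1.70); eps_p <- c(0.10, 0.21)
  vdw <- 0; elec <- 0
  n_near <- 0 # no receptor atom within 6.5 A of the probe centroid
  f_b <- min(1, n_near / 30)
  for (i in 1:2) for (j in 1:2) {
    d <- sqrt(sum((pxyz[i, ] - rxyz[j, ])^2))
    rm <- rmin_p[i] + rmin_p[j]
    ep <- sqrt(eps_p[i] * eps_p[j])
    vdw <- vdw + ep * ((rm / d)^12 - 2 * (rm / d)^6)
    elec <- elec + 332.0637 * q_p[i] * q_r[j] /
      (4 * d * (1 - 0.5 * f_b) * d)
  }
  expect_equal(unname(sc$components["vdw"]), vdw, tolerance = 1e-8)
  expect_equal(unname(sc$components["electrostatic"]), elec,
               tolerance = 1e-8)
  expect_equal(unname(sc$components["solvation"]), 0)

  # clashes score +Inf
  clash <- probe_pose("S", rigid_transform(translation = c(0.5, 0, 0)))
  expect_identical(score_probe(rec, clash)$delta_g, Inf)
})

test_that("zeroed charges give exactly zero electrostatics", {
  rec <- structure_from_atoms(
    atom_row("A", 10, "ALA", c("CB", "CA"), c("C", "C"),
             c(0, 1.5), 0, 0))  # apolar receptor, all charges zero
  pose <- probe_pose("P", rigid_transform(translation = c(6, 0, 0)))
  sc <- score_probe(rec, pose)
  expect_identical(unname(sc$components["electrostatic"]), 0)
})

test_that("a lysine probe binds the anionic cup with dominant electrostatics", {
  cup <- cup_fixture()
  # hand-placed pose: side chain pointing down the pocket axis, N-zeta
  # ~2.5 A from the carboxylate oxygens
  rot <- vinlock:::axis_angle_rotation(c(0, 1, 0), pi / 2) # +x -> -z
  pose <- probe_pose("K", rigid_transform(rot, c(0, 0, 2.5)))
  sc <- score_probe(cup, pose)
  expect_lt(sc$delta_g, 0)
  expect_lt(sc$components[["electrostatic"]], sc$components[["vdw"]])
  expect_equal(sc$delta_g, sum(sc$components))
  # optimised mapping finds a strong favourable spot in the same cavity
  cav <- detect_cavities(cup, grid_spacing = 0.8, min_atoms = 30)
  sp <- map_anchoring_spots(cup, "K", seed = 3, n_starts = 20,
                            cavities = cav[1], maxit = 50)
  expect_length(sp, 1)
  expect_lt(sp[[1]]$delta_g, 0)
  expect_true(sp[[1]]$strong)
  expect_lte(sp[[1]]$delta_g, sc$delta_g + 1e-6) # optimiser at least as good
})

test_that("spot mapping is reproducible under a fixed seed", {
  cup <- cup_fixture()
  cav <- detect_cavities(cup, grid_spacing = 0.8, min_atoms = 30)
  a <- map_anchoring_spots(cup, c("K", "S"), seed = 11, n_starts = 6,
                           cavities = cav[1], maxit = 40)
  b <- map_anchoring_spots(cup, c("K", "S"), seed = 11, n_starts = 6,
                           cavities = cav[1], maxit = 40)
  expect_identical(spots_table(a), spots_table(b))
})

test_that("probe scoring is invariant under joint rigid motion", {
  cup <- cup_fixture()
  pose <- probe_pose("K", rigid_transform(translation = c(0, 0, 2)))
  sc <- score_probe(cup, pose)
  tr <- fixed_rigid_motion()
  cup2 <- transform_structure(cup, tr)
  pose2 <- pose
  pose2$transform <- rigid_transform(
    tr$rotation %*% pose$transform$rotation,
    as.numeric(tr$rotation %*% pose$transform$translation) +
      tr$translation)
  sc2 <- score_probe(cup2, pose2)
  expect_equal(sc2$delta_g, sc$delta_g, tolerance = 1e-6)
})

test_that("spots match partner residues of the probe type, none for empty partner", {
  cup <- cup_fixture()
  cav <- detect_cavities(cup, grid_spacing = 0.8, min_atoms = 30)
  sp <- map_anchoring_spots(cup, "K", seed = 3, n_starts = 15,
                            cavities = cav[1], maxit = 50)
  ctr <- colMeans(vinlock:::pose_coords(sp[[1]]$best_pose))
  partner <- structure_from_atoms(atom_row(
    "B", 975, "LYS", c("CB", "CG", "CD", "CE", "NZ"), c(rep("C", 4), "N"),
    ctr[1] + c(-0.2, 0.6, -0.2, 0.6, 0), ctr[2] + c(0, 0.4, 0.8, 1.2, 0.6),
    ctr[3] + c(0, 0, 0, 0, 0)))
  matched <- match_spots_to_partner(sp, partner)
  expect_equal(matched[[1]]$matched_residue, "K975")
  empty <- structure_from_atoms(atom_row("B", 1, "ALA", "CB", "C",
                                         ctr[1], ctr[2], ctr[3]))
  expect_true(is.na(match_spots_to_partner(sp, empty)[[1]]$matched_residue))
})
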