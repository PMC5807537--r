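test_that("projection CCS matches analytic disks", {
  s1 <- structure_from_atoms(atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0))
  cc <- pa_ccs(s1, gas_radius = 1.0, n_orientations = 2000)
  expect_equal(cc$value, pi * (1.7 + 1)^2, tolerance = 0.005)
  expect_gt(cc$sd, 0)
  # two atoms far apart: twice the single-disk area
  s2 <- structure_from_atoms(atom_row("A", 1:2, "ALA", "CA", "C",
                                      c(0, 200), 0, 0))
  cc2 <- pa_ccs(s2, n_orientations = 2000)
  expect_equal(cc2$value, 2 * pi * 2.7^2, tolerance = 0.01)
})

test_that("two-sphere projection matches the orientation-average oracle", {
  L <- 3.0
  s <- structure_from_atoms(atom_row("A", 1:2, "ALA", "CA", "C",
                                     c(0, L), 0, 0))
  got <- pa_ccs(s, gas_radius = 1.0, n_orientations = 4000,
                grid_spacing = 0.5)$value
  want <- oracle_two_disk_projection(L, 2.7)
  expect_equal(got, want, tolerance = 0.01)
})

test_that("projection CCS is rigid-motion invariant and monotone in atoms", {
  set.seed(4)
  xyz <- matrix(rnorm(3 * 120, sd = 6), ncol = 3)
  s <- structure_from_atoms(carbon_cluster(xyz))
  v1 <- pa_ccs(s, n_orientations = 3000, seed = 42)$value
  v2 <- pa_ccs(transform_structure(s, fixed_rigid_motion()),
               n_orientations = 3000, seed = 42)$value
  expect_equal(v2, v1, tolerance = 1e-3)
  # adding an atom never shrinks the shadow
  bigger <- structure_from_atoms(rbind(s$atoms,
                                       atom_row("A", 200, "ALA", "CA",
                                                "C", 20, 0, 0)))
  expect_gte(pa_ccs(bigger, n_orientations = 1000, seed = 42)$value, v1)
})

test_that("orientation averaging converges", {
  set.seed(9)
  s <- structure_from_atoms(carbon_cluster(matrix(rnorm(90, sd = 5),
                                                  ncol = 3)))
  a <- pa_ccs(s, n_orientations = 1500, seed = 1)
  b <- pa_ccs(s, n_orientations = 3000, seed = 1)
  expect_lt(abs(a$value - b$value), 3 * (a$sd + b$sd))
})

test_that("identity displacement reproduces the closed state", {
  s <- toy_vinculin()
  p <- default_domain_partition()
  m <- displace_tail(s, p, rigid_transform(), n_orientations = 300)
  expect_equal(m$structure$atoms, s$atoms)
  expect_equal(m$ccs$value, pa_ccs(s, n_orientations = 300)$value)
  expect_equal(m$separation,
               sqrt(sum((vinlock:::marker_position(s, 875) -
                           vinlock:::marker_position(s, 836))^2)))
})

test_that("displacement moves only the tail module and screens clashes", {
  s <- toy_vinculin()
  p <- default_domain_partition()
  tr <- rigid_transform(translation = c(0, 40, 0))
  m <- displace_tail(s, p, tr, n_orientations = 300)
  head_idx <- m$structure$atoms$resno <= 836
  expect_equal(m$structure$atoms[head_idx, ], s$atoms[head_idx, ])
  moved_idx <- m$structure$atoms$resno >= 837
  expect_equal(as.matrix(m$structure$atoms[moved_idx, c("x", "y", "z")]),
               as.matrix(s$atoms[moved_idx, c("x", "y", "z")]) +
                 rep(c(0, 40, 0), each = sum(moved_idx)),
               ignore_attr = TRUE)
  # a transform that stacks the tail onto the head is rejected
  d1_ctr <- colMeans(s$atoms[s$atoms$resno <= 252, c("x", "y", "z")])
  vt_ctr <- colMeans(s$atoms[s$atoms$resno >= 836, c("x", "y", "z")])
  expect_error(displace_tail(s, p, rigid_transform(
    translation = as.numeric(d1_ctr - vt_ctr)), compute_ccs = FALSE),
    "overlaps")
  # a transform beyond the tether is rejected
  expect_error(displace_tail(s, p, rigid_transform(
    translation = c(0, 500, 0)), compute_ccs = FALSE), "max_tether")
})

test_that("semi-open geometry separates one interface while keeping the other", {
  s <- toy_vinculin()
  p <- default_domain_partition()
  # pull hinge+Vt away from D4 along -x while keeping contact with D1
  # (clash screening relaxed: this checks the interface bookkeeping)
  m <- displace_tail(s, p, rigid_transform(translation = c(-5, 0, 0)),
                     compute_ccs = FALSE, max_clashes = Inf)
  a_d4 <- interface_area(m$structure, p, "Vt", "D4", n_points = 240)
  a_d1 <- interface_area(m$structure, p, "Vt", "D1", n_points = 240)
  expect_equal(a_d4$mean_area, 0, tolerance = 1)
  expect_gt(a_d1$mean_area, 0)
})

test_that("opening scans are monotone, deterministic and flag infeasible rows", {
  s <- toy_vinculin()
  p <- default_domain_partition()
  sc <- scan_opening(s, p, c(0, 30, 60, 90), n_poses_per_sep = 3,
                     seed = 5)
  expect_true(all(sc$feasible))
  expect_true(all(diff(sc$mean_ccs) > 0))
  expect_equal(sc$mean_ccs[1], pa_ccs(s, n_orientations = 300)$value)
  sc2 <- scan_opening(s, p, c(0, 30, 60, 90), n_poses_per_sep = 3,
                      seed = 5)
  expect_identical(sc, sc2)
  inf <- scan_opening(s, p, c(0, 1000), n_poses_per_sep = 2, seed = 5)
  expect_false(inf$feasible[2])
})

test_that("state-model assignment is one-to-many with sensible edge cases", {
  scan <- data.frame(displacement = c(0, 30, 60),
                     separation = c(8, 38, 68),
                     mean_ccs = c(900, 1030, 1070), sd_ccs = 0,
                     n_poses = 3, feasible = TRUE)
  hits <- assign_state_models(c(SO = 1050, O = 1068), scan,
                              tolerance = 0.02)
  expect_equal(hits$SO$mean_ccs, c(1030, 1070)) # deliberately one-to-many
  expect_equal(hits$O$mean_ccs, 1070)
  expect_warning(none <- assign_state_models(c(C = 500), scan),
                 "no scan model")
  expect_equal(nrow(none$C), 0)
  one <- assign_state_models(c(X = 900), scan, tolerance = 1e-6)
  expect_equal(one$X$mean_ccs, 900)
})
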