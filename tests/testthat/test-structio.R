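test_that("PDB round trip preserves atoms and coordinates", {
  atoms <- atom_row("A", 1:3, c("LYS", "GLU", "ALA"), c("CA", "CA", "CA"),
                    "C", c(0, 3.8, 7.6), c(0, 0, 1), c(0, 1, 0))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(atoms, path)
  s <- read_structure(path)
  expect_s3_class(s, "vl_structure")
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$x, atoms$x, tolerance = 1e-6)
  expect_equal(s$atoms$resid, atoms$resid)
})

test_that("the PDB writer round-trips through the reader", {
  s <- toy_vinculin()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(s, path)
  s2 <- read_structure(path)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$resno, s$atoms$resno)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-6)
})

test_that("unreadable and empty files are rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", path)
  expect_error(read_structure(path), "zero polymer atoms|unreadable")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("zero-occupancy atoms are dropped and altlocs resolved", {
  # two altloc copies of one atom, plus a zero-occupancy atom
  lines <- c(
    "ATOM      1  CA ALYS A   1       0.000   0.000   0.000  0.70  0.00           C",
    "ATOM      2  CA BLYS A   1       1.000   0.000   0.000  0.30  0.00           C",
    "ATOM      3  CB  LYS A   1       2.000   0.000   0.000  0.00  0.00           C",
    "ATOM      4  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 2)
  ca1 <- s$atoms[s$atoms$resno == 1, ]
  expect_equal(ca1$x, 0) # highest-occupancy altloc kept
})

test_that("domain selection respects partition ranges and chains", {
  s <- toy_vinculin()
  p <- default_domain_partition()
  vt <- select_domain(s, p, "Vt")
  expect_true(all(vt$atoms$resno >= 896 & vt$atoms$resno <= 1066))
  expect_error(select_domain(s, p, "D9"), "unknown domain")
  expect_error(select_domain(s, p, "D1", chain = "Z"), "unknown chain")
  expect_warning(sel <- select_domain(
    structure_from_atoms(atom_row("A", 500, "ALA", "CA", "C", 0, 0, 0)),
    p, "Vt"), "empty")
  expect_equal(nrow(sel$atoms), 0)
  # identity: fixture spanning one range returns all atoms
  s3 <- structure_from_atoms(atom_row("A", 900:902, "ALA", "CA", "C",
                                      0:2, 0, 0))
  expect_equal(nrow(select_domain(s3, p, "Vt")$atoms), 3)
})

test_that("partition YAML round trip matches the built-in default", {
  p <- default_domain_partition()
  y <- read_domain_partition(system.file("extdata",
                                         "partition_vinculin.yaml",
                                         package = "vinlock"))
  expect_equal(unclass(p)[names(p)],
               unclass(y)[names(p)],
               ignore_attr = TRUE)
  expect_equal(attr(y, "tail_offset_metavinculin"), 68)
})

test_that("SASA matches the analytic sphere and is additive at range", {
  s1 <- structure_from_atoms(atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0))
  a1 <- sum(sasa(s1, 1.4, 960))
  expect_equal(a1, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  s2 <- structure_from_atoms(atom_row("A", 1:2, "ALA", "CA", "C",
                                      c(0, 100), 0, 0))
  expect_equal(sum(sasa(s2, 1.4, 960)), 2 * a1, tolerance = 1e-9)
})

test_that("overlapping-sphere SASA agrees with a quadrature oracle", {
  r <- 1.7; probe <- 1.4
  for (d in c(1.0, 2.5, 4.0)) {
    s <- structure_from_atoms(atom_row("A", 1:2, "ALA", "CA", "C",
                                       c(0, d), 0, 0))
    got <- sum(sasa(s, probe, 2000))
    want <- oracle_two_sphere_sasa(c(0, 0, 0), c(d, 0, 0), r, r, probe)
    expect_equal(got, want, tolerance = 0.01)
  }
  # coincident duplicates split the shared surface instead of doubling
  s0 <- structure_from_atoms(atom_row("A", 1:2, "ALA", "CA", "C",
                                      c(0, 0), 0, 0))
  expect_equal(sum(sasa(s0, probe, 960)), 4 * pi * (r + probe)^2,
               tolerance = 0.01)
})

test_that("hydrogen bonds are tiered, sorted and symmetric in groups", {
  donor <- structure_from_atoms(
    atom_row("A", 975, "LYS", c("CA", "NZ"), c("C", "N"),
             c(0, 0), c(0, 0), c(3, 0)))
  acceptor <- structure_from_atoms(
    atom_row("A", 772, "GLU", c("CA", "O"), c("C", "O"),
             c(5, 2.9), c(0, 0), c(3, 0)))
  hb <- find_hbonds(donor, acceptor, 3.5, 4.0)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9)
  expect_equal(hb$tier, "short")
  expect_equal(hb$donor_atom, "NZ")
  expect_equal(hb$acceptor_atom, "O")
  # symmetry: swapping the groups resolves the same donor/acceptor pair
  hb2 <- find_hbonds(acceptor, donor, 3.5, 4.0)
  expect_equal(hb2$donor_atom, hb$donor_atom)
  expect_equal(hb2$distance, hb$distance)
  # long tier
  acceptor_far <- structure_from_atoms(
    atom_row("A", 772, "GLU", "O", "O", 3.8, 0, 0))
  expect_equal(find_hbonds(donor, acceptor_far)$tier, "long")
  # beyond the cutoff: empty
  acceptor_out <- structure_from_atoms(
    atom_row("A", 772, "GLU", "O", "O", 5.0, 0, 0))
  expect_equal(nrow(find_hbonds(donor, acceptor_out)), 0)
  expect_error(find_hbonds(donor, acceptor, 4.0, 3.5))
})

test_that("proline backbone N does not donate", {
  pro <- structure_from_atoms(atom_row("A", 10, "PRO", "N", "N", 0, 0, 0))
  acc <- structure_from_atoms(atom_row("A", 20, "GLU", "O", "O", 3, 0, 0))
  expect_equal(nrow(find_hbonds(pro, acc)), 0)
  gly <- structure_from_atoms(atom_row("A", 10, "GLY", "N", "N", 0, 0, 0))
  expect_equal(nrow(find_hbonds(gly, acc)), 1)
})

test_that("interface area is symmetric, rigid-motion invariant and zero at range", {
  s <- toy_vinculin()
  p <- default_domain_partition()
  ab <- interface_area(s, p, "Vt", "D4", n_points = 480)
  ba <- interface_area(s, p, "D4", "Vt", n_points = 480)
  expect_gt(ab$mean_area, 0)
  expect_equal(ab$mean_area, ba$mean_area, tolerance = 1e-9)
  moved <- transform_structure(s, fixed_rigid_motion())
  ab2 <- interface_area(moved, p, "Vt", "D4", n_points = 480)
  expect_equal(ab2$mean_area, ab$mean_area, tolerance = 1e-6)
  # far-apart domains: zero area, no hydrogen bonds, no error
  far <- structure_from_atoms(rbind(
    domain_blob(1:27, c(0, 0, 0)), domain_blob(896:922, c(100, 0, 0))))
  rep0 <- interface_area(far, p, "Vt", "D1", n_points = 240)
  expect_equal(rep0$mean_area, 0)
  expect_equal(nrow(rep0$hbonds), 0)
})

test_that("per-chain interface areas average into mean_area", {
  at <- rbind(domain_blob(718:744, c(0, 0, 0), chain = "A"),
              domain_blob(896:922, c(5, 0, 0), chain = "A"),
              domain_blob(718:744, c(100, 0, 0), chain = "B"),
              domain_blob(896:922, c(105.5, 0, 0), chain = "B"))
  s <- structure_from_atoms(at)
  rep <- interface_area(s, default_domain_partition(), "Vt", "D4",
                        n_points = 480)
  expect_equal(length(rep$per_chain_area), 2)
  expect_equal(rep$mean_area, mean(rep$per_chain_area))
  expect_gt(rep$per_chain_area[["A"]], rep$per_chain_area[["B"]])
})

test_that("interface comparison matches bonds across numbering offsets", {
  mk_report <- function(donor_resno) {
    hb <- data.frame(chain = "A", donor_resno = donor_resno,
                     donor_resid = "LYS", donor_atom = "NZ",
                     acceptor_resno = 772, acceptor_resid = "GLU",
                     acceptor_atom = "O", distance = 2.35,
                     tier = "short", stringsAsFactors = FALSE)
    structure(list(domain_a = "Vt", domain_b = "D4",
                   per_chain_area = c(A = 700), mean_area = 700,
                   hbonds = hb, character = "electrostatic",
                   source_id = "x"), class = "interface_report")
  }
  ref <- mk_report(975)
  # identity: no losses, no deltas
  same <- compare_interfaces(ref, ref)
  expect_equal(nrow(same$lost), 0)
  expect_equal(same$matched$delta, 0)
  expect_equal(same$area_delta, 0)
  # +68 tail offset: K975 matches K1043
  meta <- mk_report(1043)
  meta$hbonds$distance <- 3.02
  cmp <- compare_interfaces(ref, meta, offset = 68)
  expect_equal(nrow(cmp$lost), 0)
  expect_equal(cmp$matched$delta, 3.02 - 2.35, tolerance = 1e-9)
  # removed bond reported as lost
  gone <- mk_report(975)
  gone$hbonds <- gone$hbonds[0, ]
  cmp2 <- compare_interfaces(ref, gone)
  expect_equal(nrow(cmp2$lost), 1)
  expect_error(compare_interfaces(ref, structure(
    modifyList(unclass(ref), list(domain_b = "D1")),
    class = "interface_report")), "different domain pairs")
})
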