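# Shared fixtures and independent oracles, all built in code.

# ---- structure builders ----------------------------------------------------

atom_row <- function(chain, resno, resid, elety, element, x, y, z,
                     occ = 1) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             element = element, x = x, y = y, z = z, occ = occ,
             stringsAsFactors = FALSE)
}

# n carbon pseudo-atoms at given coordinates
carbon_cluster <- function(xyz, resno_start = 1, chain = "A") {
  n <- nrow(xyz)
  atom_row(chain, resno_start + seq_len(n) - 1, "ALA", "CB", "C",
           xyz[, 1], xyz[, 2], xyz[, 3])
}

# cubic blob of CA atoms covering the given residue numbers
domain_blob <- function(resnos, center, spacing = 2.2, chain = "A") {
  k <- ceiling(length(resnos)^(1 / 3))
  g <- as.matrix(expand.grid(0:(k - 1), 0:(k - 1),
                             0:(k - 1)))[seq_along(resnos), ,
                                         drop = FALSE] * spacing
  atom_row(chain, resnos, "ALA", "CA", "C", g[, 1] + center[1],
           g[, 2] + center[2], g[, 3] + center[3])
}

# toy full-length structure on the vinculin residue numbering: a Vt blob
# bridging D1 and D4 blobs (in contact with both), hinge blob carrying
# marker residue 875 beyond D4
toy_vinculin <- function() {
  at <- rbind(domain_blob(1:252, c(-17, 0, 0)),     # D1: x -17..-3.8
              domain_blob(718:836, c(12, 0, 0)),    # D4: x 12..20.8
              domain_blob(837:895, c(24, 0, 0)),    # hinge
              domain_blob(896:1066, c(-1, 2, 2)))   # Vt: x -1..10
  structure_from_atoms(at, "toy")
}

# hemispherical "cup" of carbons with a glutamate carboxylate at the
# bottom: one concave pocket, everything else convex
cup_fixture <- function() {
  pts <- list()
  R <- 6
  for (th in seq(0, pi / 2, length.out = 7)) {
    nphi <- max(3, round(12 * sin(th) + 1))
    for (ph in seq(0, 2 * pi, length.out = nphi)[-1])
      pts[[length(pts) + 1]] <- c(R * sin(th) * cos(ph),
                                  R * sin(th) * sin(ph),
                                  -R * cos(th))
  }
  xyz <- unique(round(do.call(rbind, pts), 3))
  atoms <- carbon_cluster(xyz)
  glu <- atom_row("A", nrow(xyz) + 1, "GLU", c("CD", "OE1", "OE2"),
                  c("C", "O", "O"), c(0, 0.6, -0.6), c(0, 1.0, 1.0),
                  c(-5.2, -4.9, -4.9))
  structure_from_atoms(rbind(atoms, glu), "cup")
}

# solid convex ball of carbons (no pockets)
ball_fixture <- function(radius = 5, spacing = 1.8) {
  g <- seq(-radius, radius, by = spacing)
  xyz <- as.matrix(expand.grid(g, g, g))
  xyz <- xyz[rowSums(xyz^2) <= radius^2, ]
  structure_from_atoms(carbon_cluster(xyz), "ball")
}

# write a minimal PDB file for read_structure tests
write_mini_pdb <- function(atoms, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$elety) < 4, paste0(" ", atoms$elety), atoms$elety),
    " ", atoms$resid, atoms$chain, atoms$resno, " ",
    atoms$x, atoms$y, atoms$z, atoms$occ, 0, atoms$element)
  writeLines(c(lines, "END"), path)
  path
}

# user-supplied deposited vinculin structure (PDB 1TR2); not
# redistributed with the package. Looked up via
# options(vinlock.structure_dir = ...) or the package extdata directory.
deposited_structure_path <- function() {
  dirs <- c(getOption("vinlock.structure_dir"),
            system.file("extdata", package = "vinlock"),
            file.path(path.expand("~"), "structures"))
  for (d in dirs) {
    if (is.null(d) || !nzchar(d)) next
    for (f in c("1tr2.pdb", "1TR2.pdb", "1tr2.cif", "1TR2.cif")) {
      p <- file.path(d, f)
      if (file.exists(p)) return(p)
    }
  }
  NA_character_
}

# ---- independent oracles ---------------------------------------------------

# brute-force spherical quadrature of two-sphere SASA (lat/long grid,
# deliberately a different point set and code path than the package)
oracle_two_sphere_sasa <- function(c1, c2, r1, r2, probe, n_lat = 200) {
  area_one <- function(ca, cb, ra, rb) {
    Ra <- ra + probe; Rb <- rb + probe
    th <- (seq_len(n_lat) - 0.5) / n_lat * pi
    acc <- 0
    for (t in th) {
      nph <- max(8, round(2 * n_lat * sin(t)))
      ph <- (seq_len(nph) - 0.5) / nph * 2 * pi
      p <- cbind(ca[1] + Ra * sin(t) * cos(ph),
                 ca[2] + Ra * sin(t) * sin(ph),
                 ca[3] + Ra * cos(t))
      free <- sqrt(rowSums(sweep(p, 2, cb)^2)) >= Rb
      acc <- acc + sum(free) * sin(t) * (pi / n_lat) * (2 * pi / nph)
    }
    Ra^2 * acc
  }
  area_one(c1, c2, r1, r2) + area_one(c2, c1, r2, r1)
}

# exact orientation-averaged projected area of two equal disks from two
# spheres (centres L apart, inflated radius r): numeric integral over the
# uniform cosine of the axis-view angle
oracle_two_disk_projection <- function(L, r) {
  lens <- function(s) {
    if (s >= 2 * r) return(0)
    2 * r^2 * acos(s / (2 * r)) - (s / 2) * sqrt(4 * r^2 - s^2)
  }
  f <- Vectorize(function(u) {
    s <- L * sqrt(1 - u^2)
    2 * pi * r^2 - lens(s)
  })
  stats::integrate(f, 0, 1, rel.tol = 1e-9)$value
}

# brute-force re-implementation of the cavity-point definition (plain
# loops over grid cells and the 26 ray directions; no package code paths)
oracle_cavity_points <- function(s, grid_spacing, probe_reach,
                                 enclosure_cutoff = 0.70,
                                 ray_length = 6) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  rad <- vinlock:::vdw_radius(s$atoms$element)
  lo <- apply(xyz, 2, min) - probe_reach - grid_spacing
  hi <- apply(xyz, 2, max) + probe_reach + grid_spacing
  gx <- seq(lo[1], hi[1], by = grid_spacing)
  gy <- seq(lo[2], hi[2], by = grid_spacing)
  gz <- seq(lo[3], hi[3], by = grid_spacing)
  inside_fn <- function(p) {
    d <- sqrt(colSums((t(xyz) - p)^2))
    any(d < rad)
  }
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  out <- NULL
  for (ix in seq_along(gx)) for (iy in seq_along(gy))
    for (iz in seq_along(gz)) {
      p <- c(gx[ix], gy[iy], gz[iz])
      d <- sqrt(colSums((t(xyz) - p)^2))
      if (any(d < rad)) next          # occupied
      if (!any(d <= probe_reach)) next # no atom contact
      hits <- 0
      for (di in seq_len(nrow(dirs))) {
        v <- dirs[di, ]
        steps <- max(1, floor(ray_length /
                                (grid_spacing * sqrt(sum(v^2)))))
        for (k in seq_len(steps)) {
          jx <- ix + k * v[1]; jy <- iy + k * v[2]; jz <- iz + k * v[3]
          if (jx < 1 || jy < 1 || jz < 1 || jx > length(gx) ||
              jy > length(gy) || jz > length(gz)) break
          if (inside_fn(c(gx[jx], gy[jy], gz[jz]))) {
            hits <- hits + 1
            break
          }
        }
      }
      if (hits / nrow(dirs) >= enclosure_cutoff)
        out <- rbind(out, p, deparse.level = 0)
    }
  out
}

# deterministic rotation+translation used in invariance tests
fixed_rigid_motion <- function() {
  rot <- vinlock:::axis_angle_rotation(c(1, 2, 3), 1.1)
  rigid_transform(rot, c(5, -3, 2))
}

transform_structure <- function(s, tr) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  s$atoms[, c("x", "y", "z")] <- apply_transform(xyz, tr)
  s
}
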