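#' @title Anchoring-spot mapping
#' @name anchors
#' @description Detection of small surface cavities and scoring of single
#'   amino-acid side-chain probes placed in them. An anchoring spot is a
#'   cavity plus the probe type that binds it most favourably; spots with
#'   binding free energy below a cutoff are "strong" and are compared with
#'   the residues observed across a domain-domain interface. The scoring
#'   function is a coarse semi-empirical sum of Lennard-Jones, screened
#'   Coulomb and atomic-solvation terms; the package makes no claim of
#'   reproducing literature binding energies numerically - recovery of
#'   anchor residue identities is the supported use.
NULL

# ---- coarse force-field tables --------------------------------------------

# Lennard-Jones parameters by element (rmin in Angstrom, eps in kcal/mol).
LJ_RMIN <- c(C = 1.90, N = 1.80, O = 1.70, S = 2.00, H = 1.20, P = 2.10)
LJ_EPS <- c(C = 0.10, N = 0.16, O = 0.21, S = 0.25, H = 0.02, P = 0.20)

lj_params <- function(element) {
  el <- toupper(element)
  bad <- !(el %in% names(LJ_RMIN))
  if (any(bad)) stop("no force-field parameters for atom element(s): ",
                     paste(unique(el[bad]), collapse = ", "))
  list(rmin = unname(LJ_RMIN[el]), eps = unname(LJ_EPS[el]))
}

# Coarse partial charges by residue chemistry (units of e). Formal charges
# are spread over the terminal polar atoms; backbone amide dipole is
# represented by +/- partial charges on N and O.
atom_charge <- function(resid, elety) {
  q <- numeric(length(resid))
  q[elety == "O"] <- -0.40
  q[elety == "OXT"] <- -0.50
  q[elety == "N"] <- 0.25
  q[resid %in% c("ASP") & elety %in% c("OD1", "OD2")] <- -0.50
  q[resid %in% c("GLU") & elety %in% c("OE1", "OE2")] <- -0.50
  q[resid == "LYS" & elety == "NZ"] <- 1.00
  q[resid == "ARG" & elety %in% c("NH1", "NH2")] <- 0.50
  q[resid == "ARG" & elety == "NE"] <- 0.20
  q[resid == "HIS" & elety %in% c("ND1", "NE2")] <- 0.15
  q[resid %in% c("ASN") & elety == "OD1"] <- -0.40
  q[resid %in% c("ASN") & elety == "ND2"] <- 0.30
  q[resid %in% c("GLN") & elety == "OE1"] <- -0.40
  q[resid %in% c("GLN") & elety == "NE2"] <- 0.30
  q[resid %in% c("SER", "THR") & elety %in% c("OG", "OG1")] <- -0.30
  q[resid == "TYR" & elety == "OH"] <- -0.25
  q
}

# Atomic solvation parameters (kcal/mol/A^2) applied to buried area:
# burying apolar carbon is favourable, burying polar/charged atoms is
# penalised (the electrostatic term compensates when the contact is
# complementary).
atom_asp <- function(element, charge) {
  asp <- ifelse(toupper(element) == "C", -0.016, 0.006)
  asp[abs(charge) >= 0.4] <- 0.024
  asp
}

# ---- probe library ---------------------------------------------------------

# Extended-conformation side-chain geometries built from idealised bond
# lengths/angles; one canonical rigid rotamer per type, atoms from C-beta
# (plus C-alpha for the short beta-branched types).
zig <- function(k) c(1.27 * k, 0.42 * (k %% 2), 0)

probe_atom <- function(elety, element, pos) {
  data.frame(elety = elety, element = element, x = pos[1], y = pos[2],
             z = pos[3], stringsAsFactors = FALSE)
}

branch2 <- function(origin, dir_deg, bond) {
  th <- dir_deg * pi / 180
  origin + bond * c(cos(th), sin(th), 0)
}

#' Single-residue probe geometry
#'
#' @param type one-letter amino-acid code from the library
#'   (K, R, E, D, N, Q, T, I, P, F, S).
#' @return data.frame of side-chain atoms in a local frame (C-beta at the
#'   origin, chain extended along +x) with element and partial charge.
#' @export
probe_geometry <- function(type) {
  res3 <- c(K = "LYS", R = "ARG", E = "GLU", D = "ASP", N = "ASN",
            Q = "GLN", T = "THR", I = "ILE", P = "PRO", F = "PHE",
            S = "SER")
  if (!type %in% names(res3)) stop("unknown probe type: ", type)
  g <- switch(type,
    K = rbind(probe_atom("CB", "C", zig(0)), probe_atom("CG", "C", zig(1)),
              probe_atom("CD", "C", zig(2)), probe_atom("CE", "C", zig(3)),
              probe_atom("NZ", "N", zig(4))),
    R = rbind(probe_atom("CB", "C", zig(0)), probe_atom("CG", "C", zig(1)),
              probe_atom("CD", "C", zig(2)), probe_atom("NE", "N", zig(3)),
              probe_atom("CZ", "C", zig(4)),
              probe_atom("NH1", "N", branch2(zig(4), 60, 1.33)),
              probe_atom("NH2", "N", branch2(zig(4), -60, 1.33))),
    E = rbind(probe_atom("CB", "C", zig(0)), probe_atom("CG", "C", zig(1)),
              probe_atom("CD", "C", zig(2)),
              probe_atom("OE1", "O", branch2(zig(2), 60, 1.25)),
              probe_atom("OE2", "O", branch2(zig(2), -60, 1.25))),
    D = rbind(probe_atom("CB", "C", zig(0)), probe_atom("CG", "C", zig(1)),
              probe_atom("OD1", "O", branch2(zig(1), 60, 1.25)),
              probe_atom("OD2", "O", branch2(zig(1), -60, 1.25))),
    N = rbind(probe_atom("CB", "C", zig(0)), probe_atom("CG", "C", zig(1)),
              probe_atom("OD1", "O", branch2(zig(1), 60, 1.23)),
              probe_atom("ND2", "N", branch2(zig(1), -60, 1.33))),
    Q = rbind(probe_atom("CB", "C", zig(0)), probe_atom("CG", "C", zig(1)),
              probe_atom("CD", "C", zig(2)),
              probe_atom("OE1", "O", branch2(zig(2), 60, 1.23)),
              probe_atom("NE2", "N", branch2(zig(2), -60, 1.33))),
    T = rbind(probe_atom("CA", "C", c(-1.27, 0.42, 0)),
              probe_atom("CB", "C", zig(0)),
              probe_atom("OG1", "O", branch2(zig(0), 60, 1.43)),
              probe_atom("CG2", "C", branch2(zig(0), -60, 1.53))),
    I = rbind(probe_atom("CA", "C", c(-1.27, 0.42, 0)),
              probe_atom("CB", "C", zig(0)),
              probe_atom("CG1", "C", zig(1)),
              probe_atom("CD1", "C", zig(2)),
              probe_atom("CG2", "C", branch2(zig(0), -70, 1.53))),
    P = rbind(probe_atom("CB", "C", zig(0)), probe_atom("CG", "C", zig(1)),
              probe_atom("CD", "C", branch2(zig(1), 75, 1.53))),
    F = {
      ctr <- zig(1) + c(1.39, 0, 0)
      ring <- t(vapply(seq(0, 300, by = 60), function(a) {
        th <- (180 - a) * pi / 180
        ctr + 1.39 * c(cos(th), sin(th), 0)
      }, numeric(3)))
      rbind(probe_atom("CB", "C", zig(0)),
            probe_atom("CG", "C", ring[1, ]),
            probe_atom("CD1", "C", ring[2, ]),
            probe_atom("CE1", "C", ring[3, ]),
            probe_atom("CZ", "C", ring[4, ]),
            probe_atom("CE2", "C", ring[5, ]),
            probe_atom("CD2", "C", ring[6, ]))
    },
    S = rbind(probe_atom("CB", "C", zig(0)),
              probe_atom("OG", "O", branch2(zig(0), 60, 1.43))))
  g$resid <- res3[[type]]
  g$charge <- atom_charge(g$resid, g$elety)
  rownames(g) <- NULL
  g
}

#' Construct a probe pose
#'
#' @param probe_type one-letter code (see `probe_geometry()`).
#' @param transform `rigid_transform` taking the local probe frame into
#'   the receptor frame.
#' @return `probe_pose` object.
#' @export
probe_pose <- function(probe_type, transform = rigid_transform()) {
  geom <- probe_geometry(probe_type)
  structure(list(probe_type = probe_type, geometry = geom,
                 transform = transform), class = "probe_pose")
}

pose_coords <- function(pose) {
  apply_transform(as.matrix(pose$geometry[, c("x", "y", "z")]),
                  pose$transform)
}

# ---- cavity detection ------------------------------------------------------

# shift a 3-D logical array by integer offsets, padding with FALSE
shift3 <- function(a, v) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (v[k] >= 0) {
      if (v[k] >= d[k]) return(out)
      dst[[k]] <- 1:(d[k] - v[k])
      src[[k]] <- (1 + v[k]):d[k]
    } else {
      if (-v[k] >= d[k]) return(out)
      dst[[k]] <- (1 - v[k]):d[k]
      src[[k]] <- 1:(d[k] + v[k])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Detect small surface cavities
#'
#' Grid/ray pocket finder: the structure is rasterised onto a cubic grid
#' of occupied (inside a van der Waals sphere) and solvent cells. For
#' every solvent cell in probe reach of the surface, rays are marched
#' along the 26 lattice directions up to `ray_length`; the enclosure of a
#' cell is the fraction of rays that hit protein. Cells with enclosure at
#' least `enclosure_cutoff` are cavity points (a convex surface blocks
#' only about half the directions), the rest are open solvent. Cavity
#' points are clustered into 26-connected components; a cluster's depth
#' is the largest Euclidean distance from a member point to the nearest
#' open-solvent point, and clusters are returned sorted by decreasing
#' depth.
#'
#' @param s `vl_structure` with at least `min_atoms` atoms.
#' @param grid_spacing Angstrom (default 0.8).
#' @param probe_reach contact radius tying grid cells to lining atoms
#'   (default 4.5).
#' @param enclosure_cutoff minimum blocked-ray fraction for a cavity cell
#'   (default 0.70).
#' @param ray_length ray-march length in Angstrom (default 6).
#' @param min_points discard clusters smaller than this (default 5).
#' @param min_atoms structures below this size give an empty result with a
#'   warning (default 50).
#' @return list of `cavity` objects (centroid, mouth_radius, depth,
#'   lining atom indices, member points).
#' @export
detect_cavities <- function(s, grid_spacing = 0.8, probe_reach = 4.5,
                            enclosure_cutoff = 0.70, ray_length = 6,
                            min_points = 5, min_atoms = 50) {
  if (nrow(s$atoms) < min_atoms) {
    warning("structure too small for cavity detection")
    return(list())
  }
  xyz <- coords(s)
  rad <- vdw_radius(s$atoms$element)
  lo <- apply(xyz, 2, min) - probe_reach - grid_spacing
  hi <- apply(xyz, 2, max) + probe_reach + grid_spacing
  gx <- seq(lo[1], hi[1], by = grid_spacing)
  gy <- seq(lo[2], hi[2], by = grid_spacing)
  gz <- seq(lo[3], hi[3], by = grid_spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  n <- nrow(pts)
  contact <- logical(n)
  inside <- logical(n)
  chunk <- 8000L
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(n, i0 + chunk - 1L)
    d2 <- outer(rowSums(pts[i0:i1, , drop = FALSE]^2), rowSums(xyz^2),
                "+") - 2 * pts[i0:i1, , drop = FALSE] %*% t(xyz)
    contact[i0:i1] <- rowSums(d2 <= probe_reach^2) >= 1L
    inside[i0:i1] <- apply(sweep(d2, 2, rad^2, "-") < 0, 1, any)
  }
  dims <- c(length(gx), length(gy), length(gz))
  occ <- array(inside, dims)
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  blocked <- array(0L, dims)
  for (di in seq_len(nrow(dirs))) {
    v <- dirs[di, ]
    steps <- max(1L, floor(ray_length /
                             (grid_spacing * sqrt(sum(v^2)))))
    hit <- array(FALSE, dims)
    acc <- occ
    for (k in seq_len(steps)) {
      acc <- shift3(acc, v)
      hit <- hit | acc
    }
    blocked <- blocked + hit
  }
  enclosure <- as.vector(blocked) / nrow(dirs)
  solvent <- !inside & contact
  cav <- solvent & enclosure >= enclosure_cutoff
  open <- solvent & enclosure < enclosure_cutoff
  if (!any(cav)) return(list())
  # cluster cavity points on the integer grid (26-connectivity)
  idx <- which(cav)
  gi <- arrayInd(idx, c(length(gx), length(gy), length(gz)))
  keymap <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(idx))
    assign(paste(gi[i, ], collapse = ","), i, envir = keymap)
  comp <- integer(length(idx))
  ncomp <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in seq_along(idx)) {
    if (comp[i] != 0L) next
    ncomp <- ncomp + 1L
    queue <- i
    comp[i] <- ncomp
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      nb <- sweep(offs, 2, gi[cur, ], "+")
      keys <- apply(nb, 1, paste, collapse = ",")
      for (k in keys) {
        j <- keymap[[k]]
        if (!is.null(j) && comp[j] == 0L) {
          comp[j] <- ncomp
          queue <- c(queue, j)
        }
      }
    }
  }
  open_pts <- pts[open, , drop = FALSE]
  out <- list()
  for (cc in seq_len(ncomp)) {
    member <- pts[idx[comp == cc], , drop = FALSE]
    if (nrow(member) < min_points) next
    centroid <- colMeans(member)
    mouth_radius <- max(sqrt(rowSums(sweep(member, 2, centroid)^2)))
    depth <- if (nrow(open_pts)) {
      d2o <- outer(rowSums(member^2), rowSums(open_pts^2), "+") -
        2 * member %*% t(open_pts)
      max(sqrt(pmax(0, apply(d2o, 1, min))))
    } else mouth_radius + grid_spacing
    depth <- max(depth, grid_spacing / 2)
    d2a <- outer(rowSums(member^2), rowSums(xyz^2), "+") -
      2 * member %*% t(xyz)
    lining <- which(apply(d2a <= probe_reach^2, 2, any))
    out[[length(out) + 1]] <- structure(
      list(centroid = centroid, mouth_radius = mouth_radius, depth = depth,
           lining_atoms = lining, points = member), class = "cavity")
  }
  out[order(-vapply(out, function(cv) cv$depth, numeric(1)))]
}

#' @export
print.cavity <- function(x, ...) {
  cat(sprintf(
    "cavity at (%.1f, %.1f, %.1f): depth %.1f A, mouth %.1f A, %d lining atoms\n",
    x$centroid[1], x$centroid[2], x$centroid[3], x$depth, x$mouth_radius,
    length(x$lining_atoms)))
  invisible(x)
}

# ---- probe scoring ---------------------------------------------------------

#' Score a probe pose against a receptor
#'
#' Semi-empirical binding score: Lennard-Jones + Coulomb with a
#' distance-dependent dielectric (eps = 4r) additionally reduced by the
#' fraction of protein burial around the probe (the approaching protein
#' displaces water and weakens the screening) + atomic-solvation-parameter
#' term on the area buried in the contact. Poses with any interatomic
#' distance below `clash_cutoff` score +Inf.
#'
#' @param s receptor `vl_structure`.
#' @param pose `probe_pose`.
#' @param clash_cutoff Angstrom (default 2.0).
#' @param interaction_cutoff pair cutoff for energy sums (default 12).
#' @param sasa_points quadrature points for the buried-area term
#'   (default 120; the term is deterministic for a fixed value).
#' @return list with `delta_g` and `components` (vdw, electrostatic,
#'   solvation), all kcal/mol.
#' @export
score_probe <- function(s, pose, clash_cutoff = 2.0,
                        interaction_cutoff = 12, sasa_points = 120) {
  pxyz <- pose_coords(pose)
  rxyz <- coords(s)
  pq <- pose$geometry$charge
  rq <- atom_charge(s$atoms$resid, s$atoms$elety)
  inf_score <- list(delta_g = Inf,
                    components = c(vdw = Inf, electrostatic = Inf,
                                   solvation = Inf))
  # cull receptor to the interaction neighbourhood of the probe centroid
  ctr <- colMeans(pxyz)
  extent <- max(sqrt(rowSums(sweep(pxyz, 2, ctr)^2)))
  d2c <- rowSums(sweep(rxyz, 2, ctr)^2)
  near <- d2c <= (interaction_cutoff + extent)^2
  if (!any(near))
    return(list(delta_g = 0,
                components = c(vdw = 0, electrostatic = 0, solvation = 0)))
  rx <- rxyz[near, , drop = FALSE]
  rqn <- rq[near]
  relem <- s$atoms$element[near]
  d2 <- outer(rowSums(pxyz^2), rowSums(rx^2), "+") - 2 * pxyz %*% t(rx)
  d <- sqrt(pmax(d2, 1e-12))
  if (min(d) < clash_cutoff) return(inf_score)
  lp <- lj_params(pose$geometry$element)
  lr <- lj_params(relem)
  rmin <- outer(lp$rmin, lr$rmin, "+")
  epsm <- sqrt(outer(lp$eps, lr$eps))
  use <- d <= interaction_cutoff
  sr6 <- (rmin / d)^6
  vdw <- sum((epsm * (sr6^2 - 2 * sr6))[use])
  # burial factor from local protein density around the probe
  n_near <- sum(d2c <= 6.5^2)
  f_buried <- min(1, n_near / 30)
  qq <- outer(pq, rqn)
  elec <- sum((332.0637 * qq / (4 * d * (1 - 0.5 * f_buried) * d))[use])
  # buried-area (desolvation) term over probe + contacting receptor shell
  shell <- which(apply(d <= 8, 2, any))
  asp_p <- atom_asp(pose$geometry$element, pq)
  a_probe_free <- sasa_atoms(pxyz, vdw_radius(pose$geometry$element),
                             1.4, sasa_points)
  if (length(shell)) {
    sh <- rx[shell, , drop = FALSE]
    sh_rad <- vdw_radius(relem[shell])
    asp_r <- atom_asp(relem[shell], rqn[shell])
    a_shell_free <- sasa_atoms(sh, sh_rad, 1.4, sasa_points)
    all_xyz <- rbind(pxyz, sh)
    all_rad <- c(vdw_radius(pose$geometry$element), sh_rad)
    a_cplx <- sasa_atoms(all_xyz, all_rad, 1.4, sasa_points)
    np <- nrow(pxyz)
    buried <- pmax(0, c(a_probe_free, a_shell_free) - a_cplx)
    solv <- sum(c(asp_p, asp_r) * buried)
  } else solv <- 0
  comps <- c(vdw = vdw, electrostatic = elec, solvation = solv)
  list(delta_g = sum(comps), components = comps)
}

# ---- spot mapping ----------------------------------------------------------

pose_from_par <- function(probe_type, par) {
  ang <- sqrt(sum(par[4:6]^2))
  rot <- if (ang < 1e-9) diag(3) else axis_angle_rotation(par[4:6], ang)
  probe_pose(probe_type, rigid_transform(rot, par[1:3]))
}

soft_score <- function(s, probe_type, par, clash_cutoff) {
  pose <- pose_from_par(probe_type, par)
  sc <- score_probe(s, pose, clash_cutoff = clash_cutoff)
  if (is.finite(sc$delta_g)) return(sc$delta_g)
  # softened clash penalty keeps the optimiser informative
  md <- min_dist_cpp(pose_coords(pose), coords(s))
  50 + 100 * (clash_cutoff - md)
}

#' Map anchoring spots on a receptor surface
#'
#' For every detected cavity and probe type, the probe is placed at random
#' positions/orientations inside the cavity and locally optimised
#' (Nelder-Mead over the 6 rigid degrees of freedom); the best pose per
#' cavity x probe is kept. Spots at or below `strong_cutoff` are flagged
#' strong. Fully seeded and reproducible.
#'
#' @param s receptor `vl_structure` (whole structure or a domain).
#' @param probe_types character vector of one-letter probe codes.
#' @param strong_cutoff kcal/mol (default -3).
#' @param seed integer seed.
#' @param n_starts random starts per cavity x probe (default 500).
#' @param cavities optional precomputed list from `detect_cavities()`.
#' @param grid_spacing forwarded to `detect_cavities()`.
#' @param maxit Nelder-Mead iteration cap per start (default 80).
#' @param clash_cutoff Angstrom (default 2.0).
#' @return list of `anchoring_spot` objects sorted by delta_g.
#' @export
map_anchoring_spots <- function(s, probe_types, strong_cutoff = -3,
                                seed = 7, n_starts = 500, cavities = NULL,
                                grid_spacing = 0.8, maxit = 80,
                                clash_cutoff = 2.0) {
  if (nrow(s$atoms) == 0) stop("receptor is empty")
  if (is.null(cavities)) cavities <- detect_cavities(s, grid_spacing)
  spots <- list()
  with_seed(seed, {
    for (ci in seq_along(cavities)) {
      cv <- cavities[[ci]]
      for (pt in probe_types) {
        best <- NULL
        for (k in seq_len(n_starts)) {
          start_pt <- cv$points[sample.int(nrow(cv$points), 1), ] +
            rnorm(3, 0, 0.3)
          axis <- rnorm(3)
          ang <- runif(1, 0, pi)
          par0 <- c(start_pt, axis / sqrt(sum(axis^2)) * ang)
          fit <- optim(par0, function(p)
            soft_score(s, pt, p, clash_cutoff),
            method = "Nelder-Mead", control = list(maxit = maxit))
          if (is.null(best) || fit$value < best$value) best <- fit
        }
        pose <- pose_from_par(pt, best$par)
        sc <- score_probe(s, pose, clash_cutoff = clash_cutoff)
        if (!is.finite(sc$delta_g)) next
        spots[[length(spots) + 1]] <- structure(
          list(cavity_index = ci, cavity = cv, best_pose = pose,
               delta_g = sc$delta_g, components = sc$components,
               strong = sc$delta_g <= strong_cutoff,
               matched_residue = NA_character_),
          class = "anchoring_spot")
      }
    }
  })
  spots[order(vapply(spots, function(x) x$delta_g, numeric(1)))]
}

#' @export
print.anchoring_spot <- function(x, ...) {
  cat(sprintf(
    "anchoring spot: probe %s, dG %.2f kcal/mol (vdw %.2f, elec %.2f, solv %.2f)%s%s\n",
    x$best_pose$probe_type, x$delta_g, x$components["vdw"],
    x$components["electrostatic"], x$components["solvation"],
    if (x$strong) " [strong]" else "",
    if (!is.na(x$matched_residue)) paste0(" -> ", x$matched_residue) else ""))
  invisible(x)
}

#' Match anchoring spots to partner residues
#'
#' A spot is matched when the partner structure carries a residue of the
#' probe's amino-acid type whose side-chain centroid lies within
#' `match_radius` of the posed probe's centroid.
#'
#' @param spots list from `map_anchoring_spots()`.
#' @param partner `vl_structure` in the same frame as the receptor.
#' @param match_radius Angstrom (default 2.0).
#' @return the spots with `matched_residue` filled ("K975"-style labels)
#'   or NA.
#' @export
match_spots_to_partner <- function(spots, partner, match_radius = 2.0) {
  one3 <- c(K = "LYS", R = "ARG", E = "GLU", D = "ASP", N = "ASN",
            Q = "GLN", T = "THR", I = "ILE", P = "PRO", F = "PHE",
            S = "SER")
  a <- partner$atoms
  side <- !(a$elety %in% c("N", "CA", "C", "O", "OXT"))
  for (i in seq_along(spots)) {
    sp <- spots[[i]]
    res3 <- one3[[sp$best_pose$probe_type]]
    sel <- a$resid == res3 & side
    if (!any(sel)) next
    ctr <- colMeans(pose_coords(sp$best_pose))
    cand <- a[sel, , drop = FALSE]
    cen <- do.call(rbind, lapply(
      split(seq_len(nrow(cand)), paste(cand$chain, cand$resno)),
      function(ix) colMeans(as.matrix(cand[ix, c("x", "y", "z")]))))
    dd <- sqrt(rowSums(sweep(cen, 2, ctr)^2))
    if (min(dd) <= match_radius) {
      lab <- rownames(cen)[which.min(dd)]
      resno <- sub("^\\S+ ", "", lab)
      spots[[i]]$matched_residue <- paste0(names(one3)[one3 == res3],
                                           resno)
    }
  }
  spots
}

#' Write best probe poses as a PDB file
#'
#' One residue per spot (chain Z, residue number = spot index), for
#' visual inspection alongside the receptor.
#'
#' @param spots list of `anchoring_spot`.
#' @param path output PDB.
#' @return the path, invisibly.
#' @export
write_spots_pdb <- function(spots, path) {
  rows <- do.call(rbind, lapply(seq_along(spots), function(i) {
    sp <- spots[[i]]
    xyz <- pose_coords(sp$best_pose)
    data.frame(chain = "Z", resno = i,
               resid = sp$best_pose$geometry$resid,
               elety = sp$best_pose$geometry$elety,
               element = sp$best_pose$geometry$element,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
               stringsAsFactors = FALSE)
  }))
  write_structure_pdb(structure_from_atoms(rows, "anchoring_spots"),
                      path)
}

#' Tabulate anchoring spots
#'
#' @param spots list of `anchoring_spot`.
#' @return data.frame (cavity, probe, delta_g, components, strong,
#'   matched residue), one row per spot.
#' @export
spots_table <- function(spots) {
  if (!length(spots))
    return(data.frame(cavity = integer(), probe = character(),
                      delta_g = numeric(), vdw = numeric(),
                      electrostatic = numeric(), solvation = numeric(),
                      strong = logical(), matched_residue = character()))
  do.call(rbind, lapply(spots, function(x)
    data.frame(cavity = x$cavity_index, probe = x$best_pose$probe_type,
               delta_g = x$delta_g, vdw = x$components[["vdw"]],
               electrostatic = x$components[["electrostatic"]],
               solvation = x$components[["solvation"]], strong = x$strong,
               matched_residue = x$matched_residue,
               stringsAsFactors = FALSE)))
}
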