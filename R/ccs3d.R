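#' @title Theoretical collision cross sections and opening models
#' @name ccs3d
#' @description Projection-approximation CCS of all-atom structures and
#'   rigid-body construction of semi-open/open conformer models in which
#'   the tail bundle (with its hinge) is displaced from the head. The CCS
#'   of a structure is the orientation-averaged area of its projected
#'   shadow, with atoms drawn as disks inflated by the drift-gas radius.
NULL

#' CCS value container
#'
#' @param value CCS in Angstrom^2 (> 0).
#' @param sd uncertainty (>= 0).
#' @param method "projection_approx" or "calibrated_experimental".
#' @return `ccs_value` object.
#' @export
ccs_value <- function(value, sd = 0,
                      method = c("projection_approx",
                                 "calibrated_experimental")) {
  method <- match.arg(method)
  stopifnot(is.finite(value), value > 0, sd >= 0)
  structure(list(value = value, sd = sd, method = method),
            class = "ccs_value")
}

#' @export
print.ccs_value <- function(x, ...) {
  cat(sprintf("CCS %.0f +/- %.0f A^2 (%s)\n", x$value, x$sd, x$method))
  invisible(x)
}

#' Projection-approximation CCS
#'
#' Mean projected shadow area over uniformly random orientations; each
#' atom is a disk of radius (element vdW radius + `gas_radius`), and the
#' shadow is rasterised at `grid_spacing`. The reported sd is the standard
#' error over orientations. Fully seeded.
#'
#' @param s `vl_structure`.
#' @param gas_radius effective drift-gas radius, Angstrom (default 1.0).
#' @param n_orientations random orientations (>= 100; default 3000).
#' @param grid_spacing raster resolution, Angstrom (default 1.0).
#' @param scale_factor global multiplier on the result (default 1.0).
#' @param seed integer seed (default 42).
#' @return `ccs_value`.
#' @export
pa_ccs <- function(s, gas_radius = 1.0, n_orientations = 3000,
                   grid_spacing = 1.0, scale_factor = 1.0, seed = 42) {
  stopifnot(nrow(s$atoms) > 0, n_orientations >= 100, gas_radius > 0)
  rot_off <- with_seed(seed, list(rot = random_rotations(n_orientations),
                                  off = matrix(runif(2 * n_orientations),
                                               ncol = 2)))
  areas <- proj_area_cpp(coords(s),
                         vdw_radius(s$atoms$element) + gas_radius,
                         rot_off$rot, grid_spacing, rot_off$off)
  ccs_value(scale_factor * mean(areas),
            scale_factor * stats::sd(areas) / sqrt(n_orientations),
            "projection_approx")
}

# ---- opening models --------------------------------------------------------

moved_atom_mask <- function(s, p, moved_domains, chain = NULL) {
  a <- s$atoms
  keep <- rep(FALSE, nrow(a))
  for (lab in moved_domains) {
    rng <- partition_ranges(p, lab)
    for (i in seq_len(nrow(rng)))
      keep <- keep | (a$resno >= rng[i, 1] & a$resno <= rng[i, 2])
  }
  if (!is.null(chain)) keep <- keep & a$chain == chain
  keep
}

marker_position <- function(s, resno, chain = NULL) {
  a <- s$atoms
  sel <- a$resno == resno & a$elety == "CA"
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel)) stop("marker residue ", resno, " has no CA atom")
  as.numeric(a[which(sel)[1], c("x", "y", "z")])
}

#' Displace the tail module rigidly
#'
#' Applies a rigid transform to the tail-side atoms (by default the hinge
#' and Vt together, so the hinge-resident marker residue travels with the
#' tail) and reports the marker separation, clash count and optionally the
#' projection CCS of the result. Chain continuity across the (partially
#' disordered) hinge is deliberately not modelled.
#'
#' @param s single-conformer `vl_structure` (use one chain).
#' @param p `domain_partition`.
#' @param transform `rigid_transform` applied to the moved atoms about the
#'   moved set's centroid.
#' @param markers two residue numbers (moved, static) whose C-alpha
#'   distance defines the separation; default c(875, 836).
#' @param moved_domains domain labels that move (default hinge + Vt).
#' @param max_tether largest admissible marker separation, Angstrom
#'   (default 130; about an extended 39-residue linker).
#' @param max_clashes reject transforms producing more heavy-atom overlaps
#'   than this (default 25 at `clash_cutoff` 2.4 A).
#' @param clash_cutoff Angstrom.
#' @param compute_ccs evaluate `pa_ccs()` on the model (default TRUE).
#' @param ... passed to `pa_ccs()`.
#' @return `opening_model`: list with the displaced structure, transform,
#'   separation, clash count, CCS and a state label slot.
#' @export
displace_tail <- function(s, p, transform, markers = c(875, 836),
                          moved_domains = c("hinge", "Vt"),
                          max_tether = 130, max_clashes = 25,
                          clash_cutoff = 2.4, compute_ccs = TRUE, ...) {
  mask <- moved_atom_mask(s, p, moved_domains)
  if (!any(mask)) stop("no atoms in moved domains")
  xyz <- coords(s)
  ctr <- colMeans(xyz[mask, , drop = FALSE])
  moved_xyz <- apply_transform(xyz[mask, , drop = FALSE], transform,
                               center = ctr)
  out <- s
  out$atoms[mask, c("x", "y", "z")] <- moved_xyz
  sep <- sqrt(sum((marker_position(out, markers[1]) -
                     marker_position(out, markers[2]))^2))
  if (sep > max_tether)
    stop(sprintf("marker separation %.1f A exceeds max_tether %.1f A",
                 sep, max_tether))
  clashes <- clash_count_cpp(moved_xyz, xyz[!mask, , drop = FALSE],
                             clash_cutoff)
  if (clashes > max_clashes)
    stop(sprintf("transform produces %d heavy-atom overlaps (max %d)",
                 clashes, max_clashes))
  model <- list(base = s, structure = out, transform = transform,
                moved_domains = moved_domains, markers = markers,
                separation = sep, clash_count = clashes,
                ccs = if (compute_ccs) pa_ccs(out, ...) else NULL,
                state_label = NA_character_)
  class(model) <- "opening_model"
  model
}

#' @export
print.opening_model <- function(x, ...) {
  cat(sprintf(
    "opening model: markers %d-%d separated %.1f A, %d clashes%s\n",
    x$markers[1], x$markers[2], x$separation, x$clash_count,
    if (!is.null(x$ccs)) sprintf(", CCS %.0f A^2", x$ccs$value) else ""))
  invisible(x)
}

#' Scan tail displacement versus CCS
#'
#' For each requested displacement (increase of the marker separation over
#' the closed state, so 0 reproduces the input), random tether-respecting
#' rigid poses of the tail module are generated and their projection CCS
#' averaged. Displacements whose implied marker separation exceeds
#' `max_tether` are returned flagged infeasible.
#'
#' @param s,p,markers,moved_domains,max_tether,max_clashes,clash_cutoff
#'   as in `displace_tail()`.
#' @param displacements increasing numeric vector of separation increases
#'   (Angstrom).
#' @param n_poses_per_sep random poses per displacement (default 5).
#' @param seed integer seed.
#' @param max_rotation largest random tail rotation (radians,
#'   default 0.5).
#' @param n_orientations orientations per CCS evaluation (default 300;
#'   smaller than the `pa_ccs()` default because the scan averages over
#'   poses as well).
#' @param max_attempts pose-generation attempts per accepted pose.
#' @return data.frame (displacement, separation, mean_ccs, sd_ccs,
#'   n_poses, feasible).
#' @export
scan_opening <- function(s, p, displacements, n_poses_per_sep = 5,
                         seed = 42, markers = c(875, 836),
                         moved_domains = c("hinge", "Vt"),
                         max_tether = 130, max_clashes = 25,
                         clash_cutoff = 2.4, max_rotation = 0.5,
                         n_orientations = 300, max_attempts = 60) {
  stopifnot(!is.unsorted(displacements))
  pos_a <- marker_position(s, markers[1])
  pos_b <- marker_position(s, markers[2])
  closed_sep <- sqrt(sum((pos_a - pos_b)^2))
  mask <- moved_atom_mask(s, p, moved_domains)
  ctr <- colMeans(coords(s)[mask, , drop = FALSE])
  rows <- vector("list", length(displacements))
  with_seed(seed, {
    for (i in seq_along(displacements)) {
      d <- displacements[i]
      target_sep <- closed_sep + d
      if (target_sep > max_tether) {
        rows[[i]] <- data.frame(displacement = d, separation = target_sep,
                                mean_ccs = NA_real_, sd_ccs = NA_real_,
                                n_poses = 0L, feasible = FALSE)
        next
      }
      ccs_vals <- numeric(0)
      if (d == 0) {
        m <- displace_tail(s, p, rigid_transform(), markers,
                           moved_domains, max_tether, max_clashes,
                           clash_cutoff, compute_ccs = TRUE,
                           n_orientations = n_orientations)
        ccs_vals <- m$ccs$value
      } else {
        tries <- 0
        while (length(ccs_vals) < n_poses_per_sep &&
               tries < max_attempts * n_poses_per_sep) {
          tries <- tries + 1
          axis <- rnorm(3)
          rot <- axis_angle_rotation(axis, runif(1, 0, max_rotation))
          # rotate about the tail centroid, then translate so the moved
          # marker lands at the target separation from the static marker
          a_rot <- as.numeric(rot %*% (pos_a - ctr)) + ctr
          u <- rnorm(3)
          # bias the direction away from the head so most draws are
          # clash-free
          away <- (pos_a - pos_b)
          u <- u / sqrt(sum(u^2)) + away / sqrt(sum(away^2))
          u <- u / sqrt(sum(u^2))
          tr <- rigid_transform(rot, pos_b + target_sep * u - a_rot)
          m <- tryCatch(
            displace_tail(s, p, tr, markers, moved_domains, max_tether,
                          max_clashes, clash_cutoff, compute_ccs = TRUE,
                          n_orientations = n_orientations),
            error = function(e) NULL)
          if (!is.null(m)) ccs_vals <- c(ccs_vals, m$ccs$value)
        }
      }
      rows[[i]] <- data.frame(
        displacement = d, separation = target_sep,
        mean_ccs = if (length(ccs_vals)) mean(ccs_vals) else NA_real_,
        sd_ccs = if (length(ccs_vals) > 1) stats::sd(ccs_vals) else 0,
        n_poses = length(ccs_vals),
        feasible = length(ccs_vals) > 0)
    }
  })
  do.call(rbind, rows)
}

#' Match experimental state CCS values to scan models
#'
#' Deliberately one-to-many: for each experimental CCS all scan rows
#' within the relative tolerance are candidates (distinct geometries can
#' share a CCS).
#'
#' @param experimental named numeric vector of CCS per state (A^2).
#' @param scan data.frame from `scan_opening()`.
#' @param tolerance relative CCS tolerance (default 0.02).
#' @return named list of data.frames (possibly empty, with a warning).
#' @export
assign_state_models <- function(experimental, scan, tolerance = 0.02) {
  stopifnot(nrow(scan) > 0)
  out <- lapply(seq_along(experimental), function(i) {
    tgt <- experimental[i]
    hit <- scan[scan$feasible & !is.na(scan$mean_ccs) &
                  abs(scan$mean_ccs - tgt) <= tolerance * tgt, ,
                drop = FALSE]
    if (nrow(hit) == 0)
      warning("no scan model within tolerance of CCS ", tgt)
    hit
  })
  names(out) <- names(experimental) %||%
    paste0("state", seq_along(experimental))
  out
}
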