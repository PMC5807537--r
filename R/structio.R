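#' @title Structure container and I/O
#' @name structio
#' @description Light-weight all-atom structure container used throughout
#'   the package, read from PDB or mmCIF via bio3d. Waters are dropped,
#'   zero-occupancy atoms are dropped, and alternate locations are resolved
#'   to the highest-occupancy conformer so that downstream geometry is
#'   deterministic.
NULL

# van der Waals radii (Angstrom) by element; Bondi-style values with a
# generic fallback for rare elements.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               FE = 1.40, ZN = 1.39, MG = 1.73, CA = 1.75, "NA" = 1.80,
               K = 2.20)
VDW_DEFAULT <- 1.70

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL", "MSE")

new_structure <- function(atoms, source_id = "unknown") {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z",
            "occ")
  stopifnot(all(need %in% names(atoms)))
  atoms <- as.data.frame(atoms)[, need]
  atoms$chain <- as.character(atoms$chain)
  atoms$resid <- toupper(as.character(atoms$resid))
  atoms$elety <- as.character(atoms$elety)
  atoms$element <- toupper(as.character(atoms$element))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in structure")
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancy outside [0, 1]")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_id = source_id),
            class = "vl_structure")
}

#' Build a structure from an atom table
#'
#' Mostly used by tests and generators; `read_structure()` is the usual
#' entry point for real coordinate files.
#'
#' @param atoms data.frame with columns chain, resno, resid, elety,
#'   element, x, y, z, occ.
#' @param source_id identifier carried through reports (e.g. a PDB code).
#' @return `vl_structure`.
#' @export
structure_from_atoms <- function(atoms, source_id = "synthetic") {
  new_structure(atoms, source_id)
}

#' Read a structure from PDB or mmCIF
#'
#' ATOM/HETATM records are loaded, waters excluded, zero-occupancy atoms
#' dropped and alternate locations reduced to the highest-occupancy copy.
#'
#' @param path coordinate file.
#' @param format "auto" (by extension), "pdb" or "cif".
#' @param keep_hetero keep non-water HETATM records (default TRUE).
#' @return `vl_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           keep_hetero = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("unreadable structure file: ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[!(toupper(at$resid) %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  occ <- suppressWarnings(as.numeric(at$o))
  occ[is.na(occ)] <- 1
  at <- at[occ > 0, , drop = FALSE]
  occ <- occ[occ > 0]
  if (nrow(at) == 0) stop("zero polymer atoms in ", path)
  # alternate locations: keep highest occupancy per atom site
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "|")
  ord <- order(key, -occ)
  at <- at[ord, , drop = FALSE]
  occ <- occ[ord]
  keep <- !duplicated(key[ord])
  at <- at[keep, , drop = FALSE]
  occ <- pmin(occ[keep], 1)
  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  miss <- is.na(element) | element == ""
  element[miss] <- element_from_name(at$elety[miss])
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, element = element,
                      x = at$x, y = at$y, z = at$z, occ = occ,
                      stringsAsFactors = FALSE)
  # restore deposited order
  atoms <- atoms[order(match(paste(atoms$chain, atoms$resno, atoms$elety),
                             paste(pdb$atom$chain, pdb$atom$resno,
                                   pdb$atom$elety))), ]
  src <- toupper(sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                     ignore.case = TRUE))
  s <- new_structure(atoms, source_id = src)
  if (!any(s$atoms$resid %in% AMINO3)) stop("zero polymer atoms in ", path)
  s
}

# Guess an element symbol from a PDB atom name ("NZ" -> N, "1HB" -> H).
element_from_name <- function(elety) {
  nm <- gsub("[0-9' ]", "", toupper(elety))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "SE", "NA"),
                two, substr(nm, 1, 1))
  out[out == ""] <- "C"
  out
}

#' @export
print.vl_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure %s: %d atoms, %d chains (%s), residues %d-%d\n",
              x$source_id, nrow(a), length(unique(a$chain)),
              paste(unique(a$chain), collapse = ","),
              min(a$resno), max(a$resno)))
  invisible(x)
}

#' Chains of a structure
#' @param s `vl_structure`.
#' @return character vector of chain identifiers in deposited order.
#' @export
structure_chains <- function(s) unique(s$atoms$chain)

coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

subset_structure <- function(s, idx) {
  new_structure(s$atoms[idx, , drop = FALSE], s$source_id)
}

#' Write a structure as a PDB file
#'
#' Minimal ATOM-record writer for exporting opening models and probe
#' poses for visual inspection.
#'
#' @param s `vl_structure`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  a <- s$atoms
  name4 <- ifelse(nchar(a$elety) < 4, paste0(" ", formatC(a$elety,
                                                          width = -3)),
                  a$elety)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000, name4, a$resid,
    substr(a$chain, 1, 1), a$resno %% 10000, a$x, a$y, a$z, a$occ, 0,
    a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Merge two structures (atom-table concatenation)
#' @param a,b `vl_structure` objects.
#' @return combined `vl_structure`.
#' @export
merge_structures <- function(a, b) {
  new_structure(rbind(a$atoms, b$atoms), a$source_id)
}

# ---- domain partition ------------------------------------------------------

#' Default vinculin domain partition
#'
#' Residue ranges for the five helix-bundle domains, hinge and the
#' metavinculin insert. The head (Vh) is D1-D4; Vt is the tail bundle.
#' Metavinculin tail numbering is shifted by +68 relative to vinculin
#' (68-residue insert after residue 915). The ranges are a configuration
#' value, not code: edit the YAML returned by
#' `system.file("extdata", "partition_vinculin.yaml", package = "vinlock")`
#' or pass your own file to `read_domain_partition()`.
#'
#' @return `domain_partition`: named list of inclusive residue ranges.
#' @export
default_domain_partition <- function() {
  p <- list(D1 = c(1, 252), D2 = c(253, 485), D3 = c(486, 717),
            D4 = c(718, 836), hinge = c(837, 895), Vt = c(896, 1066),
            insert = c(916, 983))
  attr(p, "tail_offset_metavinculin") <- 68
  class(p) <- "domain_partition"
  p
}

#' Read a domain partition from YAML
#'
#' The file maps domain labels to two-element [start, end] residue ranges;
#' an optional `tail_offset_metavinculin` scalar gives the insert-induced
#' numbering shift.
#'
#' @param path YAML file.
#' @return `domain_partition`.
#' @export
read_domain_partition <- function(path) {
  y <- yaml::read_yaml(path)
  off <- y$tail_offset_metavinculin %||% 68
  y$tail_offset_metavinculin <- NULL
  p <- lapply(y, function(r) as.numeric(r[1:2]))
  stopifnot(length(p) > 0, all(vapply(p, length, 1L) == 2))
  attr(p, "tail_offset_metavinculin") <- off
  class(p) <- "domain_partition"
  p
}

partition_ranges <- function(p, label) {
  if (!label %in% names(p)) stop("unknown domain label: ", label)
  r <- p[[label]]
  matrix(r, ncol = 2)
}

#' Select a domain from a structure
#'
#' @param s `vl_structure`.
#' @param p `domain_partition`.
#' @param label domain label present in `p` (e.g. "Vt").
#' @param chain chain identifier, or NULL for all chains.
#' @return `vl_structure` restricted to the domain (possibly empty, with a
#'   warning).
#' @export
select_domain <- function(s, p, label, chain = NULL) {
  rng <- partition_ranges(p, label)
  a <- s$atoms
  keep <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(rng)))
    keep <- keep | (a$resno >= rng[i, 1] & a$resno <= rng[i, 2])
  if (!is.null(chain)) {
    if (!chain %in% a$chain) stop("unknown chain: ", chain)
    keep <- keep & a$chain == chain
  }
  if (!any(keep)) warning("empty selection for domain ", label)
  subset_structure(s, keep)
}

# ---- SASA ------------------------------------------------------------------

# Rotate coordinates into a canonical principal-axes frame (signs fixed
# by third moments, right-handed) and snap to 1e-6 A. The quadrature
# point set is fixed in space, so without this SASA would change slightly
# under rigid-body motion; in the canonical frame the computation is
# bit-identical for any rigidly moved copy of the same structure.
canonical_xyz <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  cv <- crossprod(xc) / max(1, nrow(xc))
  ev <- eigen(cv, symmetric = TRUE)
  V <- ev$vectors
  for (j in 1:3) {
    s <- sum((xc %*% V[, j])^3)
    if (abs(s) < 1e-9) s <- sum(xc %*% V[, j])
    if (s < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  round(xc %*% V, 6)
}

sasa_atoms <- function(xyz, radii, probe, n_points) {
  sasa_cpp(canonical_xyz(xyz), radii, probe, as.integer(n_points))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA with a deterministic Fibonacci-lattice point set, so
#' repeated calls are bit-identical. Coincident spheres share boundary
#' points evenly instead of double counting.
#'
#' @param s `vl_structure`.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (>= 32; default 960).
#' @return numeric vector of per-atom areas (Angstrom^2); `sum()` gives the
#'   total SASA.
#' @export
sasa <- function(s, probe_radius = 1.4, n_points = 960) {
  stopifnot(probe_radius > 0, n_points >= 32)
  if (nrow(s$atoms) == 0) return(numeric(0))
  sasa_atoms(coords(s), vdw_radius(s$atoms$element), probe_radius,
             n_points)
}

# ---- hydrogen bonds --------------------------------------------------------

# Donor/acceptor heavy atoms by residue chemistry. The deposited models
# carry no hydrogens, so the criterion is distance-only between heavy
# atoms that could carry a polar H (donor) or a lone pair (acceptor).
HB_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG")
HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")

hb_flag <- function(atoms, table) {
  ok <- atoms$elety %in% table$backbone & atoms$resid %in% AMINO3
  if (any(atoms$resid == "PRO" & atoms$elety == "N") &&
      identical(table, HB_DONORS))
    ok[atoms$resid == "PRO" & atoms$elety == "N"] <- FALSE
  for (res in setdiff(names(table), "backbone"))
    ok <- ok | (atoms$resid == res & atoms$elety %in% table[[res]])
  ok
}

#' Find hydrogen bonds between two atom groups
#'
#' Distance-only criterion on donor/acceptor heavy atoms: pairs closer
#' than `short_cutoff` are tier "short", pairs between the cutoffs tier
#' "long". Donor and acceptor roles are resolved by residue chemistry, so
#' the result is symmetric in the two groups.
#'
#' @param group_a,group_b `vl_structure` subsets (typically two domains of
#'   one chain).
#' @param short_cutoff,long_cutoff Angstrom; 0 < short < long.
#' @return data.frame, one row per bond (chain, donor residue/atom,
#'   acceptor residue/atom, distance, tier), sorted by distance.
#' @export
find_hbonds <- function(group_a, group_b, short_cutoff = 3.5,
                        long_cutoff = 4.0) {
  stopifnot(short_cutoff > 0, short_cutoff < long_cutoff)
  empty <- data.frame(chain = character(), donor_resno = integer(),
                      donor_resid = character(), donor_atom = character(),
                      acceptor_resno = integer(),
                      acceptor_resid = character(),
                      acceptor_atom = character(), distance = numeric(),
                      tier = character(), stringsAsFactors = FALSE)
  pairs_one_way <- function(da, ab) {
    don <- da$atoms[hb_flag(da$atoms, HB_DONORS), , drop = FALSE]
    acc <- ab$atoms[hb_flag(ab$atoms, HB_ACCEPTORS), , drop = FALSE]
    if (nrow(don) == 0 || nrow(acc) == 0) return(empty)
    dx <- outer(don$x, acc$x, "-")
    dy <- outer(don$y, acc$y, "-")
    dz <- outer(don$z, acc$z, "-")
    d <- sqrt(dx^2 + dy^2 + dz^2)
    hit <- which(d <= long_cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0) return(empty)
    data.frame(chain = don$chain[hit[, 1]],
               donor_resno = don$resno[hit[, 1]],
               donor_resid = don$resid[hit[, 1]],
               donor_atom = don$elety[hit[, 1]],
               acceptor_resno = acc$resno[hit[, 2]],
               acceptor_resid = acc$resid[hit[, 2]],
               acceptor_atom = acc$elety[hit[, 2]],
               distance = d[hit], stringsAsFactors = FALSE)
  }
  out <- rbind(pairs_one_way(group_a, group_b),
               pairs_one_way(group_b, group_a))
  if (nrow(out) == 0) return(empty)
  out$tier <- ifelse(out$distance < short_cutoff, "short", "long")
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- interface area --------------------------------------------------------

# Classify an interface by the chemistry of the atoms that lose area:
# charged side-chain fraction high -> electrostatic, apolar carbon
# fraction high -> hydrophobic, otherwise mixed.
interface_character <- function(atoms, buried) {
  b <- buried > 1e-6
  if (!any(b)) return("none")
  at <- atoms[b, , drop = FALSE]
  w <- buried[b]
  charged <- (at$resid %in% c("ASP", "GLU") & grepl("^O[DE]", at$elety)) |
    (at$resid == "LYS" & at$elety == "NZ") |
    (at$resid == "ARG" & at$elety %in% c("NE", "NH1", "NH2"))
  apolar <- at$element == "C" & !(at$elety %in% c("C", "CA"))
  fc <- sum(w[charged]) / sum(w)
  fa <- sum(w[apolar]) / sum(w)
  if (fc >= 0.25) "electrostatic" else if (fa >= 0.60) "hydrophobic"
  else "mixed"
}

#' Buried interface area between two domains
#'
#' Per chain, the buried solvent-accessible area is
#' (SASA(a) + SASA(b) - SASA(a united with b)) / 2 (half the buried SASA,
#' PISA convention), and the report averages over chains. Hydrogen bonds
#' across the interface are censused with `find_hbonds()`.
#'
#' @param s `vl_structure`.
#' @param p `domain_partition`.
#' @param a,b domain labels.
#' @param probe_radius,n_points passed to `sasa()`.
#' @param short_cutoff,long_cutoff passed to `find_hbonds()`.
#' @return `interface_report`: list with domain pair, per-chain areas,
#'   mean area, hydrogen-bond table and a character tag.
#' @export
interface_area <- function(s, p, a, b, probe_radius = 1.4, n_points = 960,
                           short_cutoff = 3.5, long_cutoff = 4.0) {
  chains <- structure_chains(s)
  per_chain <- numeric(0)
  hb_all <- NULL
  char_votes <- character(0)
  for (ch in chains) {
    da <- suppressWarnings(select_domain(s, p, a, ch))
    db <- suppressWarnings(select_domain(s, p, b, ch))
    if (nrow(da$atoms) == 0 || nrow(db$atoms) == 0) next
    un <- merge_structures(da, db)
    # one shared canonical frame for all three evaluations, so the
    # separate-domain and complex areas cancel exactly where the domains
    # do not touch, and the whole report is rigid-motion invariant
    uxyz <- canonical_xyz(coords(un))
    na_ <- nrow(da$atoms)
    rad <- vdw_radius(un$atoms$element)
    sa <- sasa_cpp(uxyz[seq_len(na_), , drop = FALSE],
                   rad[seq_len(na_)], probe_radius,
                   as.integer(n_points))
    sb <- sasa_cpp(uxyz[-seq_len(na_), , drop = FALSE],
                   rad[-seq_len(na_)], probe_radius,
                   as.integer(n_points))
    su <- sasa_cpp(uxyz, rad, probe_radius, as.integer(n_points))
    buried <- c(sa, sb) - su
    area <- sum(buried) / 2
    per_chain[ch] <- max(0, area)
    hb <- find_hbonds(da, db, short_cutoff, long_cutoff)
    hb_all <- rbind(hb_all, hb)
    char_votes <- c(char_votes, interface_character(un$atoms, buried))
  }
  if (length(per_chain) == 0)
    stop("domains ", a, " and ", b, " are empty in every chain")
  char <- char_votes[char_votes != "none"]
  report <- list(domain_a = a, domain_b = b, per_chain_area = per_chain,
                 mean_area = mean(per_chain),
                 hbonds = hb_all %||% find_hbonds(
                   subset_structure(s, integer(0)),
                   subset_structure(s, integer(0))),
                 character = if (length(char)) names(sort(table(char),
                                                          decreasing = TRUE))[1]
                 else "none",
                 source_id = s$source_id)
  class(report) <- "interface_report"
  report
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface %s-%s (%s): mean area %.0f A^2 (%s); %d H-bonds\n",
              x$domain_a, x$domain_b, x$source_id, x$mean_area,
              paste(sprintf("%.0f", x$per_chain_area), collapse = "/"),
              nrow(x$hbonds)))
  cat("  character:", x$character, "\n")
  invisible(x)
}

#' Write an interface report to JSON and CSV
#'
#' @param report `interface_report`.
#' @param json_path,csv_path output files (NULL to skip either).
#' @return invisibly, the report.
#' @export
write_interface_report <- function(report, json_path = NULL,
                                   csv_path = NULL) {
  if (!is.null(json_path)) {
    out <- report
    class(out) <- NULL
    out$hbonds <- report$hbonds
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(csv_path)) write.csv(report$hbonds, csv_path,
                                    row.names = FALSE)
  invisible(report)
}

#' Compare interface reports across variants
#'
#' Hydrogen bonds are matched by donor and acceptor identity
#' (residue number + atom name) after applying a residue-number offset to
#' the comparison report (metavinculin tail numbering is +68). Bonds of
#' the reference with no partner are "lost"; matched bonds report the
#' distance change.
#'
#' @param reference,other `interface_report`s for the same domain pair.
#' @param offset residue-number offset added to reference donor/acceptor
#'   numbers before matching against `other` (e.g. 68 for the
#'   vinculin-to-metavinculin tail shift). Applied only to residues at or
#'   beyond `offset_from`.
#' @param offset_from first residue number the offset applies to
#'   (default 916, the insert position).
#' @return list with `matched` (distance deltas) and `lost` data.frames
#'   plus the mean-area delta.
#' @export
compare_interfaces <- function(reference, other, offset = 0,
                               offset_from = 916) {
  if (reference$domain_a != other$domain_a ||
      reference$domain_b != other$domain_b)
    stop("reports cover different domain pairs")
  shift <- function(resno) ifelse(resno >= offset_from, resno + offset,
                                  resno)
  ref <- reference$hbonds
  oth <- other$hbonds
  # collapse chains: take per-bond (identity) minimum distance per report
  collapse <- function(hb, apply_offset) {
    if (nrow(hb) == 0)
      return(data.frame(key = character(), distance = numeric(),
                        stringsAsFactors = FALSE))
    dn <- if (apply_offset) shift(hb$donor_resno) else hb$donor_resno
    an <- if (apply_offset) shift(hb$acceptor_resno) else hb$acceptor_resno
    k <- paste(dn, hb$donor_atom, an, hb$acceptor_atom, sep = "|")
    agg <- tapply(hb$distance, k, min)
    data.frame(key = names(agg), distance = as.numeric(agg),
               stringsAsFactors = FALSE)
  }
  r <- collapse(ref, TRUE)
  o <- collapse(oth, FALSE)
  m <- merge(r, o, by = "key", suffixes = c("_ref", "_other"))
  if (nrow(m)) m$delta <- m$distance_other - m$distance_ref
  lost <- r[!r$key %in% o$key, , drop = FALSE]
  gained <- o[!o$key %in% r$key, , drop = FALSE]
  list(matched = m, lost = lost, gained = gained,
       area_delta = other$mean_area - reference$mean_area)
}
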