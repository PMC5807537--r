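#' @title Native MS charge states and traveling-wave CCS calibration
#' @name imms
#' @description Charge-state envelope analysis of native electrospray
#'   spectra, power-law calibration of traveling-wave drift times against
#'   CCS standards, conversion of drift times to CCS, and compact/extended
#'   ensemble profiling.
NULL

PROTON_MASS <- 1.00728 # Da

#' Spectrum container
#'
#' @param mz strictly increasing m/z values (Th).
#' @param intensity matched non-negative intensities.
#' @param metadata free-form list.
#' @return `spectrum` object.
#' @export
spectrum <- function(mz, intensity, metadata = list()) {
  stopifnot(length(mz) == length(intensity), !is.unsorted(mz,
                                                          strictly = TRUE),
            all(intensity >= 0))
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 metadata = metadata), class = "spectrum")
}

#' Read a spectrum from CSV (columns mz, intensity)
#' @param path CSV file.
#' @return `spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  d <- read.csv(path)
  spectrum(d$mz, d$intensity, metadata = list(source = path))
}

#' Read one spectrum from an mzML file
#'
#' Requires the mzR package (Bioconductor); only the spectrum dimension
#' is read.
#'
#' @param path mzML file.
#' @param scan scan number (default 1).
#' @return `spectrum`.
#' @export
read_spectrum_mzml <- function(path, scan = 1) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  pk <- mzR::peaks(ms, scan)
  ord <- order(pk[, 1])
  spectrum(pk[ord, 1], pk[ord, 2], metadata = list(source = path,
                                                   scan = scan))
}

#' Read mobility records from CSV
#'
#' Expected columns: z (or charge), voltage, drift_ms, intensity.
#'
#' @param path CSV file.
#' @return data.frame (charge, voltage, drift_ms, intensity).
#' @export
read_mobility_csv <- function(path) {
  d <- read.csv(path)
  if ("z" %in% names(d) && !"charge" %in% names(d))
    names(d)[names(d) == "z"] <- "charge"
  need <- c("charge", "drift_ms")
  if (!all(need %in% names(d)))
    stop("mobility CSV needs columns: charge (or z), drift_ms")
  if (is.null(d$intensity)) d$intensity <- 1
  if (is.null(d$voltage)) d$voltage <- NA_real_
  d[, c("charge", "voltage", "drift_ms", "intensity")]
}

#' Detect charge states in a native spectrum
#'
#' Peaks are local maxima above a prominence floor, centroided by
#' intensity-weighted mean over a +/-`window`-bin neighbourhood. Charges
#' are assigned by scanning candidate charges for the highest-m/z peak and
#' choosing the assignment under which all peak masses agree best; the
#' neutral mass is the intensity-weighted mean of the per-peak masses.
#'
#' @param sp `spectrum`.
#' @param min_rel_intensity relative-intensity threshold defining "major"
#'   charge states (default 0.05 of the base peak).
#' @param floor detection floor as a fraction of the base peak
#'   (default 0.01).
#' @param window centroid half-window in bins (default 3).
#' @param proton_mass Da.
#' @param max_charge largest charge considered (default 80).
#' @param min_separation minimum m/z separation between distinct peaks
#'   (Th, default 20); closer maxima are shoulders of the taller peak.
#' @param smooth_bins running-mean pre-smoothing window for maximum
#'   detection (default 5 bins).
#' @return `charge_state_set`: entries table (z, centroid_mz,
#'   relative_intensity, major), inferred mass, envelope centre and major
#'   count.
#' @export
detect_charge_states <- function(sp, min_rel_intensity = 0.05,
                                 floor = 0.01, window = 3,
                                 proton_mass = PROTON_MASS,
                                 max_charge = 80, min_separation = 20,
                                 smooth_bins = 5) {
  y_raw <- sp$intensity
  n <- length(y_raw)
  y <- if (smooth_bins > 1 && n > smooth_bins)
    as.numeric(stats::filter(y_raw, rep(1 / smooth_bins, smooth_bins),
                             sides = 2)) else y_raw
  y[is.na(y)] <- 0
  base <- max(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_max & y >= floor * base)
  # prominence-style suppression: accept candidates tallest-first,
  # rejecting any within min_separation of an accepted peak
  cand <- cand[order(-y[cand])]
  acc <- integer(0)
  for (i in cand)
    if (!length(acc) || all(abs(sp$mz[acc] - sp$mz[i]) >= min_separation))
      acc <- c(acc, i)
  cand <- sort(acc)
  if (length(cand) < 2)
    stop("charge indeterminate: fewer than 2 resolvable peaks")
  # centroid over a window scaled to the smoothing width, on raw data
  centroid <- vapply(cand, function(i) {
    lo <- max(1, i - window); hi <- min(n, i + window)
    sum(sp$mz[lo:hi] * y_raw[lo:hi]) / sum(y_raw[lo:hi])
  }, numeric(1))
  height <- y[cand]
  ord <- order(centroid, decreasing = TRUE)
  centroid <- centroid[ord]; height <- height[ord]
  cands <- list()
  for (z1 in 1:max_charge) {
    m1 <- z1 * (centroid[1] - proton_mass)
    z <- pmax(1, round(m1 / (centroid - proton_mass)))
    if (any(duplicated(z))) next
    mass <- z * (centroid - proton_mass)
    cands[[length(cands) + 1]] <- list(z = z, mass = mass,
                                       cost = stats::sd(mass) /
                                         mean(mass))
  }
  if (!length(cands))
    stop("charge indeterminate: no consistent assignment")
  costs <- vapply(cands, function(cc) cc$cost, numeric(1))
  # integer multiples of the true charges are equally self-consistent
  # (harmonics); take the lowest-charge assignment among the best
  ok <- which(costs <= 1.5 * min(costs) + 1e-9)
  best <- cands[[ok[1]]]
  rel <- height / max(height)
  entries <- data.frame(z = best$z, centroid_mz = centroid,
                        relative_intensity = rel,
                        major = rel >= min_rel_intensity)
  entries <- entries[order(entries$z), ]
  rownames(entries) <- NULL
  out <- list(entries = entries,
              inferred_mass = weighted.mean(best$mass, height),
              envelope_center_mz = weighted.mean(centroid, height),
              n_major = sum(entries$major))
  class(out) <- "charge_state_set"
  out
}

#' @export
print.charge_state_set <- function(x, ...) {
  cat(sprintf(
    "charge states: %d major (of %d detected), mass %.0f Da, envelope centre %.0f Th\n",
    x$n_major, nrow(x$entries), x$inferred_mass, x$envelope_center_mz))
  invisible(x)
}

# ---- calibration -----------------------------------------------------------

#' Fit a traveling-wave CCS calibration
#'
#' Drift times are corrected for the mass-dependent instrument delay
#' (t' = t - edc * sqrt(m/z) / 1000), literature CCS values are reduced by
#' charge and reduced mass (ccs' = ccs / (z * sqrt(1/m + 1/gas_mass))),
#' and ln(ccs') is regressed on ln(t') to give the power law
#' ccs' = a * t'^b.
#'
#' @param cal calibrant table: data.frame with columns mass (Da), charge,
#'   ccs (A^2), drift_ms; >= 3 rows.
#' @param edc instrument delay coefficient (default 1.57).
#' @param gas_mass drift-gas mass, Da (default 28.0134, N2).
#' @return `calibration_model` with coefficients, per-calibrant relative
#'   residuals and the corrected-drift range.
#' @export
fit_calibration <- function(cal, edc = 1.57, gas_mass = 28.0134) {
  need <- c("mass", "charge", "ccs", "drift_ms")
  stopifnot(all(need %in% names(cal)))
  if (nrow(cal) < 3) stop("need at least 3 calibrants")
  mz <- (cal$mass + cal$charge * PROTON_MASS) / cal$charge
  tprime <- cal$drift_ms - edc * sqrt(mz) / 1000
  if (any(tprime <= 0)) {
    bad <- which(tprime <= 0)
    lab <- if ("name" %in% names(cal)) cal$name[bad] else bad
    stop("non-positive corrected drift time for calibrant(s): ",
         paste(lab, collapse = ", "))
  }
  ccs_red <- cal$ccs / (cal$charge * sqrt(1 / cal$mass + 1 / gas_mass))
  fit <- lm(log(ccs_red) ~ log(tprime))
  a <- exp(unname(coef(fit)[1]))
  b <- unname(coef(fit)[2])
  resid_rel <- (a * tprime^b - ccs_red) / ccs_red
  out <- list(coeff_a = a, exponent_b = b, edc_coefficient = edc,
              gas_mass = gas_mass, fit_residuals = resid_rel,
              drift_range = range(tprime))
  class(out) <- "calibration_model"
  out
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "TW calibration: ccs' = %.4g * t'^%.4f (edc %.2f, gas %.2f Da), max |resid| %.2g\n",
    x$coeff_a, x$exponent_b, x$edc_coefficient, x$gas_mass,
    max(abs(x$fit_residuals))))
  invisible(x)
}

# vectorised drift -> CCS (no replicate handling); used by fingerprints
calibrated_ccs <- function(model, drift_ms, charge, mass) {
  mz <- (mass + charge * PROTON_MASS) / charge
  tprime <- drift_ms - model$edc_coefficient * sqrt(mz) / 1000
  if (any(tprime <= 0)) stop("non-positive corrected drift time")
  model$coeff_a * tprime^model$exponent_b * charge *
    sqrt(1 / mass + 1 / model$gas_mass)
}

#' Convert mobility records to a CCS value
#'
#' Replicate records (e.g. repeated wave heights) are combined:
#' the value is the intensity-weighted mean and the sd the spread across
#' replicates. Results outside the calibrant drift range are flagged
#' (attribute "extrapolated").
#'
#' @param rec data.frame with columns charge, drift_ms and optionally
#'   intensity (single charge state).
#' @param analyte_mass Da.
#' @param model `calibration_model`.
#' @return `ccs_value` (method "calibrated_experimental").
#' @export
ccs_from_drift <- function(rec, analyte_mass, model) {
  stopifnot(nrow(rec) >= 1, length(unique(rec$charge)) == 1)
  w <- rec$intensity %||% rep(1, nrow(rec))
  if (is.null(rec$intensity)) w <- rep(1, nrow(rec))
  ccs <- calibrated_ccs(model, rec$drift_ms, rec$charge, analyte_mass)
  mz <- (analyte_mass + rec$charge * PROTON_MASS) / rec$charge
  tprime <- rec$drift_ms - model$edc_coefficient * sqrt(mz) / 1000
  out <- ccs_value(weighted.mean(ccs, w),
                   if (length(ccs) > 1) stats::sd(ccs) else 0,
                   "calibrated_experimental")
  attr(out, "extrapolated") <- any(tprime < model$drift_range[1] |
                                     tprime > model$drift_range[2])
  out
}

# ---- ensemble profiling ----------------------------------------------------

# deterministic 1-D two-means split (Lloyd with quantile init)
split_two <- function(x, w) {
  c1 <- quantile(rep(x, pmax(1, round(w))), 0.25, names = FALSE)
  c2 <- quantile(rep(x, pmax(1, round(w))), 0.90, names = FALSE)
  for (i in 1:50) {
    lower <- abs(x - c1) <= abs(x - c2)
    n1 <- weighted.mean(x[lower], w[lower])
    n2 <- if (any(!lower)) weighted.mean(x[!lower], w[!lower]) else c2
    if (abs(n1 - c1) + abs(n2 - c2) < 1e-9) break
    c1 <- n1; c2 <- n2
  }
  list(lower = lower, c1 = c1, c2 = c2)
}

#' Profile a conformer ensemble across charge states
#'
#' Converts per-charge mobility records to CCS, splits the ensemble into a
#' compact and an extended population at a threshold of
#' (compact centroid + k_sd * compact sd), and reports per-charge CCS,
#' population shares, the extended intensity fraction and the maximum
#' CCS.
#'
#' @param records data.frame (charge, drift_ms, intensity) spanning >= 2
#'   charge states.
#' @param analyte_mass Da.
#' @param model `calibration_model`.
#' @param k_sd threshold multiplier (default 3).
#' @return list with per-charge table, threshold, extended_fraction and
#'   max_ccs.
#' @export
ensemble_profile <- function(records, analyte_mass, model, k_sd = 3) {
  if (length(unique(records$charge)) < 2)
    stop("need records for at least 2 charge states")
  w <- records$intensity %||% rep(1, nrow(records))
  ccs <- calibrated_ccs(model, records$drift_ms, records$charge,
                        analyte_mass)
  sp <- split_two(ccs, w)
  # robust compact statistics: median/MAD core of the lower cluster, so
  # extended ions leaking into that cluster do not inflate the sd
  low <- ccs[sp$lower]
  med <- median(low)
  madv <- stats::mad(low)
  core <- sp$lower & abs(ccs - med) <= 3 * max(madv, 1e-9)
  compact_mu <- weighted.mean(ccs[core], w[core])
  compact_sd <- sqrt(weighted.mean((ccs[core] - compact_mu)^2, w[core]))
  # guard: a unimodal ensemble splits into halves of one peak, which
  # would put the threshold inside the peak; require genuine separation
  sep <- (sp$c2 - sp$c1) / max(compact_sd, 1e-9)
  threshold <- if (sep > 4) compact_mu + k_sd * compact_sd else
    max(ccs) + 1
  ext <- ccs > threshold
  per_charge <- do.call(rbind, lapply(split(seq_along(ccs),
                                            records$charge), function(ix) {
    data.frame(z = records$charge[ix[1]],
               ccs = weighted.mean(ccs[ix], w[ix]),
               population = sum(w[ix]) / sum(w))
  }))
  per_charge <- per_charge[order(per_charge$z), ]
  rownames(per_charge) <- NULL
  list(per_charge = per_charge, threshold = threshold,
       compact_centroid = compact_mu, compact_sd = compact_sd,
       extended_fraction = sum(w[ext]) / sum(w), max_ccs = max(ccs))
}
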