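#' @title Synthetic instrument- and microscope-data generator
#' @name synthgen
#' @description Seeded generators for every input the pipeline consumes:
#'   native spectra, calibrant tables, CIU mobility records, conformer
#'   ensembles and focal-adhesion image series. Per-variant defaults live
#'   in YAML parameter files (one per vinculin form) whose fields either
#'   transcribe published values (state CCS centroids, transition onsets,
#'   charge-state counts, extended fractions, decay slopes) or are
#'   explicitly marked free. All generators are deterministic for a fixed
#'   seed.
NULL

#' Load variant parameters
#'
#' @param name one of "vinculin", "metavinculin", "T12", "T12_A974K", or
#'   a path to a YAML parameter file with the same schema.
#' @return `variant_params` list.
#' @export
variant_params <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "variants", paste0(name, ".yaml"),
                package = "vinlock")
  if (path == "" || !file.exists(path))
    stop("unknown variant or missing parameter file: ", name)
  v <- yaml::read_yaml(path)
  stopifnot(!is.null(v$name), !is.null(v$mass),
            !is.null(v$charge_states))
  cc <- vapply(v$state_ccs, function(s) s$centroid, numeric(1))
  if (is.unsorted(cc)) stop("state centroids must be ordered C < SO < O")
  ef <- v$ensemble$extended_fraction %||% 0
  stopifnot(ef >= 0, ef <= 1)
  class(v) <- "variant_params"
  v
}

#' Names of the packaged variants
#' @return character vector.
#' @export
packaged_variants <- function() c("vinculin", "metavinculin", "T12",
                                  "T12_A974K")

#' Default traveling-wave calibration truth
#'
#' The generating coefficients used by every synthetic mobility dataset;
#' fitting `gen_calibrants()` output at zero noise recovers them exactly.
#' @return list(a, b, edc, gas_mass).
#' @export
default_calibration_truth <- function() {
  list(a = 350, b = 0.55, edc = 1.57, gas_mass = 28.0134)
}

# invert the calibration power law: CCS -> drift time (ms)
drift_from_ccs <- function(ccs, charge, mass, truth) {
  red <- ccs / (charge * sqrt(1 / mass + 1 / truth$gas_mass))
  tprime <- (red / truth$a)^(1 / truth$b)
  mz <- (mass + charge * PROTON_MASS) / charge
  tprime + truth$edc * sqrt(mz) / 1000
}

#' Generate a synthetic calibrant set
#'
#' Fictional but physically plausible protein standards (globular-scaling
#' CCS, native-like charges) whose drift times are solved exactly from
#' the calibration truth, optionally with multiplicative noise.
#'
#' @param truth list from `default_calibration_truth()`.
#' @param n number of calibrants (>= 3, default 8).
#' @param noise multiplicative drift-time noise sd (default 0).
#' @param seed integer seed.
#' @return data.frame (name, mass, charge, ccs, drift_ms).
#' @export
gen_calibrants <- function(truth = default_calibration_truth(), n = 8,
                           noise = 0, seed = 1) {
  if (n < 3) stop("need at least 3 calibrants")
  mass <- exp(seq(log(25000), log(1.3e6), length.out = n))
  charge <- pmax(1, round(0.06 * sqrt(mass)))
  ccs <- round(2.7 * mass^(2 / 3))
  drift <- drift_from_ccs(ccs, charge, mass, truth)
  if (noise > 0)
    drift <- with_seed(seed, drift * (1 + noise * rnorm(n)))
  data.frame(name = sprintf("syncal%02d", seq_len(n)), mass = mass,
             charge = charge, ccs = ccs, drift_ms = drift)
}

#' Default calibration model
#'
#' Calibration fitted to the packaged noiseless synthetic calibrants;
#' identical to the generator truth up to floating point.
#' @return `calibration_model`.
#' @export
default_calibration <- function() {
  fit_calibration(gen_calibrants(noise = 0))
}

#' Generate a native mass spectrum
#'
#' Gaussian peaks at (M + z * 1.00728) / z with the variant's per-charge
#' weights, multiplicative intensity noise and a small positive baseline.
#'
#' @param v `variant_params`.
#' @param seed integer seed (default: the variant file's seed).
#' @param n_points m/z grid size (default 6000).
#' @param peak_width_mz overrides the variant's peak width (Th).
#' @return `spectrum`.
#' @export
gen_spectrum <- function(v, seed = v$seed, n_points = 6000,
                         peak_width_mz = v$peak_width_mz %||% 6) {
  z <- as.numeric(v$charge_states$z)
  w <- as.numeric(v$charge_states$weight)
  stopifnot(length(z) == length(w), all(w >= 0))
  w <- w / max(w)
  centres <- (v$mass + z * PROTON_MASS) / z
  rng <- range(centres) + c(-40, 40) * peak_width_mz
  mz <- seq(rng[1], rng[2], length.out = n_points)
  y <- rowSums(vapply(seq_along(z), function(i)
    w[i] * exp(-0.5 * ((mz - centres[i]) / peak_width_mz)^2),
    numeric(n_points)))
  noise <- v$spectrum_noise %||% 0.03
  with_seed(seed, {
    y <- y * (1 + noise * rnorm(n_points)) +
      0.002 * abs(rnorm(n_points))
  })
  spectrum(mz, pmax(y, 0),
           metadata = list(variant = v$name, mass = v$mass, seed = seed))
}

# voltage-dependent state occupancies from the two logistic transitions
state_occupancy <- function(v, voltages) {
  p1 <- stats::plogis((voltages - v$transitions$c_so$mid) /
                        v$transitions$c_so$scale)
  p2 <- stats::plogis((voltages - v$transitions$so_o$mid) /
                        v$transitions$so_o$scale)
  cbind(C = 1 - p1, SO = p1 * (1 - p2), O = p1 * p2)
}

#' Generate collision-induced-unfolding mobility records
#'
#' Per collision voltage, ion counts are Poisson around
#' `mean_ions_per_voltage`; each ion draws a conformer state from the
#' logistic occupancy model, a CCS from that state's Gaussian, and a
#' drift time by inverting the calibration truth (plus multiplicative
#' jitter). Records carry the variant's CIU charge state.
#'
#' @param v `variant_params`.
#' @param voltages collision-voltage grid (default 50-240 V step 5).
#' @param truth calibration truth.
#' @param seed integer seed.
#' @param mean_ions mean ions per voltage (default from the variant
#'   file).
#' @return data.frame (charge, voltage, drift_ms, intensity) with the
#'   occupancy truth matrix as attribute "occupancy".
#' @export
gen_ciu <- function(v, voltages = seq(50, 240, by = 5),
                    truth = default_calibration_truth(), seed = v$seed,
                    mean_ions = v$mean_ions_per_voltage %||% 2000) {
  stopifnot(min(voltages) >= 50, max(voltages) <= 240)
  occ <- state_occupancy(v, voltages)
  cents <- vapply(v$state_ccs, function(s) s$centroid, numeric(1))
  widths <- vapply(v$state_ccs, function(s) s$width, numeric(1))
  z <- v$ciu_charge %||% 17
  jitter <- v$drift_noise %||% 0.003
  recs <- with_seed(seed, {
    out <- vector("list", length(voltages))
    for (i in seq_along(voltages)) {
      n <- rpois(1, mean_ions)
      if (n == 0) {
        out[[i]] <- NULL
        next
      }
      st <- sample.int(3, n, replace = TRUE, prob = occ[i, ])
      ccs <- rnorm(n, cents[st], widths[st])
      drift <- drift_from_ccs(ccs, z, v$mass, truth) *
        (1 + jitter * rnorm(n))
      out[[i]] <- data.frame(charge = z, voltage = voltages[i],
                             drift_ms = drift, intensity = 1)
    }
    do.call(rbind, out)
  })
  attr(recs, "occupancy") <- occ
  attr(recs, "state_ccs") <- cents
  recs
}

#' Generate a conformer-ensemble mobility dataset
#'
#' A mixture of a compact population (Gaussian CCS at the variant's
#' closed-state centroid, low charges) and an extended population
#' (uniform CCS up to the variant's maximum, high charges) at the
#' variant's extended fraction.
#'
#' @param v `variant_params`.
#' @param n_ions total ions (>= 1000, default 10000).
#' @param truth calibration truth.
#' @param seed integer seed.
#' @return data.frame (charge, drift_ms, intensity).
#' @export
gen_ensemble <- function(v, n_ions = 10000,
                         truth = default_calibration_truth(),
                         seed = v$seed) {
  if (n_ions < 1000) stop("need n_ions >= 1000")
  en <- v$ensemble
  frac <- en$extended_fraction %||% 0
  comp_z <- en$compact_charges %||% c(19, 24)
  ext_z <- en$extended_charges %||% c(25, 56)
  c_mu <- v$state_ccs$C$centroid
  c_w <- v$state_ccs$C$width
  with_seed(seed, {
    ext <- runif(n_ions) < frac
    n_ext <- sum(ext)
    ccs <- numeric(n_ions)
    charge <- integer(n_ions)
    ccs[!ext] <- rnorm(n_ions - n_ext, c_mu, c_w)
    charge[!ext] <- sample(seq(comp_z[1], comp_z[2]), n_ions - n_ext,
                           replace = TRUE)
    if (n_ext > 0) {
      ccs[ext] <- runif(n_ext, en$extended_ccs_min %||% 7400,
                        en$extended_ccs_max %||% 13200)
      charge[ext] <- sample(seq(ext_z[1], ext_z[2]), n_ext,
                            replace = TRUE)
    }
    data.frame(charge = charge,
               drift_ms = drift_from_ccs(ccs, charge, v$mass, truth),
               intensity = 1)
  })
}

# rasterise an ellipse (centre cx/cy px, semi-axes a/b px, angle theta)
ellipse_pixels <- function(cx, cy, a, b, theta, nr, nc) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(nr, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(nc, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- rep(r0:r1, times = c1 - c0 + 1)
  cc <- rep(c0:c1, each = r1 - r0 + 1)
  dx <- cc - cx; dy <- rr - cy
  u <- dx * cos(theta) + dy * sin(theta)
  w <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (w / b)^2 <= 1
  (cc[inside] - 1L) * nr + rr[inside]
}

#' Generate a focal-adhesion time-lapse dataset
#'
#' Elliptical adhesions with log-normal areas are placed without overlap
#' on a static label mask; each adhesion's intensity follows the
#' variant's plateau-exponential Y27632 response multiplied by global
#' photobleaching, plus read noise. Frames are written as 16-bit TIFFs,
#' together with the label mask, an untreated bleaching-reference series
#' and a ground-truth table.
#'
#' @param v `variant_params`.
#' @param n_fas adhesions to place (>= 1, default 1000).
#' @param frames time points (default 60).
#' @param dt_min frame interval, minutes (default 1).
#' @param out_dir output directory (created; default a fresh tempdir).
#' @param pixel_size um per pixel (default 0.1).
#' @param img_dim image size in pixels (default 1024).
#' @param seed integer seed.
#' @return list(labels, frame_paths, times, reference, truth, manifest);
#'   `labels` is the integer mask, `truth` the per-FA ground-truth table.
#' @export
gen_fa_dataset <- function(v, n_fas = 1000, frames = 60, dt_min = 1,
                           out_dir = NULL, pixel_size = 0.1,
                           img_dim = 1024, seed = v$seed) {
  stopifnot(n_fas >= 1, frames >= 1)
  if (is.null(out_dir))
    out_dir <- tempfile(paste0("fa_", v$name, "_"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fa <- v$fa
  nr <- img_dim; nc <- img_dim
  with_seed(seed, {
    areas <- stats::rlnorm(n_fas, fa$lognormal$mu, fa$lognormal$sigma)
    aspect <- stats::rlnorm(n_fas, log(2.5), 0.2)
    theta <- runif(n_fas, 0, pi)
    base <- stats::rlnorm(n_fas, log(12000), 0.3)
    labels <- matrix(0L, nr, nc)
    truth <- vector("list", n_fas)
    placed <- 0L
    for (i in seq_len(n_fas)) {
      b_px <- sqrt(areas[i] / (pi * aspect[i])) / pixel_size
      a_px <- aspect[i] * b_px
      ok <- FALSE
      for (try in 1:40) {
        cx <- runif(1, a_px + 2, nc - a_px - 2)
        cy <- runif(1, a_px + 2, nr - a_px - 2)
        pix <- ellipse_pixels(cx, cy, a_px, b_px, theta[i], nr, nc)
        if (length(pix) && all(labels[pix] == 0L)) {
          placed <- placed + 1L
          labels[pix] <- placed
          truth[[placed]] <- data.frame(
            id = placed, area_um2 = areas[i], aspect = aspect[i],
            theta = theta[i], base_intensity = base[i],
            n_pixels = length(pix))
          ok <- TRUE
          break
        }
      }
    }
    truth <- do.call(rbind, truth[seq_len(placed)])
    times <- (seq_len(frames) - 1) * dt_min
    # per-adhesion decay-rate heterogeneity (initial slope is linear in
    # the rate, so the population-mean slope is preserved)
    rate_i <- pmax(0, rnorm(placed, fa$decay$rate,
                            fa$decay$rate_sd %||% 0))
    decayf <- vapply(times, function(tt)
      fa$decay$plateau + (1 - fa$decay$plateau) * exp(-rate_i * tt),
      numeric(placed)) # placed x frames
    truth$rate <- rate_i
    bleachf <- exp(-fa$bleach_rate * times)
    frame_paths <- character(frames)
    for (t in seq_len(frames)) {
      lut <- c(0, truth$base_intensity * decayf[, t])
      img <- lut[labels + 1L] * bleachf[t] + 100 +
        rnorm(nr * nc, 0, 25)
      frame_paths[t] <- file.path(out_dir,
                                  sprintf("intensity_%03d.tif", t))
      write_intensity_tiff(matrix(img, nr, nc), frame_paths[t])
    }
    reference <- data.frame(
      time = times,
      intensity = 1000 * bleachf * (1 + 0.004 * rnorm(frames)))
    label_path <- file.path(out_dir, "labels.tif")
    write_intensity_tiff(labels, label_path)
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    write.csv(reference, file.path(out_dir, "reference.csv"),
              row.names = FALSE)
    manifest <- list(
      schema_version = "1", variant = v$name, seed = seed,
      n_fas_requested = n_fas, n_fas_placed = placed,
      frames = frames, dt_min = dt_min, pixel_size = pixel_size,
      img_dim = img_dim,
      params = fa,
      files = c(label_path, frame_paths,
                file.path(out_dir, c("truth.csv", "reference.csv"))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(labels = labels, frame_paths = frame_paths, times = times,
         reference = reference, truth = truth, manifest = manifest)
  })
}
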