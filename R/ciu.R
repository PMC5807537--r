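#' @title Collision-induced unfolding fingerprints
#' @name ciu
#' @description Fingerprint construction (voltage x CCS intensity maps),
#'   conformer-state detection by a shared-component Gaussian mixture
#'   (common centroids/widths across voltages, per-voltage weights),
#'   transition detection (onset, completion, gradual vs abrupt) and
#'   cross-variant comparison.
NULL

#' Build a CIU fingerprint from mobility records
#'
#' Records at many collision voltages (single charge state) are converted
#' to CCS, histogrammed per voltage on a shared axis and row-normalised.
#' All-zero rows are left at zero and flagged.
#'
#' @param records data.frame (charge, voltage, drift_ms, intensity).
#' @param model `calibration_model`.
#' @param analyte_mass Da.
#' @param ccs_bins number of CCS bins (default 200).
#' @param ccs_range optional c(min, max); defaults to the data range
#'   padded by 2%.
#' @param smooth_sd optional Gaussian smoothing sd along the CCS axis in
#'   bins (0 = none).
#' @return `ciu_fingerprint`: voltages, ccs_axis (bin centres), row-
#'   normalised intensity matrix, charge state, per-row ion counts and
#'   zero-row flags.
#' @export
build_fingerprint <- function(records, model, analyte_mass,
                              ccs_bins = 200, ccs_range = NULL,
                              smooth_sd = 0) {
  z <- unique(records$charge)
  if (length(z) != 1) stop("mixed charge states in CIU records")
  voltages <- sort(unique(records$voltage))
  if (length(voltages) < 5) stop("need records at >= 5 distinct voltages")
  w <- records$intensity %||% rep(1, nrow(records))
  ccs <- calibrated_ccs(model, records$drift_ms, z, analyte_mass)
  if (is.null(ccs_range)) {
    pad <- 0.02 * diff(range(ccs))
    ccs_range <- range(ccs) + c(-pad, pad)
  }
  edges <- seq(ccs_range[1], ccs_range[2], length.out = ccs_bins + 1)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  mat <- matrix(0, length(voltages), ccs_bins,
                dimnames = list(voltages, NULL))
  for (vi in seq_along(voltages)) {
    sel <- records$voltage == voltages[vi]
    bin <- findInterval(ccs[sel], edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    cnt <- tapply(w[sel], factor(bin, levels = seq_len(ccs_bins)), sum)
    cnt[is.na(cnt)] <- 0
    mat[vi, ] <- as.numeric(cnt)
  }
  counts <- rowSums(mat)
  if (smooth_sd > 0) {
    half <- ceiling(3 * smooth_sd)
    kern <- dnorm(-half:half, sd = smooth_sd)
    kern <- kern / sum(kern)
    for (vi in seq_len(nrow(mat))) {
      padded <- c(rep(0, half), mat[vi, ], rep(0, half))
      mat[vi, ] <- stats::convolve(padded, rev(kern),
                                   type = "filter")
    }
    mat[mat < 0] <- 0
  }
  zero_rows <- counts == 0
  norm <- mat
  norm[!zero_rows, ] <- mat[!zero_rows, , drop = FALSE] /
    rowSums(mat[!zero_rows, , drop = FALSE])
  fp <- list(voltages = voltages, ccs_axis = centres, intensity = norm,
             charge_state = z, row_counts = counts,
             zero_rows = zero_rows)
  class(fp) <- "ciu_fingerprint"
  fp
}

#' @export
print.ciu_fingerprint <- function(x, ...) {
  cat(sprintf(
    "CIU fingerprint (%d+): %d voltages %g-%g V, %d CCS bins %.0f-%.0f A^2\n",
    x$charge_state, length(x$voltages), min(x$voltages), max(x$voltages),
    length(x$ccs_axis), min(x$ccs_axis), max(x$ccs_axis)))
  invisible(x)
}

#' Plot a CIU fingerprint
#' @param x `ciu_fingerprint`.
#' @param ... passed to `image()`.
#' @export
plot.ciu_fingerprint <- function(x, ...) {
  graphics::image(x$voltages, x$ccs_axis, x$intensity,
                  xlab = "collision voltage (V)",
                  ylab = expression(CCS ~ (ring(A)^2)),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  ...)
}

#' Write / read a fingerprint as a CSV matrix
#'
#' First column is the voltage, remaining column names are the CCS bin
#' centres.
#' @param fp `ciu_fingerprint`.
#' @param path CSV file.
#' @export
write_fingerprint_csv <- function(fp, path) {
  d <- data.frame(voltage = fp$voltages, fp$intensity,
                  check.names = FALSE)
  names(d)[-1] <- sprintf("%.3f", fp$ccs_axis)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_csv
#' @param charge_state charge recorded in the restored object.
#' @export
read_fingerprint_csv <- function(path, charge_state = NA_integer_) {
  d <- read.csv(path, check.names = FALSE)
  mat <- as.matrix(d[, -1, drop = FALSE])
  fp <- list(voltages = d$voltage,
             ccs_axis = as.numeric(colnames(mat)),
             intensity = unname(mat), charge_state = charge_state,
             row_counts = rowSums(mat), zero_rows = rowSums(mat) == 0)
  class(fp) <- "ciu_fingerprint"
  fp
}

# ---- shared-component mixture ---------------------------------------------

# Weighted EM for a Gaussian mixture with centroids/widths shared across
# voltages and per-voltage weights. x: bin centres; W: voltages x bins
# weight matrix (ion counts per bin).
shared_mixture_em <- function(x, W, k, mu0, sigma0, max_iter = 300,
                              tol = 1e-8) {
  nv <- nrow(W)
  nb <- length(x)
  mu <- mu0
  sigma <- pmax(sigma0, diff(range(x)) / (5 * nb))
  pi_vk <- matrix(1 / k, nv, k)
  row_tot <- rowSums(W)
  act <- row_tot > 0
  ll_old <- -Inf
  sig_floor <- max(diff(x)[1], 1e-6)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) dnorm(x, mu[j], sigma[j]),
                   numeric(nb)) # nb x k
    ll <- 0
    mu_num <- numeric(k); mu_den <- numeric(k); s2_num <- numeric(k)
    R_list <- vector("list", nv)
    for (v in which(act)) {
      num <- sweep(dens, 2, pi_vk[v, ], "*") # nb x k
      tot <- rowSums(num)
      tot[tot < 1e-300] <- 1e-300
      r <- num / tot
      wr <- r * W[v, ]
      pi_vk[v, ] <- colSums(wr) / row_tot[v]
      mu_num <- mu_num + colSums(wr * x)
      mu_den <- mu_den + colSums(wr)
      R_list[[v]] <- wr
      ll <- ll + sum(W[v, ] * log(tot))
    }
    mu_new <- ifelse(mu_den > 0, mu_num / mu_den, mu)
    for (j in seq_len(k)) {
      s2 <- 0
      for (v in which(act)) s2 <- s2 + sum(R_list[[v]][, j] *
                                             (x - mu_new[j])^2)
      s2_num[j] <- s2
    }
    sigma_new <- sqrt(ifelse(mu_den > 0, s2_num / mu_den, sigma^2))
    sigma_new <- pmax(sigma_new, sig_floor)
    conv <- abs(ll - ll_old) < tol * (abs(ll) + 1)
    mu <- mu_new; sigma <- sigma_new
    ll_old <- ll
    if (conv) break
  }
  ord <- order(mu)
  list(mu = mu[ord], sigma = sigma[ord],
       weights = pi_vk[, ord, drop = FALSE], loglik = ll_old,
       n_params = 2 * k + sum(act) * (k - 1))
}

#' Detect conformer states in a CIU fingerprint
#'
#' Fits shared-component Gaussian mixtures (1 to `max_states` components
#' with voltage-independent centroids/widths and per-voltage occupancies)
#' by seeded multi-start EM and selects the component count by BIC.
#' Components are ordered by centroid and labelled C, SO, O.
#'
#' @param fp `ciu_fingerprint`.
#' @param max_states maximum component count (default 3).
#' @param seed integer seed for the multi-start initialisation.
#' @param n_starts EM restarts per component count (default 8).
#' @param presence_threshold occupancy defining when a state is "present"
#'   (default 0.10); sets each state's voltage_range.
#' @return list of `conformer_state` objects (label, centroid, width,
#'   occupancy per voltage, voltage_range), with the fitted mixture in
#'   attributes.
#' @export
detect_states <- function(fp, max_states = 3, seed = 7, n_starts = 8,
                          presence_threshold = 0.10) {
  x <- fp$ccs_axis
  W <- fp$intensity * fp$row_counts
  pooled <- colSums(W)
  pooled_mu <- sum(x * pooled) / sum(pooled)
  pooled_sd <- sqrt(sum(pooled * (x - pooled_mu)^2) / sum(pooled))
  n_eff <- sum(fp$row_counts)
  fits <- list()
  with_seed(seed, {
    for (k in seq_len(max_states)) {
      best <- NULL
      xs <- rep(x, pmax(1, round(pooled / max(pooled) * 500)))
      for (st in seq_len(n_starts)) {
        # first start: even quantiles; later starts: random quantile
        # spreads, so separated minor components are reachable
        qs <- if (st == 1) seq(0.1, 0.9, length.out = k) else
          sort(runif(k, 0.02, 0.98))
        mu0 <- as.numeric(quantile(xs, qs)) + rnorm(k, 0, pooled_sd / 10)
        fit <- shared_mixture_em(x, W, k, mu0,
                                 rep(pooled_sd / max(1, k - 1), k))
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      best$bic <- -2 * best$loglik + best$n_params * log(n_eff)
      fits[[k]] <- best
    }
  })
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  k_best <- which.min(bics)
  fit <- fits[[k_best]]
  labels <- switch(k_best, "C", c("C", "SO"), c("C", "SO", "O"),
                   c("C", "SO", "O", paste0("X", seq_len(k_best - 3))))
  if (k_best < 2)
    warning("fewer than 2 resolvable conformer components")
  states <- lapply(seq_len(k_best), function(j) {
    occ <- fit$weights[, j]
    occ[fp$zero_rows] <- 0
    present <- which(occ >= presence_threshold)
    vr <- if (length(present)) range(fp$voltages[present]) else
      c(NA_real_, NA_real_)
    structure(list(label = labels[j], centroid = fit$mu[j],
                   width = fit$sigma[j], occupancy = stats::setNames(
                     occ, fp$voltages),
                   voltage_range = vr,
                   presence_threshold = presence_threshold),
              class = "conformer_state")
  })
  attr(states, "fit") <- fit
  attr(states, "bic") <- bics
  attr(states, "voltages") <- fp$voltages
  states
}

#' @export
print.conformer_state <- function(x, ...) {
  cat(sprintf(
    "state %s: centroid %.0f A^2 (width %.0f), present %s-%s V\n",
    x$label, x$centroid, x$width,
    format(x$voltage_range[1]), format(x$voltage_range[2])))
  invisible(x)
}

#' Tabulate conformer states
#' @param states list from `detect_states()`.
#' @return data.frame (label, centroid, width, first/last presence V).
#' @export
states_table <- function(states) {
  do.call(rbind, lapply(states, function(s)
    data.frame(label = s$label, centroid = s$centroid, width = s$width,
               v_first = s$voltage_range[1], v_last = s$voltage_range[2])))
}

#' Detect transitions between adjacent conformer states
#'
#' For each adjacent state pair the transition onset is the first voltage
#' at which the new state is present (occupancy >= threshold), the
#' completion is the last voltage at which the old state is present, and
#' the coexistence width their difference. Transitions with coexistence
#' at least `gradual_min_width` are "gradual", otherwise "abrupt".
#'
#' @param states list from `detect_states()`.
#' @param step voltage grid step (V, default 5).
#' @param presence_threshold occupancy threshold (default 0.10).
#' @param gradual_min_width V (default 3 * step).
#' @return data.frame of transition reports (one row per adjacent pair).
#' @export
detect_transitions <- function(states, step = 5,
                               presence_threshold = 0.10,
                               gradual_min_width = 3 * step) {
  if (length(states) < 2) stop("need >= 2 states")
  voltages <- as.numeric(names(states[[1]]$occupancy))
  rows <- list()
  for (i in seq_len(length(states) - 1)) {
    old <- states[[i]]; new <- states[[i + 1]]
    new_on <- voltages[new$occupancy >= presence_threshold]
    old_on <- voltages[old$occupancy >= presence_threshold]
    if (!length(new_on) || !length(old_on)) {
      rows[[i]] <- data.frame(
        from_state = old$label, to_state = new$label,
        onset_voltage = NA_real_, completion_voltage = NA_real_,
        coexistence_width = NA_real_, mode = "absent")
      next
    }
    onset <- min(new_on)
    completion <- max(old_on)
    coex <- completion - onset
    rows[[i]] <- data.frame(
      from_state = old$label, to_state = new$label,
      onset_voltage = onset, completion_voltage = completion,
      coexistence_width = coex,
      mode = if (coex >= gradual_min_width) "gradual" else "abrupt")
  }
  do.call(rbind, rows)
}

#' Voltage stability (dwell) per state
#'
#' @param states list from `detect_states()`.
#' @param step voltage step (default 5).
#' @param presence_threshold occupancy threshold (default 0.10).
#' @return data.frame (state, v_first, v_last, dwell) where dwell is the
#'   presence extent in volts (one isolated grid point dwells `step`).
#' @export
stability_profile <- function(states, step = 5,
                              presence_threshold = 0.10) {
  voltages <- as.numeric(names(states[[1]]$occupancy))
  do.call(rbind, lapply(states, function(s) {
    on <- voltages[s$occupancy >= presence_threshold]
    data.frame(state = s$label,
               v_first = if (length(on)) min(on) else NA_real_,
               v_last = if (length(on)) max(on) else NA_real_,
               dwell = if (length(on)) max(on) - min(on) + step else 0)
  }))
}

# interpolate a fingerprint onto a new CCS axis, renormalising rows
rebin_fingerprint <- function(fp, axis) {
  mat <- t(apply(fp$intensity, 1, function(row)
    approx(fp$ccs_axis, row, xout = axis, yleft = 0, yright = 0)$y))
  tot <- rowSums(mat)
  mat[tot > 0, ] <- mat[tot > 0, , drop = FALSE] / tot[tot > 0]
  fp$ccs_axis <- axis
  fp$intensity <- mat
  fp$zero_rows <- tot == 0
  fp
}

#' Compare CIU fingerprints across variants
#'
#' Aligns fingerprints on a shared CCS axis (interpolating where the axes
#' differ), extracts per-variant CCS profiles at selected voltages, and
#' tabulates the first transition onset per variant.
#'
#' @param fingerprints named list of `ciu_fingerprint`.
#' @param at_voltages voltages for the profile overlay
#'   (default c(100, 125, 230)).
#' @param seed forwarded to `detect_states()`.
#' @param ... forwarded to `detect_states()`.
#' @return list with `profiles` (long data.frame: variant, voltage, ccs,
#'   intensity) and `onsets` (variant, onset_voltage, mode).
#' @export
compare_variants <- function(fingerprints, at_voltages = c(100, 125, 230),
                             seed = 7, ...) {
  stopifnot(length(fingerprints) >= 1, !is.null(names(fingerprints)))
  axis <- fingerprints[[1]]$ccs_axis
  aligned <- lapply(fingerprints, function(fp)
    if (isTRUE(all.equal(fp$ccs_axis, axis))) fp else
      rebin_fingerprint(fp, axis))
  profiles <- do.call(rbind, lapply(names(aligned), function(nm) {
    fp <- aligned[[nm]]
    do.call(rbind, lapply(at_voltages, function(v) {
      vi <- which.min(abs(fp$voltages - v))
      data.frame(variant = nm, voltage = fp$voltages[vi],
                 ccs = fp$ccs_axis, intensity = fp$intensity[vi, ])
    }))
  }))
  onsets <- do.call(rbind, lapply(names(aligned), function(nm) {
    st <- detect_states(aligned[[nm]], seed = seed, ...)
    tr <- if (length(st) >= 2) detect_transitions(st) else NULL
    data.frame(variant = nm,
               onset_voltage = if (!is.null(tr)) tr$onset_voltage[1]
               else NA_real_,
               mode = if (!is.null(tr)) tr$mode[1] else "absent")
  }))
  list(profiles = profiles, onsets = onsets)
}
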