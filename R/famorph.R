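#' @title Focal-adhesion morphometry and decay kinetics
#' @name famorph
#' @description Per-adhesion measurements from labelled masks (area,
#'   maximal Feret length, mean fluorescence), log-normal size-
#'   distribution fits, photobleaching correction against a reference
#'   series, and plateau-exponential decay fits of FA intensity after
#'   contractility inhibition (Y27632).
NULL

FA_SMALL_AREA <- 1   # um^2; "small" class boundary
FA_SHORT_LENGTH <- 2 # um;   "short" class boundary

# maximal Feret diameter of a pixel blob (pixel centres, convex hull)
feret_diameter <- function(rowcol) {
  if (nrow(rowcol) == 1) return(0)
  h <- grDevices::chull(rowcol)
  pts <- rowcol[h, , drop = FALSE]
  d2 <- outer(rowSums(pts^2), rowSums(pts^2), "+") - 2 * pts %*% t(pts)
  sqrt(max(d2))
}

#' Measure focal adhesions from a labelled mask
#'
#' @param label_image integer matrix; 0 = background, positive integers
#'   label individual adhesions.
#' @param intensity_image numeric matrix, same shape.
#' @param pixel_size um per pixel edge.
#' @param small_area,short_length class boundaries (um^2, um); classes are
#'   half-open: small iff area < small_area, short iff length <
#'   short_length.
#' @return data.frame, one row per label: id, area (um^2), length (um,
#'   maximal Feret diameter over pixel centres), mean_intensity,
#'   size_class, length_class.
#' @export
measure_fas <- function(label_image, intensity_image,
                        pixel_size = 0.1,
                        small_area = FA_SMALL_AREA,
                        short_length = FA_SHORT_LENGTH) {
  stopifnot(all(dim(label_image) == dim(intensity_image)),
            pixel_size > 0)
  lab <- as.integer(label_image)
  pos <- lab > 0L
  if (!any(pos))
    return(data.frame(id = integer(), area = numeric(),
                      length = numeric(), mean_intensity = numeric(),
                      size_class = character(),
                      length_class = character()))
  ids <- sort(unique(lab[pos]))
  counts <- tabulate(lab[pos])
  inten <- as.numeric(intensity_image)
  sums <- rowsum(inten[pos], lab[pos])
  idx_by_id <- split(which(pos), lab[pos])
  nr <- nrow(label_image)
  out <- data.frame(
    id = ids,
    area = counts[ids] * pixel_size^2,
    length = vapply(as.character(ids), function(k) {
      ix <- idx_by_id[[k]]
      rc <- cbind((ix - 1L) %% nr + 1L, (ix - 1L) %/% nr + 1L)
      feret_diameter(rc) * pixel_size
    }, numeric(1)),
    mean_intensity = sums[as.character(ids), 1] / counts[ids],
    row.names = NULL)
  out$size_class <- ifelse(out$area < small_area, "small", "large")
  out$length_class <- ifelse(out$length < short_length, "short", "long")
  out
}

#' Fit a log-normal size distribution
#'
#' Maximum-likelihood fit with 95% confidence intervals from the
#' asymptotic standard errors (or a nonparametric bootstrap).
#'
#' @param areas positive areas (um^2), n >= 20.
#' @param ci "normal" (default) or "bootstrap".
#' @param n_boot bootstrap replicates when ci = "bootstrap".
#' @return `size_distribution_fit`: mu/sigma (log space), their 95% CIs,
#'   the fitted median exp(mu) and n.
#' @export
fit_size_distribution <- function(areas, ci = c("normal", "bootstrap"),
                                  n_boot = 500) {
  ci <- match.arg(ci)
  if (length(areas) < 20)
    stop("need at least 20 areas (got ", length(areas), ")")
  bad <- which(areas <= 0)
  if (length(bad))
    stop("non-positive areas at positions: ",
         paste(head(bad, 10), collapse = ", "))
  if (stats::sd(log(areas)) < 1e-10)
    stop("degenerate size distribution: all areas equal (sigma -> 0)")
  fit <- MASS::fitdistr(areas, "lognormal")
  mu <- unname(fit$estimate["meanlog"])
  sigma <- unname(fit$estimate["sdlog"])
  if (ci == "normal") {
    ci_mu <- mu + c(-1, 1) * qnorm(0.975) * fit$sd["meanlog"]
    ci_sigma <- sigma + c(-1, 1) * qnorm(0.975) * fit$sd["sdlog"]
  } else {
    reps <- replicate(n_boot, {
      b <- sample(areas, replace = TRUE)
      c(mean(log(b)), stats::sd(log(b)))
    })
    ci_mu <- quantile(reps[1, ], c(0.025, 0.975), names = FALSE)
    ci_sigma <- quantile(reps[2, ], c(0.025, 0.975), names = FALSE)
  }
  structure(list(family = "log-normal", mu = mu, sigma = sigma,
                 ci95 = list(mu = ci_mu, sigma = ci_sigma),
                 median = exp(mu), n = length(areas)),
            class = "size_distribution_fit")
}

#' @export
print.size_distribution_fit <- function(x, ...) {
  cat(sprintf(
    "log-normal fit (n=%d): mu %.3f [%.3f, %.3f], sigma %.3f [%.3f, %.3f]; median %.2f um^2\n",
    x$n, x$mu, x$ci95$mu[1], x$ci95$mu[2], x$sigma, x$ci95$sigma[1],
    x$ci95$sigma[2], x$median))
  invisible(x)
}

#' Correct a fluorescence series for photobleaching
#'
#' corrected(t) = series(t) * reference(0) / reference(t), with the
#' reference smoothed before division. The default smoother fits a
#' mono-exponential to the reference (bleaching is first-order
#' photochemistry), which avoids the boundary bias of running-window
#' smoothers on a decaying curve; a centred running mean is available as
#' an alternative.
#'
#' @param series data.frame (time, intensity) for the treated signal, or
#'   a frames x adhesions matrix (each column corrected independently).
#' @param reference data.frame (time, intensity) for an untreated
#'   bleaching control on the same time base.
#' @param smooth "exp" (default), "mean" or "none".
#' @param smooth_window running-mean window when smooth = "mean"
#'   (default 5).
#' @return corrected series (data.frame) or matrix, matching the input.
#' @export
bleach_correct <- function(series, reference,
                           smooth = c("exp", "mean", "none"),
                           smooth_window = 5) {
  smooth <- match.arg(smooth)
  is_mat <- is.matrix(series)
  tser <- if (is_mat) reference$time else series$time
  if (is_mat) {
    if (nrow(series) != nrow(reference))
      stop("series and reference must share the same time base")
  } else if (!isTRUE(all.equal(series$time, reference$time)))
    stop("series and reference must share the same time base")
  ref <- reference$intensity
  if (any(ref <= 0)) stop("reference intensity reaches zero")
  if (smooth == "exp") {
    ref <- exp(stats::fitted(lm(log(ref) ~ reference$time)))
  } else if (smooth == "mean" && smooth_window > 1) {
    half <- floor(smooth_window / 2)
    n <- length(ref)
    ref <- vapply(seq_len(n), function(i)
      mean(reference$intensity[max(1, i - half):min(n, i + half)]),
      numeric(1))
  }
  if (any(ref <= 0)) stop("reference intensity reaches zero")
  fac <- ref[1] / ref
  if (is_mat) series * fac else
    data.frame(time = tser, intensity = series$intensity * fac)
}

#' Fit a plateau-exponential decay
#'
#' I(t) = plateau + (1 - plateau) * exp(-rate * t) for a series
#' normalised to 1 at t = 0; the initial slope is
#' 100 * rate * (1 - plateau) in %/min. Confidence intervals come from a
#' bootstrap over adhesions when a per-FA intensity matrix is supplied,
#' otherwise from the asymptotic covariance.
#'
#' @param series data.frame (time in min, intensity), >= 6 points,
#'   intensity(0) ~ 1.
#' @param fa_matrix optional frames x adhesions matrix of per-FA
#'   intensities (same rows as `series`); enables the FA bootstrap.
#' @param n_boot bootstrap replicates (default 200).
#' @return `decay_fit`: rate (1/min), plateau, initial_slope (%/min),
#'   ci95 on rate and slope, flags.
#' @export
fit_decay <- function(series, fa_matrix = NULL, n_boot = 200) {
  t <- series$time
  y <- series$intensity
  if (length(t) < 6) stop("need at least 6 time points")
  if (abs(y[1] - 1) > 0.05)
    warning("series does not start near 1; fit assumes normalisation at t = 0")
  fit_one <- function(yy) {
    if (stats::sd(yy) < 1e-12) return(c(rate = 0, plateau = 1))
    p0 <- max(min(min(yy), 0.99), 0)
    tail_drop <- max(1e-3, 1 - p0)
    r0 <- max(0.001, -coef(lm(log(pmax(yy - p0 * 0.9, 1e-3)) ~ t))[2])
    fit <- tryCatch(
      suppressWarnings(
        nls(yy ~ plateau + (1 - plateau) * exp(-rate * t),
            start = list(plateau = p0 * 0.9, rate = r0),
            algorithm = "port", lower = c(0, 0), upper = c(1, 10),
            control = list(warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) return(c(rate = 0, plateau = 1))
    cf <- coef(fit)
    c(rate = unname(cf["rate"]), plateau = unname(cf["plateau"]))
  }
  est <- fit_one(y)
  slope <- 100 * est["rate"] * (1 - est["plateau"])
  if (!is.null(fa_matrix)) {
    stopifnot(nrow(fa_matrix) == length(t))
    reps <- replicate(n_boot, {
      cols <- sample.int(ncol(fa_matrix), replace = TRUE)
      m <- rowMeans(fa_matrix[, cols, drop = FALSE])
      e <- fit_one(m / m[1])
      c(e["rate"], 100 * e["rate"] * (1 - e["plateau"]))
    })
    ci_rate <- quantile(reps[1, ], c(0.025, 0.975), names = FALSE)
    ci_slope <- quantile(reps[2, ], c(0.025, 0.975), names = FALSE)
  } else {
    # crude residual-based interval: refit on residual-resampled series
    res <- y - (est["plateau"] + (1 - est["plateau"]) *
                  exp(-est["rate"] * t))
    reps <- replicate(n_boot, {
      e <- fit_one(pmax(y + sample(res, replace = TRUE), 0))
      c(e["rate"], 100 * e["rate"] * (1 - e["plateau"]))
    })
    ci_rate <- quantile(reps[1, ], c(0.025, 0.975), names = FALSE)
    ci_slope <- quantile(reps[2, ], c(0.025, 0.975), names = FALSE)
  }
  structure(list(rate = unname(est["rate"]),
                 plateau = unname(est["plateau"]),
                 initial_slope = unname(slope),
                 ci95 = list(rate = ci_rate, initial_slope = ci_slope),
                 bleach_corrected = NA,
                 flat = est["rate"] == 0 || ci_rate[1] <= 1e-9),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay fit: rate %.4f /min [%.4f, %.4f], plateau %.2f, initial slope %.2f %%/min [%.2f, %.2f]\n",
    x$rate, x$ci95$rate[1], x$ci95$rate[2], x$plateau, x$initial_slope,
    x$ci95$initial_slope[1], x$ci95$initial_slope[2]))
  invisible(x)
}

#' Per-frame FA intensity series from an image-series dataset
#'
#' Runs `measure_fas()` on every frame of a generated or measured
#' dataset, subtracts the background (median intensity outside all
#' labels) and returns the mean-FA series plus the per-FA matrix for
#' bootstrap CIs.
#'
#' @param labels integer label matrix (static mask).
#' @param frame_paths TIFF files, one per frame (16-bit).
#' @param times time of each frame (min).
#' @param pixel_size um per pixel.
#' @return list(series = data.frame(time, intensity), fa_matrix,
#'   morphometry = frame-1 `measure_fas()` table).
#' @export
fa_intensity_series <- function(labels, frame_paths, times,
                                pixel_size = 0.1) {
  stopifnot(length(frame_paths) == length(times))
  fa_mat <- NULL
  morpho <- NULL
  for (i in seq_along(frame_paths)) {
    img <- read_intensity_tiff(frame_paths[i])
    meas <- measure_fas(labels, img, pixel_size)
    if (i == 1) {
      morpho <- meas
      fa_mat <- matrix(NA_real_, length(frame_paths), nrow(meas))
    }
    bg <- median(img[labels == 0L])
    fa_mat[i, ] <- meas$mean_intensity - bg
  }
  series <- data.frame(time = times, intensity = rowMeans(fa_mat))
  list(series = series, fa_matrix = fa_mat, morphometry = morpho)
}

#' Read a 16-bit TIFF as a numeric matrix (counts)
#' @param path TIFF file.
#' @return numeric matrix scaled back to 0..65535 counts.
#' @export
read_intensity_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 65535)
}

#' Write a counts matrix as a 16-bit TIFF
#' @param mat numeric matrix of counts (0..65535).
#' @param path output file.
#' @export
write_intensity_tiff <- function(mat, path) {
  tiff::writeTIFF(pmin(pmax(mat, 0), 65535) / 65535, path,
                  bits.per.sample = 16)
  invisible(path)
}
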