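#' Calibrate a per-HU Gaussian noise lookup table from a paired scan
#'
#' For every CT number occurring in the reference (standard-protocol) image
#' within the selected slices, computes the sample mean and sample standard
#' deviation (n-1 denominator) of the co-located voxels of the low-dose
#' image. Sample statistics are used deliberately instead of least-squares
#' Gaussian histogram fits: the fit is sensitive to histogram binning, which
#' would have to be tuned per CT number, while the sample estimators are
#' not. The reference image is treated as noise-free, so all paired
#' variance is attributed to the low-dose image.
#'
#' Bins with fewer than `min_samples` voxels are filled by linear
#' interpolation between the nearest well-populated bins (constant
#' continuation at the ends) and flagged `interpolated`.
#'
#' @param reference CT [volume3d()], the standard-protocol image.
#' @param low_dose CT [volume3d()] aligned to `reference`.
#' @param slice_selection integer vector of sagittal (x-axis) slice indices,
#'   1-based; default the 11 central sagittal slices (central slice plus 5
#'   to each side). Use `NULL` explicitly for all voxels via
#'   `seq_len(nx)`.
#' @param bin_width reference-HU bin width (default 1 HU; CT numbers are
#'   integers).
#' @param min_samples minimum voxels per bin for a direct estimate
#'   (default 100).
#' @param protocol optional [scan_protocol()] recorded as metadata.
#' @return a `noise_lut`: data.frame with columns `reference_hu`,
#'   `mean_hu`, `sigma_hu`, `n_samples`, `interpolated`, plus metadata
#'   attributes.
#' @export
calibrate_noise <- function(reference, low_dose, slice_selection = NULL,
                            bin_width = 1, min_samples = 100,
                            protocol = NULL) {
  stop_if_misaligned(reference$grid, low_dose$grid)
  nx <- reference$grid$size[1]
  if (is.null(slice_selection)) {
    mid <- (nx + 1L) %/% 2L
    slice_selection <- (mid - 5L):(mid + 5L)
  }
  slice_selection <- as.integer(slice_selection)
  if (length(slice_selection) == 0L) stop("slice selection is empty")
  if (any(slice_selection < 1L | slice_selection > nx)) {
    stop("slice selection outside the volume (1..", nx, ")")
  }
  ref <- as.numeric(reference$values[slice_selection, , ])
  low <- as.numeric(low_dose$values[slice_selection, , ])

  bin <- round(ref / bin_width) * bin_width
  agg <- rowsum(cbind(low, low^2, 1), group = bin)
  hu <- as.numeric(rownames(agg))
  n <- agg[, 3]
  m <- agg[, 1] / n
  ssq <- pmax(agg[, 2] - n * m^2, 0)
  s <- ifelse(n > 1, sqrt(ssq / (n - 1)), 0)
  filled <- n >= min_samples
  if (!any(filled)) {
    stop("no reference-HU bin reaches min_samples = ", min_samples,
         " voxels; calibration impossible")
  }
  # dense bin axis over the observed range, linear interpolation for gaps
  grid_hu <- seq(min(hu), max(hu), by = bin_width)
  fhu <- hu[filled]
  fm <- m[filled]
  fs <- s[filled]
  if (length(fhu) == 1L) {
    mean_i <- rep(fm, length(grid_hu))
    sig_i <- rep(fs, length(grid_hu))
  } else {
    mean_i <- stats::approx(fhu, fm, xout = grid_hu, rule = 2)$y
    sig_i <- stats::approx(fhu, fs, xout = grid_hu, rule = 2)$y
  }
  n_i <- integer(length(grid_hu))
  n_i[match(hu, grid_hu)] <- as.integer(n)
  interp <- !(grid_hu %in% fhu)
  lut <- data.frame(reference_hu = grid_hu, mean_hu = mean_i,
                    sigma_hu = sig_i, n_samples = n_i,
                    interpolated = as.integer(interp))
  attr(lut, "bin_width") <- bin_width
  attr(lut, "min_samples") <- min_samples
  attr(lut, "protocol") <- protocol
  class(lut) <- c("noise_lut", "data.frame")
  lut
}

#' Build a lookup table directly from the tube-current scaling law
#'
#' Constructs an identity-mean table with constant sigma
#' `sigma0 * sqrt(I_ref / I)` over an HU domain, optionally with the
#' anchor's systematic mean shift. This is the model-based alternative to
#' [calibrate_noise()] when no paired scan is available.
#'
#' @param anchor a [noise_anchor()].
#' @param tube_current_ma target protocol current, mA.
#' @param hu_range integer HU domain covered (default -1024..3071).
#' @param mean_shift apply the anchor mean shift? Default FALSE.
#' @return a `noise_lut`.
#' @export
lut_from_anchor <- function(anchor, tube_current_ma,
                            hu_range = c(-1024, 3071), mean_shift = FALSE) {
  sigma <- sigma_at_current(anchor, tube_current_ma)
  hu <- seq(hu_range[1], hu_range[2])
  mu <- if (mean_shift) anchor$mean_shift_hu else 0
  lut <- data.frame(reference_hu = hu, mean_hu = hu + mu, sigma_hu = sigma,
                    n_samples = 0L, interpolated = 0L)
  attr(lut, "bin_width") <- 1
  attr(lut, "min_samples") <- 0L
  class(lut) <- c("noise_lut", "data.frame")
  lut
}

#' Look up lookup-table entries for HU values
#'
#' Constant extrapolation beyond the table ends (the nearest end bin is
#' used); with `extrapolate = FALSE` out-of-domain HU raise an error
#' listing the offending values.
#'
#' @param lut a `noise_lut`.
#' @param hu numeric vector of reference HU.
#' @param extrapolate allow constant end extrapolation (default TRUE).
#' @return list with numeric vectors `mean_hu` and `sigma_hu`.
#' @export
lut_lookup <- function(lut, hu, extrapolate = TRUE) {
  bw <- attr(lut, "bin_width")
  lo <- lut$reference_hu[1]
  hi <- lut$reference_hu[nrow(lut)]
  q <- round(hu / bw) * bw
  if (!extrapolate && any(q < lo | q > hi)) {
    bad <- sort(unique(q[q < lo | q > hi]))
    stop("HU values outside the lookup-table domain [", lo, ", ", hi, "]: ",
         paste(utils::head(bad, 20), collapse = ", "))
  }
  idx <- pmin(pmax(round((q - lo) / bw), 0), (hi - lo) / bw) + 1
  list(mean_hu = lut$mean_hu[idx], sigma_hu = lut$sigma_hu[idx])
}

#' Read/write a noise lookup table as CSV
#'
#' Columns: `reference_hu, mean_hu, sigma_hu, n_samples, interpolated`
#' (header mandatory).
#' @param lut a `noise_lut`.
#' @param path CSV path.
#' @return `read_lut`: a `noise_lut`; `write_lut`: `path` invisibly.
#' @export
write_lut <- function(lut, path) {
  utils::write.csv(as.data.frame(lut), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lut
#' @param bin_width bin width recorded on read (default 1).
#' @export
read_lut <- function(path, bin_width = 1) {
  df <- utils::read.csv(path)
  need <- c("reference_hu", "mean_hu", "sigma_hu", "n_samples",
            "interpolated")
  if (!all(need %in% names(df))) {
    stop("lookup-table CSV must have columns: ", paste(need, collapse = ", "))
  }
  lut <- df[need]
  attr(lut, "bin_width") <- bin_width
  class(lut) <- c("noise_lut", "data.frame")
  lut
}

#' Gaussianity report for one reference-HU bin
#'
#' Histograms the low-dose CT numbers of the voxels whose reference CT
#' number falls in the requested bin, fits a Gaussian by least squares to
#' the histogram, and reports the fitted parameters next to the sample
#' mean/sigma. The goodness metric is the coefficient of determination of
#' the fit. A degenerate bin (zero spread) is reported without a fit.
#'
#' @param reference,low_dose aligned CT [volume3d()] objects.
#' @param bin reference CT number of the bin to analyze.
#' @param slice_selection as in [calibrate_noise()].
#' @param bin_width reference bin width (default 1).
#' @param min_samples minimum voxels required in the bin (default 100).
#' @return list with `histogram` (mids, counts), `fit` (amplitude, mean,
#'   sigma) or NULL if degenerate, `sample` (mean, sigma, n),
#'   `r_squared`, `degenerate`.
#' @export
gaussianity_report <- function(reference, low_dose, bin,
                               slice_selection = NULL, bin_width = 1,
                               min_samples = 100) {
  stop_if_misaligned(reference$grid, low_dose$grid)
  nx <- reference$grid$size[1]
  if (is.null(slice_selection)) {
    mid <- (nx + 1L) %/% 2L
    slice_selection <- (mid - 5L):(mid + 5L)
  }
  ref <- as.numeric(reference$values[slice_selection, , ])
  low <- as.numeric(low_dose$values[slice_selection, , ])
  sel <- round(ref / bin_width) * bin_width == bin
  v <- low[sel]
  if (length(v) < min_samples) {
    stop("bin ", bin, " has only ", length(v), " voxels (< ", min_samples,
         ")")
  }
  smean <- mean(v)
  ssd <- stats::sd(v)
  if (ssd == 0) {
    return(list(histogram = NULL, fit = NULL,
                sample = list(mean = smean, sigma = 0, n = length(v)),
                r_squared = NA_real_, degenerate = TRUE))
  }
  h <- graphics::hist(v, breaks = seq(min(v) - 0.5, max(v) + 0.5, by = 1),
                      plot = FALSE)
  xs <- h$mids
  ys <- h$counts
  obj <- function(p) {
    pred <- exp(p[1]) * exp(-0.5 * (xs - p[2])^2 / exp(2 * p[3]))
    sum((ys - pred)^2)
  }
  p0 <- c(log(max(ys)), smean, log(ssd))
  opt <- stats::optim(p0, obj, method = "BFGS",
                      control = list(maxit = 500))
  fit <- list(amplitude = exp(opt$par[1]), mean = opt$par[2],
              sigma = exp(opt$par[3]))
  pred <- fit$amplitude * exp(-0.5 * (xs - fit$mean)^2 / fit$sigma^2)
  r2 <- 1 - sum((ys - pred)^2) / sum((ys - mean(ys))^2)
  list(histogram = list(mids = xs, counts = ys), fit = fit,
       sample = list(mean = smean, sigma = ssd, n = length(v)),
       r_squared = r2, degenerate = FALSE)
}

#' Fit the tube-current scaling of the noise
#'
#' Least-squares fit of log(sigma) against log(I): the Poisson photon
#' statistics of CT predict sigma proportional to 1/sqrt(I), i.e. an
#' exponent of -0.5. The exponent can also be fixed (e.g. at -0.5), in
#' which case only the reference sigma is estimated.
#'
#' @param tube_current_ma numeric vector of tube currents, mA (>= 2 distinct
#'   values unless `exponent` is fixed).
#' @param sigma_hu noise sigma at HU 0 for each current, HU (> 0).
#' @param i_ref_ma reference current at which `sigma_ref` is quoted
#'   (default the smallest supplied current).
#' @param exponent NULL to fit the exponent, or a fixed value such as -0.5.
#' @return a `current_scaling` list: `i_ref_ma`, `sigma_ref_hu`,
#'   `exponent`.
#' @export
fit_current_scaling <- function(tube_current_ma, sigma_hu,
                                i_ref_ma = min(tube_current_ma),
                                exponent = NULL) {
  if (any(tube_current_ma <= 0)) stop("tube currents must be positive")
  if (any(sigma_hu <= 0)) stop("sigma values must be positive")
  lx <- log(tube_current_ma / i_ref_ma)
  ly <- log(sigma_hu)
  if (is.null(exponent)) {
    if (length(unique(tube_current_ma)) < 2) {
      stop("at least two distinct tube currents are required to fit the ",
           "exponent")
    }
    fit <- stats::lm.fit(cbind(1, lx), ly)
    exponent <- unname(fit$coefficients[2])
    sigma_ref <- exp(unname(fit$coefficients[1]))
  } else {
    sigma_ref <- exp(mean(ly - exponent * lx))
  }
  structure(list(i_ref_ma = i_ref_ma, sigma_ref_hu = sigma_ref,
                 exponent = exponent), class = "current_scaling")
}

#' Predict sigma at a tube current from a fitted scaling model
#' @param model a `current_scaling` from [fit_current_scaling()].
#' @param tube_current_ma tube current, mA.
#' @return predicted sigma, HU.
#' @export
predict_sigma <- function(model, tube_current_ma) {
  if (any(tube_current_ma <= 0)) stop("tube current must be positive")
  model$sigma_ref_hu * (tube_current_ma / model$i_ref_ma)^model$exponent
}

#' Synthesize a low-dose CT volume from a lookup table
#'
#' Each output voxel is drawn independently from
#' Gaussian(mean(HU), sigma(HU)) of its input CT number, with table lookup
#' per voxel. A single vectorized standard-normal stream in voxel storage
#' order is drawn from the seed and transformed per voxel, so the result is
#' independent of any bin iteration order and reproducible.
#'
#' By default the assigned CT numbers are re-integerized (half-away-from-
#' zero) and clamped to the HU range for storage; `integerize = FALSE`
#' returns the raw assigned values, which is what the reassignment QA
#' compares (see [qa_synthesis()]).
#'
#' @param clean CT [volume3d()].
#' @param lut a `noise_lut` whose (extrapolated) domain covers all HU in
#'   `clean`.
#' @param seed integer seed.
#' @param integerize round/clamp to integer HU (default TRUE).
#' @param extrapolate passed to [lut_lookup()].
#' @return CT [volume3d()] (or scalar volume when `integerize = FALSE`).
#' @export
synthesize_low_dose <- function(clean, lut, seed = 1, integerize = TRUE,
                                extrapolate = TRUE) {
  entry <- lut_lookup(lut, as.numeric(clean$values),
                      extrapolate = extrapolate)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  z <- stats::rnorm(length(clean$values))
  assigned <- entry$mean_hu + entry$sigma_hu * z
  if (integerize) {
    ct_volume(array(round_hu(assigned), clean$grid$size), clean$grid)
  } else {
    volume3d(array(assigned, clean$grid$size), clean$grid, kind = "scalar")
  }
}

#' Reassignment QA of a synthetic low-dose volume
#'
#' Checks that the synthesis actually assigned a new CT number to (nearly)
#' every voxel: fraction = count(synthetic != clean) / total, pass iff
#' fraction >= `threshold` (default 0.999). Run this on the raw assigned
#' values (`integerize = FALSE` in [synthesize_low_dose()]): comparing
#' after integer re-quantization would count chance coincidences of the
#' rounded draw with the original CT number as "not reassigned".
#'
#' @param clean CT [volume3d()].
#' @param synthetic synthesized volume aligned to `clean`.
#' @param threshold pass threshold on the reassigned fraction
#'   (default 0.999).
#' @return list: `fraction_reassigned`, `n_changed`, `n_total`,
#'   `threshold`, `pass`.
#' @export
qa_synthesis <- function(clean, synthetic, threshold = 0.999) {
  stop_if_misaligned(clean$grid, synthetic$grid)
  n <- length(clean$values)
  changed <- sum(synthetic$values != clean$values)
  frac <- changed / n
  list(fraction_reassigned = frac, n_changed = changed, n_total = n,
       threshold = threshold, pass = frac >= threshold)
}
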