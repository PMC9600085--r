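#' DVH metrics of a structure
#'
#' Computes D98, D2, Dmean, Dmax, Dmin and D_1cc (minimum dose to the most
#' irradiated 1 cc) plus the full cumulative DVH curve. Dx uses the
#' lower-bound convention without interpolation: the largest dose d such
#' that at least x% of the structure volume receives >= d, i.e. the
#' ceiling(x n / 100)-th value of the doses sorted in decreasing order.
#' D_1cc is the minimum dose among the ceiling(1 cc / voxel volume)
#' highest-dose voxels; a structure smaller than 1 cc falls back to Dmin
#' with a warning.
#'
#' @param dose a dose [volume3d()].
#' @param mask a mask [volume3d()] aligned to the dose grid, or an integer
#'   vector of dose-grid voxel indices.
#' @param curve_points number of points of the cumulative DVH curve
#'   (default 201).
#' @return a `dvh_metrics` list: `d98_gy`, `d2_gy`, `dmean_gy`, `dmax_gy`,
#'   `dmin_gy`, `d1cc_gy`, `volume_cc`, `curve` (data.frame dose_gy,
#'   volume_fraction).
#' @export
dvh_metrics <- function(dose, mask, curve_points = 201) {
  if (inherits(mask, "volume3d")) {
    stop_if_misaligned(dose$grid, mask$grid, "dose and mask")
    idx <- which(mask$values > 0.5)
  } else {
    idx <- as.integer(mask)
  }
  if (length(idx) == 0) stop("structure mask is empty")
  d <- sort(as.numeric(dose$values)[idx], decreasing = TRUE)
  n <- length(d)
  vox_cc <- voxel_volume_cc(dose$grid)
  dx <- function(x) d[ceiling(x * n / 100)]
  k1cc <- ceiling(1 / vox_cc)
  d1cc <- if (k1cc > n) {
    warning("structure smaller than 1 cc; D_1cc falls back to Dmin")
    d[n]
  } else {
    d[k1cc]
  }
  grid_d <- seq(0, max(d), length.out = curve_points)
  frac <- vapply(grid_d, function(t) mean(d >= t), numeric(1))
  structure(list(d98_gy = dx(98), d2_gy = dx(2), dmean_gy = mean(d),
                 dmax_gy = d[1], dmin_gy = d[n], d1cc_gy = d1cc,
                 volume_cc = n * vox_cc,
                 curve = data.frame(dose_gy = grid_d,
                                    volume_fraction = frac)),
            class = "dvh_metrics")
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty masks are defined to have
#' Dice 1 (identical emptiness); symmetric in its arguments.
#'
#' @param a,b mask [volume3d()] objects on aligned grids.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stop_if_misaligned(a$grid, b$grid, "masks")
  na <- sum(a$values > 0.5)
  nb <- sum(b$values > 0.5)
  if (na + nb == 0) return(1.0)
  2 * sum(a$values > 0.5 & b$values > 0.5) / (na + nb)
}

#' Gamma evaluation criteria
#'
#' @param dose_percent dose-difference criterion as % of the normalization
#'   dose (default 2).
#' @param distance_mm distance-to-agreement criterion in mm (default 2).
#' @param normalization `"global"` (reference maximum, the convention
#'   recorded in every result) or `"local"` is not offered; global only.
#' @param threshold_percent low-dose cutoff: reference voxels below this %
#'   of the normalization dose are excluded (default 10).
#' @return a `gamma_criteria` list.
#' @export
gamma_criteria <- function(dose_percent = 2, distance_mm = 2,
                           normalization = "global",
                           threshold_percent = 10) {
  if (dose_percent <= 0 || distance_mm <= 0 || threshold_percent <= 0) {
    stop("gamma criteria must be strictly positive")
  }
  structure(list(dose_percent = dose_percent, distance_mm = distance_mm,
                 normalization = normalization,
                 threshold_percent = threshold_percent),
            class = "gamma_criteria")
}

#' Gamma index between two dose distributions
#'
#' For each reference voxel above the low-dose threshold, gamma is the
#' minimum over evaluated-dose positions within the search radius of
#' sqrt((dose difference / dose criterion)^2 + (distance / DTA)^2), with
#' trilinear interpolation of the evaluated dose at sub-voxel offsets.
#' Offsets are visited in order of increasing radius with early
#' termination, which gives the same minimum as exhaustive search over the
#' discretized offsets. Normalization is global to the reference maximum.
#' Note gamma is not symmetric in (reference, evaluated).
#'
#' @param reference reference dose [volume3d()].
#' @param evaluated evaluated dose [volume3d()] on an aligned grid
#'   (resample first if needed).
#' @param criteria a [gamma_criteria()].
#' @param search_radius_mm search radius (default 3 x DTA).
#' @param step_mm sub-voxel refinement step (default DTA / 10).
#' @return a `gamma_result`: `gamma` volume (NA outside evaluated voxels),
#'   `pass_rate_percent`, `n_evaluated`, `n_passed`, `criteria`.
#' @export
gamma_index <- function(reference, evaluated, criteria = gamma_criteria(),
                        search_radius_mm = 3 * criteria$distance_mm,
                        step_mm = criteria$distance_mm / 10) {
  stop_if_misaligned(reference$grid, evaluated$grid, "dose volumes")
  if (search_radius_mm < min(reference$grid$spacing)) {
    stop("search radius smaller than one voxel")
  }
  dmax <- max(reference$values)
  if (dmax <= 0) stop("reference dose is identically zero")
  dose_crit <- criteria$dose_percent / 100 * dmax
  thresh <- criteria$threshold_percent / 100 * dmax
  g <- cpp_gamma(as.numeric(reference$values), as.numeric(evaluated$values),
                 reference$grid$size, reference$grid$spacing,
                 dose_crit, criteria$distance_mm, thresh,
                 search_radius_mm, step_mm)
  n_eval <- sum(!is.na(g))
  n_pass <- sum(g <= 1, na.rm = TRUE)
  structure(list(gamma = volume3d(array(ifelse(is.na(g), 0, g),
                                        reference$grid$size),
                                  reference$grid, kind = "scalar"),
                 gamma_values = g,
                 pass_rate_percent = 100 * n_pass / max(n_eval, 1),
                 n_evaluated = n_eval, n_passed = n_pass,
                 criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma %g%%/%gmm (global, %g%% threshold): pass rate %.2f%% (%d/%d voxels)\n",
              x$criteria$dose_percent, x$criteria$distance_mm,
              x$criteria$threshold_percent, x$pass_rate_percent,
              x$n_passed, x$n_evaluated))
  invisible(x)
}

#' Percentage differences between two DVH metric sets
#'
#' `100 (low - ref) / denominator`. For target Dx metrics the conventional
#' denominator is the prescription dose (so the percentages live on the
#' same scale as clinical goals like D98 >= 95%); for OAR metrics it is the
#' reference metric value. Both conventions are selectable per call and the
#' choice is recorded in the output.
#'
#' @param metrics_low,metrics_ref named lists of [dvh_metrics()] per
#'   structure (same structure names).
#' @param metric_fields named character: which metric field to compare per
#'   structure (e.g. `c(hr_ctv = "d98_gy", cord = "d1cc_gy")`).
#' @param denominators either `"reference"`, or a named numeric vector of
#'   prescription doses per structure (structures present in the vector use
#'   the prescription, the rest the reference value).
#' @return data.frame: structure, metric, value_low, value_ref,
#'   denominator, denominator_kind, percent_diff. Entries with a zero
#'   denominator are flagged (`percent_diff = NA`).
#' @export
percent_difference <- function(metrics_low, metrics_ref, metric_fields,
                               denominators = "reference") {
  stopifnot(all(names(metric_fields) %in% names(metrics_low)),
            all(names(metric_fields) %in% names(metrics_ref)))
  rows <- lapply(names(metric_fields), function(snm) {
    fld <- metric_fields[[snm]]
    lo <- metrics_low[[snm]][[fld]]
    re <- metrics_ref[[snm]][[fld]]
    if (is.numeric(denominators) && snm %in% names(denominators)) {
      den <- denominators[[snm]]
      kind <- "prescription"
    } else {
      den <- re
      kind <- "reference"
    }
    data.frame(structure = snm, metric = fld, value_low = lo,
               value_ref = re, denominator = den, denominator_kind = kind,
               percent_diff = if (den == 0) NA_real_ else
                 100 * (lo - re) / den)
  })
  do.call(rbind, rows)
}

#' Cohort summary: median and min-max per metric
#'
#' @param cases list of data.frames with columns `structure`, `metric`,
#'   `value` (one per case).
#' @param path optional CSV output path.
#' @return data.frame: structure, metric, median, min, max, n_cases.
#' @export
summarize_cohort <- function(cases, path = NULL) {
  if (length(cases) < 1) stop("at least one case is required")
  all <- do.call(rbind, lapply(seq_along(cases), function(i) {
    df <- cases[[i]]
    df$case <- i
    df
  }))
  key <- interaction(all$structure, all$metric, drop = TRUE)
  out <- do.call(rbind, lapply(split(all, key), function(d) {
    data.frame(structure = d$structure[1], metric = d$metric[1],
               median = stats::median(d$value), min = min(d$value),
               max = max(d$value), n_cases = nrow(d))
  }))
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
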