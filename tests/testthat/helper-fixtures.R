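# Fixtures and independent oracles shared across test files.
# Everything is generated in code; nothing is read from disk.

# small water box: uniform 0 HU (RSP 1) cube
water_volume <- function(n = c(60, 60, 60), spacing = c(2, 2, 2),
                         hu = 0) {
  g <- grid3d_centered(n, spacing)
  ct_volume(array(hu, n), g)
}

# a coarse head phantom for fast pipeline-level tests
small_phantom_spec <- function(seed = 11, texture = 5) {
  phantom_spec(size = c(64, 64, 32), spacing = c(4, 4, 5),
               texture_sigma_hu = texture, seed = seed)
}

# uniform-HU calibration volume with a given voxel count
flat_ct <- function(n_voxels = 1e5, hu = 0) {
  dims <- c(50, 50, ceiling(n_voxels / 2500))
  g <- grid3d(dims, c(1, 1, 1))
  ct_volume(array(hu, dims), g)
}

# one-spot plan aimed along +y into a volume, for 1D depth-dose checks
single_spot_plan <- function(range_mm, sigma_air_mm = 5, rs_wet = 40,
                             iso = c(0, 0, 0), gantry_deg = 0, weight = 1) {
  plan_spec(
    beams = list(list(
      gantry_deg = gantry_deg,
      spots = data.frame(u_mm = 0, v_mm = 0, range_mm = range_mm,
                         energy_mev = energy_from_range(range_mm),
                         sigma_air_mm = sigma_air_mm, weight = weight),
      range_shifter_wet_mm = rs_wet, air_gap_mm = 30)),
    isocenter_mm = iso)
}

# Exhaustive-sort DVH oracle: largest dose d (among observed doses) such
# that at least x% of the voxels receive >= d; brute force over candidates.
oracle_dx <- function(doses, x) {
  n <- length(doses)
  cand <- sort(unique(doses), decreasing = TRUE)
  for (d in cand) {
    if (sum(doses >= d) >= x * n / 100) return(d)
  }
  min(doses)
}

oracle_d1cc <- function(doses, voxel_cc) {
  k <- ceiling(1 / voxel_cc)
  sorted <- sort(doses, decreasing = TRUE)
  sorted[min(k, length(doses))]
}

# Brute-force gamma for a 1D profile (constant along y, z): exhaustive
# search over fine spatial offsets with linear interpolation.
oracle_gamma_1d <- function(ref, ev, spacing_mm, dose_crit_abs, dta_mm,
                            search_mm = 3 * dta_mm, step_mm = 0.01) {
  n <- length(ref)
  xs <- (seq_len(n) - 1) * spacing_mm
  interp <- function(x) {
    if (x < 0 || x > xs[n]) return(NA_real_)
    stats::approx(xs, ev, xout = x)$y
  }
  vapply(seq_len(n), function(i) {
    best <- Inf
    for (t in seq(-search_mm, search_mm, by = step_mm)) {
      de <- interp(xs[i] + t)
      if (is.na(de)) next
      g <- sqrt(((de - ref[i]) / dose_crit_abs)^2 + (t / dta_mm)^2)
      if (g < best) best <- g
    }
    best
  }, numeric(1))
}

# independent per-bin mean/sd oracle used against calibrate_noise
oracle_bin_stats <- function(ref, low) {
  sp <- split(low, ref)
  data.frame(hu = as.numeric(names(sp)),
             mean = vapply(sp, mean, numeric(1)),
             sd = vapply(sp, stats::sd, numeric(1)),
             n = vapply(sp, length, numeric(1)))
}
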