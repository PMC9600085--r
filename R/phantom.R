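#' CT scan protocol description
#'
#' @param tube_current_ma tube current, mA (> 0).
#' @param ctdi_vol_mgy volume CT dose index, mGy (> 0).
#' @param tube_voltage_kv tube voltage, kV.
#' @param pitch helical pitch factor.
#' @param slice_thickness_mm reconstructed slice thickness, mm.
#' @param label protocol label.
#' @return a `scan_protocol` object.
#' @export
scan_protocol <- function(tube_current_ma, ctdi_vol_mgy,
                          tube_voltage_kv = 140, pitch = 0.6,
                          slice_thickness_mm = 2.5,
                          label = sprintf("%gmA", tube_current_ma)) {
  if (tube_current_ma <= 0) stop("tube current must be positive")
  if (ctdi_vol_mgy <= 0) stop("CTDI_vol must be positive")
  structure(list(tube_current_ma = tube_current_ma,
                 ctdi_vol_mgy = ctdi_vol_mgy,
                 tube_voltage_kv = tube_voltage_kv, pitch = pitch,
                 slice_thickness_mm = slice_thickness_mm, label = label),
            class = "scan_protocol")
}

#' Built-in head scanning protocol table
#'
#' The seven tube-current settings of the study scanner, from the clinical
#' standard protocol (400 mA, 166 mGy) down to the lowest achievable tube
#' current (10 mA, 4.2 mGy), all at 140 kV, pitch 0.6 and 2.5 mm slices.
#' CTDI_vol is proportional to tube current at fixed kV and pitch, so the
#' table spans a factor of 40 in imaging dose.
#'
#' @return list of [scan_protocol()] objects, highest dose first.
#' @examples
#' tab <- builtin_protocol_table()
#' tab[[1]]$ctdi_vol_mgy / tab[[7]]$ctdi_vol_mgy  # dose-reduction factor
#' @export
builtin_protocol_table <- function() {
  ma <- c(400, 200, 100, 50, 25, 15, 10)
  mgy <- c(166, 83, 41.5, 20.7, 10.4, 6.2, 4.2)
  lab <- c("STD", "200mA", "100mA", "50mA", "25mA", "15mA", "10mA")
  mapply(function(a, g, l) scan_protocol(a, g, label = l), ma, mgy, lab,
         SIMPLIFY = FALSE)
}

#' Export the protocol table as a data frame / CSV
#' @param path optional CSV path; if given the table is written there.
#' @return data.frame of protocol parameters.
#' @export
protocol_table_df <- function(path = NULL) {
  tab <- builtin_protocol_table()
  df <- data.frame(
    label = vapply(tab, `[[`, character(1), "label"),
    tube_current_ma = vapply(tab, `[[`, numeric(1), "tube_current_ma"),
    ctdi_vol_mgy = vapply(tab, `[[`, numeric(1), "ctdi_vol_mgy"),
    tube_voltage_kv = vapply(tab, `[[`, numeric(1), "tube_voltage_kv"),
    pitch = vapply(tab, `[[`, numeric(1), "pitch"),
    slice_thickness_mm = vapply(tab, `[[`, numeric(1), "slice_thickness_mm"))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Specification of the parametric digital head phantom
#'
#' The phantom is built from geometric primitives (ellipsoids, cylinders,
#' ellipsoidal shells) with per-compartment mean HU and HU texture sigma,
#' mirror-symmetric about the mid-sagittal (x = 0) plane. Axes: +x patient
#' left, +y posterior, +z superior; the grid is centered on the origin.
#'
#' @param size voxel counts (default 128 x 128 x 64).
#' @param spacing mm (default 2 x 2 x 2.5).
#' @param texture_sigma_hu within-compartment HU texture sigma (default 5).
#' @param seed integer seed for the texture.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(128, 128, 64), spacing = c(2, 2, 2.5),
                         texture_sigma_hu = 5, seed = 20221021) {
  structure(list(grid = grid3d_centered(size, spacing),
                 texture_sigma_hu = texture_sigma_hu, seed = seed),
            class = "phantom_spec")
}

# geometric primitives on precomputed center coordinates
ellipsoid_mask <- function(x, y, z, center, semi) {
  ((x - center[1]) / semi[1])^2 + ((y - center[2]) / semi[2])^2 +
    ((z - center[3]) / semi[3])^2 <= 1
}
zcyl_mask <- function(x, y, z, center_xy, radius, z0, z1) {
  (x - center_xy[1])^2 + (y - center_xy[2])^2 <= radius^2 & z >= z0 & z <= z1
}

#' Generate the digital head phantom
#'
#' Builds a head-and-neck CT volume with air (-1000 HU), soft-tissue (~30
#' HU), brain (~40 HU) and bone (~1000 HU) compartments — cranium with
#' brain, a frontal sinus air cavity, a neck with vertebral column, spinal
#' canal and an air-filled larynx lumen — plus a structure set: nested
#' high-risk and low-risk CTVs in the neck, spinal cord, brainstem, left and
#' right parotids, pharyngeal constrictors and larynx. Deterministic for a
#' fixed seed; texture noise is Gaussian per compartment and values are
#' re-integerized half-away-from-zero.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `ct` ([volume3d()] of kind `"ct"`) and
#'   `structures` (a [structure_set()]), plus `geometry` (the analytic
#'   primitive parameters, useful for closed-form volume checks).
#' @export
generate_head_phantom <- function(spec = phantom_spec()) {
  g <- spec$grid
  pts <- grid_center_points(g)
  x <- pts[, 1]
  y <- pts[, 2]
  z <- pts[, 3]

  geom <- list(
    head = list(center = c(0, 0, 25), semi = c(75, 88, 50)),
    brain_scale = 0.85,
    skull_inner = 0.86,
    sinus = list(center = c(0, -55, 20), semi = c(12, 10, 10)),
    neck = list(center_xy = c(0, 0), radius = 52, z0 = -80, z1 = 10),
    vertebra = list(center_xy = c(0, 25), r_outer = 14, r_inner = 8,
                    z0 = -80, z1 = 10),
    cord = list(center_xy = c(0, 25), radius = 4, z0 = -80, z1 = 10),
    brainstem = list(center_xy = c(0, 15), radius = 8, z0 = 10, z1 = 45),
    hr_ctv = list(center = c(0, -15, -30), semi = c(18, 15, 20)),
    lr_ctv = list(center = c(0, -15, -30), semi = c(30, 25, 32)),
    parotid_l = list(center = c(38, 0, -5), semi = c(10, 14, 12)),
    parotid_r = list(center = c(-38, 0, -5), semi = c(10, 14, 12)),
    constrictors = list(center_xy = c(0, 3), radius = 7, z0 = -60, z1 = -30),
    larynx = list(center = c(0, -35, -55), semi = c(11, 11, 14)),
    larynx_lumen = list(center = c(0, -37, -55), semi = c(5, 5, 10)))

  head <- ellipsoid_mask(x, y, z, geom$head$center, geom$head$semi)
  brain <- ellipsoid_mask(x, y, z, geom$head$center,
                          geom$head$semi * geom$brain_scale)
  skull <- head & !ellipsoid_mask(x, y, z, geom$head$center,
                                  geom$head$semi * geom$skull_inner)
  sinus <- ellipsoid_mask(x, y, z, geom$sinus$center, geom$sinus$semi)
  neck <- zcyl_mask(x, y, z, geom$neck$center_xy, geom$neck$radius,
                    geom$neck$z0, geom$neck$z1)
  vert <- zcyl_mask(x, y, z, geom$vertebra$center_xy, geom$vertebra$r_outer,
                    geom$vertebra$z0, geom$vertebra$z1) &
    !zcyl_mask(x, y, z, geom$vertebra$center_xy, geom$vertebra$r_inner,
               geom$vertebra$z0, geom$vertebra$z1)
  cord <- zcyl_mask(x, y, z, geom$cord$center_xy, geom$cord$radius,
                    geom$cord$z0, geom$cord$z1)
  lumen <- ellipsoid_mask(x, y, z, geom$larynx_lumen$center,
                          geom$larynx_lumen$semi)

  hu <- rep(-1000, length(x))       # air background
  hu[neck] <- 30                    # soft tissue
  hu[head] <- 30
  hu[brain] <- 40
  hu[skull & z > -10] <- 1000       # cranial bone
  hu[vert] <- 1000                  # vertebral column
  hu[cord] <- 35
  hu[sinus] <- -1000
  hu[lumen] <- -1000

  inside <- hu > -1000
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  noise <- stats::rnorm(length(hu), 0, spec$texture_sigma_hu)
  hu[inside] <- hu[inside] + noise[inside]
  hu <- round_hu(hu)

  masks <- list(
    hr_ctv = ellipsoid_mask(x, y, z, geom$hr_ctv$center, geom$hr_ctv$semi),
    lr_ctv = ellipsoid_mask(x, y, z, geom$lr_ctv$center, geom$lr_ctv$semi),
    cord = cord,
    brainstem = zcyl_mask(x, y, z, geom$brainstem$center_xy,
                          geom$brainstem$radius, geom$brainstem$z0,
                          geom$brainstem$z1),
    parotid_l = ellipsoid_mask(x, y, z, geom$parotid_l$center,
                               geom$parotid_l$semi),
    parotid_r = ellipsoid_mask(x, y, z, geom$parotid_r$center,
                               geom$parotid_r$semi),
    constrictors = zcyl_mask(x, y, z, geom$constrictors$center_xy,
                             geom$constrictors$radius, geom$constrictors$z0,
                             geom$constrictors$z1),
    larynx = ellipsoid_mask(x, y, z, geom$larynx$center, geom$larynx$semi))
  body <- head | neck
  for (nm in names(masks)) {
    if (any(masks[[nm]] & !body)) {
      stop("structure ", nm, " extends outside the head contour")
    }
  }
  roles <- c(hr_ctv = "target-HR", lr_ctv = "target-LR", cord = "oar",
             brainstem = "oar", parotid_l = "oar", parotid_r = "oar",
             constrictors = "oar", larynx = "oar")
  ss <- structure_set(g, lapply(masks, function(m)
    array(as.numeric(m), g$size)), roles)
  list(ct = ct_volume(array(hu, g$size), g), structures = ss,
       geometry = geom)
}

#' Noise anchor of the lowest-dose protocol
#'
#' The per-voxel Gaussian noise measured at HU 0 for the 10 mA protocol:
#' sigma 20 HU with a -0.45 HU mean shift relative to the 400 mA standard
#' protocol. Noise at other currents scales as sigma0 * sqrt(I_ref / I).
#'
#' @param sigma0_hu noise sigma at the reference current, HU.
#' @param i_ref_ma reference tube current, mA.
#' @param mean_shift_hu systematic HU shift of the low-dose image.
#' @return a `noise_anchor` list.
#' @export
noise_anchor <- function(sigma0_hu = 20, i_ref_ma = 10,
                         mean_shift_hu = -0.45) {
  if (sigma0_hu <= 0) stop("sigma0 must be positive")
  if (i_ref_ma <= 0) stop("reference current must be positive")
  structure(list(sigma0_hu = sigma0_hu, i_ref_ma = i_ref_ma,
                 mean_shift_hu = mean_shift_hu), class = "noise_anchor")
}

#' Predicted noise sigma at a tube current under the sqrt law
#' @param anchor a [noise_anchor()].
#' @param tube_current_ma tube current, mA.
#' @return sigma in HU.
#' @export
sigma_at_current <- function(anchor, tube_current_ma) {
  if (tube_current_ma <= 0) stop("tube current must be positive")
  anchor$sigma0_hu * sqrt(anchor$i_ref_ma / tube_current_ma)
}

#' Simulate a low-dose scan paired to a clean reference
#'
#' Adds independent per-voxel Gaussian noise to the clean volume with
#' sigma(I) = sigma0 * sqrt(I_ref / I) for the protocol's tube current
#' (photon counts are Poisson in the tube current, so the CT-number noise
#' scales as the inverse square root), plus the anchor's systematic mean
#' shift. Values are re-integerized half-away-from-zero and clamped to the
#' HU range. Deterministic for a fixed seed.
#'
#' @param clean a CT [volume3d()].
#' @param protocol a [scan_protocol()].
#' @param anchor a [noise_anchor()]; sigma must be positive.
#' @param seed integer seed.
#' @param mean_shift apply the anchor's mean shift? Default TRUE.
#' @return noisy CT [volume3d()].
#' @export
simulate_paired_scan <- function(clean, protocol, anchor = noise_anchor(),
                                 seed = 1, mean_shift = TRUE) {
  sigma <- sigma_at_current(anchor, protocol$tube_current_ma)
  mu <- if (mean_shift) anchor$mean_shift_hu else 0
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  noisy <- clean$values + mu + stats::rnorm(length(clean$values), 0, sigma)
  ct_volume(array(round_hu(noisy), clean$grid$size), clean$grid)
}
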