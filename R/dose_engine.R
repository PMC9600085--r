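## Analytic pencil-beam proton dose surrogate.
##
## This engine deliberately replaces Monte Carlo transport with a fast
## analytic model that preserves the properties the study exercises:
## linearity in spot weights, HU sensitivity mediated entirely by
## water-equivalent path length (WEPL), and mm-scale lateral and distal
## dose gradients. It does not model nuclear interactions, halo, or
## scanner-specific beam optics.

#' HU to relative-stopping-power calibration
#'
#' Piecewise-linear control points mapping CT number to proton stopping
#' power relative to water, with constant extrapolation beyond the
#' endpoints. HU must be strictly increasing, RSP non-negative and
#' non-decreasing, and RSP(0 HU) must be 1 (water anchor).
#'
#' The default curve has a flat segment between -1024 and -940 HU
#' (air stays air), mirroring clinical stoichiometric calibrations, which
#' are insensitive to CT-number fluctuations at sub-lung densities; a
#' steep air segment would otherwise rectify zero-mean HU noise in the
#' air surrounding the patient into a systematic WEPL increase.
#'
#' @param hu numeric vector of control-point CT numbers.
#' @param rsp numeric vector of relative stopping powers.
#' @return an `rsp_calibration`.
#' @export
rsp_calibration <- function(hu = c(-1024, -940, 0, 1000, 3071),
                            rsp = c(0.001, 0.001, 1.0, 1.54, 2.60)) {
  if (length(hu) != length(rsp) || length(hu) < 2) {
    stop("calibration needs matching HU/RSP vectors of length >= 2")
  }
  if (any(diff(hu) <= 0)) stop("calibration HU must be strictly increasing")
  if (any(rsp < 0) || any(diff(rsp) < 0)) {
    stop("calibration RSP must be non-negative and non-decreasing")
  }
  if (min(abs(hu)) > 0 || abs(rsp[which(hu == 0)] - 1) > 1e-9) {
    stop("calibration must anchor RSP(0 HU) = 1 (water)")
  }
  structure(list(hu = hu, rsp = rsp), class = "rsp_calibration")
}

#' Convert a CT volume to relative stopping power
#'
#' Per-voxel piecewise-linear interpolation of the calibration curve;
#' monotone non-decreasing in HU, constant beyond the endpoints.
#'
#' @param ct CT [volume3d()].
#' @param calib an [rsp_calibration()].
#' @return scalar [volume3d()] of RSP.
#' @export
hu_to_rsp <- function(ct, calib = rsp_calibration()) {
  v <- stats::approx(calib$hu, calib$rsp, xout = as.numeric(ct$values),
                     rule = 2)$y
  volume3d(array(v, ct$grid$size), ct$grid, kind = "scalar")
}

#' Water-equivalent path length along a ray
#'
#' Exact Siddon-type voxel traversal: WEPL is the sum over traversed voxels
#' of geometric intersection length times voxel RSP, independent of
#' traversal order.
#'
#' @param rsp scalar RSP [volume3d()].
#' @param entry_mm physical entry point (mm), length 3.
#' @param direction direction vector (normalized internally), length 3.
#' @return list: `wepl_mm`, `length_mm`, `intersects`. A ray missing the
#'   volume (or grazing it over zero length) returns WEPL 0 with a warning.
#' @export
trace_wepl <- function(rsp, entry_mm, direction) {
  stop_if_not_identity_direction(rsp$grid, "ray tracing")
  d <- direction / sqrt(sum(direction^2))
  res <- cpp_wepl_ray(as.numeric(rsp$values), rsp$grid$size,
                      rsp$grid$spacing, rsp$grid$origin,
                      as.numeric(entry_mm), as.numeric(d))
  if (!res$intersects) {
    warning("ray does not intersect the volume; WEPL = 0")
  }
  list(wepl_mm = res$wepl, length_mm = res$length,
       intersects = res$intersects)
}

#' Analytic Bragg depth-dose curve
#'
#' Parametric closed form: a rising entrance plateau switched off just
#' proximal to a Gaussian peak centered at the nominal range. The distal
#' Gaussian width gives an 80-20% distal falloff of 3 mm water and a
#' peak-to-entrance ratio of about 3; dose is zero beyond the range plus
#' the distal falloff width. The curve is normalized to peak = 1 and its
#' single maximum sits at the nominal range.
#'
#' @param range_mm nominal range in mm water (> 0).
#' @param depth_mm depths in mm water (>= 0).
#' @return relative dose values in `[0, 1]`.
#' @export
bragg_depth_dose <- function(range_mm, depth_mm) {
  if (range_mm <= 0) stop("range must be positive")
  if (any(depth_mm < 0)) stop("depth must be non-negative")
  cpp_bragg(as.numeric(depth_mm), range_mm)
}

## ---- beam geometry -------------------------------------------------------

# Gantry convention: 0 deg = source anterior of the patient, angles increase
# clockwise viewed from the patient's feet. Axes: +x patient left,
# +y posterior, +z superior. The beam direction (source -> isocenter) is
# therefore (-sin a, cos a, 0); 180 deg is the posterior-anterior field.
beam_axes <- function(gantry_deg) {
  a <- gantry_deg * pi / 180
  list(d = c(-sin(a), cos(a), 0),
       u = c(cos(a), sin(a), 0),
       v = c(0, 0, 1))
}

# range-energy power law through (65 MeV, 37 mm) and (225 MeV, 325 mm) water
RE_EXP <- log(325 / 37) / log(225 / 65)
RE_COEF <- 37 / 65^RE_EXP

#' Range-energy conversion for protons in water
#'
#' Power law `R = a E^p` through the implementation anchor points
#' 65 MeV -> 37 mm and 225 MeV -> 325 mm water (exponent ~1.75).
#' @param energy_mev proton energy, MeV.
#' @return range in mm water.
#' @export
range_from_energy <- function(energy_mev) RE_COEF * energy_mev^RE_EXP

#' @rdname range_from_energy
#' @param range_mm range in mm water.
#' @return energy in MeV.
#' @export
energy_from_range <- function(range_mm) (range_mm / RE_COEF)^(1 / RE_EXP)

#' Spot sigma in air as a function of energy
#'
#' Linear interpolation between the beam-model endpoints 6.4 mm at 65 MeV
#' and 2.5 mm at 225 MeV, clamped outside that interval.
#' @param energy_mev proton energy, MeV.
#' @return sigma in air, mm.
#' @export
sigma_air_from_energy <- function(energy_mev) {
  stats::approx(c(65, 225), c(6.4, 2.5), xout = energy_mev, rule = 2)$y
}

#' Build a three-field spot-scanning plan on a target
#'
#' Places pencil-beam spots on a lateral grid covering the target's
#' beam's-eye-view projection (with margin), and energy layers covering the
#' target's WEPL extent along each spot ray, for each gantry angle. Each
#' beam uses a range shifter (default 40 mm water-equivalent, 30 mm minimum
#' air gap). Spot sigma in air follows the energy via
#' [sigma_air_from_energy()]. All spots start at unit weight; scale with
#' [scale_plan()] or re-optimize with [adapt_weights()].
#'
#' @param ct planning CT [volume3d()].
#' @param target_mask target [volume3d()] mask (typically the low-risk CTV).
#' @param gantry_deg gantry angles in degrees (default 60, 180, 300).
#' @param isocenter_mm isocenter (default the target mask centroid).
#' @param spot_spacing_mm lateral spot spacing (default 5).
#' @param layer_spacing_mm water-equivalent layer spacing (default 5).
#' @param lateral_margin_mm lateral margin around the projection (default 5).
#' @param range_shifter_wet_mm range shifter water-equivalent thickness
#'   (default 40).
#' @param air_gap_mm minimum air gap, mm (metadata; default 30).
#' @param prescriptions_gy named prescription doses, Gy(RBE).
#' @param calib [rsp_calibration()] used for the WEPL placement rays.
#' @return a `plan_spec`: beams (each with gantry angle and a spot table
#'   `u_mm, v_mm, range_mm, energy_mev, sigma_air_mm, weight`),
#'   prescriptions, range shifter and scale.
#' @export
make_plan <- function(ct, target_mask, gantry_deg = c(60, 180, 300),
                      isocenter_mm = NULL, spot_spacing_mm = 5,
                      layer_spacing_mm = 5, lateral_margin_mm = 5,
                      range_shifter_wet_mm = 40, air_gap_mm = 30,
                      prescriptions_gy = c(hr_ctv = 70, lr_ctv = 57),
                      calib = rsp_calibration()) {
  stop_if_misaligned(ct$grid, target_mask$grid, "CT and target mask")
  rsp <- hu_to_rsp(ct, calib)
  g <- ct$grid
  midx <- which(target_mask$values > 0.5)
  if (length(midx) == 0) stop("target mask is empty")
  ijk <- arrayInd(midx, g$size) - 1L
  pts <- vox2phys(g, ijk)
  if (is.null(isocenter_mm)) isocenter_mm <- colMeans(pts)

  beams <- lapply(gantry_deg, function(ang) {
    ax <- beam_axes(ang)
    rel <- sweep(pts, 2, isocenter_mm, `-`)
    uu <- rel %*% ax$u
    vv <- rel %*% ax$v
    # symmetric lateral grid: offsets are multiples of the spot spacing
    nu <- ceiling((max(abs(range(uu))) + lateral_margin_mm) / spot_spacing_mm)
    nv <- ceiling((max(abs(range(vv))) + lateral_margin_mm) / spot_spacing_mm)
    ugrid <- seq(-nu, nu) * spot_spacing_mm
    vgrid <- seq(-nv, nv) * spot_spacing_mm
    spots <- list()
    # Spot placement samples a symmetric 4-ray bundle around the spot axis
    # (finite spot width): the averaged target-entry/exit WEPL is stable
    # when the nominal axis lies exactly on a voxel-boundary plane, where a
    # single ray's voxel column would be resolved by an arbitrary
    # tie-break. Diagonal offsets keep every ray off the nominal axis and
    # the set is closed under mirroring.
    bundle <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
    for (us in ugrid) {
      for (vs in vgrid) {
        w_in <- w_out <- numeric(0)
        for (r in seq_len(nrow(bundle))) {
          p0 <- isocenter_mm + (us + bundle[r, 1]) * ax$u +
            (vs + bundle[r, 2]) * ax$v - 2000 * ax$d
          hit <- cpp_ray_mask_wepl(as.numeric(rsp$values),
                                   as.numeric(target_mask$values),
                                   g$size, g$spacing, g$origin,
                                   as.numeric(p0), as.numeric(ax$d))
          if (hit$hit) {
            w_in <- c(w_in, hit$w_in)
            w_out <- c(w_out, hit$w_out)
          }
        }
        if (length(w_in) == 0) next
        layers <- seq(mean(w_in), mean(w_out) + layer_spacing_mm * 0.999,
                      by = layer_spacing_mm)
        rng <- layers + range_shifter_wet_mm
        en <- energy_from_range(rng)
        spots[[length(spots) + 1L]] <-
          data.frame(u_mm = us, v_mm = vs, range_mm = rng,
                     energy_mev = en,
                     sigma_air_mm = sigma_air_from_energy(en), weight = 1)
      }
    }
    if (length(spots) == 0) {
      warning("beam at ", ang, " deg misses the target; no spots placed")
      spots <- data.frame(u_mm = numeric(), v_mm = numeric(),
                          range_mm = numeric(), energy_mev = numeric(),
                          sigma_air_mm = numeric(), weight = numeric())
    } else {
      spots <- do.call(rbind, spots)
    }
    list(gantry_deg = ang, spots = spots,
         range_shifter_wet_mm = range_shifter_wet_mm,
         air_gap_mm = air_gap_mm)
  })
  structure(list(beams = beams, isocenter_mm = isocenter_mm,
                 prescriptions_gy = prescriptions_gy, scale = 1),
            class = "plan_spec")
}

#' Assemble a plan from explicit beam tables
#'
#' Low-level constructor for hand-built plans (e.g. a single spot): each
#' beam is a list with `gantry_deg`, a `spots` data.frame (`u_mm, v_mm,
#' range_mm, sigma_air_mm, weight`), `range_shifter_wet_mm` and
#' `air_gap_mm`. [make_plan()] is the high-level interface.
#'
#' @param beams list of beam lists as above.
#' @param isocenter_mm isocenter, mm.
#' @param prescriptions_gy named prescription doses.
#' @param scale global weight scale (default 1).
#' @return a `plan_spec`.
#' @export
plan_spec <- function(beams, isocenter_mm,
                      prescriptions_gy = c(hr_ctv = 70, lr_ctv = 57),
                      scale = 1) {
  for (b in beams) {
    stopifnot(is.numeric(b$gantry_deg), is.data.frame(b$spots))
    if (any(b$spots$weight < 0)) stop("spot weights must be >= 0")
  }
  structure(list(beams = beams, isocenter_mm = isocenter_mm,
                 prescriptions_gy = prescriptions_gy, scale = scale),
            class = "plan_spec")
}

#' @export
print.plan_spec <- function(x, ...) {
  cat("plan_spec:", length(x$beams), "beams,",
      sum(vapply(x$beams, function(b) nrow(b$spots), integer(1))),
      "spots, scale", format(x$scale), "\n")
  for (b in x$beams) {
    cat(sprintf("  gantry %5.1f deg: %d spots, range shifter %g mm WET\n",
                b$gantry_deg, nrow(b$spots), b$range_shifter_wet_mm))
  }
  invisible(x)
}

n_beamlets <- function(plan) {
  sum(vapply(plan$beams, function(b) nrow(b$spots), integer(1)))
}

plan_weights <- function(plan) {
  unlist(lapply(plan$beams, function(b) b$spots$weight), use.names = FALSE)
}

set_plan_weights <- function(plan, w) {
  at <- 0L
  for (i in seq_along(plan$beams)) {
    nb <- nrow(plan$beams[[i]]$spots)
    plan$beams[[i]]$spots$weight <- w[at + seq_len(nb)]
    at <- at + nb
  }
  plan
}

#' Scale all spot weights of a plan by a factor
#' @param plan a `plan_spec`.
#' @param factor multiplicative factor (applied to the plan scale).
#' @return the scaled plan.
#' @export
scale_plan <- function(plan, factor) {
  plan$scale <- plan$scale * factor
  plan
}

#' Compute the dose of a plan on a CT volume
#'
#' For each beam, traces the radiological depth (WEPL) of every dose-grid
#' voxel along the beam direction through the CT, then superposes the spot
#' doses: weight x lateral Gaussian (variance = sigma_air^2 plus a
#' depth-broadening term) x the analytic Bragg curve evaluated at the
#' water depth including the range-shifter WET. Dose is exactly linear in
#' the spot weights.
#'
#' @param plan a `plan_spec` from [make_plan()].
#' @param ct CT [volume3d()] to compute on.
#' @param dose_grid target [grid3d()] (default: the CT grid).
#' @param calib [rsp_calibration()].
#' @param per_beam also return the per-beam dose volumes (default FALSE).
#' @return a dose [volume3d()]; with `per_beam = TRUE`, a list
#'   `total`, `beams`.
#' @export
compute_dose <- function(plan, ct, dose_grid = NULL,
                         calib = rsp_calibration(), per_beam = FALSE) {
  if (is.null(dose_grid)) dose_grid <- ct$grid
  rsp <- hu_to_rsp(ct, calib)
  per <- lapply(plan$beams, function(b) {
    if (nrow(b$spots) == 0) {
      return(dose_volume(array(0, dose_grid$size), dose_grid))
    }
    ax <- beam_axes(b$gantry_deg)
    geo <- cpp_wepl_depth_volume(as.numeric(rsp$values), rsp$grid$size,
                                 rsp$grid$spacing, rsp$grid$origin,
                                 dose_grid$size, dose_grid$spacing,
                                 dose_grid$origin,
                                 as.numeric(ax$d),
                                 as.numeric(plan$isocenter_mm),
                                 as.numeric(ax$u), as.numeric(ax$v))
    sp <- as.matrix(b$spots[c("u_mm", "v_mm", "range_mm", "sigma_air_mm",
                              "weight")])
    d <- cpp_beam_dose(geo$u, geo$v, geo$wepl, sp, b$range_shifter_wet_mm)
    dose_volume(array(d * plan$scale, dose_grid$size), dose_grid)
  })
  total <- dose_volume(array(Reduce(`+`, lapply(per, `[[`, "values")),
                             dose_grid$size), dose_grid)
  if (per_beam) list(total = total, beams = per) else total
}

#' Build the dose-influence matrix of a plan
#'
#' Column j holds the unit-weight dose map of beamlet j on the dose grid;
#' entries below `truncation` times the column maximum are dropped. The
#' reconstruction `Dij %*% w` matches [compute_dose()] within the
#' truncation-induced error.
#'
#' @param plan a `plan_spec`.
#' @param ct CT [volume3d()].
#' @param dose_grid target [grid3d()] (default: CT grid).
#' @param calib [rsp_calibration()].
#' @param truncation per-column relative truncation threshold in (0, 1)
#'   (default 1e-4).
#' @return list: `dij` (sparse dgCMatrix, dose-grid voxels x beamlets,
#'   Gy(RBE) per unit weight, plan scale included), `index` (data.frame
#'   beamlet -> beam/row map), `dose_grid`.
#' @export
build_dij <- function(plan, ct, dose_grid = NULL,
                      calib = rsp_calibration(), truncation = 1e-4) {
  if (truncation >= 1) stop("truncation must be < 1")
  if (is.null(dose_grid)) dose_grid <- ct$grid
  rsp <- hu_to_rsp(ct, calib)
  nvox <- grid_nvoxel(dose_grid)
  trip <- list()
  index <- list()
  offset <- 0L
  for (bi in seq_along(plan$beams)) {
    b <- plan$beams[[bi]]
    if (nrow(b$spots) == 0) next
    ax <- beam_axes(b$gantry_deg)
    geo <- cpp_wepl_depth_volume(as.numeric(rsp$values), rsp$grid$size,
                                 rsp$grid$spacing, rsp$grid$origin,
                                 dose_grid$size, dose_grid$spacing,
                                 dose_grid$origin, as.numeric(ax$d),
                                 as.numeric(plan$isocenter_mm),
                                 as.numeric(ax$u), as.numeric(ax$v))
    sp <- as.matrix(b$spots[c("u_mm", "v_mm", "range_mm", "sigma_air_mm",
                              "weight")])
    res <- cpp_beam_dij(geo$u, geo$v, geo$wepl, sp, b$range_shifter_wet_mm,
                        truncation)
    trip[[length(trip) + 1L]] <- data.frame(i = res$i + 1L,
                                            j = res$j + 1L + offset,
                                            x = res$x)
    index[[length(index) + 1L]] <- data.frame(beamlet = offset +
                                                seq_len(nrow(b$spots)),
                                              beam = bi,
                                              spot_row = seq_len(nrow(b$spots)))
    offset <- offset + nrow(b$spots)
  }
  tr <- do.call(rbind, trip)
  dij <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x * plan$scale,
                              dims = c(nvox, offset))
  list(dij = dij, index = do.call(rbind, index), dose_grid = dose_grid)
}

#' Re-optimize beamlet weights against dose objectives
#'
#' Minimizes a quadratic one-sided penalty over non-negative weights by
#' projected gradient descent with backtracking (the objective is
#' guaranteed non-increasing per iteration). Objectives reference
#' structures as dose-grid voxel index sets; supported types:
#' \describe{
#'   \item{`min`}{per-voxel underdose below `dose_gy` is penalized
#'     (targets).}
#'   \item{`max`}{per-voxel overdose above `dose_gy` is penalized.}
#'   \item{`mean_max`}{the structure mean above `dose_gy` is penalized
#'     (OAR mean constraints).}
#' }
#'
#' @param dij result of [build_dij()] (or a plain voxels-x-beamlets
#'   matrix).
#' @param structures named list of integer voxel index vectors on the dose
#'   grid.
#' @param objectives list of lists with fields `structure`, `type`,
#'   `dose_gy`, optional `weight` (penalty weight, default 1).
#' @param initial_weights starting weights (default all 1).
#' @param iterations maximum iterations (default 100).
#' @param tol stop when the relative objective decrease falls below this
#'   (default 1e-6).
#' @return list: `weights`, `trace` (objective per iteration, monotone
#'   non-increasing), `converged`.
#' @export
adapt_weights <- function(dij, structures, objectives,
                          initial_weights = NULL, iterations = 100,
                          tol = 1e-6) {
  D <- if (is.list(dij) && !is.null(dij$dij)) dij$dij else dij
  nb <- ncol(D)
  w <- if (is.null(initial_weights)) rep(1, nb) else as.numeric(initial_weights)
  if (length(w) != nb) stop("initial weights length must equal beamlets")
  for (ob in objectives) {
    vox <- structures[[ob$structure]]
    if (is.null(vox) || length(vox) == 0) {
      stop("objective references empty/unknown structure: ", ob$structure)
    }
  }
  subD <- lapply(objectives, function(ob) D[structures[[ob$structure]], ,
                                            drop = FALSE])
  penalty <- function(w) {
    f <- 0
    for (k in seq_along(objectives)) {
      ob <- objectives[[k]]
      lam <- if (is.null(ob$weight)) 1 else ob$weight
      d <- as.numeric(subD[[k]] %*% w)
      f <- f + switch(ob$type,
        min = lam * mean(pmax(ob$dose_gy - d, 0)^2),
        max = lam * mean(pmax(d - ob$dose_gy, 0)^2),
        mean_max = lam * max(mean(d) - ob$dose_gy, 0)^2,
        stop("unknown objective type: ", ob$type))
    }
    f
  }
  gradient <- function(w) {
    gr <- numeric(nb)
    for (k in seq_along(objectives)) {
      ob <- objectives[[k]]
      lam <- if (is.null(ob$weight)) 1 else ob$weight
      S <- subD[[k]]
      d <- as.numeric(S %*% w)
      n <- length(d)
      gk <- switch(ob$type,
        min = as.numeric(Matrix::crossprod(S, -2 * lam *
                                             pmax(ob$dose_gy - d, 0) / n)),
        max = as.numeric(Matrix::crossprod(S, 2 * lam *
                                             pmax(d - ob$dose_gy, 0) / n)),
        mean_max = {
          v <- max(mean(d) - ob$dose_gy, 0)
          as.numeric(Matrix::crossprod(S, rep(2 * lam * v / n, n)))
        })
      gr <- gr + gk
    }
    gr
  }
  f <- penalty(w)
  trace <- f
  eta <- 1 / max(1e-12, sum(gradient(w)^2) / max(f, 1e-12))
  converged <- FALSE
  for (it in seq_len(iterations)) {
    g <- gradient(w)
    gn <- sum(g^2)
    if (gn < 1e-30) {
      converged <- TRUE
      break
    }
    accepted <- FALSE
    for (bt in 1:40) {
      w_new <- pmax(w - eta * g, 0)
      f_new <- penalty(w_new)
      if (f_new <= f) {
        accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!accepted) {
      converged <- TRUE
      break
    }
    if (f > 0 && (f - f_new) / max(f, 1e-300) < tol) {
      w <- w_new
      f <- f_new
      trace <- c(trace, f)
      converged <- TRUE
      break
    }
    w <- w_new
    f <- f_new
    trace <- c(trace, f)
    eta <- eta * 1.5
  }
  list(weights = w, trace = trace, converged = converged)
}

#' Voxel index sets of a structure set on a dose grid
#'
#' Resamples each mask (nearest neighbour) onto the dose grid and returns
#' the linear voxel indices, for use with [adapt_weights()] and
#' [dvh_metrics()].
#' @param ss a [structure_set()].
#' @param dose_grid target [grid3d()].
#' @return named list of integer vectors.
#' @export
structure_voxels <- function(ss, dose_grid) {
  lapply(ss$masks, function(m) {
    mm <- resample_to_grid(m, dose_grid, "nearest")
    which(mm$values > 0.5)
  })
}
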