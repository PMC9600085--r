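#' Experiment configuration
#'
#' Assembles and validates the configuration of the low-dose fraction
#' experiment: exactly one of a phantom specification or a CT volume path,
#' the protocol list (default: the built-in table), the noise anchor, plan
#' geometry, gamma criteria and the master seed. All downstream randomness
#' (texture, paired-scan noise, synthesis) derives from the master seed, so
#' the whole experiment is a pure function of (config, seed).
#'
#' @param phantom a [phantom_spec()], or NULL when `ct_path` is given.
#' @param ct_path path to a CT volume readable by [read_volume()], or NULL.
#' @param structure_paths named list of mask volume paths (required with
#'   `ct_path`).
#' @param protocols list of [scan_protocol()]s (default: built-in table).
#' @param anchor a [noise_anchor()].
#' @param noise_mode `"calibrate"` (simulate a paired phantom scan and
#'   calibrate the lookup table from it, the full measurement chain) or
#'   `"anchor"` (build the table directly from the scaling law).
#' @param gantry_deg gantry angles (default 60, 180, 300).
#' @param range_shifter_wet_mm range shifter WET (default 40).
#' @param spot_spacing_mm,layer_spacing_mm spot/layer spacing (default 5).
#' @param dose_grid dose [grid3d()] or NULL for the CT grid.
#' @param gamma a [gamma_criteria()].
#' @param prescriptions_gy named prescriptions (default hr_ctv 70,
#'   lr_ctv 57).
#' @param seed master seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(phantom = phantom_spec(), ct_path = NULL,
                              structure_paths = NULL,
                              protocols = builtin_protocol_table(),
                              anchor = noise_anchor(),
                              noise_mode = c("calibrate", "anchor"),
                              gantry_deg = c(60, 180, 300),
                              range_shifter_wet_mm = 40,
                              spot_spacing_mm = 5, layer_spacing_mm = 5,
                              dose_grid = NULL,
                              gamma = gamma_criteria(),
                              prescriptions_gy = c(hr_ctv = 70, lr_ctv = 57),
                              seed = 1) {
  noise_mode <- match.arg(noise_mode)
  if (is.null(phantom) == is.null(ct_path)) {
    stop("exactly one of `phantom` and `ct_path` must be provided")
  }
  structure(list(phantom = phantom, ct_path = ct_path,
                 structure_paths = structure_paths, protocols = protocols,
                 anchor = anchor, noise_mode = noise_mode,
                 gantry_deg = gantry_deg,
                 range_shifter_wet_mm = range_shifter_wet_mm,
                 spot_spacing_mm = spot_spacing_mm,
                 layer_spacing_mm = layer_spacing_mm,
                 dose_grid = dose_grid, gamma = gamma,
                 prescriptions_gy = prescriptions_gy, seed = seed),
            class = "experiment_config")
}

# per-protocol sub-seeds derived from the master seed (kept below 2^31)
derive_seed <- function(seed, i, salt = 0L) {
  (as.integer(seed) * 7919L + i * 104729L + salt * 7L) %% 2000000011L
}

load_experiment_inputs <- function(config) {
  if (!is.null(config$phantom)) {
    ph <- generate_head_phantom(config$phantom)
    list(ct = ph$ct, structures = ph$structures)
  } else {
    ct <- read_volume(config$ct_path, kind = "ct")
    if (is.null(config$structure_paths)) {
      stop("structure_paths are required with an external CT volume")
    }
    masks <- lapply(config$structure_paths, function(p)
      read_volume(p, kind = "mask"))
    list(ct = ct, structures = structure_set(ct$grid, masks))
  }
}

#' Run the low-dose fraction experiment
#'
#' The end-to-end evaluation of low-dose scanning protocols against the
#' standard-protocol reference, at desk scale. For each protocol it
#' (1) builds the per-HU noise lookup table (by calibrating on a simulated
#' paired phantom scan, or directly from the scaling law), (2) synthesizes
#' the low-dose volume and runs the reassignment QA, (3) computes the dose
#' of the SAME plan with the SAME contours on the clean and the low-dose
#' volume — isolating the dose-calculation effect of image noise — and
#' (4) reports DVH metrics and percentage differences (targets against the
#' prescription, OARs against the reference value) plus per-beam and
#' combined gamma against the clean-volume dose.
#'
#' With `adapt = TRUE` the beamlet weights are additionally re-optimized on
#' each volume via the dose-influence matrix before comparison.
#'
#' @param config an [experiment_config()].
#' @param output_dir optional directory for report.json / metrics.csv /
#'   lut CSVs.
#' @param adapt re-optimize weights per volume (default FALSE).
#' @param verbose log stage progress (default FALSE).
#' @return an `experiment_report`: per-protocol QA, DVH metrics,
#'   percentage differences, gamma results, plus plan info, seed and
#'   config echo.
#' @export
run_fraction_experiment <- function(config, output_dir = NULL,
                                    adapt = FALSE, verbose = FALSE) {
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            ...)
  stage <- function(name, protocol, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed for protocol '", protocol, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  inputs <- load_experiment_inputs(config)
  ct <- inputs$ct
  ss <- inputs$structures
  say("building plan (", length(config$gantry_deg), " beams)")
  plan <- make_plan(ct, ss$masks$lr_ctv, gantry_deg = config$gantry_deg,
                    spot_spacing_mm = config$spot_spacing_mm,
                    layer_spacing_mm = config$layer_spacing_mm,
                    range_shifter_wet_mm = config$range_shifter_wet_mm,
                    prescriptions_gy = config$prescriptions_gy)
  dose_grid <- if (is.null(config$dose_grid)) ct$grid else config$dose_grid
  say("reference dose on the clean volume")
  clean_pb <- compute_dose(plan, ct, dose_grid, per_beam = TRUE)
  svox <- structure_voxels(ss, dose_grid)
  # normalize the plan so the HR-CTV median equals its prescription
  med <- stats::median(as.numeric(clean_pb$total$values)[svox$hr_ctv])
  rx_hr <- config$prescriptions_gy[["hr_ctv"]]
  plan <- scale_plan(plan, rx_hr / med)
  clean_pb$total$values <- clean_pb$total$values * (rx_hr / med)
  for (i in seq_along(clean_pb$beams)) {
    clean_pb$beams[[i]]$values <- clean_pb$beams[[i]]$values * (rx_hr / med)
  }
  metric_fields <- c(hr_ctv = "d98_gy", lr_ctv = "d98_gy",
                     cord = "d1cc_gy", parotid_l = "dmean_gy",
                     parotid_r = "dmean_gy", constrictors = "dmean_gy",
                     larynx = "dmean_gy")
  metric_fields <- metric_fields[names(metric_fields) %in% names(svox)]
  dvh_of <- function(dosevol) {
    out <- lapply(names(metric_fields), function(nm)
      dvh_metrics(dosevol, svox[[nm]]))
    names(out) <- names(metric_fields)
    out
  }
  clean_dvh <- dvh_of(clean_pb$total)

  per_protocol <- list()
  for (i in seq_along(config$protocols)) {
    pr <- config$protocols[[i]]
    say("protocol ", pr$label)
    lut <- stage("lut", pr$label, {
      if (config$noise_mode == "calibrate") {
        paired <- simulate_paired_scan(ct, pr, config$anchor,
                                       seed = derive_seed(config$seed, i, 1L))
        calibrate_noise(ct, paired, protocol = pr)
      } else {
        lut_from_anchor(config$anchor, pr$tube_current_ma)
      }
    })
    syn_seed <- derive_seed(config$seed, i, 2L)
    qa <- stage("qa", pr$label, {
      raw <- synthesize_low_dose(ct, lut, seed = syn_seed,
                                 integerize = FALSE)
      qa_synthesis(ct, raw)
    })
    low_ct <- stage("synthesize", pr$label,
                    synthesize_low_dose(ct, lut, seed = syn_seed))
    if (adapt) {
      dijr <- stage("dij", pr$label, build_dij(plan, low_ct, dose_grid))
      objectives <- default_objectives(config$prescriptions_gy, svox)
      ad <- stage("adapt", pr$label,
                  adapt_weights(dijr, svox, objectives,
                                initial_weights = plan_weights(plan) *
                                  plan$scale))
      plan_low <- set_plan_weights(plan, ad$weights / plan$scale)
    } else {
      plan_low <- plan
    }
    low_pb <- stage("dose", pr$label,
                    compute_dose(plan_low, low_ct, dose_grid,
                                 per_beam = TRUE))
    low_dvh <- dvh_of(low_pb$total)
    denom <- config$prescriptions_gy[intersect(names(config$prescriptions_gy),
                                               names(metric_fields))]
    pdiff <- percent_difference(low_dvh, clean_dvh, metric_fields,
                                denominators = denom)
    gam <- stage("gamma", pr$label, {
      combined <- gamma_index(clean_pb$total, low_pb$total, config$gamma)
      beams <- lapply(seq_along(clean_pb$beams), function(bi)
        gamma_index(clean_pb$beams[[bi]], low_pb$beams[[bi]], config$gamma))
      list(combined = combined, beams = beams)
    })
    per_protocol[[pr$label]] <- list(
      protocol = pr, qa = qa, lut = lut,
      dvh_low = low_dvh, percent_diff = pdiff,
      gamma_combined = gam$combined,
      gamma_per_beam_percent = vapply(gam$beams, `[[`, numeric(1),
                                      "pass_rate_percent"))
  }
  report <- structure(list(per_protocol = per_protocol,
                           dvh_clean = clean_dvh, plan = plan,
                           metric_fields = metric_fields,
                           seed = config$seed, config = config),
                      class = "experiment_report")
  if (!is.null(output_dir)) write_experiment_report(report, output_dir)
  report
}

default_objectives <- function(prescriptions_gy, svox) {
  obj <- list(
    list(structure = "hr_ctv", type = "min",
         dose_gy = prescriptions_gy[["hr_ctv"]], weight = 100),
    list(structure = "hr_ctv", type = "max",
         dose_gy = 1.07 * prescriptions_gy[["hr_ctv"]], weight = 100),
    list(structure = "lr_ctv", type = "min",
         dose_gy = prescriptions_gy[["lr_ctv"]], weight = 50))
  oar_caps <- c(cord = 45, parotid_l = 26, parotid_r = 26,
                constrictors = 42, larynx = 40, brainstem = 54)
  for (nm in intersect(names(oar_caps), names(svox))) {
    type <- if (nm %in% c("cord", "brainstem")) "max" else "mean_max"
    obj[[length(obj) + 1L]] <- list(structure = nm, type = type,
                                    dose_gy = oar_caps[[nm]], weight = 1)
  }
  obj
}

#' Tidy metrics table of an experiment report
#' @param report an `experiment_report`.
#' @return data.frame: protocol, structure, metric, value_low, value_ref,
#'   percent_diff, qa_fraction, gamma_combined_percent.
#' @export
report_metrics_df <- function(report) {
  do.call(rbind, lapply(names(report$per_protocol), function(lbl) {
    p <- report$per_protocol[[lbl]]
    df <- p$percent_diff
    df$protocol <- lbl
    df$qa_fraction <- p$qa$fraction_reassigned
    df$gamma_combined_percent <- p$gamma_combined$pass_rate_percent
    df
  }))
}

write_experiment_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  df <- report_metrics_df(report)
  utils::write.csv(df, file.path(output_dir, "metrics.csv"),
                   row.names = FALSE)
  summary <- list(
    seed = report$seed,
    protocols = lapply(report$per_protocol, function(p) list(
      label = p$protocol$label,
      tube_current_ma = p$protocol$tube_current_ma,
      ctdi_vol_mgy = p$protocol$ctdi_vol_mgy,
      qa_fraction = p$qa$fraction_reassigned,
      qa_pass = p$qa$pass,
      gamma_combined_percent = p$gamma_combined$pass_rate_percent,
      gamma_per_beam_percent = p$gamma_per_beam_percent,
      max_abs_target_d98_percent =
        max(abs(p$percent_diff$percent_diff[
          p$percent_diff$denominator_kind == "prescription"])),
      max_abs_oar_percent =
        max(abs(p$percent_diff$percent_diff[
          p$percent_diff$denominator_kind == "reference"])))))
  jsonlite::write_json(summary, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (lbl in names(report$per_protocol)) {
    write_lut(report$per_protocol[[lbl]]$lut,
              file.path(output_dir, paste0("lut_", lbl, ".csv")))
  }
  invisible(output_dir)
}

#' Contour-similarity experiment
#'
#' Propagates the high-risk CTV, the low-risk CTV and the union of all
#' OARs through two deformation fields (ground-truth stand-ins for the two
#' registrations of a daily image pair) and reports the Dice coefficient
#' between the two propagations per structure.
#'
#' @param structures a [structure_set()] with roles tagged.
#' @param field_a,field_b [deformation_field()]s on the structure grid
#'   (use [identity_deformation()] for the reference side).
#' @return data.frame: structure, dice.
#' @export
run_contour_similarity <- function(structures, field_a, field_b) {
  stop_if_misaligned(field_a$grid, field_b$grid, "deformation fields")
  stop_if_misaligned(structures$grid, field_a$grid,
                     "structures and deformation fields")
  oars <- structures_with_role(structures, "oar")
  if (length(oars) == 0) stop("structure set has no OARs")
  union_oar <- Reduce(`|`, lapply(oars, function(nm)
    structures$masks[[nm]]$values > 0.5))
  sel <- list(
    hr_ctv = structures$masks$hr_ctv,
    lr_ctv = structures$masks$lr_ctv,
    oar_union = mask_volume(array(as.numeric(union_oar),
                                  structures$grid$size), structures$grid))
  rows <- lapply(names(sel), function(nm) {
    a <- apply_deformation(sel[[nm]], field_a, "nearest")
    b <- apply_deformation(sel[[nm]], field_b, "nearest")
    data.frame(structure = nm, dice = dice(a, b))
  })
  do.call(rbind, rows)
}
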