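# RSP conversion, WEPL tracing, Bragg curve, dose, Dij, weight adaptation.

test_that("HU to RSP: anchors, linearity between control points, monotonicity", {
  g <- grid3d(c(3, 1, 1), c(1, 1, 1))
  ct <- ct_volume(array(c(0, -1000, 500), c(3, 1, 1)), g)
  rsp <- hu_to_rsp(ct)
  expect_equal(rsp$values[1, 1, 1], 1.0)      # water anchor
  expect_equal(rsp$values[2, 1, 1], 0.001)    # air
  # midpoint between the (0, 1.0) and (1000, 1.54) control points
  expect_equal(rsp$values[3, 1, 1], (1.0 + 1.54) / 2)
  expect_error(rsp_calibration(hu = c(0, 0, 10), rsp = c(1, 1, 1.1)),
               "increasing")
  expect_error(rsp_calibration(hu = c(-10, 0, 10), rsp = c(1.2, 1, 1.1)),
               "non-decreasing")
})

test_that("Siddon WEPL: water, scaled media, oblique chords, misses", {
  wat <- hu_to_rsp(water_volume(c(60, 60, 60), c(2, 2, 2)))
  # 100 mm geometric path inside water
  r <- trace_wepl(wat, c(-40, 0, 0), c(1, 0, 0))
  expect_equal(r$wepl_mm, 100, tolerance = 1e-9)
  # uniform RSP 0.5: same path gives 50 mm
  half <- volume3d(array(0.5, wat$grid$size), wat$grid)
  expect_equal(trace_wepl(half, c(-40, 0, 0), c(1, 0, 0))$wepl_mm, 50,
               tolerance = 1e-9)
  # oblique unit direction: WEPL equals the chord length in water
  d <- c(1, 1, 0) / sqrt(2)
  ro <- trace_wepl(wat, c(-200, -200, 0), d)
  expect_equal(ro$wepl_mm, ro$length_mm, tolerance = 1e-9)
  expect_equal(ro$length_mm, 120 * sqrt(2), tolerance = 1e-9)
  expect_warning(trace_wepl(wat, c(500, 500, 500), c(0, 0, 1)),
                 "intersect")
})

test_that("WEPL noise averages out along the path (central-limit scaling)", {
  # relative spread of WEPL over 200 noisy realizations shrinks like
  # 1/sqrt(path voxels): 200 mm vs 50 mm paths -> ratio ~ 0.5
  reps <- 200
  relsd <- vapply(c(200, 50), function(len) {
    g <- grid3d(c(len, 9, 9), c(1, 1, 1))
    n <- prod(g$size)
    set.seed(len)
    w <- vapply(seq_len(reps), function(r) {
      ct <- ct_volume(array(round_hu(rnorm(n, 0, 20)), g$size), g)
      trace_wepl(hu_to_rsp(ct), c(-0.5, 4, 4), c(1, 0, 0))$wepl_mm
    }, numeric(1))
    sd(w) / mean(w)
  }, numeric(1))
  ratio <- relsd[1] / relsd[2]
  expect_lt(abs(ratio - 0.5), 0.1)  # within 20% of the CLT prediction
})

test_that("Bragg curve: bounded entrance, peak at range, distal cutoff", {
  depths <- seq(0, 320, by = 0.05)
  dd <- bragg_depth_dose(150, depths)
  expect_gt(dd[1], 0)
  expect_lt(dd[1], 1)
  expect_lt(abs(depths[which.max(dd)] - 150), 0.5)
  expect_equal(max(dd), 1, tolerance = 1e-4)
  expect_equal(bragg_depth_dose(150, 300), 0)
  expect_error(bragg_depth_dose(-10, 5), "positive")
  expect_error(bragg_depth_dose(150, -5), "non-negative")
  # entrance-to-peak ratio around 3
  expect_gt(1 / dd[1], 2.5)
  expect_lt(1 / dd[1], 4.5)
})

test_that("range-energy map hits its anchors and sigma_air interpolates", {
  expect_equal(range_from_energy(65), 37, tolerance = 1e-9)
  expect_equal(range_from_energy(225), 325, tolerance = 1e-9)
  expect_equal(energy_from_range(37), 65, tolerance = 1e-9)
  expect_equal(sigma_air_from_energy(65), 6.4)
  expect_equal(sigma_air_from_energy(225), 2.5)
  expect_equal(sigma_air_from_energy(145), (6.4 + 2.5) / 2)
})

test_that("dose is linear in spot weights and zero for zero weights", {
  wat <- water_volume(c(40, 40, 20), c(3, 3, 3))
  mkplan <- function(w1, w2) {
    plan_spec(beams = list(list(
      gantry_deg = 0,
      spots = data.frame(u_mm = c(-5, 5), v_mm = 0, range_mm = c(80, 90),
                         energy_mev = NA, sigma_air_mm = 4,
                         weight = c(w1, w2)),
      range_shifter_wet_mm = 40, air_gap_mm = 30)),
      isocenter_mm = c(0, 0, 0))
  }
  d0 <- compute_dose(mkplan(0, 0), wat)
  expect_true(all(d0$values == 0))
  da <- compute_dose(mkplan(1, 0), wat)
  db <- compute_dose(mkplan(0, 2), wat)
  dab <- compute_dose(mkplan(1, 2), wat)
  expect_equal(dab$values, da$values + db$values, tolerance = 1e-9)
})

test_that("single spot in water peaks at nominal range minus shifter WET", {
  wat <- water_volume(c(40, 40, 40), c(2, 2, 2))  # 40 mm half-extent
  plan <- single_spot_plan(range_mm = 100, rs_wet = 40)  # peak 60 mm deep
  d <- compute_dose(plan, wat)
  # central axis: nearest voxels to x = 0, z = 0; entry surface y = -40 mm
  axis <- d$values[20, , 20]
  ys <- wat$grid$origin[2] + (seq_len(40) - 1) * wat$grid$spacing[2]
  peak_depth <- ys[which.max(axis)] + 40
  expect_lt(abs(peak_depth - (100 - 40)), 2 + 1e-9)  # one dose-grid step
  # 1D oracle: WEPL depth of each axis voxel + shifter WET vs the Bragg
  # curve evaluated directly at those depths
  depths <- ys + 40 + 40
  oracle_axis <- bragg_depth_dose(100, depths)
  expect_equal(which.max(axis), which.max(oracle_axis))
})

test_that("dose is invariant under relabeling of spots and beams", {
  wat <- water_volume(c(30, 30, 20), c(3, 3, 3))
  spots <- data.frame(u_mm = c(-6, 0, 6, 0), v_mm = c(0, -6, 0, 6),
                      range_mm = c(70, 80, 90, 85), energy_mev = NA,
                      sigma_air_mm = 4, weight = c(1, 2, 3, 4))
  mk <- function(ord, beam_ord = 1:2) {
    beams <- list(
      list(gantry_deg = 0, spots = spots[ord, ],
           range_shifter_wet_mm = 40, air_gap_mm = 30),
      list(gantry_deg = 90, spots = spots[ord, ],
           range_shifter_wet_mm = 40, air_gap_mm = 30))
    plan_spec(beams = beams[beam_ord], isocenter_mm = c(0, 0, 0))
  }
  d1 <- compute_dose(mk(1:4), wat)
  d2 <- compute_dose(mk(c(3, 1, 4, 2), beam_ord = 2:1), wat)
  expect_equal(d2$values, d1$values, tolerance = 1e-12)
})

test_that("three-field dose on a mirror-symmetric phantom is mirror-symmetric", {
  ph <- generate_head_phantom(small_phantom_spec(texture = 0))
  plan <- make_plan(ph$ct, ph$structures$masks$lr_ctv,
                    spot_spacing_mm = 8, layer_spacing_mm = 8)
  d <- compute_dose(plan, ph$ct)
  mirrored <- d$values[rev(seq_len(dim(d$values)[1])), , ]
  dmax <- max(d$values)
  expect_lt(max(abs(d$values - mirrored)) / dmax, 0.005)
})

test_that("Dij reconstruction matches direct dose within truncation error", {
  ph <- generate_head_phantom(small_phantom_spec(texture = 0))
  plan <- make_plan(ph$ct, ph$structures$masks$hr_ctv,
                    spot_spacing_mm = 10, layer_spacing_mm = 10)
  direct <- compute_dose(plan, ph$ct)
  dj <- build_dij(plan, ph$ct)
  expect_true(all(dj$dij@x >= 0))
  recon <- as.numeric(dj$dij %*% plan_weights(plan))
  dmax <- max(direct$values)
  expect_lt(max(abs(recon - as.numeric(direct$values))) / dmax, 0.005)
  # gamma self-consistency between reconstructed and direct dose
  drecon <- dose_volume(array(recon, direct$grid$size), direct$grid)
  g <- gamma_index(direct, drecon)
  expect_equal(g$pass_rate_percent, 100)
  expect_error(build_dij(plan, ph$ct, truncation = 1), "truncation")
})

test_that("a one-beamlet plan yields a single Dij column equal to its dose", {
  wat <- water_volume(c(30, 30, 20), c(3, 3, 3))
  plan <- single_spot_plan(range_mm = 80)
  dj <- build_dij(plan, wat, truncation = 1e-6)
  expect_equal(ncol(dj$dij), 1)
  direct <- compute_dose(plan, wat)
  col <- as.numeric(dj$dij[, 1])
  keep <- col > 0
  expect_equal(col[keep], as.numeric(direct$values)[keep],
               tolerance = 1e-12)
})

test_that("weight adaptation: fixed point, monotone trace, linear scaling", {
  wat <- water_volume(c(30, 30, 16), c(3, 3, 3))
  target <- array(0, wat$grid$size)
  target[13:18, 13:18, 7:10] <- 1
  plan <- make_plan(wat, mask_volume(target, wat$grid),
                    gantry_deg = c(0, 180), spot_spacing_mm = 6,
                    layer_spacing_mm = 6)
  dj <- build_dij(plan, wat)
  svox <- list(tgt = which(target > 0.5))
  # fixed point: an objective that is already satisfied leaves weights alone
  res0 <- adapt_weights(dj, svox,
                        list(list(structure = "tgt", type = "min",
                                  dose_gy = 0)),
                        initial_weights = plan_weights(plan))
  expect_equal(res0$weights, plan_weights(plan))
  # optimize to a prescription; trace must never increase
  obj <- function(rx) list(list(structure = "tgt", type = "min",
                                dose_gy = rx),
                           list(structure = "tgt", type = "max",
                                dose_gy = 1.07 * rx))
  w0 <- rep(0, ncol(dj$dij))
  r1 <- adapt_weights(dj, svox, obj(1), initial_weights = w0,
                      iterations = 60)
  expect_true(all(diff(r1$trace) <= 1e-12))
  expect_true(all(r1$weights >= 0))
  # linear engine: scaling the prescription by k scales the weights by k
  r2 <- adapt_weights(dj, svox, obj(2), initial_weights = w0,
                      iterations = 60)
  nz <- r1$weights > 1e-8 * max(r1$weights)
  expect_lt(max(abs(r2$weights[nz] / r1$weights[nz] - 2)), 0.02)
  expect_error(adapt_weights(dj, svox,
                             list(list(structure = "nope", type = "min",
                                       dose_gy = 1))), "structure")
})
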