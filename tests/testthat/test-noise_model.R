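# Per-HU noise lookup-table calibration, scaling fit, synthesis and QA.

test_that("calibrating an identical pair gives identity means and zero sigma", {
  ph <- generate_head_phantom(small_phantom_spec())
  lut <- calibrate_noise(ph$ct, ph$ct)
  filled <- lut[lut$interpolated == 0, ]
  expect_gt(nrow(filled), 0)
  expect_equal(filled$mean_hu, filled$reference_hu)
  expect_true(all(filled$sigma_hu == 0))
})

test_that("calibration recovers the low-dose Gaussian at HU 0", {
  # uniform 0 HU reference; low-dose adds N(-0.45, 20) per voxel
  clean <- flat_ct(1e5, hu = 0)
  set.seed(123)
  low <- ct_volume(array(round_hu(clean$values +
                                    rnorm(length(clean$values), -0.45, 20)),
                         clean$grid$size), clean$grid)
  lut <- calibrate_noise(clean, low, slice_selection = seq_len(50))
  b0 <- lut[lut$reference_hu == 0, ]
  expect_equal(b0$interpolated, 0L)
  expect_lt(abs(b0$sigma_hu - 20) / 20, 0.02)
  expect_lt(abs(b0$mean_hu - (-0.45)), 0.15)
})

test_that("per-compartment sigmas are recovered and match a direct oracle", {
  g <- grid3d(c(40, 50, 50), c(1, 1, 1))
  ref <- array(0, g$size)
  ref[1:20, , ] <- 1000
  clean <- ct_volume(ref, g)
  set.seed(5)
  noise <- ifelse(ref == 1000, rnorm(length(ref), 0, 5),
                  rnorm(length(ref), 0, 20))
  low <- ct_volume(array(round_hu(ref + noise), g$size), g)
  lut <- calibrate_noise(clean, low, slice_selection = seq_len(40))
  oracle <- oracle_bin_stats(as.numeric(ref), as.numeric(low$values))
  for (hu in c(0, 1000)) {
    entry <- lut[lut$reference_hu == hu, ]
    o <- oracle[oracle$hu == hu, ]
    expect_equal(entry$mean_hu, o$mean)
    expect_equal(entry$sigma_hu, o$sd)  # n-1 denominator on both sides
  }
  expect_lt(abs(lut$sigma_hu[lut$reference_hu == 0] - 20) / 20, 0.03)
  expect_lt(abs(lut$sigma_hu[lut$reference_hu == 1000] - 5) / 5, 0.03)
})

test_that("gaps between observed HU bins are linearly interpolated", {
  g <- grid3d(c(20, 20, 20), c(1, 1, 1))
  ref <- array(rep(c(0, 10), each = 4000), g$size)
  clean <- ct_volume(ref, g)
  low <- ct_volume(ref + ifelse(ref == 0, 2, 6), g)  # shifts 2 and 6
  lut <- calibrate_noise(clean, low, slice_selection = seq_len(20))
  expect_equal(nrow(lut), 11)
  mid <- lut[lut$reference_hu == 5, ]
  expect_equal(mid$interpolated, 1L)
  expect_equal(mid$mean_hu, 9)  # linear between mean(0)=2 and mean(10)=16
  expect_error(calibrate_noise(clean, low, slice_selection = seq_len(20),
                               min_samples = 1e7), "min_samples")
})

test_that("calibration is an unbiased estimator of mu and sigma", {
  # 100 replicates at n = 1e5, true (mu, sigma) = (-0.45, 20)
  clean <- flat_ct(1e5, hu = 0)
  n <- length(clean$values)
  mus <- sigmas <- numeric(100)
  set.seed(99)
  for (r in 1:100) {
    low <- ct_volume(array(round_hu(rnorm(n, -0.45, 20)), clean$grid$size),
                     clean$grid)
    lut <- calibrate_noise(clean, low, slice_selection = seq_len(50))
    b0 <- lut[lut$reference_hu == 0, ]
    mus[r] <- b0$mean_hu
    sigmas[r] <- b0$sigma_hu
  }
  expect_lt(abs(mean(sigmas) - 20) / 20, 0.005)
  expect_lt(abs(mean(mus) - (-0.45)), 0.05)
})

test_that("gaussianity report: self-consistent fit, degeneracy, and R2 ranking", {
  clean <- flat_ct(1e5, hu = 0)
  n <- length(clean$values)
  set.seed(31)
  low <- ct_volume(array(round_hu(rnorm(n, 0, 20)), clean$grid$size),
                   clean$grid)
  rep_g <- gaussianity_report(clean, low, bin = 0,
                              slice_selection = seq_len(50))
  expect_false(rep_g$degenerate)
  expect_lt(abs(rep_g$fit$mean - rep_g$sample$mean), 0.05 * 20)
  expect_lt(abs(rep_g$fit$sigma - rep_g$sample$sigma) / rep_g$sample$sigma,
            0.05)
  # constant residuals: degenerate, no fit attempted
  same <- gaussianity_report(clean, clean, bin = 0,
                             slice_selection = seq_len(50))
  expect_true(same$degenerate)
  expect_null(same$fit)
  # uniform residuals of equal variance fit a Gaussian worse
  unif <- ct_volume(array(round_hu(runif(n, -20 * sqrt(3), 20 * sqrt(3))),
                          clean$grid$size), clean$grid)
  rep_u <- gaussianity_report(clean, unif, bin = 0,
                              slice_selection = seq_len(50))
  expect_gt(rep_g$r_squared, rep_u$r_squared)
  expect_error(gaussianity_report(clean, low, bin = 500,
                                  slice_selection = seq_len(50)), "voxels")
})

test_that("current-scaling fit recovers the exact inverse-sqrt law", {
  currents <- c(400, 200, 100, 50, 25, 15, 10)
  sigmas <- 20 * sqrt(10 / currents)
  model <- fit_current_scaling(currents, sigmas, i_ref_ma = 10)
  expect_equal(model$exponent, -0.5, tolerance = 1e-6)
  expect_equal(model$sigma_ref_hu, 20, tolerance = 1e-6)
  # fixed-exponent prediction: sigma(40 mA) from sigma(10 mA) = 20 is 10
  fixed <- fit_current_scaling(10, 20, i_ref_ma = 10, exponent = -0.5)
  expect_equal(predict_sigma(fixed, 40), 10, tolerance = 1e-9)
  expect_error(fit_current_scaling(10, 20), "distinct")
  expect_error(fit_current_scaling(c(10, 20), c(-1, 5)), "positive")
})

test_that("synthesis: degenerate identity, determinism, calibration round trip", {
  ph <- generate_head_phantom(small_phantom_spec())
  hu_range <- range(ph$ct$values)
  ident <- data.frame(reference_hu = seq(hu_range[1], hu_range[2]),
                      mean_hu = seq(hu_range[1], hu_range[2]),
                      sigma_hu = 0, n_samples = 0L, interpolated = 0L)
  attr(ident, "bin_width") <- 1
  class(ident) <- c("noise_lut", "data.frame")
  expect_identical(synthesize_low_dose(ph$ct, ident, seed = 1)$values,
                   ph$ct$values)
  lut <- lut_from_anchor(noise_anchor(), 10)
  s1 <- synthesize_low_dose(ph$ct, lut, seed = 4)
  s2 <- synthesize_low_dose(ph$ct, lut, seed = 4)
  expect_identical(s1$values, s2$values)
  # round trip: calibrating on (clean, synthesized) recovers the lut sigma
  # per bin within 3% at >= 1e4 samples per bin (two well-populated bins;
  # bins near the -1024 HU clamp would see a truncated Gaussian instead)
  g2 <- grid3d(c(40, 50, 50), c(1, 1, 1))
  two <- ct_volume(array(rep(c(0, 1000), each = 50000), g2$size), g2)
  syn2 <- synthesize_low_dose(two, lut, seed = 8)
  recal <- calibrate_noise(two, syn2, slice_selection = seq_len(40))
  filled <- recal[recal$n_samples >= 1e4, ]
  expect_equal(nrow(filled), 2)
  expect_true(all(abs(filled$sigma_hu - 20) / 20 < 0.03))
})

test_that("out-of-domain HU error lists the offending values", {
  g <- grid3d(c(4, 4, 4), c(1, 1, 1))
  clean <- ct_volume(array(500, c(4, 4, 4)), g)
  lut <- lut_from_anchor(noise_anchor(), 10, hu_range = c(-100, 100))
  expect_error(synthesize_low_dose(clean, lut, extrapolate = FALSE), "500")
  expect_silent(synthesize_low_dose(clean, lut))  # constant extrapolation
})

test_that("noise is i.i.d. within an HU bin: sigma is permutation-invariant", {
  g <- grid3d(c(40, 50, 50), c(1, 1, 1))
  ref <- array(rep(c(0, 200), each = 50000), g$size)
  clean <- ct_volume(ref, g)
  lut <- lut_from_anchor(noise_anchor(), 10)
  syn <- synthesize_low_dose(clean, lut, seed = 6)
  resid <- as.numeric(syn$values) - as.numeric(ref)
  # permute voxels within each bin and recompute the per-bin sigma
  set.seed(77)
  perm <- as.numeric(ref)
  for (hu in c(0, 200)) {
    sel <- which(ref == hu)
    shuffled <- resid[sample(sel)]
    expect_equal(sd(shuffled), sd(resid[sel]))
  }
})

test_that("reassignment QA counts changed voxels and applies the threshold", {
  ph <- generate_head_phantom(small_phantom_spec())
  qa_same <- qa_synthesis(ph$ct, ph$ct)
  expect_equal(qa_same$fraction_reassigned, 0.0)
  expect_false(qa_same$pass)
  # exactly half the voxels changed
  half <- ph$ct
  n <- length(half$values)
  half$values[seq_len(n / 2)] <- half$values[seq_len(n / 2)] + 1
  half$values <- pmin(half$values, 3071)
  expect_equal(qa_synthesis(ph$ct, half)$fraction_reassigned, 0.5)
  # lowest-dose synthesis, QA on the raw assigned values
  lut <- lut_from_anchor(noise_anchor(), 10)
  raw <- synthesize_low_dose(ph$ct, lut, seed = 2, integerize = FALSE)
  qa <- qa_synthesis(ph$ct, raw)
  expect_gte(qa$fraction_reassigned, 0.999)
  expect_true(qa$pass)
})

test_that("lookup tables round-trip through the CSV interface", {
  lut <- lut_from_anchor(noise_anchor(), 40, hu_range = c(-50, 50))
  path <- file.path(tempdir(), "lut.csv")
  write_lut(lut, path)
  back <- read_lut(path)
  expect_equal(back$reference_hu, lut$reference_hu)
  expect_equal(back$sigma_hu, lut$sigma_hu)
  writeLines("a,b\n1,2", path)
  expect_error(read_lut(path), "columns")
  unlink(path)
})
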