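# DVH metrics, Dice, gamma index, percentage differences, cohort summary.

test_that("DVH metrics: uniform dose, counted Dx, hottest-1cc convention", {
  # uniform structure: every metric equals the uniform dose
  g <- grid3d(c(10, 10, 1), c(10, 10, 10))  # 1 cc voxels
  uni <- dose_volume(array(10, c(10, 10, 1)), g)
  m <- dvh_metrics(uni, seq_len(100))
  expect_equal(c(m$d98_gy, m$d2_gy, m$dmean_gy, m$dmax_gy, m$d1cc_gy),
               rep(10, 5))
  # 100 voxels with doses 1..100 Gy: D98 = 3, D2 = 99 (lower-bound count)
  ramp <- dose_volume(array(1:100, c(10, 10, 1)), g)
  m2 <- dvh_metrics(ramp, seq_len(100))
  expect_equal(m2$d98_gy, 3)
  expect_equal(m2$d2_gy, 99)
  expect_equal(m2$d1cc_gy, 100)  # hottest single 1 cc voxel
  # 2 cc structure, half 10 Gy / half 20 Gy: D_1cc = 20, Dmean = 15
  g4 <- grid3d(c(4, 1, 1), c(5, 10, 10))  # 0.5 cc voxels
  d4 <- dose_volume(array(c(10, 10, 20, 20), c(4, 1, 1)), g4)
  m3 <- dvh_metrics(d4, 1:4)
  expect_equal(m3$d1cc_gy, 20)
  expect_equal(m3$dmean_gy, 15)
  # sub-1cc structure falls back to Dmin with a warning
  expect_warning(msmall <- dvh_metrics(d4, 4), "1 cc")
  expect_equal(msmall$d1cc_gy, 20)
  expect_error(dvh_metrics(d4, integer(0)), "empty")
})

test_that("DVH metrics agree exactly with the exhaustive-sort oracle", {
  g <- grid3d(c(10, 10, 10), c(4, 4, 4))  # 0.064 cc voxels
  set.seed(12)
  for (rep in 1:5) {
    doses <- round(runif(1000, 0, 80), 2)
    dv <- dose_volume(array(doses, c(10, 10, 10)), g)
    m <- dvh_metrics(dv, seq_len(1000))
    expect_equal(m$d98_gy, oracle_dx(doses, 98))
    expect_equal(m$d2_gy, oracle_dx(doses, 2))
    expect_equal(m$dmean_gy, mean(doses))
    expect_equal(m$dmax_gy, max(doses))
    expect_equal(m$d1cc_gy, oracle_d1cc(doses, voxel_volume_cc(g)))
  }
  # invariants: Dmax >= D2 >= D98, curve monotone from 1 to 0
  dv <- dose_volume(array(runif(1000, 0, 80), c(10, 10, 10)), g)
  m <- dvh_metrics(dv, seq_len(1000))
  expect_true(m$dmax_gy >= m$d2_gy && m$d2_gy >= m$d98_gy)
  expect_true(all(diff(m$curve$volume_fraction) <= 0))
  expect_equal(m$curve$volume_fraction[1], 1)
})

test_that("Dice: identity, disjointness, arithmetic, symmetry, empty case", {
  g <- grid3d(c(20, 20, 5), c(2, 2, 2))
  a <- array(0, g$size)
  a[1:10, 1:10, ] <- 1
  b <- array(0, g$size)
  b[11:20, 11:20, ] <- 1
  ma <- mask_volume(a, g)
  mb <- mask_volume(b, g)
  expect_equal(dice(ma, ma), 1.0)
  expect_equal(dice(ma, mb), 0.0)
  # |A| = |B| = 100, |A intersect B| = 90 -> 0.9
  a2 <- array(0, g$size)
  a2[1:100] <- 1
  b2 <- array(0, g$size)
  b2[11:110] <- 1
  m2a <- mask_volume(a2, g)
  m2b <- mask_volume(b2, g)
  expect_equal(dice(m2a, m2b), 0.9)
  expect_equal(dice(m2b, m2a), dice(m2a, m2b))
  empty <- mask_volume(array(0, g$size), g)
  expect_equal(dice(empty, empty), 1.0)
  g2 <- grid3d(c(20, 20, 5), c(2, 2, 3))
  expect_error(dice(ma, mask_volume(b, g2)), "aligned")
})

test_that("gamma: identity, uniform 2% offset, and low-dose threshold", {
  g <- grid3d(c(12, 12, 6), c(2, 2, 2))
  ref <- dose_volume(array(50, c(12, 12, 6)), g)
  same <- gamma_index(ref, ref)
  expect_equal(same$pass_rate_percent, 100)
  expect_true(all(same$gamma_values == 0, na.rm = TRUE))
  # evaluated = reference * 1.02 with global 2% normalization:
  # gamma = 1 at (every) D_max voxel, pass rate 100
  up <- dose_volume(ref$values * 1.02, g)
  g2 <- gamma_index(ref, up)
  expect_equal(g2$pass_rate_percent, 100)
  expect_equal(max(g2$gamma_values, na.rm = TRUE), 1, tolerance = 1e-6)
  # voxels below 10% of the reference maximum are excluded
  mix <- array(50, c(12, 12, 6))
  mix[1:3, , ] <- 1
  refm <- dose_volume(mix, g)
  gm <- gamma_index(refm, refm)
  expect_equal(gm$n_evaluated, sum(mix >= 5))
  expect_error(gamma_index(ref, up, search_radius_mm = 0.5), "radius")
})

test_that("gamma on a shifted 1D ramp matches the exhaustive-search oracle", {
  n <- 101
  g <- grid3d(c(n, 1, 1), c(1, 1, 1))
  ref_prof <- seq(0, 100, length.out = n)
  ev_prof <- c(0, ref_prof[-n])  # shifted 1 mm along +x
  ref <- dose_volume(array(ref_prof, c(n, 1, 1)), g)
  ev <- dose_volume(array(ev_prof, c(n, 1, 1)), g)
  res <- gamma_index(ref, ev)
  evaluated <- which(!is.na(res$gamma_values))
  # 1 mm shift against a 2 mm DTA: gamma <= 0.5 everywhere, all pass
  expect_true(all(res$gamma_values[evaluated] <= 0.5 + 1e-6))
  expect_equal(res$pass_rate_percent, 100)
  oracle <- oracle_gamma_1d(ref_prof, ev_prof, 1, 0.02 * 100, 2)
  expect_lt(max(abs(res$gamma_values[evaluated] - oracle[evaluated])),
            0.05)
})

test_that("gamma is asymmetric and monotone in the criteria", {
  g <- grid3d(c(15, 1, 1), c(2, 2, 2))
  flat <- array(50, c(15, 1, 1))
  spiky <- flat
  spiky[8, 1, 1] <- 100
  a <- dose_volume(spiky, g)  # reference with a hot spike
  b <- dose_volume(flat, g)
  fwd <- gamma_index(a, b)   # spike has no counterpart: fails there
  bwd <- gamma_index(b, a)   # flat reference is matched everywhere nearby
  expect_lt(fwd$pass_rate_percent, 100)
  expect_equal(bwd$pass_rate_percent, 100)
  expect_false(isTRUE(all.equal(fwd$pass_rate_percent,
                                bwd$pass_rate_percent)))
  # tightening criteria can only lower the pass rate
  gg <- grid3d(c(20, 20, 6), c(2, 2, 2))
  set.seed(8)
  base <- 40 + 20 * exp(-((row(matrix(0, 20, 20)) - 10)^2 +
                            (col(matrix(0, 20, 20)) - 10)^2) / 40)
  refv <- dose_volume(array(rep(base, 6), c(20, 20, 6)), gg)
  evv <- dose_volume(refv$values * (1 + rnorm(2400, 0, 0.015)), gg)
  loose <- gamma_index(refv, evv, gamma_criteria(2, 2))
  tight <- gamma_index(refv, evv, gamma_criteria(1, 1))
  expect_gte(loose$pass_rate_percent, tight$pass_rate_percent)
})

test_that("percentage differences follow the two denominator conventions", {
  mk <- function(d98, dmean) {
    structure(list(d98_gy = d98, dmean_gy = dmean), class = "dvh_metrics")
  }
  low <- list(ctv = mk(66.85, 60), oar = mk(10, 20.6))
  ref <- list(ctv = mk(66.5, 60), oar = mk(10, 20))
  out <- percent_difference(low, ref,
                            c(ctv = "d98_gy", oar = "dmean_gy"),
                            denominators = c(ctv = 70))
  expect_equal(out$percent_diff[out$structure == "ctv"], 0.5)
  expect_equal(out$denominator_kind[out$structure == "ctv"],
               "prescription")
  expect_equal(out$percent_diff[out$structure == "oar"], 3.0)
  expect_equal(out$denominator_kind[out$structure == "oar"], "reference")
  ident <- percent_difference(ref, ref, c(ctv = "d98_gy", oar = "dmean_gy"))
  expect_true(all(ident$percent_diff == 0))
  zero <- list(o = mk(1, 0))
  expect_true(is.na(percent_difference(list(o = mk(1, 5)), zero,
                                       c(o = "dmean_gy"))$percent_diff))
})

test_that("cohort summary: medians and min-max bracket the cases", {
  mkcase <- function(v) data.frame(structure = "ctv", metric = "d98",
                                   value = v)
  single <- summarize_cohort(list(mkcase(2)))
  expect_equal(c(single$median, single$min, single$max), c(2, 2, 2))
  three <- summarize_cohort(list(mkcase(1), mkcase(2), mkcase(3)))
  expect_equal(c(three$median, three$min, three$max), c(2, 1, 3))
  outlier <- summarize_cohort(list(mkcase(1.9), mkcase(2), mkcase(2.1),
                                   mkcase(2.05), mkcase(50)))
  expect_equal(outlier$median, 2.05)
  expect_equal(outlier$max, 50)
  expect_equal(outlier$min, 1.9)
})
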