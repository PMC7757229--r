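test_that("despiking preserves constants and removes isolated spikes", {
  expect_equal(despike(rep(3.2, 40)), rep(3.2, 40))
  x <- rep(0.005, 50)
  x[23] <- 5        # a single outlier of any magnitude
  expect_equal(despike(x), rep(0.005, 50))
  expect_error(despike(c(1, 2, 3)), "at least 7")
  expect_error(despike(c(1:8, NA)), "finite")
})

test_that("despiking equals the two-pass brute-force reference", {
  set.seed(101)
  for (n in c(7, 8, 20, 100)) {
    x <- runif(n)
    expect_equal(despike(x), brute_despike(x))
  }
})

test_that("despiking is near-idempotent", {
  set.seed(102)
  x <- cumsum(rnorm(80))
  once <- despike(x)
  twice <- despike(once)
  expect_lte(max(abs(twice - once)), max(abs(once - x)))
})

test_that("drift correction recovers an additive offset and aligns the deep band", {
  p <- flat_profile(bbp = 4e-4, cp = 0.02)
  q <- correct_cp_drift(p)
  expect_equal(q$drift_offset_applied, 0, tolerance = 1e-12)

  p2 <- p
  p2$cp660 <- p$cp660 + 0.01
  q2 <- correct_cp_drift(p2)
  expect_equal(q2$drift_offset_applied, -0.01, tolerance = 1e-9)
  band <- q2$depth >= 950 & q2$depth <= 1050
  expect_equal(median(q2$bbp700[band]) / median(q2$cp660[band]), 0.02,
               tolerance = 1e-9)
})

test_that("drift correction flags shallow or sign-breaking profiles", {
  p <- flat_profile()
  p$depth <- p$depth / 2          # never reaches the deep band
  q <- correct_cp_drift(p)
  expect_identical(q$qc_flags$cp_drift, "too_shallow")
  expect_identical(q$cp660, p$cp660)

  p2 <- flat_profile()
  p2$cp660[1:5] <- 1e-4           # offset would push these below zero
  p2$bbp700[p2$depth >= 950] <- 1e-5
  q2 <- correct_cp_drift(p2)
  expect_identical(q2$qc_flags$cp_drift, "nonpositive_cp")
})

test_that("alignment-constant sensitivity stays within the fleet surface spread", {
  sc <- small_scenario()
  prof <- generate_float_series(sc)[seq(1, 60, by = 6)]
  surf_cp <- function(target) vapply(prof, function(p) {
    q <- qc_profile(p, target_ratio = target)
    mean(q$cp660[q$depth <= 15])
  }, numeric(1))
  lo <- surf_cp(0.01); mid <- surf_cp(0.02); hi <- surf_cp(0.03)
  expect_lt(max(abs(hi - lo)), diff(range(mid)))
})

test_that("mixed layer depth follows the density-threshold rule", {
  n <- 200
  z <- seq(1, 200, length.out = n)
  base <- list(depth = z, salinity = rep(34, n))
  # sharp two-layer step at 50 m
  p <- c(base, list(temperature = ifelse(z < 50, 12, 5)))
  expect_lt(abs(estimate_mld(p) - 50), 1.5 * diff(z)[1])
  # perfectly uniform density: never crossed
  p2 <- c(base, list(temperature = rep(8, n)))
  expect_equal(estimate_mld(p2), max(z))
  # linear density ramp below 10 m: closed form 10 + 0.03/g
  g <- 0.01  # kg m-4, built by inverting sigma-t locally in salinity
  sig0 <- sw_sigma_t(10, 34)
  target_sigma <- sig0 + g * pmax(z - 10, 0)
  sal <- vapply(target_sigma, function(s)
    uniroot(function(sl) sw_sigma_t(10, sl) - s, c(25, 45))$root, numeric(1))
  p3 <- list(depth = z, temperature = rep(10, n), salinity = sal)
  expect_equal(estimate_mld(p3), 10 + 0.03 / g, tolerance = 0.02)
  expect_error(estimate_mld(list(depth = c(1, 5), salinity = c(34, 34),
                                 temperature = c(5, 5))))
})

test_that("quenching correction rebuilds the surface from backscattering", {
  # constant fchl/bbp over the mixed layer: correction is a no-op
  n <- 100; z <- seq(1, 100, length.out = n)
  p <- list(depth = z, fchl = rep(0.3, n), bbp700 = rep(1e-3, n))
  out <- correct_npq(p, mld = 60)
  expect_equal(out$fchl, p$fchl)
  expect_lte(out$quench_depth, 60)

  # generator round-trip: quenched surface recovered within 1%
  sc <- small_scenario(noise = noise_off, spike_rate = 0, npq_strength = 0.5)
  prof <- generate_float_series(sc)
  for (p in prof[c(10, 45)]) {
    q <- qc_profile(p)
    expect_lt(max(abs(q$fchl - p$truth$fchl)) / max(p$truth$fchl), 0.01)
    expect_lte(q$quench_depth, q$mld)
  }

  # never decreases fchl above the quench depth, never touches below
  set.seed(7)
  pz <- list(depth = z, fchl = 0.3 * (1 - 0.5 * pmax(0, 1 - z / 30)) +
               abs(rnorm(n, 0, 0.01)), bbp700 = rep(1e-3, n))
  o <- correct_npq(pz, mld = 60)
  up <- z < o$quench_depth
  expect_true(all(o$fchl[up] >= pz$fchl[up] - 1e-12))
  expect_identical(o$fchl[!up], pz$fchl[!up])

  # non-positive backscattering in the mixed layer: flagged, no correction
  pb <- list(depth = z, fchl = rep(0.3, n), bbp700 = c(-1e-4, rep(1e-3, n - 1)))
  ob <- correct_npq(pb, mld = 60)
  expect_identical(ob$flag, "nonpositive_bbp")
  expect_identical(ob$fchl, pb$fchl)
})

test_that("chlorophyll calibration applies slope and satellite factor", {
  x <- c(0.1, 0.5, 1)
  expect_identical(calibrate_chl(x, 1, 1), x)
  expect_equal(calibrate_chl(x, 2, 1.5), x * 3)
  # float chl uniformly half the satellite chl -> factor 2
  sf <- estimate_satellite_factor(float_chl = c(0.2, 0.3, 0.4),
                                  sat_chl = c(0.4, 0.6, 0.8),
                                  non_bloom = rep(TRUE, 3))
  expect_equal(sf$factor, 2)
  expect_false(sf$flagged)
  # clipped to [0.25, 4]; no usable matchup -> 1, flagged
  expect_equal(estimate_satellite_factor(1, 100, TRUE)$factor, 4)
  expect_true(estimate_satellite_factor(1, 2, FALSE)$flagged)
})

test_that("surface averages and ratios follow the 15 m layer means", {
  p <- flat_profile()
  p$depth <- seq(2, 1050, by = 4)
  n <- length(p$depth)
  p$temperature <- rep(5, n); p$salinity <- rep(34, n)
  p$bbp700 <- rep(0.002, n); p$fchl <- rep(0.5, n); p$cp660 <- rep(0.1, n)
  q <- qc_profile(p)
  rec <- surface_average(q)
  expect_equal(rec$ratio_bbp_chl, 0.002 / 0.5)  # 0.004 m2 mg-1

  p$bbp700 <- rep(2.6e-4, n); p$cp660 <- rep(0.02, n)
  p$bbp700[p$depth >= 950] <- 4e-4  # deep band already aligned at 0.02
  q2 <- qc_profile(p)
  rec2 <- surface_average(q2)
  expect_equal(rec2$ratio_bbp_cp, 0.013, tolerance = 1e-6)

  # layer mean equals the brute-force mean of the same samples
  sel <- q$depth <= 15
  expect_equal(rec$bbp_surf, sum(q$bbp700[sel]) / sum(sel))
})

test_that("full QC recovers all truth channels within 1% at zero noise", {
  sc <- small_scenario(noise = noise_off)  # spikes, quenching, drift all on
  prof <- generate_float_series(sc)
  for (p in prof[seq(2, 60, by = 9)]) {
    q <- qc_profile(p)
    tr <- p$truth
    relerr <- function(est, tru) max(abs(est - tru)) / diff(range(tru))
    expect_lt(relerr(q$bbp700, tr$bbp), 0.01)
    expect_lt(relerr(q$fchl, tr$fchl), 0.01)
    expect_lt(relerr(q$cp660, tr$cp), 0.01)
    band <- q$depth >= 950 & q$depth <= 1050
    expect_equal(median(q$bbp700[band]) / median(q$cp660[band]), 0.02,
                 tolerance = 1e-6)
  }
})
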