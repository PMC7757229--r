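#' Despike a bio-optical profile
#'
#' Removes transient positive spikes (particle aggregates or mesopelagic
#' organisms passing the detector) by a 5-point moving median filter
#' followed by a 7-point moving average filter. Window edges are handled by
#' truncation (shrinking windows near the profile boundaries), which
#' preserves profile length and surface values feeding the 0-15 m average.
#'
#' @param values Numeric vector along depth; all values must be finite and
#'   at least 7 are required.
#' @return Smoothed vector, same length.
#' @examples
#' x <- rep(1, 20); x[10] <- 50
#' all(despike(x) == 1)
#' @export
despike <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("despike() requires finite numeric values", call. = FALSE)
  n <- length(values)
  if (n < 7)
    stop("despike() requires at least 7 samples; profile unusable for optics",
         call. = FALSE)
  med <- as.numeric(runmed(values, 5, endrule = "keep"))
  for (i in c(1L, 2L, n - 1L, n))  # truncated windows at the edges
    med[i] <- median(values[max(1L, i - 2L):min(n, i + 2L)])
  csum <- cumsum(c(0, med))
  lo <- pmax(seq_len(n) - 3L, 1L)
  hi <- pmin(seq_len(n) + 3L, n)
  (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)
}

#' Correct transmissometer fouling drift
#'
#' Sinking material accumulating on the transmissometer window inflates
#' c_p over a float's life. Each profile is re-aligned by a single additive
#' offset chosen so that the ratio of the deep-band medians of b_bp and
#' c_p equals the deep reference value (0.02 at the 1000 m reference; the
#' 950-1050 m band median is used for robustness to residual spikes).
#'
#' @param profile A `float_profile` (despiked `bbp700` and `cp660`
#'   recommended).
#' @param target_ratio Deep b_bp/c_p alignment constant (default 0.02).
#' @param band Depth band (m) over which deep medians are taken.
#' @return The profile with corrected `cp660`, plus `drift_offset_applied`
#'   and `qc_flags$cp_drift` (one of "ok", "too_shallow",
#'   "nonpositive_cp").
#' @export
correct_cp_drift <- function(profile, target_ratio = 0.02,
                             band = c(950, 1050)) {
  p <- profile
  p$qc_flags <- c(p$qc_flags, list(cp_drift = "ok"))
  p$drift_offset_applied <- NA_real_
  if (is.null(p$cp660)) {
    p$qc_flags$cp_drift <- "no_cp"
    return(p)
  }
  in_band <- p$depth >= band[1] & p$depth <= band[2]
  if (!any(in_band) || max(p$depth) < band[1]) {
    p$qc_flags$cp_drift <- "too_shallow"
    return(p)
  }
  m_bbp <- median(p$bbp700[in_band])
  m_cp <- median(p$cp660[in_band])
  if (!is.finite(m_bbp) || !is.finite(m_cp)) {
    p$qc_flags$cp_drift <- "too_shallow"
    return(p)
  }
  offset <- m_bbp / target_ratio - m_cp
  cp_new <- p$cp660 + offset
  if (any(cp_new <= 0)) {
    p$qc_flags$cp_drift <- "nonpositive_cp"
    return(p)
  }
  p$cp660 <- cp_new
  p$drift_offset_applied <- offset
  p
}

#' Estimate the mixed layer depth (density threshold)
#'
#' Shallowest depth at which potential density (sigma-t at 0 dbar,
#' [sw_sigma_t()]) exceeds its value at the 10 m reference depth by
#' `threshold` kg m^-3, linearly interpolated between samples. Returns the
#' deepest sampled depth if the threshold is never exceeded.
#'
#' @param profile A `float_profile` with `temperature` and `salinity`.
#' @param threshold Density offset, kg m^-3 (default 0.03).
#' @param ref_depth Reference depth, m (default 10).
#' @return Mixed layer depth in meters.
#' @export
estimate_mld <- function(profile, threshold = 0.03, ref_depth = 10) {
  z <- profile$depth
  if (length(z) < 2 || diff(range(z)) < 10)
    stop("estimate_mld() needs temperature/salinity over >= 2 depths spanning 10 m")
  if (max(z) < ref_depth)
    stop("estimate_mld(): no sample at or below the ", ref_depth,
         " m reference depth")
  sigma <- sw_sigma_t(profile$temperature, profile$salinity)
  sigma_ref <- approx(z, sigma, xout = ref_depth, rule = 2)$y
  target <- sigma_ref + threshold
  below <- which(z >= ref_depth & sigma > target)
  if (!length(below)) return(max(z))
  j <- below[1]
  if (j == 1) return(z[1])
  # linear interpolation between the bracketing samples
  z0 <- z[j - 1]; z1 <- z[j]; s0 <- sigma[j - 1]; s1 <- sigma[j]
  if (s1 == s0) return(z1)
  max(ref_depth, z0 + (target - s0) * (z1 - z0) / (s1 - s0))
}

#' Correct fluorescence for non-photochemical quenching
#'
#' Sunlight depresses chlorophyll fluorescence per unit chlorophyll near
#' the surface. Following the backscattering-extrapolation family of
#' corrections: the quench depth is the depth of maximum fchl/b_bp within
#' the mixed layer; above it, fluorescence is rebuilt as
#' `bbp700(z) * (fchl/bbp700)(quench_depth)`; at and below it, fluorescence
#' is unchanged.
#'
#' @param profile A `float_profile` with despiked `fchl` and `bbp700`.
#' @param mld Mixed layer depth (m), e.g. from [estimate_mld()].
#' @return List with `fchl` (corrected array), `quench_depth` (m) and
#'   `flag` ("ok" or "nonpositive_bbp" when no correction was applied).
#' @export
correct_npq <- function(profile, mld) {
  z <- profile$depth
  in_ml <- z <= mld
  if (any(profile$bbp700[in_ml] <= 0))
    return(list(fchl = profile$fchl, quench_depth = NA_real_,
                flag = "nonpositive_bbp"))
  ratio <- profile$fchl[in_ml] / profile$bbp700[in_ml]
  qi <- which.max(ratio)              # ties resolve to the shallowest depth
  quench_depth <- z[in_ml][qi]
  fchl <- profile$fchl
  up <- z < quench_depth
  fchl[up] <- profile$bbp700[up] * ratio[qi]
  list(fchl = fchl, quench_depth = quench_depth, flag = "ok")
}

#' Convert corrected fluorescence to chlorophyll-a concentration
#'
#' `chl = fchl * factory_slope * satellite_factor`: the sensor's factory
#' calibration slope followed by a regional adjustment against satellite
#' [Chl-a] (see [estimate_satellite_factor()]) that compensates spatial
#' variation in the in-situ slope.
#'
#' @param fchl_corrected Quenching-corrected fluorescence array.
#' @param factory_slope Factory calibration coefficient (> 0).
#' @param satellite_factor Regional satellite adjustment (> 0, default 1).
#' @return Chlorophyll-a array, mg m^-3.
#' @export
calibrate_chl <- function(fchl_corrected, factory_slope = 1,
                          satellite_factor = 1) {
  stopifnot(factory_slope > 0, satellite_factor > 0)
  fchl_corrected * factory_slope * satellite_factor
}

#' Estimate the satellite chlorophyll adjustment factor
#'
#' Median, over non-bloom matchups, of satellite [Chl-a] over the float's
#' surface [Chl-a] before adjustment, clipped to [0.25, 4]. Bloom matchups
#' are excluded because satellite [Chl-a] retrievals are biased inside
#' coccolithophore blooms.
#'
#' @param float_chl Float surface [Chl-a] before adjustment, one per cycle.
#' @param sat_chl Matched satellite [Chl-a], one per cycle.
#' @param non_bloom Logical: cycle is outside any detected bloom period.
#' @return List with `factor` and `flagged` (TRUE when no usable non-bloom
#'   matchup existed and the factor defaulted to 1).
#' @export
estimate_satellite_factor <- function(float_chl, sat_chl, non_bloom) {
  ok <- non_bloom & is.finite(float_chl) & is.finite(sat_chl) & float_chl > 0
  if (!any(ok)) return(list(factor = 1, flagged = TRUE))
  f <- median(sat_chl[ok] / float_chl[ok])
  list(factor = min(max(f, 0.25), 4), flagged = FALSE)
}

#' Full quality control of one float profile
#'
#' Applies the QC chain in order: despiking of the bio-optical channels,
#' transmissometer drift correction, mixed-layer depth, quenching
#' correction, chlorophyll calibration.
#'
#' @param profile A `float_profile`.
#' @param factory_slope,satellite_factor Passed to [calibrate_chl()].
#' @param target_ratio Deep alignment constant for [correct_cp_drift()].
#' @param mld_threshold Density threshold for [estimate_mld()].
#' @return A `qc_profile`: the input plus `chl`, corrected `fchl`,
#'   `bbp700`, `cp660`, `mld`, `quench_depth`, `drift_offset_applied`,
#'   and `qc_flags`.
#' @export
qc_profile <- function(profile, factory_slope = 1, satellite_factor = 1,
                       target_ratio = 0.02, mld_threshold = 0.03) {
  p <- profile
  p$qc_flags <- list()
  optics_ok <- length(p$depth) >= 7
  if (!optics_ok) {
    p$qc_flags$optics <- "too_few_samples"
  } else {
    p$bbp700 <- despike(p$bbp700)
    p$fchl <- despike(p$fchl)
    if (!is.null(p$cp660)) p$cp660 <- despike(p$cp660)
    p$qc_flags$optics <- "ok"
  }
  p <- correct_cp_drift(p, target_ratio = target_ratio)
  p$mld <- estimate_mld(p, threshold = mld_threshold)
  npq <- correct_npq(p, p$mld)
  p$fchl <- npq$fchl
  p$quench_depth <- npq$quench_depth
  p$qc_flags$npq <- npq$flag
  p$chl <- calibrate_chl(p$fchl, factory_slope, satellite_factor)
  class(p) <- c("qc_profile", "float_profile")
  p
}

#' Average a quality-controlled profile over the satellite surface layer
#'
#' Ocean-colour satellites sense roughly the first 15 m; surface values are
#' arithmetic means over samples with depth <= `layer`, and the optical
#' ratios are formed from the layer means. Standard deviations over the
#' layer are retained for error bars.
#'
#' @param profile A `qc_profile`.
#' @param layer Surface layer thickness, m (default 15).
#' @return One-row tibble (`surface_record`): identifiers, layer means and
#'   sds, `ratio_bbp_chl` (m^2 mg^-1), `ratio_bbp_cp`, `mld`, and `flag`.
#' @export
surface_average <- function(profile, layer = 15) {
  p <- profile
  sel <- p$depth <= layer
  mean_sd <- function(x) {
    if (is.null(x)) return(c(NA_real_, NA_real_, 0))
    v <- x[sel][is.finite(x[sel])]
    c(mean(v), stats::sd(v), length(v))
  }
  b <- mean_sd(p$bbp700); ch <- mean_sd(p$chl); cp <- mean_sd(p$cp660)
  flag <- "ok"
  if (b[3] < 2 || ch[3] < 2) flag <- "too_few_surface_samples"
  if (identical(p$qc_flags$cp_drift, "nonpositive_cp")) cp[1] <- NA_real_
  tibble::tibble(
    float_id = p$float_id, cycle = p$cycle, date = p$date,
    lat = p$lat, lon = p$lon,
    bbp_surf = b[1], bbp_surf_sd = b[2],
    cp_surf = cp[1], cp_surf_sd = cp[2],
    chl_surf = ch[1], chl_surf_sd = ch[2],
    ratio_bbp_chl = b[1] / ch[1],
    ratio_bbp_cp = if (is.na(cp[1])) NA_real_ else b[1] / cp[1],
    mld = if (is.null(p$mld)) NA_real_ else p$mld,
    drift_offset_applied = if (is.null(p$drift_offset_applied))
      NA_real_ else p$drift_offset_applied,
    flag = flag)
}

#' Surface records for a whole float series
#'
#' Runs [qc_profile()] and [surface_average()] over a list of profiles.
#'
#' @param profiles List of `float_profile` objects.
#' @inheritParams qc_profile
#' @param layer Surface layer thickness, m.
#' @return Tibble with one `surface_record` row per cycle.
#' @export
surface_records <- function(profiles, factory_slope = 1,
                            satellite_factor = 1, target_ratio = 0.02,
                            layer = 15) {
  qc <- lapply(profiles, qc_profile, factory_slope = factory_slope,
               satellite_factor = satellite_factor,
               target_ratio = target_ratio)
  dplyr::bind_rows(lapply(qc, surface_average, layer = layer))
}
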