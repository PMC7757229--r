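#' Configure a synthetic bloom scenario
#'
#' Defines the study conditions emulated by the synthetic-ocean generator:
#' a temperate/subpolar spring-summer season with a non-calcifying
#' (diatom-like) chlorophyll bloom followed by a coccolithophore bloom of
#' moderate intensity, sampled by a daily-cycling profiling float under a
#' partly cloudy satellite. All downstream stages (quality control, matchup
#' compositing, phenology, classification) are testable against the truth
#' channels this generator returns alongside the corrupted observations.
#'
#' Defaults emulate a Southern Ocean season: a ~50-day calcite pulse
#' peaking at 1.0 mmol m^-3 [PIC] (observed bloom-average [PIC] in such
#' moderate blooms is close to 1), a preceding chlorophyll bloom peaking at
#' 2 mg m^-3, 30% cloud cover, and a surface b_bp/[Chl-a] ratio that is at
#' least 3x its non-bloom baseline everywhere inside the bloom window
#' (rising to 0.012 m^2 mg^-1 at peak, the in-bloom mean reported for
#' Southern Ocean floats).
#'
#' @param duration_days Length of the simulated season (days).
#' @param start_date Calendar date of day 0.
#' @param grid_extent Named numeric vector `c(lat_min, lat_max, lon_min,
#'   lon_max)` in degrees.
#' @param pixel_size Satellite pixel size in degrees (~4 km at these
#'   latitudes with the 0.05 default).
#' @param bloom_windows List of coccolithophore bloom windows, each a named
#'   numeric vector `c(start, end, peak_pic)` (days, days, mmol m^-3).
#' @param chl_bloom_windows List of non-calcifying chlorophyll bloom
#'   windows, each `c(start, end, peak_chl)` (days, days, mg m^-3).
#' @param cloud_fraction Fraction of pixel-days masked as cloudy, in [0,1].
#' @param float_track Tibble/data.frame with columns `day`, `lat`, `lon`
#'   (one profile per row). Default: a slow diagonal drift across the grid,
#'   one cycle per day.
#' @param depth_grid Strictly increasing depths (m), surface to >= 1000 m.
#' @param noise Named list of noise levels: multiplicative log-normal sigma
#'   for `bbp`, `fchl`, `cp` and satellite fields (`sat`), additive sd for
#'   `temperature` (deg C) and `salinity`.
#' @param npq_strength Fractional surface depression of fluorescence by
#'   non-photochemical quenching, in [0,1].
#' @param cp_drift_rate Additive transmissometer fouling drift on c_p,
#'   m^-1 per cycle.
#' @param spike_rate Expected number of positive optical spikes per profile
#'   and channel (Poisson).
#' @param fchl_gain Sensor gain linking true [Chl-a] to raw fluorescence in
#'   chlorophyll-equivalent units (emulates regional miscalibration of the
#'   factory slope; the satellite adjustment step must undo it).
#' @param seed Master integer seed; all product streams derive from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(duration_days = 180L,
                            start_date = as.Date("2018-10-15"),
                            grid_extent = c(lat_min = -50, lat_max = -48,
                                            lon_min = 50, lon_max = 52),
                            pixel_size = 0.05,
                            bloom_windows = list(c(start = 100, end = 150,
                                                   peak_pic = 1.0)),
                            chl_bloom_windows = list(c(start = 30, end = 80,
                                                       peak_chl = 2.0)),
                            cloud_fraction = 0.3,
                            float_track = NULL,
                            depth_grid = c(seq(1, 240, by = 1),
                                           seq(242, 400, by = 2),
                                           seq(405, 600, by = 5),
                                           seq(610, 1050, by = 10)),
                            noise = list(bbp = 0.05, fchl = 0.05, cp = 0.03,
                                         temperature = 0.01,
                                         salinity = 0.002, sat = 0.05),
                            npq_strength = 0.5,
                            cp_drift_rate = 1e-5,
                            spike_rate = 2,
                            fchl_gain = 0.7,
                            seed = 42L) {
  if (is.null(float_track)) {
    day <- seq_len(duration_days)
    frac <- (day - 1) / max(duration_days - 1, 1)
    float_track <- tibble::tibble(
      day = day,
      lat = grid_extent[["lat_min"]] + (0.25 + 0.5 * frac) *
        (grid_extent[["lat_max"]] - grid_extent[["lat_min"]]),
      lon = grid_extent[["lon_min"]] + (0.2 + 0.6 * frac) *
        (grid_extent[["lon_max"]] - grid_extent[["lon_min"]]))
  }
  cfg <- list(duration_days = as.integer(duration_days),
              start_date = as.Date(start_date),
              grid_extent = grid_extent, pixel_size = pixel_size,
              bloom_windows = bloom_windows,
              chl_bloom_windows = chl_bloom_windows,
              cloud_fraction = cloud_fraction,
              float_track = tibble::as_tibble(float_track),
              depth_grid = depth_grid, noise = noise,
              npq_strength = npq_strength, cp_drift_rate = cp_drift_rate,
              spike_rate = spike_rate, fchl_gain = fchl_gain,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  validate_scenario(cfg)
  cfg
}

validate_scenario <- function(cfg) {
  stopifnot(cfg$duration_days >= 1,
            all(diff(cfg$depth_grid) > 0),
            cfg$cloud_fraction >= 0, cfg$cloud_fraction <= 1,
            cfg$npq_strength >= 0, cfg$npq_strength <= 1,
            cfg$pixel_size > 0, cfg$fchl_gain > 0)
  for (w in c(cfg$bloom_windows, cfg$chl_bloom_windows)) {
    if (w[["start"]] < 0 || w[["end"]] > cfg$duration_days ||
        w[["start"]] >= w[["end"]])
      stop("bloom window [", w[["start"]], ", ", w[["end"]],
           "] outside [0, ", cfg$duration_days, "] or empty")
  }
  invisible(cfg)
}

# One pseudo-random stream per product, derived from the master seed, so
# e.g. changing cloud_fraction does not alter profile noise.
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 59999L) * 7919 + 104729 * stream) %% 2147483647L
}

# -- deterministic underlying fields ---------------------------------------

# raised-cosine pulse: 0 outside [s, e], unimodal, exactly 1 at the centre
pulse01 <- function(day, s, e) {
  w <- numeric(length(day))
  inside <- day >= s & day <= e
  w[inside] <- (1 - cos(2 * pi * (day[inside] - s) / (e - s))) / 2
  w
}

# internal constants of the synthetic ocean
.syn <- list(
  pic_base = 0.15,       # mmol m-3 non-bloom calcite baseline (< 0.3)
  poc_base = 3.0,        # mmol m-3
  poc_per_chl = 1.5,     # mmol m-3 per mg m-3: POC co-varies with Chl
  chl_base = 0.3,        # mg m-3
  chl_in_cocco = 0.2,    # extra Chl at the coccolithophore bloom peak
  ratio_base = 1 / 300,  # m2 mg-1 non-bloom surface b_bp/[Chl-a]
  ratio_step = 3.3,      # jump factor at the bloom-window edge (>= 3x)
  ratio_peak = 0.012,    # m2 mg-1 at bloom peak (in-bloom float mean)
  rbc_base = 0.008,      # non-bloom surface b_bp/c_p
  rbc_in = 0.011,        # at bloom edges
  rbc_peak = 0.013,      # at bloom peak (proxy backscattering ratio)
  bbp_deep = 4e-4,       # m-1 below the particle layer
  chl_deep = 0.02,       # mg m-3
  rbc_deep = 0.02,       # deep b_bp/c_p used for drift alignment
  taper_len = 150,       # m, vertical decay length below the mixed layer
  t_deep = 2, t_surf0 = 4, t_surf_amp = 5,  # deg C
  salinity = 34,
  mld0 = 80, mld1 = 40,  # m, seasonal mixed-layer shoaling
  quench_frac = 0.75,    # quench depth as a fraction of the mixed layer
  spatial_amp = 0.02)    # relative spatial gradient of satellite fields

# maximum over bloom windows of a quantity that steps to `edge` at the
# window boundary and rises to `peak` at the window centre
stepped_pulse <- function(day, windows, base, edge, peak) {
  out <- rep(base, length(day))
  for (w in windows) {
    inside <- day >= w[["start"]] & day <= w[["end"]]
    v <- edge + (peak - edge) * pulse01(day, w[["start"]], w[["end"]])
    out[inside] <- pmax(out[inside], v[inside])
  }
  out
}

# scalar seasonal curves shared by the satellite grid and the float truth
scenario_curves <- function(cfg, day) {
  k <- .syn
  chl <- rep(k$chl_base, length(day))
  for (w in cfg$chl_bloom_windows)
    chl <- chl + (w[["peak_chl"]] - k$chl_base) *
      pulse01(day, w[["start"]], w[["end"]])
  for (w in cfg$bloom_windows)
    chl <- chl + k$chl_in_cocco * pulse01(day, w[["start"]], w[["end"]])
  pic <- rep(k$pic_base, length(day))
  for (w in cfg$bloom_windows)
    pic <- pmax(pic, k$pic_base + (w[["peak_pic"]] - k$pic_base) *
                  pulse01(day, w[["start"]], w[["end"]]))
  ratio <- stepped_pulse(day, cfg$bloom_windows, k$ratio_base,
                         k$ratio_step * k$ratio_base, k$ratio_peak)
  rbc <- stepped_pulse(day, cfg$bloom_windows, k$rbc_base,
                       k$rbc_in, k$rbc_peak)
  mld <- k$mld0 + (k$mld1 - k$mld0) * (day - 1) / max(cfg$duration_days - 1, 1)
  list(chl = chl, pic = pic, poc = k$poc_base + k$poc_per_chl * chl,
       ratio = ratio, rbc = rbc, bbp = ratio * chl, mld = mld,
       t_surf = k$t_surf0 + k$t_surf_amp * (day - 1) /
         max(cfg$duration_days - 1, 1))
}

# smooth deterministic spatial modulation, same for grid and float
spatial_factor <- function(cfg, lat, lon) {
  g <- cfg$grid_extent
  u <- (lat - g[["lat_min"]]) / (g[["lat_max"]] - g[["lat_min"]])
  v <- (lon - g[["lon_min"]]) / (g[["lon_max"]] - g[["lon_min"]])
  1 + .syn$spatial_amp * (sin(pi * u) * cos(pi * v) - 0.5)
}

# C1-smooth vertical shape: 1 in the mixed layer, cosine taper to 0 over
# taper_len below it
vertical_shape <- function(depth, mld, taper_len = .syn$taper_len) {
  phi <- numeric(length(depth))
  phi[depth <= mld] <- 1
  ramp <- depth > mld & depth < mld + taper_len
  phi[ramp] <- (1 + cos(pi * (depth[ramp] - mld) / taper_len)) / 2
  phi
}

# noise-free truth arrays for one profile
profile_truth <- function(cfg, day, lat, lon) {
  k <- .syn
  cv <- scenario_curves(cfg, day)
  sf <- spatial_factor(cfg, lat, lon)
  z <- cfg$depth_grid
  phi <- vertical_shape(z, cv$mld)
  chl <- k$chl_deep + (cv$chl * sf - k$chl_deep) * phi
  bbp <- k$bbp_deep + (cv$bbp * sf - k$bbp_deep) * phi
  rbc_z <- k$rbc_deep + (cv$rbc - k$rbc_deep) * phi
  cp <- bbp / rbc_z
  # temperature: uniform mixed layer, linear ramp to the deep value over
  # 60 m (a finite density gradient so the threshold MLD sits just below
  # the true mixed layer), then constant
  tt <- rep(k$t_deep, length(z))
  tt[z <= cv$mld] <- cv$t_surf
  ramp <- z > cv$mld & z < cv$mld + 60
  tt[ramp] <- cv$t_surf + (k$t_deep - cv$t_surf) * (z[ramp] - cv$mld) / 60
  qd <- k$quench_frac * cv$mld
  in_bloom <- any(vapply(cfg$bloom_windows, function(w)
    day >= w[["start"]] && day <= w[["end"]], logical(1)))
  list(depth = z, temperature = tt,
       salinity = rep(k$salinity, length(z)),
       chl = chl, fchl = chl * cfg$fchl_gain, bbp = bbp, cp = cp,
       mld = cv$mld, quench_depth = qd, bloom = in_bloom,
       ratio_surf = cv$ratio,  # bbp and chl share sf, so bbp/chl is spatially invariant
       rbc_surf = cv$rbc)
}

# quadratic quenching depression: maximal at the surface, C1-vanishing at
# the quench depth, 1 below it
npq_factor <- function(depth, quench_depth, strength) {
  f <- rep(1, length(depth))
  up <- depth < quench_depth
  f[up] <- 1 - strength * (1 - depth[up] / quench_depth)^2
  f
}

#' Generate a synthetic float profile series
#'
#' One profile per float-track day. Observed channels are corrupted
#' versions of the truth: surface fluorescence is depressed by
#' non-photochemical quenching above the simulated quench depth, beam
#' attenuation carries a cumulative additive fouling drift proportional to
#' the cycle number, all optical channels receive Poisson-placed positive
#' multiplicative spikes (x2-x10 at isolated depths) and log-normal noise.
#' The noise-free truth channels travel with each profile in `$truth` so
#' parameter-recovery tests can close the loop.
#'
#' @param config A [scenario_config()].
#' @return List of `float_profile` objects (fields: `float_id`, `cycle`,
#'   `date`, `lat`, `lon`, `depth`, `temperature`, `salinity`, `fchl`,
#'   `bbp700`, `cp660`, `truth`).
#' @export
generate_float_series <- function(config) {
  validate_scenario(config)
  trk <- config$float_track
  g <- config$grid_extent
  bad <- which(trk$lat < g[["lat_min"]] | trk$lat > g[["lat_max"]] |
                 trk$lon < g[["lon_min"]] | trk$lon > g[["lon_max"]])
  if (length(bad))
    stop("float track leaves the grid extent at cycle ", bad[1])
  nz <- length(config$depth_grid)
  np <- nrow(trk)

  truths <- lapply(seq_len(np), function(i)
    profile_truth(config, trk$day[i], trk$lat[i], trk$lon[i]))

  # stream 1: continuous measurement noise
  set.seed(sub_seed(config$seed, 1L))
  noise <- lapply(seq_len(np), function(i) list(
    bbp = exp(rnorm(nz, 0, config$noise$bbp)),
    fchl = exp(rnorm(nz, 0, config$noise$fchl)),
    cp = exp(rnorm(nz, 0, config$noise$cp)),
    temperature = rnorm(nz, 0, config$noise$temperature),
    salinity = rnorm(nz, 0, config$noise$salinity)))

  # stream 3: optical spikes
  set.seed(sub_seed(config$seed, 3L))
  spikes <- lapply(seq_len(np), function(i) {
    one <- function() {
      s <- rep(1, nz)
      k <- rpois(1, config$spike_rate)
      # spikes sit at isolated depths (>= 5 samples apart), so a 5-point
      # median window never holds more than one
      avail <- seq_len(nz)
      at <- integer(0)
      while (k > 0 && length(avail) > 0) {
        pick <- avail[sample.int(length(avail), 1)]
        at <- c(at, pick)
        avail <- avail[abs(avail - pick) >= 5]
        k <- k - 1
      }
      if (length(at)) s[at] <- runif(length(at), 2, 10)
      s
    }
    list(bbp = one(), fchl = one(), cp = one())
  })

  lapply(seq_len(np), function(i) {
    tr <- truths[[i]]
    nq <- npq_factor(tr$depth, tr$quench_depth, config$npq_strength)
    p <- list(
      float_id = "SYN0001", cycle = i,
      date = config$start_date + trk$day[i] - 1,
      lat = trk$lat[i], lon = trk$lon[i],
      depth = tr$depth,
      temperature = tr$temperature + noise[[i]]$temperature,
      salinity = tr$salinity + noise[[i]]$salinity,
      fchl = tr$fchl * nq * noise[[i]]$fchl * spikes[[i]]$fchl,
      bbp700 = tr$bbp * noise[[i]]$bbp * spikes[[i]]$bbp,
      cp660 = (tr$cp + config$cp_drift_rate * i) *
        noise[[i]]$cp * spikes[[i]]$cp,
      truth = tr)
    class(p) <- "float_profile"
    p
  })
}

#' Generate a synthetic daily satellite grid
#'
#' Gridded daily fields of [PIC], [POC], [Chl-a] and b_bp with a
#' cloud-gap mask. [PIC] follows a smooth seasonal pulse peaking at each
#' window's `peak_pic` and stays at a low baseline (< 0.3 mmol m^-3)
#' outside bloom windows; [POC] co-varies with [Chl-a] so that the calcite
#' fraction %PIC exceeds 10% only inside bloom windows.
#'
#' @param config A [scenario_config()].
#' @return A `satellite_grid` list: `dates`, `lat`, `lon`, and
#'   `time x lat x lon` arrays `pic`, `poc`, `chl`, `bbp_sat`,
#'   `valid_mask`.
#' @export
generate_satellite_grid <- function(config) {
  validate_scenario(config)
  g <- config$grid_extent
  ps <- config$pixel_size
  lat <- seq(g[["lat_min"]] + ps / 2, g[["lat_max"]] - ps / 2 + 1e-9, by = ps)
  lon <- seq(g[["lon_min"]] + ps / 2, g[["lon_max"]] - ps / 2 + 1e-9, by = ps)
  day <- seq_len(config$duration_days)
  cv <- scenario_curves(config, day)
  sf <- outer(lat, lon, function(a, b) spatial_factor(config, a, b))
  dims <- c(length(day), length(lat), length(lon))
  field <- function(curve) {
    arr <- array(0, dims)
    for (t in seq_along(day)) arr[t, , ] <- curve[t] * sf
    arr
  }
  pic <- field(cv$pic); poc <- field(cv$poc)
  chl <- field(cv$chl); bbp <- field(cv$bbp)

  # stream 4: satellite retrieval noise
  set.seed(sub_seed(config$seed, 4L))
  n <- prod(dims)
  lnoise <- function(sig) array(exp(rnorm(n, 0, sig)), dims)
  sig <- config$noise$sat
  pic <- pic * lnoise(sig); poc <- poc * lnoise(sig)
  chl <- chl * lnoise(sig); bbp <- bbp * lnoise(sig)

  # stream 2: cloud mask (consumes a fixed amount of randomness, so
  # changing cloud_fraction leaves the other streams untouched)
  set.seed(sub_seed(config$seed, 2L))
  valid <- array(runif(n) >= config$cloud_fraction, dims)

  out <- list(dates = config$start_date + day - 1, lat = lat, lon = lon,
              pic = pic, poc = poc, chl = chl, bbp_sat = bbp,
              valid_mask = valid)
  class(out) <- "satellite_grid"
  out
}

#' @export
print.float_profile <- function(x, ...) {
  cat(sprintf("<float_profile> %s cycle %d  %s  (%.3f, %.3f)  %d depths%s\n",
              x$float_id, x$cycle, format(x$date), x$lat, x$lon,
              length(x$depth), if (is.null(x$cp660)) "" else "  +cp660"))
  invisible(x)
}

#' @export
print.satellite_grid <- function(x, ...) {
  cat(sprintf("<satellite_grid> %d days x %d lat x %d lon, %.1f%% valid\n",
              length(x$dates), length(x$lat), length(x$lon),
              100 * mean(x$valid_mask)))
  invisible(x)
}
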