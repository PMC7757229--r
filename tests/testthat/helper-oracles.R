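# Independent brute-force oracles used to pin down the filtering,
# compositing and ROC operations, plus a compact scenario for fast tests.

# two-pass reference despike: median by explicitly sorting each window,
# then mean over each (truncated) window
brute_despike <- function(x) {
  n <- length(x)
  win_median <- function(w) {
    s <- sort(w); m <- length(s)
    if (m %% 2 == 1) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
  }
  med <- vapply(seq_len(n), function(i)
    win_median(x[max(1, i - 2):min(n, i + 2)]), numeric(1))
  vapply(seq_len(n), function(i) {
    w <- med[max(1, i - 3):min(n, i + 3)]
    sum(w) / length(w)
  }, numeric(1))
}

# enumeration oracle for composite(): loops over every pixel-day
brute_composite <- function(grid, lat, lon, date, box = 5, window = 9) {
  di <- abs(grid$lat - lat); dj <- abs(grid$lon - lon)
  ci <- which(di == min(di))[1]; cj <- which(dj == min(dj))[1]
  hb <- (box - 1) / 2; hw <- (window - 1) / 2
  vals <- list(pic = c(), poc = c(), chl = c(), bbp = c())
  n_used <- 0
  for (t in seq_along(grid$dates)) {
    if (abs(as.numeric(grid$dates[t] - date)) > hw) next
    for (i in seq_along(grid$lat)) {
      if (abs(i - ci) > hb) next
      for (j in seq_along(grid$lon)) {
        if (abs(j - cj) > hb) next
        if (!grid$valid_mask[t, i, j]) next
        n_used <- n_used + 1
        vals$pic <- c(vals$pic, grid$pic[t, i, j])
        vals$poc <- c(vals$poc, grid$poc[t, i, j])
        vals$chl <- c(vals$chl, grid$chl[t, i, j])
        vals$bbp <- c(vals$bbp, grid$bbp_sat[t, i, j])
      }
    }
  }
  list(pic = if (n_used) mean(vals$pic) else NA_real_,
       poc = if (n_used) mean(vals$poc) else NA_real_,
       chl_sat = if (n_used) mean(vals$chl) else NA_real_,
       bbp_sat = if (n_used) mean(vals$bbp) else NA_real_,
       n_pixels_used = n_used)
}

# counting oracle for roc_threshold(): explicit tally at each candidate
brute_roc <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- spec <- numeric(length(cand))
  for (k in seq_along(cand)) {
    tp <- fn <- tn <- fp <- 0
    for (i in seq_along(scores)) {
      call <- scores[i] > cand[k]
      if (labels[i] && call) tp <- tp + 1
      if (labels[i] && !call) fn <- fn + 1
      if (!labels[i] && !call) tn <- tn + 1
      if (!labels[i] && call) fp <- fp + 1
    }
    sens[k] <- tp / (tp + fn); spec[k] <- tn / (tn + fp)
  }
  j <- sens + spec - 1
  best <- max(which(j == max(j)))
  list(thresholds = cand, sensitivity = sens, specificity = spec,
       best_threshold = cand[best], best_sensitivity = sens[best],
       best_specificity = spec[best])
}

# a compact scenario: same structure as the default, smaller grid and
# shorter season, for unit tests that do not need 180 cycles
small_scenario <- function(seed = 11, ...) {
  args <- list(
    duration_days = 60L,
    grid_extent = c(lat_min = -49.5, lat_max = -49,
                    lon_min = 50, lon_max = 50.5),
    bloom_windows = list(c(start = 30, end = 50, peak_pic = 1.0)),
    chl_bloom_windows = list(c(start = 5, end = 25, peak_chl = 2.0)),
    seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}

noise_off <- list(bbp = 0, fchl = 0, cp = 0, temperature = 0,
                  salinity = 0, sat = 0)

# synthetic single profile reaching 1050 m, built directly (not via the
# generator) for drift-correction unit tests
flat_profile <- function(bbp = 4e-4, cp = 0.02, n = 120) {
  z <- seq(10, 1050, length.out = n)
  p <- list(float_id = "T", cycle = 1L, date = as.Date("2020-01-01"),
            lat = -49, lon = 50, depth = z,
            temperature = rep(5, n), salinity = rep(34, n),
            fchl = rep(0.2, n), bbp700 = rep(bbp, n), cp660 = rep(cp, n))
  class(p) <- "float_profile"
  p
}
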