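#' Calcite fraction of particulate carbon (%PIC)
#'
#' `%PIC = 100 * PIC / (PIC + POC)` -- the share of particulate inorganic
#' carbon in total particulate carbon, the quantity used (together with
#' [PIC] itself) to confirm that a calcite pulse is a coccolithophore
#' bloom.
#'
#' @param pic,poc Particulate inorganic / organic carbon, mmol m^-3
#'   (vectors, non-negative).
#' @return Percent in [0, 100]; `NA` where `pic + poc == 0`.
#' @examples
#' pic_fraction(0.7, 6.3)  # 10
#' @export
pic_fraction <- function(pic, poc) {
  if (any(pic < 0, na.rm = TRUE) || any(poc < 0, na.rm = TRUE))
    stop("pic_fraction(): pic and poc must be non-negative")
  total <- pic + poc
  out <- 100 * pic / total
  out[!is.na(total) & total == 0] <- NA_real_
  out
}

# index of the grid pixel nearest (lat, lon) by pixel-centre great-circle
# distance; ties break toward the south-west pixel
nearest_pixel <- function(grid, lat, lon) {
  centres <- expand.grid(lat = grid$lat, lon = grid$lon,
                         KEEP.OUT.ATTRS = FALSE)
  d <- geosphere::distHaversine(c(lon, lat),
                                cbind(centres$lon, centres$lat))
  cand <- which(d <= min(d) + 1e-6)
  cand <- cand[order(centres$lat[cand], centres$lon[cand])][1]
  c(i = ((cand - 1) %% length(grid$lat)) + 1,
    j = ((cand - 1) %/% length(grid$lat)) + 1)
}

#' Composite a satellite grid around one point and date
#'
#' Mean over all cloud-free pixels of a `box x box` pixel window centred on
#' the pixel nearest to (lat, lon), across the `window` daily fields
#' centred on `date` (default: a 9-day average of a 5x5 pixel box). The box
#' is clipped at grid edges.
#'
#' @param grid A `satellite_grid`.
#' @param lat,lon Point of interest (degrees); must lie inside the grid
#'   extent.
#' @param date Centre date.
#' @param box Box side in pixels (odd, default 5).
#' @param window Temporal window in days (odd, default 9).
#' @return One-row tibble: `pic`, `poc`, `chl_sat`, `bbp_sat` (NA if no
#'   valid pixel-day) and `n_pixels_used`.
#' @export
composite <- function(grid, lat, lon, date, box = 5, window = 9) {
  hps_lat <- (grid$lat[2] - grid$lat[1]) / 2
  hps_lon <- (grid$lon[2] - grid$lon[1]) / 2
  if (lat < grid$lat[1] - hps_lat || lat > grid$lat[length(grid$lat)] + hps_lat ||
      lon < grid$lon[1] - hps_lon || lon > grid$lon[length(grid$lon)] + hps_lon)
    stop("composite(): point (", lat, ", ", lon, ") outside grid extent")
  ctr <- nearest_pixel(grid, lat, lon)
  hb <- (box - 1) %/% 2
  hw <- (window - 1) %/% 2
  ii <- max(1, ctr[["i"]] - hb):min(length(grid$lat), ctr[["i"]] + hb)
  jj <- max(1, ctr[["j"]] - hb):min(length(grid$lon), ctr[["j"]] + hb)
  tt <- which(grid$dates >= date - hw & grid$dates <= date + hw)
  if (!length(tt))
    stop("composite(): date ", format(date), " outside grid time axis")
  valid <- grid$valid_mask[tt, ii, jj, drop = FALSE]
  n_used <- sum(valid)
  one <- function(arr) {
    v <- arr[tt, ii, jj, drop = FALSE][valid]
    if (!length(v)) NA_real_ else mean(v)
  }
  tibble::tibble(pic = one(grid$pic), poc = one(grid$poc),
                 chl_sat = one(grid$chl), bbp_sat = one(grid$bbp_sat),
                 n_pixels_used = n_used)
}

#' Build a gap-free satellite matchup series along a float track
#'
#' Applies [composite()] at every track point, then fills remaining gaps
#' (fully cloudy composite windows) by linear interpolation in time along
#' the track; leading/trailing gaps take the nearest valid value. Records
#' obtained by interpolation are flagged. Satellite [Chl-a] can be masked
#' (set missing, never interpolated) inside known bloom periods, where
#' ocean-colour chlorophyll retrievals are biased.
#'
#' @param grid A `satellite_grid`.
#' @param track Tibble/data.frame with columns `date`, `lat`, `lon`
#'   (>= 2 rows, strictly increasing dates).
#' @param box,window Compositing parameters, see [composite()].
#' @param float_id Identifier stored with the series.
#' @param mask_chl_periods Optional bloom-period tibble (see
#'   [detect_bloom_periods()]); `chl_sat` is set to `NA` for dates inside
#'   any period.
#' @return A `matchup_series` tibble: one row per cycle with `date`, `lat`,
#'   `lon`, `pic`, `poc`, `pct_pic`, `chl_sat`, `bbp_sat`,
#'   `n_pixels_used`, `interpolated`.
#' @export
build_series <- function(grid, track, box = 5, window = 9,
                         float_id = "float", mask_chl_periods = NULL) {
  track <- tibble::as_tibble(track)
  stopifnot(nrow(track) >= 2, all(diff(as.numeric(track$date)) > 0))
  rows <- lapply(seq_len(nrow(track)), function(i)
    composite(grid, track$lat[i], track$lon[i], track$date[i],
              box = box, window = window))
  out <- dplyr::bind_rows(rows)
  out <- tibble::tibble(float_id = float_id, date = track$date,
                        lat = track$lat, lon = track$lon, out)
  out$interpolated <- !is.finite(out$pic)
  tnum <- as.numeric(out$date)
  fill <- function(x) {
    if (all(is.na(x))) return(x)                  # undefined series, flagged
    zoo::na.approx(x, x = tnum, na.rm = FALSE, rule = 2)
  }
  for (v in c("pic", "poc", "chl_sat", "bbp_sat")) out[[v]] <- fill(out[[v]])
  out$pct_pic <- pic_fraction(out$pic, out$poc)
  if (!is.null(mask_chl_periods) && nrow(mask_chl_periods) > 0) {
    for (k in seq_len(nrow(mask_chl_periods))) {
      hit <- out$date >= mask_chl_periods$start_date[k] &
        out$date <= mask_chl_periods$end_date[k]
      out$chl_sat[hit] <- NA_real_
    }
  }
  class(out) <- c("matchup_series", class(out))
  out
}
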