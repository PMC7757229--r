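#' Write float profiles as a flat long-format CSV table
#'
#' One row per (cycle, depth) with columns `float_id`, `cycle`, `date`,
#' `lat`, `lon`, `depth`, `temperature`, `salinity`, `fchl`, `bbp700`,
#' `cp660` (empty when the float carries no transmissometer).
#'
#' @param profiles List of `float_profile` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    n <- length(p$depth)
    data.frame(float_id = p$float_id, cycle = p$cycle,
               date = format(p$date), lat = p$lat, lon = p$lon,
               depth = p$depth, temperature = p$temperature,
               salinity = p$salinity, fchl = p$fchl, bbp700 = p$bbp700,
               cp660 = if (is.null(p$cp660)) rep(NA_real_, n) else p$cp660)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read float profiles from a flat long-format CSV table
#'
#' Inverse of [write_profiles_csv()].
#'
#' @param path CSV path.
#' @return List of `float_profile` objects, ordered by cycle.
#' @export
read_profiles_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("float_id", "cycle", "date", "lat", "lon", "depth",
            "temperature", "salinity", "fchl", "bbp700")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("profile table lacks columns: ", paste(missing_cols, collapse = ", "))
  keys <- unique(d[, c("float_id", "cycle")])
  keys <- keys[order(keys$float_id, keys$cycle), , drop = FALSE]
  lapply(seq_len(nrow(keys)), function(k) {
    s <- d[d$float_id == keys$float_id[k] & d$cycle == keys$cycle[k], ,
           drop = FALSE]
    s <- s[order(s$depth), , drop = FALSE]
    cp <- if ("cp660" %in% names(s) && any(is.finite(s$cp660))) s$cp660 else NULL
    p <- list(float_id = s$float_id[1], cycle = s$cycle[1],
              date = as.Date(s$date[1]), lat = s$lat[1], lon = s$lon[1],
              depth = s$depth, temperature = s$temperature,
              salinity = s$salinity, fchl = s$fchl, bbp700 = s$bbp700,
              cp660 = cp)
    class(p) <- "float_profile"
    p
  })
}

#' Write a satellite grid as a flat long-format CSV table
#'
#' One row per (date, lat, lon) pixel with the four fields and the
#' validity mask. Intended for small grids and interchange; large grids
#' are better regenerated from a scenario configuration.
#'
#' @param grid A `satellite_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  idx <- expand.grid(t = seq_along(grid$dates), i = seq_along(grid$lat),
                     j = seq_along(grid$lon), KEEP.OUT.ATTRS = FALSE)
  d <- data.frame(date = format(grid$dates[idx$t]),
                  lat = grid$lat[idx$i], lon = grid$lon[idx$j],
                  pic = as.vector(grid$pic), poc = as.vector(grid$poc),
                  chl = as.vector(grid$chl),
                  bbp_sat = as.vector(grid$bbp_sat),
                  valid = as.vector(grid$valid_mask))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a satellite grid from a flat long-format CSV table
#'
#' Inverse of [write_grid_csv()].
#'
#' @param path CSV path.
#' @return A `satellite_grid`.
#' @export
read_grid_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  dates <- sort(unique(as.Date(d$date)))
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  dims <- c(length(dates), length(lat), length(lon))
  t <- match(as.Date(d$date), dates)
  i <- match(d$lat, lat); j <- match(d$lon, lon)
  lin <- t + (i - 1) * dims[1] + (j - 1) * dims[1] * dims[2]
  put <- function(v) {
    a <- array(NA_real_, dims); a[lin] <- v; a
  }
  out <- list(dates = dates, lat = lat, lon = lon,
              pic = put(d$pic), poc = put(d$poc), chl = put(d$chl),
              bbp_sat = put(d$bbp_sat),
              valid_mask = array(FALSE, dims))
  out$valid_mask[lin] <- d$valid
  class(out) <- "satellite_grid"
  out
}
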