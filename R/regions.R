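#' Point-in-polygon test (even-odd ray casting)
#'
#' Simple planar even-odd rule on lon/lat vertices; adequate for the
#' coarse regional boxes used to assign float records to temperate and
#' subpolar regions (polygons here do not cross the antimeridian).
#'
#' @param lat,lon Point coordinates (vectors, degrees).
#' @param polygon Data frame with `lon` and `lat` vertex columns (closed
#'   implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(lat, lon, polygon) {
  px <- polygon$lon; py <- polygon$lat
  nv <- length(px)
  vapply(seq_along(lat), function(k) {
    x <- lon[k]; y <- lat[k]
    inside <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      if (((py[i] > y) != (py[j] > y)) &&
          (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]))
        inside <- !inside
      j <- i
    }
    inside
  }, logical(1))
}

#' Approximate polygons of the temperate/subpolar bloom regions
#'
#' Editable rectangular approximations of the four regions where float
#' profiles inside coccolithophore blooms concentrate, all poleward of the
#' 35-degree latitude gate: the North Atlantic subpolar gyre, the
#' Patagonian shelf, and the Indian and Atlantic sectors of the Southern
#' Ocean. Intended as a starting configuration, not as authoritative
#' boundaries.
#'
#' @return Named list of data frames with `lon`, `lat` vertices.
#' @export
region_polygons <- function() {
  box <- function(lon_min, lon_max, lat_min, lat_max)
    data.frame(lon = c(lon_min, lon_max, lon_max, lon_min),
               lat = c(lat_min, lat_min, lat_max, lat_max))
  list(
    "North Atlantic subpolar gyre" = box(-65, -5, 45, 66),
    "Patagonian shelf" = box(-70, -50, -55, -38),
    "Indian sector of the Southern Ocean" = box(20, 150, -62, -38),
    "Atlantic sector of the Southern Ocean" = box(-60, 20, -62, -38))
}

#' Published regional dual thresholds
#'
#' The regional b_bp/[Chl-a] and b_bp thresholds with their reported
#' detection performances, bundled for apply-only use with
#' [classify_records()] when no local fit is possible.
#'
#' @return Tibble: `region`, `theta_ratio` (m^2 mg^-1), `theta_bbp`
#'   (m^-1), `sensitivity`, `specificity` (percent).
#' @export
published_thresholds <- function() {
  path <- system.file("extdata", "published_thresholds.csv",
                      package = "coccobloom", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}
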