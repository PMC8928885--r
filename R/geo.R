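# Geometry kernel: GPS spike filtering, minimum convex polygons, and the
# circular home-range baselines that define the migrant/resident threshold.
# All coordinates are planar metric (e.g. UTM easting/northing in meters);
# distances are Euclidean throughout.

#' Radius of the circle with a given area
#'
#' Converts a home-range area in square kilometers to the radius (in meters,
#' rounded to the nearest meter) of the circle with that area. The seasonal
#' home ranges are modelled as circles of fixed baseline area centred on each
#' bird's activity center, so this radius is what enters the migration
#' distance threshold.
#'
#' @param area_km2 Positive numeric vector of areas in km^2.
#' @return Integer-valued numeric vector of radii in meters.
#' @examples
#' radius_from_area(4.08)  # 1140
#' radius_from_area(0.058) # 136
#' @export
radius_from_area <- function(area_km2) {
  if (!is.numeric(area_km2) || any(!is.finite(area_km2)) || any(area_km2 <= 0)) {
    abort_validation("`area_km2` must be finite and > 0")
  }
  round(sqrt(area_km2 * 1e6 / pi))
}

#' Home-range baseline areas and the migration distance threshold
#'
#' Builds the circular-range baseline used to classify seasonal transitions.
#' Each bird is assumed to occupy a circular winter home range of
#' `winter_area` and a circular summer home range of `summer_area`; two
#' consecutive seasonal ranges overlap exactly when their centers are closer
#' than the sum of the two radii. A displacement strictly greater than that
#' sum (1276 m with the defaults) is classified as migration.
#'
#' @param winter_area Winter home-range area in km^2 (default 4.08, the mean
#'   95% MCP of GPS-tracked birds).
#' @param summer_area Summer home-range area in km^2 (default 0.058, the
#'   median 100% MCP across VHF-tracked birds).
#' @return An object of class `range_baseline`: a list with elements
#'   `winter_area`, `summer_area`, `winter_radius`, `summer_radius` (m) and
#'   `threshold` (m).
#' @examples
#' range_baseline()$threshold # 1276
#' @export
range_baseline <- function(winter_area = 4.08, summer_area = 0.058) {
  wr <- radius_from_area(winter_area)
  sr <- radius_from_area(summer_area)
  structure(
    list(
      winter_area = winter_area, summer_area = summer_area,
      winter_radius = wr, summer_radius = sr,
      threshold = wr + sr
    ),
    class = "range_baseline"
  )
}

#' @export
print.range_baseline <- function(x, ...) {
  cat("Circular home-range baseline\n")
  cat(sprintf("  winter: %.3f km^2 (radius %d m)\n", x$winter_area, x$winter_radius))
  cat(sprintf("  summer: %.3f km^2 (radius %d m)\n", x$summer_area, x$summer_radius))
  cat(sprintf("  migration threshold: %d m\n", x$threshold))
  invisible(x)
}

#' Single-pass GPS spike filter
#'
#' Flags implausible positions in a time-ordered GPS track. A fix at interior
#' position t is flagged as an outlier when the distance from the previous
#' fix to it exceeds twice the distance from the previous fix to the next
#' fix, i.e. `d(t-1, t) > 2 * d(t-1, t+1)`. The rule is evaluated in a single
#' pass over the original sequence; the first and last fixes are never
#' flagged.
#'
#' @param x,y Numeric coordinate vectors in meters (time order).
#' @param timestamps Optional vector of fix times; if supplied it must be
#'   strictly increasing.
#' @return A list with `retained` (integer indices of kept fixes, original
#'   order) and `flagged` (integer indices of removed fixes).
#' @export
filter_gps_outliers <- function(x, y, timestamps = NULL) {
  n <- length(x)
  if (length(y) != n) abort_validation("`x` and `y` must have equal length")
  if (n < 3) abort_validation("a track needs at least 3 fixes to filter")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_validation("track coordinates must be finite")
  }
  if (!is.null(timestamps)) {
    if (length(timestamps) != n) abort_validation("`timestamps` length mismatch")
    if (is.unsorted(timestamps, strictly = TRUE)) {
      abort_validation("`timestamps` must be strictly increasing within a track")
    }
  }
  t <- 2:(n - 1)
  d_prev_focal <- sqrt((x[t] - x[t - 1])^2 + (y[t] - y[t - 1])^2)
  d_prev_next <- sqrt((x[t + 1] - x[t - 1])^2 + (y[t + 1] - y[t - 1])^2)
  flagged <- t[d_prev_focal > 2 * d_prev_next]
  list(retained = setdiff(seq_len(n), flagged), flagged = flagged)
}

# Shoelace area of a polygon given vertex coordinates (signed; positive when
# counter-clockwise). Returns m^2 for inputs in m.
polygon_area_signed <- function(px, py) {
  nx <- c(px[-1], px[1])
  ny <- c(py[-1], py[1])
  sum(px * ny - nx * py) / 2
}

# Convex hull of a point set as counter-clockwise vertex indices, plus the
# hull area in m^2 (0 for degenerate/collinear sets).
convex_hull_ccw <- function(x, y) {
  idx <- grDevices::chull(x, y)
  if (length(idx) < 3) {
    return(list(indices = idx, area_m2 = 0))
  }
  a <- polygon_area_signed(x[idx], y[idx])
  if (a < 0) { # make counter-clockwise
    idx <- rev(idx)
    a <- -a
  }
  list(indices = idx, area_m2 = a)
}

#' Minimum convex polygon home range
#'
#' Computes a percentage minimum convex polygon: the `percent`% of fixes
#' closest to the arithmetic mean of all fixes are retained
#' (`k = max(3, floor(percent * n / 100))`, distance ties broken in favour of
#' earlier fixes), and the convex hull of the retained fixes is returned with
#' its area.
#'
#' @param x,y Numeric coordinate vectors in meters, in time order (the order
#'   is used to break distance ties).
#' @param percent Percentage of fixes to retain, in (0, 100].
#' @return A list with `vertices` (tibble of hull vertex coordinates `x`,
#'   `y`, counter-clockwise), `area_km2`, `retained` (indices of fixes kept
#'   before hull construction) and `percent`.
#' @examples
#' sq <- c(0, 1000, 1000, 0)
#' mcp(sq, c(0, 0, 1000, 1000), percent = 100)$area_km2 # 1 km^2
#' @export
mcp <- function(x, y, percent = 95) {
  n <- length(x)
  if (length(y) != n) abort_validation("`x` and `y` must have equal length")
  if (!is.numeric(percent) || length(percent) != 1 || !is.finite(percent) ||
      percent <= 0 || percent > 100) {
    abort_validation("`percent` must be a single value in (0, 100]")
  }
  if (n < 3) abort_validation("at least 3 fixes are required for an MCP")
  cx <- mean(x)
  cy <- mean(y)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  k <- max(3L, as.integer(floor(percent * n / 100)))
  keep <- order(d, seq_len(n))[seq_len(k)] # ties -> earlier fix wins
  keep <- sort(keep)
  hull <- convex_hull_ccw(x[keep], y[keep])
  if (hull$area_m2 <= 0) {
    rlang::abort("retained fixes are collinear; MCP area is degenerate (0)",
      class = "partmigr_degenerate_geometry", area_km2 = 0
    )
  }
  vi <- keep[hull$indices]
  list(
    vertices = tibble::tibble(x = x[vi], y = y[vi]),
    area_km2 = hull$area_m2 / 1e6,
    retained = keep,
    percent = percent
  )
}

#' Baseline summer home-range area across birds
#'
#' For every bird with at least 3 summer fixes, computes the area of the
#' convex hull (100% MCP) of its summer fixes, and returns the median of the
#' per-bird areas (midpoint of the two central values for an even number of
#' birds). Degenerate (collinear) fix sets contribute an area of 0.
#'
#' @param fixes A data frame with columns `bird_id`, `x_m`, `y_m` holding
#'   summer-season fixes.
#' @return A list with `median_km2` and `areas` (tibble of per-bird
#'   `bird_id`, `area_km2`, `n_fixes`).
#' @export
summer_baseline <- function(fixes) {
  stopifnot(all(c("bird_id", "x_m", "y_m") %in% names(fixes)))
  areas <- fixes |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(
      area_km2 = convex_hull_ccw(.data$x_m, .data$y_m)$area_m2 / 1e6,
      n_fixes = dplyr::n(),
      .groups = "drop"
    )
  if (nrow(areas) == 0) {
    abort_validation("no bird has >= 3 summer fixes; summer baseline undefined")
  }
  list(median_km2 = stats::median(areas$area_km2), areas = areas)
}
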