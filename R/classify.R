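# Seasonal activity centers and migrant/resident classification.
#
# The season windows follow the study design: January-March is "winter" and
# May-July is "summer"; fixes outside those windows play no part in the
# classification. Each bird-season is summarised by an activity center, and
# each pair of consecutive seasonal centers becomes one migratory decision
# (a "transition"), classified migrant when the displacement exceeds the
# circular-range overlap threshold (see [range_baseline()]).

#' Assign telemetry timestamps to analysis seasons
#'
#' @param timestamps A `Date`/`POSIXt` vector (or something coercible by
#'   `as.POSIXlt`).
#' @return A tibble with one row per timestamp: `year` (integer) and `season`
#'   (`"winter"`, `"summer"`, or `NA` for months outside January-March and
#'   May-July).
#' @examples
#' assign_season(as.Date(c("2016-02-15", "2016-06-01", "2016-04-10")))
#' @export
assign_season <- function(timestamps) {
  lt <- as.POSIXlt(timestamps)
  month <- lt$mon + 1L
  year <- lt$year + 1900L
  season <- rep(NA_character_, length(month))
  season[month %in% 1:3] <- "winter"
  season[month %in% 5:7] <- "summer"
  tibble::tibble(year = year, season = season)
}

#' Seasonal activity center, optionally shifted toward a nest
#'
#' Without a nest the activity center is the arithmetic mean of the fixes.
#' For nesting birds the center is shifted toward the nest by giving the nest
#' position and the mean of all other positions equal weight, i.e. the
#' midpoint of the two. A nest with no other fixes yields the nest position
#' itself.
#'
#' @param x,y Coordinates (m) of the non-nest fixes; may be empty if a nest
#'   is supplied.
#' @param nest Optional length-2 numeric `c(x, y)` nest position.
#' @return Numeric `c(x, y)`.
#' @export
activity_center <- function(x, y, nest = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0 && is.null(nest)) {
    abort_validation("activity center needs at least one fix or a nest position")
  }
  if (is.null(nest)) {
    return(c(mean(x), mean(y)))
  }
  stopifnot(is.numeric(nest), length(nest) == 2)
  if (length(x) == 0) {
    return(as.numeric(nest))
  }
  c((nest[1] + mean(x)) / 2, (nest[2] + mean(y)) / 2)
}

#' Per bird-season activity centers from a fix table
#'
#' Maps every analysable fix to its season, then computes one activity
#' center per bird-season. Triangulated and capture fixes are used directly;
#' nest fixes (and rows of `nests`) enter through the equal-weight nest shift
#' of [activity_center()]; pure GPS fixes are excluded, as GPS-tracked birds
#' inform only the winter home-range baseline.
#'
#' @param fixes Data frame with columns `bird_id`, `datetime`, `x_m`, `y_m`,
#'   `source` (`"triangulation"`, `"gps"`, `"nest"`, `"capture"`).
#' @param nests Optional data frame with columns `bird_id`, `year`, `x_m`,
#'   `y_m`; a nest applies to the summer season of its year.
#' @return Tibble with `bird_id`, `year`, `season`, `x`, `y`, `n_fixes`.
#' @export
seasonal_centers <- function(fixes, nests = NULL) {
  stopifnot(all(c("bird_id", "datetime", "x_m", "y_m", "source") %in% names(fixes)))
  fx <- dplyr::bind_cols(fixes, assign_season(fixes$datetime)) |>
    dplyr::filter(!is.na(.data$season), .data$source != "gps")

  nest_tbl <- fx |>
    dplyr::filter(.data$source == "nest") |>
    dplyr::distinct(.data$bird_id, .data$year, nest_x = .data$x_m, nest_y = .data$y_m)
  if (!is.null(nests) && nrow(nests) > 0) {
    stopifnot(all(c("bird_id", "year", "x_m", "y_m") %in% names(nests)))
    nest_tbl <- dplyr::bind_rows(
      nest_tbl,
      dplyr::distinct(nests, .data$bird_id, .data$year,
        nest_x = .data$x_m, nest_y = .data$y_m
      )
    ) |>
      dplyr::distinct(.data$bird_id, .data$year, .keep_all = TRUE)
  }

  fx |>
    dplyr::filter(.data$source != "nest") |>
    dplyr::group_by(.data$bird_id, .data$year, .data$season) |>
    dplyr::summarise(
      mx = mean(.data$x_m), my = mean(.data$y_m),
      n_fixes = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::left_join(nest_tbl, by = c("bird_id", "year")) |>
    dplyr::mutate(
      has_nest = .data$season == "summer" & !is.na(.data$nest_x),
      x = ifelse(.data$has_nest, (.data$nest_x + .data$mx) / 2, .data$mx),
      y = ifelse(.data$has_nest, (.data$nest_y + .data$my) / 2, .data$my)
    ) |>
    dplyr::select(bird_id, year, season, x, y, n_fixes)
}

season_rank <- function(year, season) {
  2L * as.integer(year) + as.integer(season == "summer")
}

#' Pair consecutive seasonal centers into classified transitions
#'
#' Emits one transition per consecutive season pair observed for a bird:
#' winter(y) to summer(y) and summer(y) to winter(y+1). The displacement is
#' the Euclidean distance between the two activity centers; a transition is
#' classified `"migrant"` when the distance is strictly greater than
#' `baseline$threshold` (a displacement of exactly the threshold is
#' `"resident"`). The bird's earliest winter-to-summer pair is flagged
#' `is_first_spring`.
#'
#' @param centers Output of [seasonal_centers()].
#' @param baseline A [range_baseline()].
#' @return Tibble with `bird_id`, `from_year`, `from_season`, `to_year`,
#'   `to_season`, `distance_m`, `strategy`, `is_first_spring`.
#' @export
build_transitions <- function(centers, baseline = range_baseline()) {
  stopifnot(inherits(baseline, "range_baseline"))
  if (anyDuplicated(centers[c("bird_id", "year", "season")]) > 0) {
    abort_validation("duplicate (bird, season) activity centers")
  }
  cc <- centers |>
    dplyr::mutate(rank = season_rank(.data$year, .data$season)) |>
    dplyr::arrange(.data$bird_id, .data$rank)
  tr <- cc |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::mutate(
      to_year = dplyr::lead(.data$year),
      to_season = dplyr::lead(.data$season),
      to_x = dplyr::lead(.data$x),
      to_y = dplyr::lead(.data$y),
      consecutive = dplyr::lead(.data$rank) == .data$rank + 1L
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$consecutive) & .data$consecutive) |>
    dplyr::mutate(
      distance_m = sqrt((.data$to_x - .data$x)^2 + (.data$to_y - .data$y)^2),
      strategy = ifelse(.data$distance_m > baseline$threshold, "migrant", "resident")
    ) |>
    dplyr::rename(from_year = year, from_season = season) |>
    dplyr::select(
      bird_id, from_year, from_season,
      to_year, to_season, distance_m, strategy
    )
  tr |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::mutate(
      is_first_spring = .data$from_season == "winter" &
        cumsum(.data$from_season == "winter") == 1L
    ) |>
    dplyr::ungroup()
}

#' Tabulate migratory decisions by year
#'
#' Produces a per-year table of resident and migrant counts with the
#' percentage of migrants (rounded to the nearest integer) and an overall
#' `Total` row. Transitions are attributed to the calendar year of their
#' destination season.
#'
#' @param transitions Output of [build_transitions()].
#' @param first_spring_only If `TRUE` (default), count only each bird's first
#'   winter-to-summer decision; otherwise count every transition.
#' @return Tibble with `year` (character; last row `"Total"`), `residents`,
#'   `migrants`, `total`, `pct_migrants`.
#' @export
summarize_transitions <- function(transitions, first_spring_only = TRUE) {
  tr <- if (first_spring_only) {
    dplyr::filter(transitions, .data$is_first_spring)
  } else {
    transitions
  }
  if (nrow(tr) == 0) abort_validation("no transitions to summarise")
  per_year <- tr |>
    dplyr::group_by(year = as.character(.data$to_year)) |>
    dplyr::summarise(
      residents = sum(.data$strategy == "resident"),
      migrants = sum(.data$strategy == "migrant"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year)
  total <- tibble::tibble(
    year = "Total",
    residents = sum(per_year$residents),
    migrants = sum(per_year$migrants)
  )
  dplyr::bind_rows(per_year, total) |>
    dplyr::mutate(
      total = .data$residents + .data$migrants,
      pct_migrants = round(100 * .data$migrants / .data$total)
    )
}

#' Full classification pipeline
#'
#' Convenience wrapper: seasonal activity centers, transition construction
#' and the per-year decision summary in one call.
#'
#' @inheritParams seasonal_centers
#' @inheritParams build_transitions
#' @return List with `centers`, `transitions`, `summary`
#'   (first-spring-only), and the `baseline` used.
#' @export
classify_migration <- function(fixes, nests = NULL, baseline = range_baseline()) {
  centers <- seasonal_centers(fixes, nests)
  transitions <- build_transitions(centers, baseline)
  list(
    centers = centers,
    transitions = transitions,
    summary = summarize_transitions(transitions, first_spring_only = TRUE),
    baseline = baseline
  )
}
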