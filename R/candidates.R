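# The four first-spring candidate-model sets: migratory decision (binomial),
# log movement distance (Gaussian), clutch size (CMP), nest fate (binomial),
# each ranked by AICc. One row per bird: only the first spring after capture
# enters, which makes bird identity inert and keeps every model a
# fixed-effects GLM.

state_formulas <- list(
  "Weight + Age + Weight x Age" = ~ weight_z * age_class,
  "Weight" = ~weight_z,
  "Intercept" = ~1,
  "Age" = ~age_class,
  "Weight + Age" = ~ weight_z + age_class
)

nesting_formulas <- list(
  "Intercept" = ~1,
  "Age" = ~age_class,
  "Weight" = ~weight_z,
  "Migratory strategy" = ~strategy,
  "Age + Weight" = ~ age_class + weight_z,
  "Age + Migratory strategy" = ~ age_class + strategy,
  "Migratory strategy + Weight" = ~ strategy + weight_z,
  "Migratory strategy + Age + Weight" = ~ strategy + age_class + weight_z
)

fit_candidates <- function(formulas, data, response, fitter) {
  fits <- lapply(formulas, function(f) {
    X <- stats::model.matrix(f, data = data)
    fitter(response, X)
  })
  names(fits) <- names(formulas)
  fits
}

#' Fit and rank the four first-spring candidate-model sets
#'
#' Assembles the first-spring analysis data (one row per bird) and fits the
#' standard candidate sets: (1) migratory decision, binomial with logit
#' link, candidates over standardized weight, age class and their
#' interaction; (2) `log(distance + 1)`, Gaussian, same candidates;
#' (3) clutch size, mean-parameterized CMP regression with log link,
#' candidates over migratory strategy, age and weight; (4) nest fate
#' (hatched vs failed), binomial, same candidates as (3). Body weight is
#' standardized within each analysis subset. Each set is returned as an
#' AICc-ranked [rank_models()] table together with the underlying fits.
#'
#' @param transitions Transition table from [build_transitions()].
#' @param birds Bird attribute table (`bird_id`, `age_class`, `weight_g`).
#' @param nests Nest table (`bird_id`, `year`, `clutch_size`, `fate`); used
#'   for the clutch-size and nest-fate sets. A bird's nest from its
#'   first-spring year is used.
#' @return List with elements `migration`, `distance`, `clutch_size`,
#'   `nest_fate`; each a list of `table` (ranked tibble) and `fits`.
#' @export
run_candidate_sets <- function(transitions, birds, nests) {
  need <- setdiff(c("bird_id", "age_class", "weight_g"), names(birds))
  if (length(need)) {
    abort_validation(paste("`birds` is missing columns:", paste(need, collapse = ", ")))
  }
  fs <- transitions |>
    dplyr::filter(.data$is_first_spring) |>
    dplyr::inner_join(
      dplyr::select(birds, bird_id, age_class, weight_g),
      by = "bird_id"
    ) |>
    dplyr::mutate(
      age_class = factor(.data$age_class, levels = c("adult", "juvenile")),
      weight_z = standardize(.data$weight_g),
      migrated = as.numeric(.data$strategy == "migrant")
    )

  migration_fits <- fit_candidates(state_formulas, fs, fs$migrated, fit_binomial)
  distance_fits <- fit_candidates(
    state_formulas, fs, log(fs$distance_m + 1), fit_gaussian
  )

  out <- list(
    migration = list(table = rank_models(migration_fits), fits = migration_fits),
    distance = list(table = rank_models(distance_fits), fits = distance_fits)
  )

  if (!is.null(nests) && nrow(nests) > 0) {
    need <- setdiff(c("bird_id", "year", "clutch_size", "fate"), names(nests))
    if (length(need)) {
      abort_validation(paste("`nests` is missing columns:", paste(need, collapse = ", ")))
    }
    nest_dat <- fs |>
      dplyr::inner_join(
        dplyr::select(nests, bird_id, year, clutch_size, fate),
        by = c("bird_id", "to_year" = "year")
      ) |>
      dplyr::mutate(
        weight_z = standardize(.data$weight_g),
        hatched = as.numeric(.data$fate == "hatched")
      )
    if (nrow(nest_dat) >= 8) {
      clutch_fits <- fit_candidates(
        nesting_formulas, nest_dat, nest_dat$clutch_size, fit_cmp_regression
      )
      fate_fits <- fit_candidates(
        nesting_formulas, nest_dat, nest_dat$hatched, fit_binomial
      )
      out$clutch_size <- list(table = rank_models(clutch_fits), fits = clutch_fits)
      out$nest_fate <- list(table = rank_models(fate_fits), fits = fate_fits)
    }
  }
  out
}
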