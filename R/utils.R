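abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "partmigr_validation_error", ...)
}

utils::globalVariables(c(
  "bird_id", "year", "season", "x", "y", "n_fixes",
  "from_year", "from_season", "to_year", "to_season",
  "distance_m", "strategy", "age_class", "weight_g",
  "clutch_size", "fate", "x_m", "y_m", "datetime", "source"
))

#' @importFrom rlang .data
#' @importFrom rlang %||%
#' @keywords internal
"_PACKAGE"
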