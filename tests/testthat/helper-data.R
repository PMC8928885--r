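# Shared small-data constructors for tests.

# One bird per requested displacement: winter center at the origin, summer
# center due east at that distance.
centers_at <- function(distances) {
  dplyr::bind_rows(lapply(seq_along(distances), function(i) {
    tibble::tibble(
      bird_id = paste0("b", i), year = 2016L,
      season = c("winter", "summer"), x = c(0, distances[i]), y = 0,
      n_fixes = 5L
    )
  }))
}

# Balanced grouped Gaussian data for the mixed-model tests.
sim_lmm_data <- function(n_groups, n_per, sd_a, sd_e, mu = 3, seed = 1) {
  withr::with_seed(seed, {
    g <- rep(seq_len(n_groups), each = n_per)
    y <- mu + rnorm(n_groups, 0, sd_a)[g] + rnorm(length(g), 0, sd_e)
    list(y = y, g = g)
  })
}
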