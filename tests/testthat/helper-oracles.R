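# Independent brute-force oracles used to cross-check the package's
# geometry and model-fitting code. Deliberately naive implementations that
# share no code with the package.

# Gift-wrapping (Jarvis march) convex hull; returns vertex indices.
oracle_hull <- function(x, y) {
  n <- length(x)
  start <- which.min(x + 1e-9 * y)
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (j in cand[-1]) {
      cr <- (x[nxt] - x[cur]) * (y[j] - y[cur]) - (y[nxt] - y[cur]) * (x[j] - x[cur])
      d_nxt <- (x[nxt] - x[cur])^2 + (y[nxt] - y[cur])^2
      d_j <- (x[j] - x[cur])^2 + (y[j] - y[cur])^2
      if (cr < 0 || (abs(cr) < 1e-12 && d_j > d_nxt)) nxt <- j
    }
    cur <- nxt
    if (cur == start) break
  }
  hull
}

# Shoelace polygon area (absolute), m^2.
oracle_area <- function(px, py) {
  n <- length(px)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + px[i] * py[j] - px[j] * py[i]
  }
  abs(s) / 2
}

# Brute-force percentage MCP: rank by distance to the mean (ties -> earlier
# index), keep k, hull area via the oracle hull.
oracle_mcp_area_km2 <- function(x, y, percent) {
  n <- length(x)
  d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
  k <- max(3, floor(percent * n / 100))
  keep <- order(d, seq_len(n))[seq_len(k)]
  h <- oracle_hull(x[keep], y[keep])
  oracle_area(x[keep][h], y[keep][h]) / 1e6
}

# Exhaustive evaluation of the consecutive-distance spike rule over every
# interior triple.
oracle_outlier_flags <- function(x, y) {
  n <- length(x)
  flags <- integer(0)
  for (t in 2:(n - 1)) {
    d1 <- sqrt((x[t] - x[t - 1])^2 + (y[t] - y[t - 1])^2)
    d2 <- sqrt((x[t + 1] - x[t - 1])^2 + (y[t + 1] - y[t - 1])^2)
    if (d1 > 2 * d2) flags <- c(flags, t)
  }
  flags
}

# Closed-form balanced one-way ANOVA variance components (expected mean
# squares), the REML solution for balanced data when MSB > MSW.
oracle_balanced_anova <- function(y, g) {
  g <- factor(g)
  n0 <- length(y) / nlevels(g)
  gm <- tapply(y, g, mean)
  msb <- n0 * sum((gm - mean(y))^2) / (nlevels(g) - 1)
  msw <- sum((y - gm[g])^2) / (length(y) - nlevels(g))
  list(sigma2_alpha = (msb - msw) / n0, sigma2_eps = msw)
}

# Transitions table derived straight from simulator ground truth (distance =
# true displacement), bypassing the geometry; used to test the regression
# stage in isolation.
truth_transitions <- function(sim) {
  tr <- sim$truth$seasons
  tibble::tibble(
    bird_id = tr$bird_id,
    from_year = tr$year, from_season = "winter",
    to_year = tr$year, to_season = "summer",
    distance_m = tr$displacement_m,
    strategy = tr$strategy
  ) |>
    dplyr::group_by(bird_id) |>
    dplyr::mutate(is_first_spring = dplyr::row_number() == 1) |>
    dplyr::ungroup()
}
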