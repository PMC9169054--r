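# Shared fixture builders for the test suite. All data are generated in code.

# Minimal tract table for one city.
one_city_tracts <- function(a, b, city = "c1") {
  data.frame(city_id = city, tract_id = sprintf("t%03d", seq_along(a)),
             group_a_count = a, group_b_count = b, stringsAsFactors = FALSE)
}

# Random multi-city tract table (counts <= max_count, <= max_tracts tracts),
# guaranteed to have positive totals for both groups in every city.
random_tract_table <- function(n_cities = 5, max_tracts = 5, max_count = 10) {
  do.call(rbind, lapply(seq_len(n_cities), function(c) {
    n <- sample(2:max_tracts, 1)
    repeat {
      a <- sample(0:max_count, n, replace = TRUE)
      b <- sample(0:max_count, n, replace = TRUE)
      if (sum(a) > 0 && sum(b) > 0) break
    }
    one_city_tracts(a, b, city = sprintf("c%02d", c))
  }))
}

# Independent term-by-term oracle for the dissimilarity index, written as a
# literal loop over the displayed formula (kept free of the vectorized
# implementation on purpose).
di_oracle <- function(a, b) {
  A_T <- 0; B_T <- 0
  for (i in seq_along(a)) A_T <- A_T + a[i]
  for (i in seq_along(b)) B_T <- B_T + b[i]
  s <- 0
  for (i in seq_along(a)) {
    s <- s + abs(a[i] / A_T - b[i] / B_T)
  }
  s / 2
}

# Deterministic person table with exact per-race outcome proportions,
# spread over `n_cities` cities; used for saturated-model checks.
exact_proportion_persons <- function(n_per_race = 200,
                                     props = c(White = 0.2, Brown = 0.25, Black = 0.3),
                                     n_cities = 4) {
  rows <- lapply(names(props), function(r) {
    k <- round(props[[r]] * n_per_race)
    data.frame(
      race = r,
      srh_fair_poor = rep(c(1, 0), c(k, n_per_race - k)),
      stringsAsFactors = FALSE
    )
  })
  d <- do.call(rbind, rows)
  n <- nrow(d)
  d$person_id <- sprintf("p%05d", seq_len(n))
  d$city_id <- rep_len(sprintf("c%02d", seq_len(n_cities)), n)
  d$age <- 40
  d$gender <- rep_len(c("male", "female"), n)
  d$education <- "secondary"
  d
}

# Small synthetic study used by several model tests (kept small for speed).
small_study <- function(seed = 11, ppc = c(80, 200), ...) {
  simulate_study(generative_config(persons_per_city = ppc, seed = seed, ...))
}
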