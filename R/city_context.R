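# City-level social-environment composite and assembled city context table.

#' City social-environment index
#'
#' Combines four city-level indicator percentages into a single composite:
#' each indicator is z-scored across cities (sample standard deviation,
#' denominator n - 1), the household-crowding z-score is negated so that less
#' crowding counts as better, and the index is the mean of the four
#' (possibly negated) z-scores. Higher values indicate a better city social
#' environment. By construction the index has mean zero across cities.
#'
#' @param indicators Data frame with columns `city_id`,
#'   `pct_primary_education_25plus` (% of the population aged 25+ who
#'   completed at least primary education), `pct_piped_water` (% of
#'   households with piped water), `pct_sewage_network` (% of households
#'   connected to a sewage network) and `pct_crowded_households` (% of
#'   households with more than 3 people per room; inverted in the composite).
#'   All percentages must lie in \[0, 100\] with no missing values.
#' @return Data frame `city_id`, `social_environment_index`.
#' @export
social_environment_index <- function(indicators) {
  cols <- c("pct_primary_education_25plus", "pct_piped_water",
            "pct_sewage_network", "pct_crowded_households")
  miss <- setdiff(c("city_id", cols), names(indicators))
  if (length(miss) > 0) {
    stop("indicators table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(indicators) < 2) {
    stop("at least 2 cities are required to form z-scores; got ", nrow(indicators))
  }
  x <- indicators[cols]
  if (anyNA(x)) stop("indicator values must not be missing")
  if (any(x < 0 | x > 100)) stop("indicator percentages must lie in [0, 100]")
  z <- vapply(cols, function(cl) {
    s <- stats::sd(indicators[[cl]])
    if (s == 0) stop("indicator '", cl, "' has zero variance across cities")
    (indicators[[cl]] - mean(indicators[[cl]])) / s
  }, numeric(nrow(indicators)))
  z <- matrix(z, nrow = nrow(indicators),
              dimnames = list(NULL, cols))
  z[, "pct_crowded_households"] <- -z[, "pct_crowded_households"]
  data.frame(
    city_id = as.character(indicators$city_id),
    social_environment_index = rowMeans(z),
    stringsAsFactors = FALSE
  )
}

#' Assemble the city context table
#'
#' Runs the segregation module on both tract tables, assigns tertiles, and
#' joins the social-environment index into a single per-city table used by
#' the modelling functions. Also records each city's overall Black+Brown
#' population share from the race tract table (used by the synthetic-data
#' generator and descriptives).
#'
#' @param tracts_income Tract table for income-based segregation (group A =
#'   households with income at or below 2 minimum wages).
#' @param tracts_race Tract table for race-based segregation (group A =
#'   Black + Brown residents).
#' @param indicators City indicator table (see [social_environment_index()]).
#' @return Data frame with one row per city: `city_id`,
#'   `social_environment_index`, `di_income`, `tertile_income`, `di_race`,
#'   `tertile_race`, `nonwhite_share`.
#' @export
build_city_context <- function(tracts_income, tracts_race, indicators) {
  inc <- assign_tertiles(segregation_by_dimension(tracts_income, "income"))
  rac <- assign_tertiles(segregation_by_dimension(tracts_race, "race"))
  senv <- social_environment_index(indicators)
  share <- vapply(split(tracts_race, as.character(tracts_race$city_id)), function(d) {
    sum(d$group_a_count) / sum(d$group_a_count + d$group_b_count)
  }, numeric(1))
  ctx <- data.frame(
    city_id = inc$city_id,
    di_income = inc$value,
    tertile_income = inc$tertile,
    stringsAsFactors = FALSE
  )
  ctx <- merge(ctx,
               data.frame(city_id = rac$city_id, di_race = rac$value,
                          tertile_race = rac$tertile, stringsAsFactors = FALSE),
               by = "city_id")
  ctx <- merge(ctx, senv, by = "city_id")
  ctx <- merge(ctx,
               data.frame(city_id = names(share), nonwhite_share = unname(share),
                          stringsAsFactors = FALSE),
               by = "city_id")
  if (nrow(ctx) != nrow(inc)) {
    stop("city_id sets differ between tract tables and indicators")
  }
  ctx[order(ctx$city_id), ]
}
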