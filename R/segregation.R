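# Dissimilarity indices of residential segregation and tertile classification.

#' Dissimilarity index for one city
#'
#' Computes the index of dissimilarity
#' \deqn{D = \frac{1}{2} \sum_{i=1}^{n} \left| \frac{a_i}{A_T} - \frac{b_i}{B_T} \right|}
#' over the census tracts of a single city, where \eqn{a_i}, \eqn{b_i} are the
#' tract-level counts of the two population groups being compared and
#' \eqn{A_T}, \eqn{B_T} their city totals. D ranges from 0 (both groups
#' distributed identically across tracts, complete integration) to 1 (the
#' groups occupy disjoint tracts, complete segregation), and can be read as
#' the fraction of either group that would have to move to achieve evenness.
#'
#' Tracts with zero counts for both groups are allowed and contribute zero.
#'
#' @param tracts Data frame with columns `group_a_count` and `group_b_count`
#'   (nonnegative), one row per census tract, restricted to one city. A
#'   `city_id` column, if present, is used in error messages only.
#' @return A single number in \[0, 1\].
#' @examples
#' # complete segregation: the groups live in disjoint tracts
#' dissimilarity_index(data.frame(group_a_count = c(100, 0),
#'                                group_b_count = c(0, 100)))
#' @export
dissimilarity_index <- function(tracts) {
  if (!all(c("group_a_count", "group_b_count") %in% names(tracts))) {
    stop("tracts must have columns group_a_count and group_b_count")
  }
  city <- if ("city_id" %in% names(tracts) && nrow(tracts) > 0) {
    as.character(tracts$city_id[1])
  } else "<unknown>"
  if ("city_id" %in% names(tracts) && length(unique(tracts$city_id)) > 1) {
    stop("dissimilarity_index() expects tracts from a single city; got ",
         length(unique(tracts$city_id)))
  }
  a <- as.numeric(tracts$group_a_count)
  b <- as.numeric(tracts$group_b_count)
  if (any(a < 0) || any(b < 0)) {
    stop("negative tract count in city ", city)
  }
  A <- sum(a)
  B <- sum(b)
  if (A <= 0) stop("city ", city, ": total count for group A is zero")
  if (B <= 0) stop("city ", city, ": total count for group B is zero")
  0.5 * sum(abs(a / A - b / B))
}

#' Dissimilarity indices for every city in a tract table
#'
#' @param tracts Tract table with columns `city_id`, `tract_id`,
#'   `group_a_count`, `group_b_count`. For income-based segregation group A is
#'   households with mean income at or below 2 minimum wages and group B those
#'   above; for race-based segregation group A is Black plus Brown residents
#'   and group B White residents.
#' @param dimension `"income"` or `"race"`; recorded in the output.
#' @return Data frame with one row per city: `city_id`, `dimension`, `value`
#'   (the dissimilarity index) and `tertile` (NA until [assign_tertiles()] is
#'   applied). Cities are ordered by `city_id`.
#' @export
segregation_by_dimension <- function(tracts, dimension = c("income", "race")) {
  dimension <- match.arg(dimension)
  tracts <- validate_tract_table(tracts)
  if ("dimension" %in% names(tracts)) {
    tracts <- tracts[tracts$dimension == dimension, , drop = FALSE]
    if (nrow(tracts) == 0) stop("no tracts with dimension == '", dimension, "'")
  }
  cities <- sort(unique(as.character(tracts$city_id)))
  values <- vapply(cities, function(cid) {
    dissimilarity_index(tracts[as.character(tracts$city_id) == cid, , drop = FALSE])
  }, numeric(1))
  data.frame(
    city_id = cities,
    dimension = dimension,
    value = unname(values),
    tertile = factor(rep(NA_character_, length(cities)),
                     levels = seg_levels$tertile),
    stringsAsFactors = FALSE
  )
}

#' Classify cities into segregation tertiles
#'
#' Cities are ranked by index value (ties broken by `city_id`, a stable and
#' deterministic rule) and split into contiguous thirds: the lowest third is
#' labelled `low`, the middle `medium`, the top `high`. When the number of
#' cities n is not divisible by 3, group sizes follow the floor rule
#' `diff(floor(n * (0:3) / 3))`, so sizes differ by at most one and any extra
#' city goes to the upper tertile(s).
#'
#' @param indices Data frame as returned by [segregation_by_dimension()]
#'   (columns `city_id` and `value`; other columns are carried through).
#' @return The input with `tertile` filled in plus `tertile_range_low` /
#'   `tertile_range_high`, the observed index range within each tertile.
#' @export
assign_tertiles <- function(indices) {
  n <- nrow(indices)
  if (n < 3) stop("at least 3 cities are required to form tertiles; got ", n)
  ord <- order(indices$value, as.character(indices$city_id))
  sizes <- diff(floor(n * (0:3) / 3))
  lab <- rep(seg_levels$tertile, times = sizes)
  tert <- factor(rep(NA_character_, n), levels = seg_levels$tertile)
  tert[ord] <- lab
  indices$tertile <- tert
  rng_lo <- tapply(indices$value, indices$tertile, min)
  rng_hi <- tapply(indices$value, indices$tertile, max)
  indices$tertile_range_low <- as.numeric(rng_lo[as.character(indices$tertile)])
  indices$tertile_range_high <- as.numeric(rng_hi[as.character(indices$tertile)])
  indices
}
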