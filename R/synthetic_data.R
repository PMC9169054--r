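# Synthetic study generator: census-tract tables, city indicators, and
# individual survey records with known ground truth.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generative configuration for a synthetic study
#'
#' Defaults emulate the structure of a 27-capital household survey linked to
#' census-tract data: 27 cities, a right-skewed respondent count per city
#' (range 641-3,439), race mix 41.6/48.2/10.2% White/Brown/Black, adult ages
#' truncated to 18-100 years, an overall fair/poor self-rated-health
#' prevalence calibrated to 31.5%, city random-intercept heterogeneity, and a
#' race-by-segregation-tertile interaction that widens the Black-White and
#' Brown-White gaps in more segregated cities.
#'
#' @param n_cities Number of cities.
#' @param tracts_per_city Integer range (length 2) of census tracts per city.
#' @param persons_per_city Integer range (length 2) of survey respondents per
#'   city; counts are drawn log-normally within this range so the median sits
#'   near the geometric midpoint.
#' @param race_mix Probabilities of White/Brown/Black (sums to 1).
#' @param beta Named numeric vector of generating log-odds coefficients; see
#'   Details. Missing names keep their defaults.
#' @param sigma_b City random-intercept standard deviation (log-odds scale).
#' @param segregation_race_coupling Concentration knob in \[0, 1\] for the
#'   race dimension: 0 gives identical expected tract compositions (no
#'   segregation), 1 gives single-group tracts (complete segregation).
#' @param segregation_income_coupling Same knob for the income dimension.
#' @param interaction_dimension Which segregation dimension's tertiles enter
#'   the generating outcome model (`"income"` or `"race"`).
#' @param interaction_gender_multiplier Multiplier applied to the
#'   race-by-tertile interaction coefficients for women (1 = no gender
#'   difference in effect modification).
#' @param female_prob Probability of female gender.
#' @param age_mean,age_sd Mean and SD of the (pre-truncation) age
#'   distribution in years; ages are truncated to \[18, 100\].
#' @param income_missing Fraction of respondents with missing household
#'   income (missing completely at random).
#' @param seed Integer seed; every generator call is fully deterministic
#'   given the seed.
#'
#' @details The generating outcome model is a logistic regression on the
#' linear predictor
#' `intercept + race + age + gender + education + senv + tertile +
#'  race:tertile + b_city`, with age centered at 43 years, reference levels
#' White/male/university/low, `senv` the realized city social-environment
#' index, and `b_city ~ N(0, sigma_b^2)` drawn sum-to-zero across the study's
#' cities. Coefficient names: `intercept`, `brown`, `black`, `age`, `female`,
#' `edu_secondary`, `edu_primary`, `edu_ltp`, `senv`, `tert_medium`,
#' `tert_high`, `brown_med`, `brown_high`, `black_med`, `black_high`.
#'
#' @return An object of class `seg_config` (a list).
#' @export
generative_config <- function(n_cities = 27,
                              tracts_per_city = c(40, 200),
                              persons_per_city = c(641, 3439),
                              race_mix = c(White = 0.416, Brown = 0.482, Black = 0.102),
                              beta = NULL,
                              sigma_b = 0.3,
                              segregation_race_coupling = 0.45,
                              segregation_income_coupling = 0.66,
                              interaction_dimension = c("income", "race"),
                              interaction_gender_multiplier = 1,
                              female_prob = 0.58,
                              age_mean = 43, age_sd = 16.5,
                              income_missing = 0.381,
                              seed = 1L) {
  interaction_dimension <- match.arg(interaction_dimension)
  default_beta <- c(
    intercept = -1.76, brown = 0.18, black = 0.30, age = 0.025, female = 0.25,
    edu_secondary = 0.30, edu_primary = 0.55, edu_ltp = 0.85,
    senv = -0.20, tert_medium = 0.10, tert_high = 0.20,
    brown_med = 0.08, brown_high = 0.15, black_med = 0.10, black_high = 0.25
  )
  if (!is.null(beta)) {
    unknown <- setdiff(names(beta), names(default_beta))
    if (length(unknown) > 0) {
      stop("unknown beta name(s): ", paste(unknown, collapse = ", "))
    }
    default_beta[names(beta)] <- beta
  }
  stopifnot(
    length(race_mix) == 3, abs(sum(race_mix) - 1) < 1e-8, all(race_mix >= 0),
    sigma_b >= 0,
    segregation_race_coupling >= 0, segregation_race_coupling <= 1,
    segregation_income_coupling >= 0, segregation_income_coupling <= 1,
    length(tracts_per_city) == 2, tracts_per_city[1] >= 2,
    tracts_per_city[2] >= tracts_per_city[1],
    length(persons_per_city) == 2, persons_per_city[1] >= 1,
    persons_per_city[2] >= persons_per_city[1]
  )
  structure(list(
    n_cities = as.integer(n_cities),
    tracts_per_city = as.integer(tracts_per_city),
    persons_per_city = as.integer(persons_per_city),
    race_mix = stats::setNames(as.numeric(race_mix), c("White", "Brown", "Black")),
    beta = default_beta,
    sigma_b = sigma_b,
    segregation_race_coupling = segregation_race_coupling,
    segregation_income_coupling = segregation_income_coupling,
    interaction_dimension = interaction_dimension,
    interaction_gender_multiplier = interaction_gender_multiplier,
    female_prob = female_prob,
    age_mean = age_mean, age_sd = age_sd,
    income_missing = income_missing,
    seed = as.integer(seed)
  ), class = "seg_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Tract-level group shares for one city from the two-parameter concentration
# family: mean share rho, coupling kappa in [0,1]. kappa = 0 gives identical
# shares, kappa = 1 single-group tracts, in between a Beta distribution with
# total concentration alpha = 8 * (1 - kappa) / kappa.
draw_tract_shares <- function(n, rho, kappa) {
  if (kappa < 1e-9) {
    rep(rho, n)
  } else if (kappa > 1 - 1e-9) {
    stats::rbinom(n, 1, rho)
  } else {
    alpha <- 8 * (1 - kappa) / kappa
    stats::rbeta(n, rho * alpha, (1 - rho) * alpha)
  }
}

#' Generate census-tract tables and city indicators
#'
#' Per city, tract-level group shares are drawn from a concentration family
#' whose dispersion is controlled by the coupling knobs, so the resulting
#' dissimilarity index increases monotonically in the coupling. Each city
#' gets its own effective coupling (`coupling^g`, `g ~ U(0.5, 2)`) so index
#' values spread across cities and tertiles are meaningful. Income-dimension
#' tract shares are drawn from their own family and mildly blended with the
#' race shares, yielding a small cross-dimension correlation between the two
#' indices. City indicator percentages are drawn correlated with segregation
#' so that more segregated cities score higher on the social-environment
#' composite.
#'
#' @param config A [generative_config()].
#' @return List with `tracts_income`, `tracts_race` (tract tables) and
#'   `indicators` (city indicator table).
#' @export
generate_tracts <- function(config) {
  stopifnot(inherits(config, "seg_config"))
  set.seed(config$seed)
  nc <- config$n_cities
  city_ids <- sprintf("city%02d", seq_len(nc))
  n_tr <- sample(seq(config$tracts_per_city[1], config$tracts_per_city[2]),
                 nc, replace = TRUE)
  rho_race <- clamp(stats::rbeta(nc, 0.584 * 25, (1 - 0.584) * 25), 0.05, 0.95)
  rho_inc <- clamp(stats::rbeta(nc, 0.374 * 30, (1 - 0.374) * 30), 0.05, 0.95)
  g_race <- stats::runif(nc, 0.5, 2)
  g_inc <- stats::runif(nc, 0.5, 2)
  kap_race <- config$segregation_race_coupling ^ g_race
  kap_inc <- config$segregation_income_coupling ^ g_inc

  race_list <- vector("list", nc)
  inc_list <- vector("list", nc)
  for (c in seq_len(nc)) {
    n <- n_tr[c]
    h <- sample(250:350, n, replace = TRUE)
    s <- draw_tract_shares(n, rho_race[c], kap_race[c])
    # at the degenerate knob settings counts are deterministic given shares,
    # so coupling 0 gives an evenness index of ~0 and coupling 1 exactly 1
    a <- if (kap_race[c] > 1 - 1e-9 || kap_race[c] < 1e-9) {
      as.integer(round(h * s))
    } else stats::rbinom(n, h, s)
    # guard: each city must contain both groups
    if (sum(a) == 0) a[1] <- max(1L, round(h[1] * rho_race[c]))
    if (sum(h - a) == 0) a[n] <- min(a[n], h[n] - max(1L, round(h[n] * (1 - rho_race[c]))))
    race_list[[c]] <- data.frame(
      city_id = city_ids[c], tract_id = sprintf("t%04d", seq_len(n)),
      group_a_count = a, group_b_count = h - a, stringsAsFactors = FALSE
    )
    t0 <- draw_tract_shares(n, rho_inc[c], kap_inc[c])
    # mild blend with the race shares -> small cross-dimension correlation
    t1 <- stats::plogis(0.85 * stats::qlogis(clamp(t0, 0.001, 0.999)) +
                        0.15 * stats::qlogis(clamp(s, 0.001, 0.999)))
    ai <- if (kap_inc[c] < 1e-9 && config$segregation_race_coupling < 1e-9) {
      as.integer(round(h * t1))
    } else stats::rbinom(n, h, t1)
    if (sum(ai) == 0) ai[1] <- max(1L, round(h[1] * rho_inc[c]))
    if (sum(h - ai) == 0) ai[n] <- min(ai[n], h[n] - max(1L, round(h[n] * (1 - rho_inc[c]))))
    inc_list[[c]] <- data.frame(
      city_id = city_ids[c], tract_id = sprintf("t%04d", seq_len(n)),
      group_a_count = ai, group_b_count = h - ai, stringsAsFactors = FALSE
    )
  }
  tracts_race <- do.call(rbind, race_list)
  tracts_income <- do.call(rbind, inc_list)

  di_inc <- segregation_by_dimension(tracts_income, "income")$value
  di_rac <- segregation_by_dimension(tracts_race, "race")$value
  zi <- if (stats::sd(di_inc) > 0) as.numeric(scale(di_inc)) else rep(0, nc)
  zr <- if (stats::sd(di_rac) > 0) as.numeric(scale(di_rac)) else rep(0, nc)
  base <- 0.5 * zi + 0.3 * zr + stats::rnorm(nc, 0, 0.8)
  indicators <- data.frame(
    city_id = city_ids,
    pct_primary_education_25plus = clamp(55 + 10 * base + stats::rnorm(nc, 0, 3), 0, 100),
    pct_piped_water = clamp(92 + 4 * base + stats::rnorm(nc, 0, 2), 0, 100),
    pct_sewage_network = clamp(70 + 12 * base + stats::rnorm(nc, 0, 5), 0, 100),
    pct_crowded_households = clamp(8 - 2.5 * base + stats::rnorm(nc, 0, 1.5), 0, 100),
    stringsAsFactors = FALSE
  )
  list(tracts_income = tracts_income, tracts_race = tracts_race,
       indicators = indicators)
}

# Generating linear predictor (excluding the city random intercept) for a
# person table joined with context. Race and tertile can be overridden to
# compute counterfactual predictors.
generating_eta <- function(persons, config, race = NULL, tertile = NULL) {
  b <- config$beta
  race <- race %||% as.character(persons$race)
  tertile <- tertile %||% as.character(persons$seg_tertile)
  mult <- ifelse(persons$gender == "female",
                 config$interaction_gender_multiplier, 1)
  eta <- b[["intercept"]] +
    b[["brown"]] * (race == "Brown") + b[["black"]] * (race == "Black") +
    b[["age"]] * (persons$age - AGE_CENTER) +
    b[["female"]] * (persons$gender == "female") +
    b[["edu_secondary"]] * (persons$education == "secondary") +
    b[["edu_primary"]] * (persons$education == "primary") +
    b[["edu_ltp"]] * (persons$education == "less_than_primary") +
    b[["senv"]] * persons$senv +
    b[["tert_medium"]] * (tertile == "medium") +
    b[["tert_high"]] * (tertile == "high") +
    mult * (b[["brown_med"]] * (race == "Brown") * (tertile == "medium") +
            b[["brown_high"]] * (race == "Brown") * (tertile == "high") +
            b[["black_med"]] * (race == "Black") * (tertile == "medium") +
            b[["black_high"]] * (race == "Black") * (tertile == "high"))
  as.numeric(eta)
}

# Covariate generation shared by generate_persons() and true_marginals().
# Returns the person table (with senv and seg_tertile columns joined) but no
# outcome.
generate_covariates <- function(config, context) {
  nc <- nrow(context)
  rng <- config$persons_per_city
  meanlog <- mean(log(rng))
  n_c <- round(exp(stats::rnorm(nc, meanlog, 0.35)))
  n_c <- as.integer(clamp(n_c, rng[1], rng[2]))
  n <- sum(n_c)
  city <- rep(context$city_id, times = n_c)
  idx <- rep(seq_len(nc), times = n_c)

  # survey race composition follows each city's census composition, recentered
  # (size-weighted) so the study-wide race mix hits the configured target
  target_nonwhite <- sum(config$race_mix[c("Brown", "Black")])
  w <- n_c / n
  share <- context$nonwhite_share
  if (target_nonwhite %in% c(0, 1)) {
    p_c <- rep(target_nonwhite, nc)   # degenerate mixtures are exact
  } else {
    p_c <- clamp(share + (target_nonwhite - sum(w * share)), 0.02, 0.98)
  }
  nonwhite <- stats::rbinom(n, 1, p_c[idx])
  brown_frac <- if (target_nonwhite > 0) {
    config$race_mix[["Brown"]] / target_nonwhite
  } else 0
  race <- ifelse(nonwhite == 1,
                 ifelse(stats::runif(n) < brown_frac, "Brown", "Black"),
                 "White")

  lo <- stats::pnorm(18, config$age_mean, config$age_sd)
  hi <- stats::pnorm(100, config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd)
  gender <- ifelse(stats::runif(n) < config$female_prob, "female", "male")

  senv <- context$social_environment_index[idx]
  z_race <- c(White = 0.35, Brown = -0.20, Black = -0.35)[race]
  u <- z_race + 0.3 * senv + stats::rnorm(n)
  education <- cut(u, breaks = c(-Inf, -0.715, -0.05, 1.10, Inf),
                   labels = c("less_than_primary", "primary", "secondary",
                              "university"))
  education <- factor(as.character(education), levels = seg_levels$education)

  edu_rank <- c(university = 1.5, secondary = 0.5, primary = -0.5,
                less_than_primary = -1.5)[as.character(education)]
  latent_inc <- 0.8 * edu_rank + 0.3 * senv + stats::rnorm(n)
  income_tertile <- cut(latent_inc,
                        breaks = stats::quantile(latent_inc, c(0, 1/3, 2/3, 1)),
                        labels = c("low", "medium", "high"),
                        include.lowest = TRUE)
  income_tertile <- factor(as.character(income_tertile), levels = seg_levels$tertile)
  income_tertile[stats::runif(n) < config$income_missing] <- NA

  tert_col <- if (config$interaction_dimension == "income") "tertile_income" else "tertile_race"
  data.frame(
    person_id = sprintf("p%07d", seq_len(n)),
    city_id = city,
    race = factor(race, levels = seg_levels$race),
    age = age,
    gender = factor(gender, levels = seg_levels$gender),
    education = education,
    income_tertile = income_tertile,
    senv = senv,
    seg_tertile = factor(as.character(context[[tert_col]])[idx],
                         levels = seg_levels$tertile),
    stringsAsFactors = FALSE
  )
}

#' Generate individual survey records with known ground truth
#'
#' Draws respondents city by city (race composition tied to the city's census
#' composition, ages truncated-normal, education dependent on race and city
#' context to create confounding), then generates the binary fair/poor
#' self-rated-health outcome from the configured logistic model with
#' sum-to-zero city random intercepts.
#'
#' @param config A [generative_config()].
#' @param context City context table from [build_city_context()] applied to
#'   [generate_tracts()] output.
#' @return List with `persons` (a `PersonTable` data frame; the helper
#'   columns `senv` and `seg_tertile` carry the generating city context) and
#'   `truth` (generating coefficients, sigma_b, realized city intercepts and
#'   the config).
#' @export
generate_persons <- function(config, context) {
  stopifnot(inherits(config, "seg_config"))
  need <- c("city_id", "social_environment_index", "nonwhite_share",
            "tertile_income", "tertile_race")
  miss <- setdiff(need, names(context))
  if (length(miss) > 0) stop("context is missing column(s): ", paste(miss, collapse = ", "))
  set.seed(config$seed + 1L)
  persons <- generate_covariates(config, context)
  nc <- nrow(context)
  b_c <- stats::rnorm(nc, 0, config$sigma_b)
  if (config$sigma_b > 0) b_c <- (b_c - mean(b_c)) / stats::sd(b_c) * config$sigma_b
  eta <- generating_eta(persons, config) + b_c[match(persons$city_id, context$city_id)]
  persons$srh_fair_poor <- stats::rbinom(nrow(persons), 1, stats::plogis(eta))
  list(
    persons = persons,
    truth = list(beta = config$beta, sigma_b = config$sigma_b,
                 b_city = stats::setNames(b_c, context$city_id),
                 config = config)
  )
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_tracts()], [build_city_context()]
#' and [generate_persons()] in sequence.
#'
#' @param config A [generative_config()].
#' @return List with `tracts_income`, `tracts_race`, `indicators`, `context`,
#'   `persons`, `truth`.
#' @export
simulate_study <- function(config = generative_config()) {
  g <- generate_tracts(config)
  ctx <- build_city_context(g$tracts_income, g$tracts_race, g$indicators)
  pp <- generate_persons(config, ctx)
  list(tracts_income = g$tracts_income, tracts_race = g$tracts_race,
       indicators = g$indicators, context = ctx,
       persons = pp$persons, truth = pp$truth)
}

#' Ground-truth marginal prevalences, PRs and PDs under a configuration
#'
#' Brute-force Monte-Carlo oracle: simulates a large covariate population
#' from the generating distribution (drawing as many cities as needed), then
#' computes, for each race level and each segregation tertile, the exact
#' population-averaged outcome probability under counterfactual assignment
#' of race (and tertile), integrating over the random-intercept distribution
#' by quadrature. These are the estimands that marginal standardization of a
#' correctly specified fitted model targets.
#'
#' @param config A [generative_config()].
#' @param n_persons Approximate number of simulated persons (default 1e6).
#' @return List with `prevalence` (data frame race x stratum, where stratum
#'   `"all"` standardizes race only) and `contrasts` (PR and PD for Brown and
#'   Black vs White per stratum).
#' @export
true_marginals <- function(config, n_persons = 1e6) {
  stopifnot(inherits(config, "seg_config"))
  mean_city <- exp(mean(log(config$persons_per_city)))
  nc <- max(27L, as.integer(ceiling(n_persons / mean_city)))
  big <- config
  big$n_cities <- nc
  big$seed <- config$seed + 500009L
  g <- generate_tracts(big)
  ctx <- build_city_context(g$tracts_income, g$tracts_race, g$indicators)
  set.seed(big$seed + 1L)
  persons <- generate_covariates(big, ctx)

  rule <- gauss_hermite(20)
  strata <- c("all", seg_levels$tertile)
  prev <- matrix(NA_real_, 3, length(strata),
                 dimnames = list(seg_levels$race, strata))
  for (r in seg_levels$race) {
    for (s in strata) {
      tert <- if (s == "all") NULL else rep(s, nrow(persons))
      eta <- generating_eta(persons, big, race = rep(r, nrow(persons)),
                            tertile = tert)
      prev[r, s] <- mean(pop_avg_prob(eta, config$sigma_b, rule = rule))
    }
  }
  prev_df <- data.frame(
    race = rep(rownames(prev), times = ncol(prev)),
    stratum = rep(colnames(prev), each = nrow(prev)),
    prevalence = as.numeric(prev), stringsAsFactors = FALSE
  )
  contr <- do.call(rbind, lapply(c("Brown", "Black"), function(r) {
    data.frame(comparison = r, reference = "White", stratum = strata,
               pr = prev[r, ] / prev["White", ],
               pd = prev[r, ] - prev["White", ],
               stringsAsFactors = FALSE)
  }))
  rownames(contr) <- NULL
  list(prevalence = prev_df, contrasts = contr, n_simulated = nrow(persons))
}
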