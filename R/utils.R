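# Shared helpers: quadrature rule, factor conventions, input validation.

# Canonical factor levels used throughout the package. Reference levels are
# the first entry of each vector (race = White, gender = male,
# education = university, tertile = low).
seg_levels <- list(
  race      = c("White", "Brown", "Black"),
  gender    = c("male", "female"),
  education = c("university", "secondary", "primary", "less_than_primary"),
  tertile   = c("low", "medium", "high")
)

# Age is entered linear and continuous, centered at a fixed constant (years)
# so the intercept refers to a typical adult respondent rather than age 0.
AGE_CENTER <- 43

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int e^{-z^2} g(z) dz \approx \sum_k w_k g(z_k)}
#' (physicists' convention), computed by the Golub-Welsch eigen decomposition
#' of the Jacobi matrix.
#'
#' @param n Number of nodes (positive integer).
#' @return List with `nodes` (increasing) and `weights`; weights sum to
#'   \eqn{\sqrt{\pi}}.
#' @keywords internal
gauss_hermite <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  n <- as.integer(n)
  if (n == 1L) {
    return(list(nodes = 0, weights = sqrt(pi)))
  }
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1L) / 2)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

#' Population-averaged success probability
#'
#' Integrates the inverse-logit of `eta + b` over the random-intercept
#' distribution b ~ N(0, sigma^2) by Gauss-Hermite quadrature.
#'
#' @param eta Numeric vector of linear predictors (log-odds, excluding the
#'   random intercept).
#' @param sigma Random-intercept standard deviation (scalar, >= 0).
#' @param rule Optional quadrature rule from [gauss_hermite()].
#' @param nodes Number of quadrature nodes used when `rule` is NULL.
#' @return Numeric vector of marginal probabilities, same length as `eta`.
#' @export
pop_avg_prob <- function(eta, sigma, rule = NULL, nodes = 12) {
  stopifnot(sigma >= 0)
  if (sigma == 0) {
    return(stats::plogis(as.numeric(eta)))
  }
  if (is.null(rule)) rule <- gauss_hermite(nodes)
  eta <- as.numeric(eta)
  p <- numeric(length(eta))
  for (k in seq_along(rule$nodes)) {
    p <- p + rule$weights[k] * stats::plogis(eta + sqrt(2) * sigma * rule$nodes[k])
  }
  p / sqrt(pi)
}

# Validate a tract table (one or more cities). Returns the data.frame with
# columns coerced to the canonical names, or stops with an informative error.
validate_tract_table <- function(tracts) {
  need <- c("city_id", "tract_id", "group_a_count", "group_b_count")
  miss <- setdiff(need, names(tracts))
  if (length(miss) > 0) {
    stop("tract table is missing column(s): ", paste(miss, collapse = ", "))
  }
  a <- tracts$group_a_count
  b <- tracts$group_b_count
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("tract counts must be finite")
  }
  if (any(a < 0) || any(b < 0)) {
    stop("negative tract count found; counts must be >= 0")
  }
  key <- paste(tracts$city_id, tracts$tract_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (city_id, tract_id) pairs in tract table")
  }
  tracts
}

# Coerce person-level records to canonical types/levels; errors on violations.
validate_person_table <- function(persons) {
  need <- c("person_id", "city_id", "race", "age", "gender", "education",
            "srh_fair_poor")
  miss <- setdiff(need, names(persons))
  if (length(miss) > 0) {
    stop("person table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(persons$srh_fair_poor %in% c(0, 1))) {
    stop("srh_fair_poor must be binary 0/1")
  }
  if (any(persons$age <= 0)) stop("age must be positive")
  persons$race <- factor(as.character(persons$race), levels = seg_levels$race)
  persons$gender <- factor(as.character(persons$gender), levels = seg_levels$gender)
  persons$education <- factor(as.character(persons$education),
                              levels = seg_levels$education)
  if (anyNA(persons$race)) stop("race has values outside ", paste(seg_levels$race, collapse = "/"))
  if (anyNA(persons$gender)) stop("gender has values outside ", paste(seg_levels$gender, collapse = "/"))
  if (anyNA(persons$education)) stop("education has values outside ", paste(seg_levels$education, collapse = "/"))
  persons
}

# Draws from a multivariate normal (df = Inf) or multivariate t given mean
# and covariance; the covariance is eigen-repaired to PSD if a Cholesky
# fails (tiny negative eigenvalues from numerical differentiation are
# clipped at zero). t draws with few degrees of freedom are the standard
# few-cluster calibration for sandwich-based simulation intervals.
rmvnorm_psd <- function(n, mean, sigma, df = Inf) {
  k <- length(mean)
  L <- tryCatch(chol(sigma), error = function(e) {
    e2 <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
    vals <- pmax(e2$values, 0)
    chol(e2$vectors %*% diag(vals + 1e-12, k) %*% t(e2$vectors))
  })
  z <- matrix(stats::rnorm(n * k), k, n)
  if (is.finite(df)) {
    z <- sweep(z, 2, sqrt(stats::rchisq(n, df) / df), `/`)
  }
  sweep(t(L) %*% z, 1, mean, `+`)
}
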