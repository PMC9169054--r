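# Random-intercept (city) logistic regression with city-level cluster-robust
# variance: model specifications, fitting, marginal likelihood by adaptive
# Gauss-Hermite quadrature, sandwich covariance, Wald interaction test.

#' Model specification
#'
#' Builds the fixed-effect term list for the standard model ladder. Model 1
#' adjusts race differences for age and gender; model 2 adds individual
#' education; model 3 adds the city social-environment index; models 4A/4B
#' add income/racial segregation tertiles; models 5A/5B add the
#' race-by-tertile interaction (keeping both main effects). `A` labels refer
#' to the income dimension and `B` to the race dimension. Race is always
#' included with White as the reference level.
#'
#' @param label One of `"1"`, `"2"`, `"3"`, `"4A"`, `"4B"`, `"5A"`, `"5B"`,
#'   or `"custom"`.
#' @param dimension Segregation dimension whose tertiles enter models 4/5;
#'   inferred from an A/B label when missing.
#' @param terms Character vector of fixed-effect terms, required when
#'   `label = "custom"` (e.g. `c("race", "age_c", "seg_tertile",
#'   "race:seg_tertile")`).
#' @return An object of class `seg_model_spec`.
#' @export
model_spec <- function(label, dimension = NULL, terms = NULL) {
  label <- as.character(label)
  if (label == "custom") {
    if (is.null(terms)) stop("custom specs require `terms`")
    dimension <- dimension %||% "none"
  } else {
    if (!label %in% c("1", "2", "3", "4A", "4B", "5A", "5B")) {
      stop("unknown model label '", label, "'")
    }
    stage <- substr(label, 1, 1)
    suffix <- substr(label, 2, 2)
    if (suffix %in% c("A", "B")) {
      dim_from_label <- if (suffix == "A") "income" else "race"
      if (!is.null(dimension) && dimension != dim_from_label) {
        stop("label ", label, " implies dimension '", dim_from_label,
             "' but dimension = '", dimension, "' was given")
      }
      dimension <- dim_from_label
    } else {
      dimension <- dimension %||% "none"
    }
    terms <- switch(stage,
      "1" = c("race", "age_c", "gender"),
      "2" = c("race", "age_c", "gender", "education"),
      "3" = c("race", "age_c", "gender", "education", "senv"),
      "4" = c("race", "age_c", "gender", "education", "senv", "seg_tertile"),
      "5" = c("race", "age_c", "gender", "education", "senv", "seg_tertile",
              "race:seg_tertile")
    )
  }
  uses_tert <- any(grepl("seg_tertile", terms))
  if (uses_tert && !dimension %in% c("income", "race")) {
    stop("specs with segregation terms need dimension 'income' or 'race'")
  }
  structure(list(label = label, dimension = dimension, terms = terms),
            class = "seg_model_spec")
}

# Merge persons with city context and derive model variables. Returns a data
# frame with response, covariates at canonical factor levels, and city_id.
assemble_model_frame <- function(persons, context, spec) {
  persons <- validate_person_table(persons)
  dat <- persons
  if (!is.null(context)) {
    keep <- intersect(c("city_id", "social_environment_index",
                        "tertile_income", "tertile_race"), names(context))
    dat <- merge(dat, context[keep], by = "city_id", sort = FALSE)
    if (nrow(dat) != nrow(persons)) {
      stop("some persons have city_id values absent from the context table")
    }
    dat$senv <- dat$social_environment_index
    if (spec$dimension == "income" && "tertile_income" %in% names(dat)) {
      dat$seg_tertile <- factor(as.character(dat$tertile_income),
                                levels = seg_levels$tertile)
    } else if (spec$dimension == "race" && "tertile_race" %in% names(dat)) {
      dat$seg_tertile <- factor(as.character(dat$tertile_race),
                                levels = seg_levels$tertile)
    }
  }
  vars <- unique(unlist(strsplit(spec$terms, ":", fixed = TRUE)))
  vars <- setdiff(vars, c("1", "0"))
  if ("age_c" %in% vars) dat$age_c <- dat$age - AGE_CENTER
  if ("income_tertile" %in% vars) {
    dat$income_tertile <- factor(as.character(dat$income_tertile),
                                 levels = seg_levels$tertile)
  }
  missing_vars <- setdiff(vars, names(dat))
  if (length(missing_vars) > 0) {
    stop("model variables not available: ", paste(missing_vars, collapse = ", "),
         " (is the context table missing, or the dimension wrong?)")
  }
  # drop factor levels absent from this (possibly stratified) sample so the
  # design stays full rank; reference = first remaining level
  for (v in vars) {
    if (is.factor(dat[[v]])) dat[[v]] <- droplevels(dat[[v]])
  }
  dat$city_id <- as.character(dat$city_id)
  dat
}

# Adaptive Gauss-Hermite evaluation of the marginal likelihood for the
# random-intercept logit model at theta = (beta, log sigma). Per city the
# integrand's mode is found by Newton steps and the rule is centered and
# scaled there. Returns per-city log-likelihood contributions and (if
# `score = TRUE`) the per-city score with respect to (beta, log sigma),
# where the score is the posterior expectation of the complete-data score
# evaluated by the same quadrature rule.
agq_citywise <- function(theta, X, y, ci, G, rule, score = FALSE) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1L])
  eta <- as.numeric(X %*% beta)
  z <- rule$nodes
  w <- rule$weights
  # Newton iterations for all city modes in lockstep
  b <- numeric(G)
  for (it in 1:30) {
    pr <- stats::plogis(eta + b[ci])
    g1 <- as.numeric(rowsum(y - pr, ci)) - b / sigma^2
    wgt <- as.numeric(rowsum(pr * (1 - pr), ci))
    step <- g1 / (-(wgt + 1 / sigma^2))
    if (any(!is.finite(step))) break
    b <- b - step
    if (max(abs(step)) < 1e-10) break
  }
  pr <- stats::plogis(eta + b[ci])
  wgt <- as.numeric(rowsum(pr * (1 - pr), ci))
  tau <- 1 / sqrt(wgt + 1 / sigma^2)                 # G
  bk <- b + sqrt(2) * tau %o% z                      # G x K
  EB <- eta + bk[ci, , drop = FALSE]                 # n x K
  logP <- stats::plogis(EB, log.p = TRUE)
  # log(1 - p) = log p - eta for the logistic link
  hk <- rowsum(logP - (1 - y) * EB, ci) - bk^2 / (2 * sigma^2)  # G x K
  m <- apply(hk, 1, max)
  ck <- sweep(exp(hk - m), 2, w * exp(z^2), `*`)
  sck <- rowSums(ck)
  ll <- log(sqrt(2) * tau) - log(sigma * sqrt(2 * pi)) + m + log(sck)
  S <- NULL
  if (score) {
    pik <- ck / sck                                  # posterior node weights
    resid <- y - rowSums(exp(logP) * pik[ci, , drop = FALSE])
    S <- cbind(rowsum(X * resid, ci),
               rowSums(pik * bk^2) / sigma^2 - 1)
    dimnames(S) <- NULL
  }
  list(loglik = as.numeric(ll), scores = S)
}

agq_citywise_loglik <- function(theta, X, y, ci, G, rule) {
  agq_citywise(theta, X, y, ci, G, rule, score = FALSE)$loglik
}

# City-level score matrix (G x k, analytic via quadrature) and observed
# information (k x k, central differences of the total score).
agq_scores_and_info <- function(theta, X, y, ci, G, rule) {
  k <- length(theta)
  S <- agq_citywise(theta, X, y, ci, G, rule, score = TRUE)$scores
  g_tot <- function(th) {
    colSums(agq_citywise(th, X, y, ci, G, rule, score = TRUE)$scores)
  }
  hstep <- 1e-5 * (1 + abs(theta))
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    tp <- theta; tp[j] <- tp[j] + hstep[j]
    tm <- theta; tm[j] <- tm[j] - hstep[j]
    H[j, ] <- (g_tot(tp) - g_tot(tm)) / (2 * hstep[j])
  }
  list(scores = S, info = -(H + t(H)) / 2)
}

# City-clustered sandwich for an ordinary logistic model (used when the
# random-intercept SD is estimated at the boundary sigma = 0).
glm_cluster_sandwich <- function(X, y, beta, ci, G) {
  pr <- stats::plogis(as.numeric(X %*% beta))
  W <- pr * (1 - pr)
  H <- crossprod(X * W, X)
  S <- rowsum(X * (y - pr), ci)
  S <- sweep(S, 2, colMeans(S))
  Hi <- solve(H)
  V <- Hi %*% (crossprod(S) * G / (G - 1)) %*% Hi
  (V + t(V)) / 2
}

#' Fit a random-intercept logistic regression with robust variance
#'
#' Maximizes the marginal likelihood of the multilevel logistic model with a
#' normally distributed random intercept per city, integrating each city's
#' likelihood contribution over the random intercept by adaptive
#' Gauss-Hermite quadrature (the rule is re-centered and re-scaled at each
#' city's posterior mode). Optimization is quasi-Newton (L-BFGS-B) over
#' (beta, log sigma_b) with analytic quadrature scores, started from an
#' ordinary logistic fit with sigma_b initialized at 0.1. The city-level
#' cluster-robust (sandwich) covariance of the joint parameter vector
#' (beta, log sigma_b) is computed from the per-city scores of the marginal
#' (integrated) log-likelihood. When the random-intercept SD is estimated at
#' the boundary (sigma_b ~ 0) the model reduces to ordinary logistic
#' regression and the sandwich covers beta only.
#'
#' @param persons Person table (see package overview for required columns).
#' @param context City context table from [build_city_context()]; may be NULL
#'   for specs without city-level terms if `persons` already carries `senv` /
#'   `seg_tertile` columns.
#' @param spec A [model_spec()].
#' @param nodes Number of quadrature nodes (default 12).
#' @param robust Compute the cluster-robust covariance (default TRUE). With
#'   FALSE only point estimates, sigma_b and the log-likelihood are returned
#'   (cheaper; enough for point-estimate simulation studies).
#' @return An object of class `ri_logit_fit`: a list with `beta`, `sigma_b`,
#'   `vcov_robust` (over (beta, log sigma_b), or beta only when
#'   `sigma_zero = TRUE`), `vcov_model`, `loglik`, `converged`, `n_obs`,
#'   `n_cities`, `spec`, and design metadata used for prediction.
#' @export
fit_random_intercept_logit <- function(persons, context = NULL, spec,
                                       nodes = 12, robust = TRUE) {
  stopifnot(inherits(spec, "seg_model_spec"))
  dat <- assemble_model_frame(persons, context, spec)
  if (length(unique(dat$city_id)) < 2) stop("need at least 2 cities")
  if (length(unique(dat$srh_fair_poor)) < 2) {
    stop("outcome is degenerate (all 0 or all 1)")
  }
  ff <- stats::reformulate(spec$terms, response = NULL)
  X <- stats::model.matrix(ff, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  n_city_terms <- sum(spec$terms %in% c("senv", "seg_tertile"))
  if (length(unique(dat$city_id)) < n_city_terms + 2) {
    warning("fewer cities than city-level covariates + 2; estimates unstable")
  }
  y <- dat$srh_fair_poor

  cities <- sort(unique(dat$city_id))
  ci <- match(dat$city_id, cities)
  G <- length(cities)
  rule <- gauss_hermite(nodes)

  # starting values: ordinary logistic fit, sigma_b initialized at 0.1
  g0 <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  theta0 <- c(g0$coefficients, log(0.1))
  p <- ncol(X)
  opt <- stats::optim(
    theta0,
    fn = function(th) -sum(agq_citywise(th, X, y, ci, G, rule)$loglik),
    gr = function(th) -colSums(agq_citywise(th, X, y, ci, G, rule,
                                            score = TRUE)$scores),
    method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-10)
  )
  if (opt$convergence != 0) {
    stop("random-intercept fit did not converge (optim code ", opt$convergence,
         "): ", opt$message)
  }
  theta <- opt$par
  sigma_zero <- exp(theta[p + 1L]) < 1e-3
  if (!sigma_zero) {
    # Newton polish on the quadrature score brings the gradient to ~0; the
    # observed information is computed once and reused (it is essentially
    # constant this close to the optimum)
    si <- agq_scores_and_info(theta, X, y, ci, G, rule)
    info <- si$info + diag(1e-8, p + 1L)
    gr <- colSums(si$scores)
    for (it in 1:8) {
      if (max(abs(gr)) < 1e-4) break
      step <- tryCatch(solve(info, gr), error = function(e) NULL)
      if (is.null(step)) break
      cand <- theta + step
      if (-sum(agq_citywise(cand, X, y, ci, G, rule)$loglik) > opt$value + 1e-6) break
      theta <- cand
      gr <- colSums(agq_citywise(theta, X, y, ci, G, rule,
                                 score = TRUE)$scores)
    }
    sigma_zero <- exp(theta[p + 1L]) < 1e-3
  }
  beta <- stats::setNames(theta[seq_len(p)], colnames(X))
  sigma_b <- unname(exp(theta[p + 1L]))
  grad <- colSums(agq_citywise(theta, X, y, ci, G, rule,
                               score = TRUE)$scores)
  grad_check <- if (sigma_zero) grad[seq_len(p)] else grad
  converged <- max(abs(grad_check)) < 0.1
  if (!converged && !sigma_zero) {
    warning("score not sufficiently close to zero at the optimum (max |grad| = ",
            signif(max(abs(grad_check)), 3), ")")
  }
  if (sigma_zero) {
    # boundary: model reduces to ordinary logistic regression
    beta <- stats::setNames(g0$coefficients, colnames(X))
    sigma_b <- 0
    converged <- g0$converged
  }
  vcov_robust <- NULL
  vcov_model <- NULL
  if (sigma_zero) {
    ll <- sum(y * log(stats::plogis(X %*% beta)) +
              (1 - y) * log1p(-stats::plogis(X %*% beta)))
    if (robust) {
      vcov_robust <- glm_cluster_sandwich(X, y, beta, ci, G)
      pr <- stats::plogis(as.numeric(X %*% beta))
      vcov_model <- solve(crossprod(X * (pr * (1 - pr)), X))
      dimnames(vcov_robust) <- dimnames(vcov_model) <-
        list(names(beta), names(beta))
    }
  } else {
    theta <- c(beta, log(sigma_b))
    ll <- sum(agq_citywise_loglik(theta, X, y, ci, G, rule))
    if (robust) {
      si <- agq_scores_and_info(theta, X, y, ci, G, rule)
      Hi <- solve(si$info)
      S <- sweep(si$scores, 2, colMeans(si$scores))
      vcov_robust <- Hi %*% (crossprod(S) * G / (G - 1)) %*% Hi
      vcov_robust <- (vcov_robust + t(vcov_robust)) / 2
      vcov_model <- (Hi + t(Hi)) / 2
      nms <- c(names(beta), "log_sigma_b")
      dimnames(vcov_robust) <- dimnames(vcov_model) <- list(nms, nms)
    }
  }

  structure(list(
    spec = spec,
    beta = beta,
    sigma_b = sigma_b,
    sigma_zero = sigma_zero,
    vcov_robust = vcov_robust,
    vcov_model = vcov_model,
    loglik = ll,
    converged = converged,
    n_obs = nrow(dat),
    n_cities = length(cities),
    nodes = nodes,
    design_info = list(
      formula = ff,
      terms = stats::terms(ff, data = dat),
      xlevels = stats::.getXlevels(stats::terms(ff, data = dat), dat),
      coef_names = colnames(X),
      age_center = AGE_CENTER
    ),
    context = context
  ), class = "ri_logit_fit")
}

#' @export
print.ri_logit_fit <- function(x, ...) {
  cat("Random-intercept logistic fit (model ", x$spec$label,
      if (x$spec$dimension != "none") paste0(", ", x$spec$dimension, " segregation"),
      ")\n", sep = "")
  cat(sprintf("  n = %d persons in %d cities; logLik = %.2f; sigma_b = %.4f%s\n",
              x$n_obs, x$n_cities, x$loglik, x$sigma_b,
              if (x$sigma_zero) " (boundary)" else ""))
  est <- x$beta
  if (!is.null(x$vcov_robust)) {
    se <- sqrt(diag(x$vcov_robust))[seq_along(est)]
    print(round(cbind(estimate = est, robust_se = se), 4))
  } else {
    print(round(est, 4))
  }
  invisible(x)
}

#' Fit the standard model ladder for one segregation dimension
#'
#' Fits models 1, 2, 3, then 4A/5A (income) or 4B/5B (race), reusing the same
#' sample. A fit failure yields an entry of class `ri_logit_failure` instead
#' of aborting the whole ladder.
#'
#' @inheritParams fit_random_intercept_logit
#' @param dimension `"income"` or `"race"`.
#' @return Named list of `ri_logit_fit` objects (or failure markers), in
#'   ladder order.
#' @export
model_sequence <- function(persons, context, dimension = c("income", "race"),
                           nodes = 12, robust = TRUE) {
  dimension <- match.arg(dimension)
  suffix <- if (dimension == "income") "A" else "B"
  labels <- c("1", "2", "3", paste0("4", suffix), paste0("5", suffix))
  fits <- lapply(labels, function(lb) {
    tryCatch(
      fit_random_intercept_logit(persons, context,
                                 model_spec(lb, dimension = dimension),
                                 nodes = nodes, robust = robust),
      error = function(e) structure(list(label = lb, error = conditionMessage(e)),
                                    class = "ri_logit_failure")
    )
  })
  stats::setNames(fits, labels)
}

#' Joint Wald test of the race-by-segregation interaction
#'
#' Tests, with the city-level cluster-robust covariance, the null hypothesis
#' that all race-by-tertile interaction coefficients are zero. Because the
#' robust covariance is estimated from a modest number of city clusters, the
#' Wald quadratic form W is referred to an F(q, G - 1) distribution via
#' W / q, the standard few-cluster reference, rather than to chi-squared;
#' `statistic` reports W itself.
#'
#' @param fitted An `ri_logit_fit` containing interaction terms.
#' @param coefs Optional character vector of coefficient names to test
#'   jointly; defaults to every race-by-tertile interaction coefficient.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
interaction_wald_test <- function(fitted, coefs = NULL) {
  stopifnot(inherits(fitted, "ri_logit_fit"))
  if (is.null(fitted$vcov_robust)) {
    stop("fit was computed with robust = FALSE; refit with robust = TRUE")
  }
  idx <- if (is.null(coefs)) {
    grep("^race[^:]*:seg_tertile|^seg_tertile[^:]*:race", names(fitted$beta))
  } else {
    match(coefs, names(fitted$beta))
  }
  if (anyNA(idx)) stop("unknown coefficient name(s)")
  if (length(idx) == 0) stop("model contains no race x segregation interaction terms")
  b <- fitted$beta[idx]
  V <- fitted$vcov_robust[idx, idx, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  df <- length(idx)
  list(statistic = stat, df = df,
       p_value = stats::pf(stat / df, df, fitted$n_cities - 1,
                           lower.tail = FALSE))
}
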