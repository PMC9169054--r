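# Marginal standardization: standardized prevalences, prevalence ratios and
# prevalence differences with Monte-Carlo confidence intervals.

# Rebuild the fixed-effects design matrix of a fit on (possibly
# counterfactually modified) data, using the stored terms and factor levels.
build_design <- function(fitted, dat) {
  tt <- stats::delete.response(fitted$design_info$terms)
  mf <- stats::model.frame(tt, dat, xlev = fitted$design_info$xlevels)
  X <- stats::model.matrix(tt, mf)
  if (!identical(colnames(X), fitted$design_info$coef_names)) {
    stop("design columns changed between fit and prediction")
  }
  X
}

# Counterfactually set race (and optionally the segregation tertile) in an
# assembled model frame.
counterfactual_frame <- function(fitted, persons, at) {
  dat <- assemble_model_frame(persons, fitted$context, fitted$spec)
  for (v in names(at)) {
    lev <- at[[v]]
    if (!v %in% names(dat)) stop("variable '", v, "' not in the model data")
    if (is.factor(dat[[v]])) {
      if (!lev %in% levels(dat[[v]])) {
        stop("level '", lev, "' not a level of '", v, "'")
      }
      dat[[v]] <- factor(rep(lev, nrow(dat)), levels = levels(dat[[v]]))
    } else {
      dat[[v]] <- rep(lev, nrow(dat))
    }
  }
  dat
}

#' Marginally standardized prevalence
#'
#' Counterfactually sets race (and, for interaction models, the segregation
#' tertile) to the requested level for *every* person in the sample, keeps
#' all other covariates at their observed values, computes each person's
#' population-averaged probability of the outcome (integrating the
#' inverse-logit over the random-intercept distribution by Gauss-Hermite
#' quadrature), and averages over the sample. This standardizes the estimate
#' to the covariate distribution of the full study sample.
#'
#' @param fitted A converged `ri_logit_fit`.
#' @param persons Person table the fit was built from (the standardization
#'   population).
#' @param set_race Race level to assign (`"White"`, `"Brown"`, `"Black"`),
#'   or NULL to keep observed race.
#' @param set_stratum Optional segregation tertile to assign (only for models
#'   with segregation terms).
#' @param conditional If TRUE, predict at the cluster average (random
#'   intercept fixed at 0) instead of integrating over it.
#' @return A single probability in \[0, 1\].
#' @export
standardized_prevalence <- function(fitted, persons, set_race = NULL,
                                    set_stratum = NULL, conditional = FALSE) {
  stopifnot(inherits(fitted, "ri_logit_fit"))
  if (!fitted$converged) stop("fit did not converge; refusing to standardize")
  at <- list()
  if (!is.null(set_race)) at$race <- set_race
  if (!is.null(set_stratum)) {
    if (!any(grepl("seg_tertile", fitted$spec$terms))) {
      stop("stratum requested but the model has no segregation terms")
    }
    at$seg_tertile <- set_stratum
  }
  dat <- counterfactual_frame(fitted, persons, at)
  eta <- as.numeric(build_design(fitted, dat) %*% fitted$beta)
  sigma <- if (conditional) 0 else fitted$sigma_b
  mean(pop_avg_prob(eta, sigma, nodes = fitted$nodes))
}

# Standardized prevalences for a set of (race, stratum) cells under a
# parameter matrix Theta (k x n_draws, rows = beta then optionally
# log sigma). Returns a cells x n_draws matrix. Chunked over draws.
prevalence_draws <- function(fitted, persons, cells, Theta, conditional = FALSE,
                             chunk = 250L) {
  p <- length(fitted$beta)
  has_sigma <- nrow(Theta) == p + 1L
  rule <- gauss_hermite(fitted$nodes)
  Xs <- lapply(cells, function(cl) {
    build_design(fitted, counterfactual_frame(fitted, persons, cl))
  })
  n <- nrow(Xs[[1]])
  nd <- ncol(Theta)
  out <- matrix(NA_real_, length(cells), nd)
  for (start in seq(1, nd, by = chunk)) {
    cols <- start:min(start + chunk - 1L, nd)
    B <- Theta[seq_len(p), cols, drop = FALSE]
    sig <- if (has_sigma && !conditional) exp(Theta[p + 1L, cols]) else rep(0, length(cols))
    for (ci in seq_along(cells)) {
      E <- Xs[[ci]] %*% B
      if (all(sig == 0)) {
        out[ci, cols] <- colMeans(stats::plogis(E))
      } else {
        # plogis(E + off_k) = 1 / (1 + exp(-E) * exp(-off_k)): one big exp,
        # then cheap column scalings per quadrature node
        W <- exp(-E)
        acc <- numeric(length(cols))
        for (k in seq_along(rule$nodes)) {
          sk <- exp(-sqrt(2) * sig * rule$nodes[k])
          acc <- acc + (rule$weights[k] / sqrt(pi)) *
            colMeans(1 / (1 + W * rep(sk, each = n)))
        }
        out[ci, cols] <- acc
      }
    }
  }
  out
}

#' Marginal prevalence ratios and differences with Monte-Carlo CIs
#'
#' For each comparison race level (default Brown and Black) versus the
#' reference, computes the marginally standardized prevalence ratio
#' PR = p(comparison) / p(reference) and prevalence difference
#' PD = p(comparison) - p(reference), overall or within requested segregation
#' strata. 95% confidence intervals are obtained by drawing parameter vectors
#' from the asymptotic sampling distribution centered at (beta, log sigma_b)
#' with the city-level cluster-robust covariance, recomputing every
#' standardized quantity per draw, and taking the 2.5/97.5 percentiles.
#'
#' @inheritParams standardized_prevalence
#' @param reference Reference race level (default `"White"`).
#' @param comparisons Comparison race levels.
#' @param strata NULL for overall contrasts, or a character vector of
#'   tertiles (e.g. `c("low", "medium", "high")`) for stratified contrasts
#'   from interaction models.
#' @param draws Number of Monte-Carlo draws (>= 100; default 1000).
#' @param seed Integer seed for the draws; recorded in the output.
#' @param conditional Predict at random intercept 0 rather than integrating.
#' @return Data frame of `MarginalEstimate` rows: standardized prevalences
#'   for each race level, plus PR and PD rows for each comparison, with
#'   `ci_low`/`ci_high`, `n_draws`, `seed`, `stratum` (NA for overall) and
#'   `model_label`.
#' @export
marginal_contrasts <- function(fitted, persons, reference = "White",
                               comparisons = setdiff(seg_levels$race, reference),
                               strata = NULL, draws = 1000, seed = 1,
                               conditional = FALSE) {
  stopifnot(inherits(fitted, "ri_logit_fit"))
  if (!fitted$converged) stop("fit did not converge")
  if (draws < 100) stop("at least 100 draws are required for stable percentiles")
  if (is.null(fitted$vcov_robust)) {
    stop("fit was computed with robust = FALSE; refit with robust = TRUE")
  }
  races <- unique(c(reference, comparisons))
  strata_list <- if (is.null(strata)) list(NULL) else as.list(strata)
  cells <- list()
  meta <- list()
  for (s in strata_list) {
    for (r in races) {
      cl <- list(race = r)
      if (!is.null(s)) cl$seg_tertile <- s
      cells[[length(cells) + 1L]] <- cl
      meta[[length(meta) + 1L]] <- list(race = r, stratum = s %||% NA_character_)
    }
  }

  p <- length(fitted$beta)
  theta_hat <- if (fitted$sigma_zero) fitted$beta else c(fitted$beta, log(fitted$sigma_b))
  point <- prevalence_draws(fitted, persons, cells,
                            matrix(theta_hat, ncol = 1), conditional = conditional)

  set.seed(seed)
  Theta <- rmvnorm_psd(draws, theta_hat, fitted$vcov_robust,
                       df = fitted$n_cities - 1)
  P <- prevalence_draws(fitted, persons, cells, Theta, conditional = conditional)

  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  rows <- list()
  cell_key <- vapply(meta, function(m) paste(m$race, m$stratum), character(1))
  find <- function(r, s) which(cell_key == paste(r, s %||% NA_character_))
  for (s in strata_list) {
    s_chr <- s %||% NA_character_
    for (r in races) {
      i <- find(r, s)
      ci <- qs(P[i, ])
      rows[[length(rows) + 1L]] <- data.frame(
        model_label = fitted$spec$label, contrast_type = "prevalence",
        comparison = r, reference = NA_character_, stratum = s_chr,
        estimate = point[i, 1], ci_low = ci[1], ci_high = ci[2],
        n_draws = draws, seed = seed, stringsAsFactors = FALSE
      )
    }
    iref <- find(reference, s)
    for (r in comparisons) {
      i <- find(r, s)
      pr_d <- P[i, ] / P[iref, ]
      pd_d <- P[i, ] - P[iref, ]
      ci_pr <- qs(pr_d); ci_pd <- qs(pd_d)
      rows[[length(rows) + 1L]] <- data.frame(
        model_label = fitted$spec$label, contrast_type = "PR",
        comparison = r, reference = reference, stratum = s_chr,
        estimate = point[i, 1] / point[iref, 1],
        ci_low = ci_pr[1], ci_high = ci_pr[2],
        n_draws = draws, seed = seed, stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- data.frame(
        model_label = fitted$spec$label, contrast_type = "PD",
        comparison = r, reference = reference, stratum = s_chr,
        estimate = point[i, 1] - point[iref, 1],
        ci_low = ci_pd[1], ci_high = ci_pd[2],
        n_draws = draws, seed = seed, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardized prevalence by race and segregation tertile
#'
#' The 3 x 3 grid of marginally standardized prevalences (race by tertile)
#' from an interaction model, with Monte-Carlo confidence intervals; the
#' shape behind a prevalence-by-race-and-segregation figure.
#'
#' @inheritParams marginal_contrasts
#' @return Data frame of 9 prevalence rows (race x tertile).
#' @export
prevalence_by_race_and_tertile <- function(fitted, persons, draws = 1000,
                                           seed = 1) {
  if (!any(grepl(":", fitted$spec$terms))) {
    stop("an interaction model (5A/5B) is required")
  }
  out <- marginal_contrasts(fitted, persons, strata = seg_levels$tertile,
                            draws = draws, seed = seed)
  out[out$contrast_type == "prevalence", ]
}

#' Marginal contrasts of segregation tertiles
#'
#' Standardized PR and PD for medium and high segregation versus low, with
#' race and all other covariates at observed values (the tertile rows of a
#' model-4 style table).
#'
#' @inheritParams marginal_contrasts
#' @return Data frame of MarginalEstimate rows.
#' @export
tertile_contrasts <- function(fitted, persons, draws = 1000, seed = 1) {
  stopifnot(inherits(fitted, "ri_logit_fit"))
  if (!any(grepl("seg_tertile", fitted$spec$terms))) {
    stop("model has no segregation terms")
  }
  if (draws < 100) stop("at least 100 draws are required for stable percentiles")
  cells <- lapply(seg_levels$tertile, function(t) list(seg_tertile = t))
  theta_hat <- if (fitted$sigma_zero) fitted$beta else c(fitted$beta, log(fitted$sigma_b))
  point <- prevalence_draws(fitted, persons, cells, matrix(theta_hat, ncol = 1))
  set.seed(seed)
  Theta <- rmvnorm_psd(draws, theta_hat, fitted$vcov_robust,
                       df = fitted$n_cities - 1)
  P <- prevalence_draws(fitted, persons, cells, Theta)
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  rows <- list()
  for (j in 2:3) {
    pr_d <- P[j, ] / P[1, ]; pd_d <- P[j, ] - P[1, ]
    rows[[length(rows) + 1L]] <- data.frame(
      model_label = fitted$spec$label, contrast_type = "PR",
      comparison = seg_levels$tertile[j], reference = "low",
      stratum = NA_character_, estimate = point[j, 1] / point[1, 1],
      ci_low = qs(pr_d)[1], ci_high = qs(pr_d)[2],
      n_draws = draws, seed = seed, stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <- data.frame(
      model_label = fitted$spec$label, contrast_type = "PD",
      comparison = seg_levels$tertile[j], reference = "low",
      stratum = NA_character_, estimate = point[j, 1] - point[1, 1],
      ci_low = qs(pd_d)[1], ci_high = qs(pd_d)[2],
      n_draws = draws, seed = seed, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
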