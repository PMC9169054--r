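# Full-analysis orchestration: descriptive tables, model ladders, stratified
# contrasts, prevalence grids, sensitivity runs, and output writing.

#' Descriptive table by segregation tertile
#'
#' Summarizes the sample within each tertile of one segregation dimension:
#' percent fair/poor self-rated health, race distribution, mean (SD) age,
#' percent male, education distribution, and mean (SD) city
#' social-environment index. Differences across tertiles are tested with
#' chi-squared tests (categorical) and one-way analysis of variance
#' (continuous).
#'
#' @param persons Person table.
#' @param context City context table from [build_city_context()].
#' @param dimension `"income"` or `"race"`.
#' @return Data frame in long form: `variable`, `level`, one column per
#'   tertile (`low`, `medium`, `high`), `statistic` (`"percent"` or
#'   `"mean_sd"`), and the test `p_value` (repeated within a variable).
#' @export
descriptive_table <- function(persons, context, dimension = c("income", "race")) {
  dimension <- match.arg(dimension)
  persons <- validate_person_table(persons)
  tert_col <- paste0("tertile_", dimension)
  dat <- merge(persons,
               context[, c("city_id", tert_col, "social_environment_index")],
               by = "city_id")
  dat$tertile <- factor(as.character(dat[[tert_col]]), levels = seg_levels$tertile)
  if (any(table(dat$tertile) == 0)) stop("empty segregation tertile")

  rows <- list()
  add_cat <- function(variable, x) {
    tab <- table(x, dat$tertile)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    pct <- prop.table(tab, margin = 2) * 100
    for (lev in rownames(pct)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, level = lev,
        low = pct[lev, "low"], medium = pct[lev, "medium"], high = pct[lev, "high"],
        statistic = "percent", p_value = p, stringsAsFactors = FALSE
      )
    }
  }
  add_cont <- function(variable, x) {
    p <- stats::anova(stats::lm(x ~ dat$tertile))[["Pr(>F)"]][1]
    m <- tapply(x, dat$tertile, mean)
    s <- tapply(x, dat$tertile, stats::sd)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = "mean",
      low = m[["low"]], medium = m[["medium"]], high = m[["high"]],
      statistic = "mean_sd", p_value = p, stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = "sd",
      low = s[["low"]], medium = s[["medium"]], high = s[["high"]],
      statistic = "mean_sd", p_value = p, stringsAsFactors = FALSE
    )
  }
  add_cat("srh_fair_poor", factor(dat$srh_fair_poor, levels = c(0, 1)))
  add_cat("race", dat$race)
  add_cont("age", dat$age)
  add_cat("gender", dat$gender)
  add_cat("education", dat$education)
  add_cont("social_environment_index", dat$social_environment_index)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full segregation / self-rated-health analysis
#'
#' Orchestrates the whole chain: dissimilarity indices and tertiles for both
#' dimensions, the city social-environment index, the model ladder per
#' dimension, overall and stratified marginal contrasts, the
#' prevalence-by-race-and-tertile grids, interaction Wald tests, and
#' descriptive tables. Outputs are optionally written as CSV files plus a
#' JSON run manifest.
#'
#' @param persons Person table.
#' @param tracts List with elements `income` and `race`, each a tract table.
#' @param indicators City indicator table.
#' @param config List of run options: `draws` (Monte-Carlo CI draws, default
#'   1000), `seed` (default 1), `nodes` (quadrature nodes, default 12).
#' @param out_dir Optional directory; when given, writes `table1_<dim>.csv`,
#'   `table2_<dim>.csv`, `table3_<dim>.csv`, `fig1_<dim>.csv` and
#'   `manifest.json`.
#' @return An `AnalysisResults` list: `context`, `descriptives`,
#'   `model_tables`, `stratified_tables`, `marginal_prevalences`,
#'   `interaction_pvalues`, `fits`, `provenance`.
#' @export
run_full_analysis <- function(persons, tracts, indicators,
                              config = list(), out_dir = NULL) {
  draws <- config$draws %||% 1000
  seed <- config$seed %||% 1
  nodes <- config$nodes %||% 12
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", what, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  context <- stage("segregation/context",
                   build_city_context(tracts$income, tracts$race, indicators))
  res <- list(context = context, descriptives = list(), model_tables = list(),
              stratified_tables = list(), marginal_prevalences = list(),
              interaction_pvalues = list(), fits = list())
  for (dim in c("income", "race")) {
    res$descriptives[[dim]] <- stage(paste0("descriptives/", dim),
                                     descriptive_table(persons, context, dim))
    fits <- stage(paste0("models/", dim),
                  model_sequence(persons, context, dim, nodes = nodes))
    res$fits[[dim]] <- fits
    ok <- !vapply(fits, inherits, logical(1), "ri_logit_failure")
    mt <- list()
    for (lb in names(fits)[ok]) {
      f <- fits[[lb]]
      tab <- stage(paste0("marginals/", dim, "/", lb),
                   marginal_contrasts(f, persons, draws = draws, seed = seed))
      if (startsWith(lb, "4") || startsWith(lb, "5")) {
        tab <- rbind(tab, stage(paste0("tertile-contrasts/", dim, "/", lb),
                                tertile_contrasts(f, persons, draws = draws,
                                                  seed = seed)))
      }
      mt[[lb]] <- tab
    }
    res$model_tables[[dim]] <- do.call(rbind, mt)
    lb5 <- paste0("5", if (dim == "income") "A" else "B")
    if (ok[[lb5]]) {
      f5 <- fits[[lb5]]
      res$stratified_tables[[dim]] <- stage(
        paste0("stratified/", dim),
        marginal_contrasts(f5, persons, strata = seg_levels$tertile,
                           draws = draws, seed = seed))
      res$marginal_prevalences[[dim]] <- res$stratified_tables[[dim]][
        res$stratified_tables[[dim]]$contrast_type == "prevalence", ]
      res$interaction_pvalues[[dim]] <- interaction_wald_test(f5)$p_value
    }
  }
  res$provenance <- list(
    seed = seed, draws = draws, nodes = nodes,
    n_persons = nrow(persons), n_cities = nrow(context),
    package_version = as.character(utils::packageVersion("seghealth")),
    converged = lapply(res$fits, function(fl) {
      vapply(fl, function(f) isTRUE(f$converged), logical(1))
    })
  )
  if (!is.null(out_dir)) write_analysis_results(res, out_dir)
  res
}

#' Write analysis results to CSV files plus a run manifest
#'
#' @param results An `AnalysisResults` list from [run_full_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (dim in names(results$descriptives)) {
    utils::write.csv(results$descriptives[[dim]],
                     file.path(out_dir, paste0("table1_", dim, ".csv")),
                     row.names = FALSE)
    utils::write.csv(results$model_tables[[dim]],
                     file.path(out_dir, paste0("table2_", dim, ".csv")),
                     row.names = FALSE)
    if (!is.null(results$stratified_tables[[dim]])) {
      strat <- results$stratified_tables[[dim]]
      utils::write.csv(strat[strat$contrast_type != "prevalence", ],
                       file.path(out_dir, paste0("table3_", dim, ".csv")),
                       row.names = FALSE)
      utils::write.csv(results$marginal_prevalences[[dim]],
                       file.path(out_dir, paste0("fig1_", dim, ".csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(results$context, file.path(out_dir, "city_context.csv"),
                   row.names = FALSE)
  manifest <- results$provenance
  manifest$interaction_pvalues <- results$interaction_pvalues
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Sensitivity analyses
#'
#' Re-runs the interaction analysis under the standard sensitivity variants:
#' (1) income-adjusted, refitting the interaction model with household income
#' tertile as an additional covariate on the complete-income subsample;
#' (2) stratified by gender; (3) stratified by education, dichotomized as
#' university + secondary versus primary + less than primary (configurable
#' via `config$education_high`). Strata in which fewer than 2 cities remain
#' or the outcome is degenerate are skipped with a warning.
#'
#' @param persons Person table (`income_tertile` required for the income
#'   variant).
#' @param context City context table.
#' @param dimension Segregation dimension for the interaction model.
#' @param config List: `draws`, `seed`, `nodes`, `education_high` (character
#'   vector of education levels forming the "higher" stratum).
#' @return List with elements `income_adjusted`, `by_gender`, `by_education`;
#'   each holds stratified marginal contrast tables (or NULL if skipped).
#' @export
sensitivity_runs <- function(persons, context, dimension = c("income", "race"),
                             config = list()) {
  dimension <- match.arg(dimension)
  draws <- config$draws %||% 1000
  seed <- config$seed %||% 1
  nodes <- config$nodes %||% 12
  edu_high <- config$education_high %||% c("university", "secondary")
  lb5 <- paste0("5", if (dimension == "income") "A" else "B")

  fit_strat <- function(sub, terms, what) {
    if (length(unique(sub$city_id)) < 2 || length(unique(sub$srh_fair_poor)) < 2) {
      warning("skipping ", what, ": fewer than 2 cities or degenerate outcome")
      return(NULL)
    }
    sp <- model_spec("custom", dimension = dimension, terms = terms)
    sp$label <- paste0(lb5, ":", what)
    f <- tryCatch(fit_random_intercept_logit(sub, context, sp, nodes = nodes),
                  error = function(e) {
                    warning("skipping ", what, ": ", conditionMessage(e))
                    NULL
                  })
    if (is.null(f)) return(NULL)
    marginal_contrasts(f, sub, strata = seg_levels$tertile,
                       draws = draws, seed = seed)
  }

  out <- list(income_adjusted = NULL, by_gender = NULL, by_education = NULL)

  inc_sub <- persons[!is.na(persons$income_tertile), , drop = FALSE]
  if (nrow(inc_sub) > 0) {
    out$income_adjusted <- fit_strat(
      inc_sub,
      c("race", "age_c", "gender", "education", "income_tertile", "senv",
        "seg_tertile", "race:seg_tertile"),
      "income_adjusted")
  } else {
    warning("skipping income_adjusted: no income data")
  }

  out$by_gender <- lapply(stats::setNames(seg_levels$gender, seg_levels$gender),
                          function(g) {
    fit_strat(persons[persons$gender == g, , drop = FALSE],
              c("race", "age_c", "education", "senv", "seg_tertile",
                "race:seg_tertile"),
              paste0("gender_", g))
  })

  persons$edu_stratum <- ifelse(persons$education %in% edu_high, "higher", "lower")
  out$by_education <- lapply(stats::setNames(c("higher", "lower"),
                                             c("higher", "lower")), function(e) {
    fit_strat(persons[persons$edu_stratum == e, , drop = FALSE],
              c("race", "age_c", "gender", "education", "senv", "seg_tertile",
                "race:seg_tertile"),
              paste0("education_", e))
  })
  out
}

#' Plot a prevalence-by-race-and-tertile grid
#'
#' Minimal chart of the standardized prevalence grid from
#' [prevalence_by_race_and_tertile()], with race on the x axis, one panel
#' colour per tertile, and Monte-Carlo confidence intervals as error bars.
#' Requires ggplot2.
#'
#' @param grid Data frame of prevalence rows.
#' @return A ggplot object.
#' @export
plot_prevalence_grid <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  grid$race <- factor(grid$comparison, levels = seg_levels$race)
  grid$stratum <- factor(grid$stratum, levels = seg_levels$tertile)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$race, y = .data$estimate,
                                     fill = .data$stratum)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "Standardized prevalence of fair/poor SRH",
                  fill = "Segregation") +
    ggplot2::theme_minimal()
}
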