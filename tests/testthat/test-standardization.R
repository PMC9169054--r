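test_that("saturated race-only model reproduces crude proportions, PR and PD", {
  persons <- exact_proportion_persons(
    n_per_race = 200, props = c(White = 0.2, Brown = 0.25, Black = 0.3))
  f <- fit_random_intercept_logit(persons, NULL,
                                  model_spec("custom", terms = "race"))
  expect_true(f$sigma_zero)
  # contingency-table oracle: crude group proportions
  crude <- tapply(persons$srh_fair_poor, persons$race, mean)
  for (r in c("White", "Brown", "Black")) {
    expect_equal(standardized_prevalence(f, persons, set_race = r),
                 unname(crude[r]), tolerance = 1e-6)
  }
  mc <- marginal_contrasts(f, persons, draws = 200, seed = 1)
  pr_black <- mc$estimate[mc$contrast_type == "PR" & mc$comparison == "Black"]
  pd_black <- mc$estimate[mc$contrast_type == "PD" & mc$comparison == "Black"]
  expect_equal(pr_black, 1.5, tolerance = 1e-5)
  expect_equal(pd_black, 0.1, tolerance = 1e-6)
})

test_that("law of total probability holds for the saturated fit", {
  persons <- exact_proportion_persons(n_per_race = 120)
  f <- fit_random_intercept_logit(persons, NULL,
                                  model_spec("custom", terms = "race"))
  freq <- table(persons$race) / nrow(persons)
  mix <- sum(vapply(names(freq), function(r) {
    freq[[r]] * standardized_prevalence(f, persons, set_race = r)
  }, numeric(1)))
  expect_equal(mix, mean(persons$srh_fair_poor), tolerance = 1e-6)
})

test_that("zero random-intercept predictions equal the plain inverse logit", {
  persons <- exact_proportion_persons(n_per_race = 120)
  f <- fit_random_intercept_logit(persons, NULL,
                                  model_spec("custom", terms = "race"))
  expect_identical(f$sigma_b, 0)
  expect_equal(standardized_prevalence(f, persons, set_race = "Black"),
               standardized_prevalence(f, persons, set_race = "Black",
                                       conditional = TRUE),
               tolerance = 1e-12)
})

test_that("population-averaged and conditional predictions differ when sigma_b > 0", {
  # logistic nonlinearity: integrating over b shrinks extreme probabilities
  eta <- c(-2, 0, 1.5)
  pa <- pop_avg_prob(eta, sigma = 0.8, nodes = 24)
  cond <- plogis(eta)
  expect_gt(pa[1], cond[1])
  expect_equal(pa[2], cond[2], tolerance = 1e-12)
  expect_lt(pa[3], cond[3])
  # quadrature matches a large Monte-Carlo average
  set.seed(2)
  b <- rnorm(2e5, 0, 0.8)
  expect_equal(pa[1], mean(plogis(-2 + b)), tolerance = 2e-3)
})

test_that("PR/PD consistency and CI bookkeeping hold on an interaction model", {
  st <- small_study(seed = 202, ppc = c(100, 200))
  f5 <- fit_random_intercept_logit(st$persons, st$context, model_spec("5A"))
  mc <- marginal_contrasts(f5, st$persons, strata = c("low", "medium", "high"),
                           draws = 250, seed = 7)
  # PD = p_ref * (PR - 1) exactly, per stratum and comparison
  for (s in c("low", "medium", "high")) {
    p_ref <- mc$estimate[mc$contrast_type == "prevalence" &
                         mc$comparison == "White" & mc$stratum == s]
    for (r in c("Brown", "Black")) {
      pr <- mc$estimate[mc$contrast_type == "PR" & mc$comparison == r &
                        mc$stratum == s]
      pd <- mc$estimate[mc$contrast_type == "PD" & mc$comparison == r &
                        mc$stratum == s]
      expect_equal(pd, p_ref * (pr - 1), tolerance = 1e-12)
    }
  }
  # interval bookkeeping
  expect_true(all(mc$ci_low <= mc$estimate + 1e-12))
  expect_true(all(mc$estimate <= mc$ci_high + 1e-12))
  prev <- mc[mc$contrast_type == "prevalence", ]
  expect_equal(nrow(prev), 9)
  expect_true(all(prev$estimate > 0 & prev$estimate < 1))
  expect_true(all(mc$estimate[mc$contrast_type == "PR"] > 0))
  # determinism: identical seed and draws give bit-identical intervals
  mc2 <- marginal_contrasts(f5, st$persons, strata = c("low", "medium", "high"),
                            draws = 250, seed = 7)
  expect_identical(mc, mc2)
})

test_that("standardization guards its preconditions", {
  st <- small_study(seed = 203, ppc = c(60, 100))
  f1 <- fit_random_intercept_logit(st$persons, st$context, model_spec("1"))
  expect_error(standardized_prevalence(f1, st$persons, set_race = "Black",
                                       set_stratum = "high"),
               "no segregation terms")
  expect_error(standardized_prevalence(f1, st$persons, set_race = "Asian"),
               "not a level")
  expect_error(marginal_contrasts(f1, st$persons, draws = 50), "at least 100")
})

test_that("prevalence grid requires an interaction model and fills 9 cells", {
  st <- small_study(seed = 204, ppc = c(80, 150))
  f5 <- fit_random_intercept_logit(st$persons, st$context, model_spec("5B"))
  grid <- prevalence_by_race_and_tertile(f5, st$persons, draws = 150, seed = 3)
  expect_equal(nrow(grid), 9)
  expect_true(all(grid$estimate >= 0 & grid$estimate <= 1))
  f4 <- fit_random_intercept_logit(st$persons, st$context, model_spec("4B"))
  expect_error(prevalence_by_race_and_tertile(f4, st$persons), "interaction")
})
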