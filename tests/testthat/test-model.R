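test_that("Gauss-Hermite rule reproduces known nodes and normal moments", {
  r2 <- gauss_hermite(2)
  expect_equal(r2$nodes, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(r2$weights, rep(sqrt(pi) / 2, 2), tolerance = 1e-12)
  r15 <- gauss_hermite(15)
  expect_equal(sum(r15$weights), sqrt(pi), tolerance = 1e-12)
  # E[Z^2] and E[Z^4] of a standard normal via the substitution z = x*sqrt(2)
  ez2 <- sum(r15$weights * (sqrt(2) * r15$nodes)^2) / sqrt(pi)
  ez4 <- sum(r15$weights * (sqrt(2) * r15$nodes)^4) / sqrt(pi)
  expect_equal(ez2, 1, tolerance = 1e-10)
  expect_equal(ez4, 3, tolerance = 1e-10)
})

test_that("fit agrees with the independent lme4 implementation", {
  st <- small_study(seed = 101, ppc = c(100, 220))
  f <- fit_random_intercept_logit(st$persons, st$context, model_spec("2"),
                                  robust = FALSE)
  dat <- merge(st$persons, st$context, by = "city_id")
  dat$age_c <- dat$age - 43
  g <- lme4::glmer(
    srh_fair_poor ~ race + age_c + gender + education + (1 | city_id),
    data = dat, family = binomial, nAGQ = 12,
    control = lme4::glmerControl(calc.derivs = FALSE))
  expect_equal(unname(f$beta), unname(lme4::fixef(g)), tolerance = 1e-3)
  expect_equal(f$sigma_b, sqrt(as.numeric(lme4::VarCorr(g)$city_id[1, 1])),
               tolerance = 1e-2)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-4)
})

test_that("boundary fit reduces to ordinary logistic regression", {
  # no city-level effects at all: sigma_b = 0 truth
  cfg <- generative_config(
    sigma_b = 0,
    beta = c(senv = 0, tert_medium = 0, tert_high = 0, brown_med = 0,
             brown_high = 0, black_med = 0, black_high = 0),
    persons_per_city = c(250, 450), seed = 55)
  st <- simulate_study(cfg)
  f <- fit_random_intercept_logit(st$persons, st$context, model_spec("1"))
  dat <- merge(st$persons, st$context, by = "city_id")
  dat$age_c <- dat$age - 43
  g <- glm(srh_fair_poor ~ race + age_c + gender, binomial, dat)
  expect_lt(f$sigma_b, 0.1)
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 0.01)
})

test_that("balanced intercept-only fit at the boundary returns logit(0.5) = 0", {
  persons <- data.frame(
    person_id = sprintf("p%04d", 1:800),
    city_id = rep(sprintf("c%02d", 1:8), each = 100),
    race = "White", age = 40, gender = "male", education = "secondary",
    srh_fair_poor = rep(c(0, 1), 400), stringsAsFactors = FALSE
  )
  f <- fit_random_intercept_logit(persons, NULL,
                                  model_spec("custom", terms = "1"))
  expect_true(f$sigma_zero)
  expect_equal(unname(f$beta), 0, tolerance = 1e-10)
})

test_that("estimates are stable when quadrature nodes are doubled", {
  st <- small_study(seed = 77, ppc = c(80, 160))
  f12 <- fit_random_intercept_logit(st$persons, st$context, model_spec("3"),
                                    nodes = 12, robust = FALSE)
  f24 <- fit_random_intercept_logit(st$persons, st$context, model_spec("3"),
                                    nodes = 24, robust = FALSE)
  expect_lt(max(abs(f12$beta - f24$beta)), 1e-4)
  expect_lt(abs(f12$sigma_b - f24$sigma_b), 1e-4)
})

test_that("model ladder preserves labels and likelihood nesting", {
  st <- small_study(seed = 33, ppc = c(80, 160))
  fits <- model_sequence(st$persons, st$context, "income", robust = FALSE)
  expect_identical(names(fits), c("1", "2", "3", "4A", "5A"))
  lls <- vapply(fits, function(f) f$loglik, numeric(1))
  expect_true(all(diff(lls) > -1e-6))
})

test_that("city confounder adjustment shrinks the random-intercept variance", {
  cfg <- generative_config(beta = c(senv = -0.8), sigma_b = 0.3,
                           persons_per_city = c(250, 450), seed = 44)
  st <- simulate_study(cfg)
  f2 <- fit_random_intercept_logit(st$persons, st$context, model_spec("2"),
                                   robust = FALSE)
  f3 <- fit_random_intercept_logit(st$persons, st$context, model_spec("3"),
                                   robust = FALSE)
  expect_lt(f3$sigma_b, f2$sigma_b)
})

test_that("interaction Wald test matches the 1-df identity and errors cleanly", {
  st <- small_study(seed = 66, ppc = c(100, 200))
  f5 <- fit_random_intercept_logit(st$persons, st$context, model_spec("5A"))
  w <- interaction_wald_test(f5)
  expect_gte(w$statistic, 0)
  expect_equal(w$df, 4)
  expect_true(w$p_value >= 0 && w$p_value <= 1)
  # single-coefficient test equals (estimate / robust SE)^2
  cf <- "raceBlack:seg_tertilehigh"
  w1 <- interaction_wald_test(f5, coefs = cf)
  expect_equal(w1$statistic,
               (f5$beta[[cf]] / sqrt(f5$vcov_robust[cf, cf]))^2,
               tolerance = 1e-10)
  # no interaction terms -> error
  f1 <- fit_random_intercept_logit(st$persons, st$context, model_spec("1"))
  expect_error(interaction_wald_test(f1), "no race x segregation")
})

test_that("robust and model-based standard errors broadly agree under correct specification", {
  st <- small_study(seed = 88, ppc = c(150, 300))
  f <- fit_random_intercept_logit(st$persons, st$context, model_spec("5A"))
  p <- length(f$beta)
  rse <- sqrt(diag(f$vcov_robust))[seq_len(p)]
  mse <- sqrt(diag(f$vcov_model))[seq_len(p)]
  expect_true(all(rse / mse > 0.4 & rse / mse < 2.5))
})

test_that("degenerate inputs raise informative errors", {
  st <- small_study(seed = 9, ppc = c(50, 80))
  # rank-deficient design: senv entered twice under two names
  sp <- model_spec("custom", terms = c("senv", "social_environment_index"))
  expect_error(
    fit_random_intercept_logit(st$persons, st$context, sp),
    "rank deficient")
  one_city <- st$persons[st$persons$city_id == st$persons$city_id[1], ]
  expect_error(
    fit_random_intercept_logit(one_city, st$context, model_spec("1")),
    "at least 2 cities")
  const <- st$persons
  const$srh_fair_poor <- 1
  expect_error(
    fit_random_intercept_logit(const, st$context, model_spec("1")),
    "degenerate")
})
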