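test_that("dissimilarity index matches analytic endpoints and hand evaluation", {
  # disjoint tracts: complete segregation
  expect_identical(dissimilarity_index(one_city_tracts(c(100, 0), c(0, 100))), 1)
  # proportionally identical tracts: complete integration
  expect_identical(dissimilarity_index(one_city_tracts(c(50, 50), c(20, 20))), 0)
  expect_identical(
    dissimilarity_index(one_city_tracts(c(50, 50, 25, 25), c(20, 20, 10, 10))), 0)
  # hand evaluation: 1/2 (|0.8-0.2| + |0.1-0.4| + |0.1-0.4|) = 0.6
  expect_equal(dissimilarity_index(one_city_tracts(c(8, 1, 1), c(2, 4, 4))), 0.6)
  # empty tracts contribute zero
  expect_equal(
    dissimilarity_index(one_city_tracts(c(8, 1, 1, 0), c(2, 4, 4, 0))), 0.6)
})

test_that("dissimilarity index errors name the city and group", {
  expect_error(dissimilarity_index(one_city_tracts(c(0, 0), c(5, 5), city = "X")),
               "city X.*group A")
  expect_error(dissimilarity_index(one_city_tracts(c(5, 5), c(0, 0), city = "X")),
               "city X.*group B")
  expect_error(dissimilarity_index(one_city_tracts(c(-1, 5), c(5, 5), city = "X")),
               "negative")
})

test_that("dissimilarity index agrees with the term-by-term oracle on random tables", {
  set.seed(42)
  for (rep in 1:200) {
    tt <- random_tract_table(n_cities = 1, max_tracts = 5, max_count = 10)
    expect_equal(dissimilarity_index(tt),
                 di_oracle(tt$group_a_count, tt$group_b_count),
                 tolerance = 1e-12)
  }
})

test_that("dissimilarity index is symmetric, scale invariant and merge invariant", {
  set.seed(7)
  for (rep in 1:50) {
    tt <- random_tract_table(n_cities = 1, max_tracts = 6, max_count = 20)
    d <- dissimilarity_index(tt)
    expect_gte(d, 0)
    expect_lte(d, 1)
    # symmetry
    sw <- tt
    sw$group_a_count <- tt$group_b_count
    sw$group_b_count <- tt$group_a_count
    expect_identical(dissimilarity_index(sw), d)
    # scale invariance of one group's counts
    sc <- tt
    sc$group_a_count <- tt$group_a_count * 7.5
    expect_equal(dissimilarity_index(sc), d, tolerance = 1e-12)
    # merging two proportionally identical tracts leaves the index unchanged
    mg <- rbind(tt, tt[1, ])
    mg$tract_id <- sprintf("t%03d", seq_len(nrow(mg)))
    m2 <- tt
    m2$group_a_count[1] <- 2 * tt$group_a_count[1]
    m2$group_b_count[1] <- 2 * tt$group_b_count[1]
    expect_equal(dissimilarity_index(mg), dissimilarity_index(m2),
                 tolerance = 1e-12)
  }
})

test_that("segregation_by_dimension returns one index per city with invariances", {
  set.seed(5)
  tt <- random_tract_table(n_cities = 27, max_tracts = 8, max_count = 30)
  idx <- segregation_by_dimension(tt, "race")
  expect_equal(nrow(idx), 27)
  expect_true(all(idx$value >= 0 & idx$value <= 1))
  expect_true(all(idx$dimension == "race"))
  # duplicating every tract within a city leaves values unchanged
  dup <- rbind(tt, transform(tt, tract_id = paste0(tract_id, "bis")))
  expect_equal(segregation_by_dimension(dup, "race")$value, idx$value,
               tolerance = 1e-12)
})

test_that("tertile assignment partitions cities monotonically in value", {
  idx27 <- data.frame(city_id = sprintf("c%02d", 1:27),
                      value = seq(0.1, 0.6, length.out = 27))
  t27 <- assign_tertiles(idx27)
  expect_equal(as.integer(table(t27$tertile)), c(9, 9, 9))
  expect_true(all(t27$value[t27$tertile == "low"] <
                  t27$value[t27$tertile == "medium"][1]))
  # rank order for three cities
  t3 <- assign_tertiles(data.frame(city_id = c("a", "b", "c"),
                                   value = c(0.1, 0.2, 0.3)))
  expect_equal(as.character(t3$tertile), c("low", "medium", "high"))
  # four cities: floor rule gives sizes 1/1/2
  t4 <- assign_tertiles(data.frame(city_id = sprintf("c%d", 1:4),
                                   value = c(1, 2, 3, 4)))
  expect_equal(as.integer(table(t4$tertile)), c(1, 1, 2))
  # deterministic stable tie-break on city_id
  tie <- data.frame(city_id = c("b", "a", "c"), value = c(0.2, 0.2, 0.2))
  expect_identical(assign_tertiles(tie)$tertile[order(tie$city_id)],
                   factor(c("low", "medium", "high"),
                          levels = c("low", "medium", "high")))
  # range metadata covers each tertile's observed values
  expect_true(all(t27$tertile_range_low <= t27$value &
                  t27$value <= t27$tertile_range_high))
  expect_error(assign_tertiles(idx27[1:2, ]), "at least 3")
})
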