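# Life-table YLL computation via the age-interval midpoint rule.

test_that("interval midpoints follow the 5-year and open-ended rules", {
  expect_identical(interval_midpoint(50L, 54L), 52L)
  expect_identical(interval_midpoint(70L, 74L), 72L)
  expect_identical(interval_midpoint(85L, NA), 87L)
  expect_identical(interval_midpoint(85L, NA, open_ended_offset = 5L), 90L)
  expect_error(interval_midpoint(60L, 55L), class = "preventyll_invalid_input")
})

test_that("age restriction keeps only strata starting at 50+ and is idempotent", {
  mt <- mortality_table(rep("male", 3), c(45L, 50L, 55L), c(49L, 54L, 59L),
                        c(10, 20, 30))
  r1 <- restrict_age50plus(mt)
  expect_identical(r1$age_lower, c(50L, 55L))
  expect_identical(restrict_age50plus(r1), r1)
  empty <- restrict_age50plus(mortality_table("male", 40L, 44L, 5))
  expect_identical(nrow(empty), 0L)
})

test_that("expectancy lookup: exact, interpolated, and out-of-range cases", {
  lt <- life_table(rep("male", 3), c(52L, 53L, 54L), c(30, 29.2, 28.4))
  expect_equal(lookup_expectancy(lt, "male", 53), 29.2)
  expect_equal(lookup_expectancy(lt, "male", 52.5, interpolate = TRUE),
               (30 + 29.2) / 2)
  expect_equal(lookup_expectancy(lt, "male", 52, interpolate = TRUE), 30)
  expect_error(lookup_expectancy(lt, "male", 60), class = "preventyll_lookup_error")
  expect_error(lookup_expectancy(lt, "female", 52), class = "preventyll_lookup_error")
})

test_that("single-stratum YLL is deaths times midpoint expectancy", {
  mt <- mortality_table("male", 50L, 54L, 100)
  lt <- life_table("male", 52L, 30)
  res <- compute_yll(mt, lt)
  expect_equal(res$total_yll, 3000)
  expect_equal(res$total_deaths_50plus, 100L)
  expect_equal(sum(res$per_stratum$yll), res$total_yll)
})

test_that("an empty table yields zero burden", {
  mt <- mortality_table("male", 40L, 44L, 50)   # below the age cut
  lt <- life_table("male", 42L, 40)
  res <- compute_yll(mt, lt)
  expect_equal(res$total_yll, 0)
  expect_equal(res$total_deaths_50plus, 0L)
})

test_that("a missing life-table entry names the offending stratum", {
  mt <- mortality_table("female", 50L, 54L, 10)
  lt <- life_table("female", 60L, 20)
  expect_error(compute_yll(mt, lt), "female 50-54",
               class = "preventyll_lookup_error")
})

test_that("YLL is linear in death counts and additive over disjoint tables", {
  set.seed(11)
  tabs <- random_tables()
  base <- compute_yll(tabs$mortality, tabs$life_table)
  scaled <- mortality_table(tabs$mortality$sex, tabs$mortality$age_lower,
                            tabs$mortality$age_upper, tabs$mortality$deaths * 3L)
  expect_equal(compute_yll(scaled, tabs$life_table)$total_yll, 3 * base$total_yll)

  males <- tabs$mortality[tabs$mortality$sex == "male", ]
  females <- tabs$mortality[tabs$mortality$sex == "female", ]
  part <- function(df) mortality_table(df$sex, df$age_lower, df$age_upper, df$deaths)
  expect_equal(compute_yll(part(males), tabs$life_table)$total_yll +
                 compute_yll(part(females), tabs$life_table)$total_yll,
               base$total_yll)
})

test_that("record order never changes the totals", {
  set.seed(12)
  tabs <- random_tables()
  mt <- tabs$mortality
  perm <- sample(nrow(mt))
  shuffled <- mortality_table(mt$sex[perm], mt$age_lower[perm],
                              mt$age_upper[perm], mt$deaths[perm])
  expect_equal(compute_yll(shuffled, tabs$life_table)$total_yll,
               compute_yll(mt, tabs$life_table)$total_yll)
})

test_that("compute_yll matches the nested-loop oracle on random tables", {
  set.seed(2024)
  for (rep in 1:50) {
    tabs <- random_tables()
    got <- compute_yll(tabs$mortality, tabs$life_table)$total_yll
    ref <- oracle_yll(as.data.frame(tabs$mortality), as.data.frame(tabs$life_table))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("mortality-table validation rejects duplicates, overlaps and bad counts", {
  expect_error(mortality_table(c("male", "male"), c(50L, 50L), c(54L, 54L), c(1, 2)),
               "duplicate", class = "preventyll_invalid_input")
  expect_error(mortality_table(c("male", "male"), c(50L, 53L), c(54L, 57L), c(1, 2)),
               "overlap", class = "preventyll_invalid_input")
  expect_error(mortality_table("male", 50L, 54L, -3),
               class = "preventyll_invalid_input")
  expect_error(mortality_table("male", 50L, 54L, 2.5),
               class = "preventyll_invalid_input")
  expect_error(life_table("male", 52L, -1), class = "preventyll_invalid_input")
  expect_warning(life_table(c("male", "male"), c(52L, 53L), c(20, 25)),
                 "non-increasing")
})
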