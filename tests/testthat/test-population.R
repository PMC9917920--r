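test_that("largest-remainder allocation conserves totals and breaks ties
           lexicographically", {
  tg <- toy_targets()
  # equal split of 3: lexicographically first cells get the extra unit
  tg2 <- marginal_target_set(
    "t", 10, c(male = 0.5, female = 0.5), c(UC = 1, CD = 0),
    data.frame(condition = "UC", sex = c("male", "female"), mean = 50,
               sd = 10), c(18, 74))
  cc <- allocate_cell_counts(tg2, 3)
  expect_equal(cc$count[cc$sex == "male" & cc$condition == "UC"], 2L)
  expect_equal(cc$count[cc$sex == "female" & cc$condition == "UC"], 1L)

  # conservation over random proportions and totals
  set.seed(11)
  for (i in 1:50) {
    ps <- runif(1, 0.01, 0.99)
    pc <- runif(1, 0.01, 0.99)
    tot <- sample(0:10000, 1)
    tgi <- marginal_target_set(
      "t", max(tot, 1), c(male = ps, female = 1 - ps),
      c(UC = pc, CD = 1 - pc),
      data.frame(condition = rep(c("UC", "CD"), each = 2),
                 sex = rep(c("male", "female"), 2), mean = 50, sd = 10),
      c(18, 74))
    cci <- allocate_cell_counts(tgi, tot)
    expect_identical(sum(cci$count), as.integer(tot))
    expect_true(all(cci$count >= 0))
  }
  expect_error(allocate_cell_counts(tg, -1), "nonnegative")
})

test_that("the published Tokyo sex marginal is reproduced at any total", {
  tg <- regional_targets("tokyo")
  cc <- allocate_cell_counts(tg, 1000)
  expect_equal(sum(cc$count[cc$sex == "male"]), 561L)
  expect_equal(sum(cc$count[cc$sex == "female"]), 439L)
})

test_that("generated populations reproduce configured totals and shares
           exactly and are seed-deterministic", {
  tg <- regional_targets("hokkaido")
  a1 <- suppressWarnings(generate_population(tg, 20000, seed = 5))
  a2 <- suppressWarnings(generate_population(tg, 20000, seed = 5))
  expect_identical(a1, a2)
  s <- population_summary(a1)
  expect_equal(s$total_weight, 438983, tolerance = 1e-12)
  expect_equal(100 * s$condition_shares[["UC"]], 73.1, tolerance = 0.001)
  expect_equal(100 * s$sex_shares[["male"]], 44.5, tolerance = 0.001)
  expect_equal(sum(s$sex_shares), 1, tolerance = 1e-9)
  expect_equal(sum(s$condition_shares), 1, tolerance = 1e-9)
  expect_true(all(a1$age >= 18 & a1$age <= 74))
  expect_true(all(a1$weight > 0))
  expect_error(generate_population(tg, 1e7, seed = 1), "exceeds")
})

test_that("population_summary handles degenerate inputs", {
  one <- toy_population(n_agents = 2000)[1, ]
  s <- population_summary(one)
  expect_true(all(s$sex_shares %in% c(0, 1)))
  expect_true(is.na(s$age_by_cell$sd[!is.na(s$age_by_cell$mean)][1]))
  expect_error(population_summary(toy_population()[0, ]), "empty")
})

test_that("agent tables round-trip through CSV", {
  a <- toy_population(n_agents = 200)
  f <- tempfile(fileext = ".csv")
  write_agents(a, f)
  b <- read_agents(f)
  expect_equal(nrow(b), 200)
  expect_equal(b$weight, a$weight, tolerance = 1e-9)
  expect_identical(b$sex, a$sex)
})
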