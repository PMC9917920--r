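test_that("a perfect seed gets uniform weights and zero objective", {
  tg <- toy_targets(total = 1000)
  seed <- data.frame(sex = rep(c("male", "female"), each = 2),
                     condition = rep(c("UC", "CD"), 2))
  lw <- localize_weights(seed, tg)
  expect_equal(lw$objective_value, 0, tolerance = 1e-6)
  expect_equal(unname(lw$cells$weight), rep(250, 4), tolerance = 1e-6)
  expect_equal(sum(lw$cells$weight), 1000, tolerance = 1e-9)
})

test_that("the two-cell program has the closed-form solution", {
  tg <- marginal_target_set(
    "t", 1000, c(male = 0.561, female = 0.439), c(UC = 1, CD = 0),
    data.frame(condition = "UC", sex = c("male", "female"), mean = 50,
               sd = 10), c(18, 74))
  seed <- data.frame(sex = c("male", "female"), condition = c("UC", "UC"))
  lw <- localize_weights(seed, tg)
  expect_equal(unname(lw$cells$weight), c(561, 439), tolerance = 1e-6)
  expect_equal(lw$objective_value, 0, tolerance = 1e-6)
})

test_that("the LP optimum matches exact basic-solution enumeration on small
           instances", {
  set.seed(9)
  for (i in 1:5) {
    # seed populations missing one cell so the optimum is not trivially 0
    cells <- expand.grid(sex = c("male", "female"),
                         condition = c("UC", "CD"),
                         stringsAsFactors = FALSE)[sample(1:4, 3), ]
    ps <- runif(1, 0.3, 0.7)
    pc <- runif(1, 0.3, 0.7)
    total <- 100
    tg <- marginal_target_set(
      "t", total, c(male = ps, female = 1 - ps), c(UC = pc, CD = 1 - pc),
      data.frame(condition = rep(c("UC", "CD"), each = 2),
                 sex = rep(c("male", "female"), 2), mean = 50, sd = 10),
      c(18, 74))
    seed_pop <- cells[rep(seq_len(nrow(cells)), 2), ]
    lw <- localize_weights(seed_pop, tg)
    oracle <- localize_bruteforce(
      unique(seed_pop), total * tg$sex_proportions,
      total * tg$condition_proportions, total)
    expect_equal(lw$objective_value, oracle, tolerance = 1e-6)
  }
})

test_that("a target category with no seed support is an infeasibility error
           naming the category", {
  tg <- toy_targets(total = 1000)
  seed <- data.frame(sex = c("male", "male"), condition = c("UC", "CD"))
  expect_error(localize_weights(seed, tg), "zero seed support: sex=female")
  expect_error(localize_weights(seed[0, ], tg), "empty")
})
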