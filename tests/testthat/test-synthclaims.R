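test_that("without growth or disruption the mean curves are constant", {
  truth <- claims_ground_truth(10, growth = 1, base_total_patients = 0,
                               biologic_share = 0)
  mc <- claims_mean_curve(truth, 12)
  expect_true(all(mc$new_patients == 10))
  expect_equal(mc$total_patients, cumsum(rep(10, 12)))
})

test_that("dip depth and second-wave damping follow the stated profile
           arithmetic", {
  truth <- claims_ground_truth(
    10, growth = 1, base_total_patients = 1000, catchup_rate = 0,
    disruption = list(onset_week = 5, depth = 0.5, recovery_weeks = 4))
  mc <- claims_mean_curve(truth, 12)
  expect_equal(mc$new_patients[6], 5)           # 50% of the undipped mean
  expect_equal(mc$new_patients[8], 10 * (1 - 0.5 * (1 - 2 / 4)))

  truth2 <- claims_ground_truth(
    10, growth = 1, base_total_patients = 1000, catchup_rate = 0,
    disruption = list(onset_week = 2, depth = 0.5, recovery_weeks = 2,
                      second_onset_week = 8, second_ratio = 0.4))
  mc2 <- claims_mean_curve(truth2, 12)
  first_def <- 10 - mc2$new_patients[3]
  second_def <- 10 - mc2$new_patients[9]
  expect_equal(second_def / first_def, 0.4, tolerance = 1e-9)
})

test_that("generation is seed-deterministic and byte-compatible with the
           demand-series CSV contract", {
  truth <- claims_fixture("tokyo")
  s1 <- generate_claims_series(truth, 20, seed = 5)
  s2 <- generate_claims_series(truth, 20, seed = 5)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  f <- tempfile(fileext = ".csv")
  write_series(s1, f)
  s3 <- read_series(f)
  expect_equal(as.data.frame(s3), as.data.frame(s1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the Monte-Carlo mean over replicates converges to the analytic
           mean curve", {
  truth <- claims_ground_truth(
    25, growth = 1.08, base_total_patients = 2000, dispersion = 10,
    disruption = list(onset_week = 8, depth = 0.4, recovery_weeks = 6))
  n_weeks <- 20
  n_rep <- 400
  mc <- claims_mean_curve(truth, n_weeks)
  draws <- vapply(seq_len(n_rep), function(r) {
    generate_claims_series(truth, n_weeks, seed = 5000 + r)$new_patients
  }, numeric(n_weeks))
  mhat <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(n_rep)
  z <- abs(mhat - mc$new_patients) / se
  expect_true(all(z < 4))
  expect_gte(mean(z < 2), 0.9)
})

test_that("the regional presets differ in scale and recovery and the slower
           preset shows a biologic bump before its dip", {
  tk <- claims_fixture("tokyo")
  hk <- claims_fixture("hokkaido")
  expect_gt(tk$base_total_patients, hk$base_total_patients)
  expect_gt(hk$disruption$recovery_weeks, tk$disruption$recovery_weeks)
  mc <- claims_mean_curve(hk, hk$disruption$onset_week + 30)
  undipped <- claims_mean_curve(
    claims_ground_truth(hk$base_weekly_new_patients, hk$growth,
                        hk$base_total_patients,
                        biologic_share = hk$biologic_share),
    hk$disruption$onset_week + 30)
  ratio <- mc$biologics / undipped$biologics
  bump_weeks <- hk$disruption$onset_week + seq_len(hk$disruption$biologic_bump[2])
  expect_true(all(ratio[bump_weeks] > 1))
  expect_lt(min(ratio), 0.8)
})
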