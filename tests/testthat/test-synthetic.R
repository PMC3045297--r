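test_that("generation is deterministic in (suite, seed) and seed-sensitive", {
  suite <- two_arm_suite(-15, -5, n_a = 30, n_b = 30)
  a <- generate_cohort(suite, 5)
  b <- generate_cohort(suite, 5)
  c <- generate_cohort(suite, 6)
  expect_identical(a, b)
  expect_false(identical(a$visits, c$visits))
})

test_that("degenerate arms behave: n = 0 emits nothing, completion 1 forces endpoint visits", {
  arms <- rbind(
    toy_arm(n = 0),
    toy_arm(arm = "placebo", dose = NA, n = 25, completion = 1)
  )
  suite <- make_suite(toy_trial_meta(), arms, toy_covariates())
  co <- generate_cohort(suite, 3)
  expect_equal(nrow(co$subjects), 25)
  expect_true(all(co$subjects$completed))
  endpoint_visits <- co$visits$week == 6
  expect_equal(sum(endpoint_visits), 25)
  expect_equal(sum(co$subjects$treatment_group == "PALI_6_12"), 0)
})

test_that("generated cohorts satisfy the structural invariants", {
  co <- generate_cohort(default_suite(), 9)
  expect_silent(validate_subjects(co$subjects))
  expect_silent(validate_visits(co$visits, co$subjects))
  expect_silent(validate_events(co$events, co$subjects, co$visits))
  # PANSS total is the sum of the five factor scores wherever factors exist
  fac <- co$visits[!is.na(co$visits$panss_negative), ]
  expect_equal(
    fac$panss_total,
    fac$panss_negative + fac$panss_positive + fac$panss_anxiety_depression +
      fac$panss_disorganized_thoughts + fac$panss_hostility_excitement
  )
  # the factor-score-free trial and the CGI-free trial are respected
  v1 <- co$visits[co$visits$subject_id %in%
                    co$subjects$subject_id[co$subjects$trial_id == "RIS-USA-1"], ]
  expect_true(all(is.na(v1$panss_negative)))
  v72 <- co$visits[co$visits$subject_id %in%
                     co$subjects$subject_id[co$subjects$trial_id == "RIS-USA-72"], ]
  expect_true(all(is.na(v72$cgi_s)))
})

test_that("covariate moments are recovered against the truncated-normal oracle", {
  suite <- two_arm_suite(-15, -5, n_a = 120, n_b = 0)
  reps <- 50
  ages <- numeric(0); panss <- numeric(0); female <- numeric(0)
  for (r in seq_len(reps)) {
    co <- generate_cohort(suite, 100 + r)
    ages <- c(ages, co$subjects$age)
    panss <- c(panss, co$subjects$baseline_panss_total)
    female <- c(female, co$subjects$sex == "female")
  }
  n <- length(ages)
  target_age <- truncnorm_mean(37, 11, 18, 65)
  expect_lt(abs(mean(ages) - target_age), 3 * 11 / sqrt(n))
  target_panss <- truncnorm_mean(94, 12, 70, 120)
  expect_lt(abs(mean(panss) - target_panss), 3 * 12 / sqrt(n))
  expect_lt(abs(mean(female) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("dropout calibration: realized completion sits in the binomial band", {
  suite <- two_arm_suite(-15, -5, n_a = 200, n_b = 200,
                         completion_a = 0.648, completion_b = 0.368)
  reps <- 15
  done_a <- 0L; done_b <- 0L
  for (r in seq_len(reps)) {
    co <- generate_cohort(suite, 200 + r)
    act <- co$subjects$treatment_group == "PALI_6_12"
    done_a <- done_a + sum(co$subjects$completed[act])
    done_b <- done_b + sum(co$subjects$completed[!act])
  }
  n <- 200L * reps
  band <- function(p) 2.576 * sqrt(p * (1 - p) / n)
  expect_lt(abs(done_a / n - 0.648), band(0.648))
  expect_lt(abs(done_b / n - 0.368), band(0.368))
})

test_that("LOCF effect calibration: realized LOCF arm mean matches the target", {
  suite <- two_arm_suite(-18.4, -6.5, sd_a = 22.7, sd_b = 24,
                         n_a = 150, n_b = 150,
                         completion_a = 0.648, completion_b = 0.368)
  reps <- 40
  ch_a <- numeric(0); ch_b <- numeric(0)
  for (r in seq_len(reps)) {
    co <- generate_cohort(suite, 300 + r)
    ep <- locf_endpoint(co$subjects, co$visits, toy_trial_meta(),
                        measures = "panss_total")
    act <- ep$subject_id %in%
      co$subjects$subject_id[co$subjects$treatment_group == "PALI_6_12"]
    ch_a <- c(ch_a, ep$change[act])
    ch_b <- c(ch_b, ep$change[!act])
  }
  expect_lt(abs(mean(ch_a) - (-18.4)), 3 * sd(ch_a) / sqrt(length(ch_a)))
  expect_lt(abs(mean(ch_b) - (-6.5)), 3 * sd(ch_b) / sqrt(length(ch_b)))
})

test_that("an unsatisfiable entry window names the offending arm", {
  suite <- two_arm_suite(-15, -5, n_a = 10, n_b = 0)
  suite$covariates$panss_mean <- 300   # no mass inside 70-120
  expect_error(generate_cohort(suite, 1), "unsatisfiable truncation window.*T1")
})

test_that("summarize_cohort handles single-subject groups and empty events", {
  co <- generate_cohort(two_arm_suite(-15, -5, n_a = 1, n_b = 20), 4)
  sm <- summarize_cohort(co$subjects, co$visits,
                         co$events[0, , drop = FALSE])
  one <- sm$demographics[sm$demographics$group == "PALI_6_12", ]
  expect_equal(one$n, 1)
  expect_equal(one$age_mean, co$subjects$age[co$subjects$treatment_group == "PALI_6_12"])
  expect_true(is.na(one$age_sd))
  expect_equal(nrow(sm$ae), 0)
})
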