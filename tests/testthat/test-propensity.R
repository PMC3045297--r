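test_that("propensity fit reduces to the group prevalence with constant covariates", {
  s <- make_subjects(10)
  fit <- fit_propensity(s, case_ids = s$subject_id[1:3])
  expect_true(all(abs(fit$scores - 0.3) < 1e-8))
})

test_that("single binary covariate fit equals the closed-form log odds ratio", {
  s <- make_subjects(40)
  s$sex <- rep(c("female", "male"), each = 20)
  # cases: 15 of 20 females, 5 of 20 males
  cases <- c(s$subject_id[1:15], s$subject_id[21:25])
  fit <- fit_propensity(s, cases, covariates = "sex")
  or <- (15 / 5) / (5 / 15)
  expect_equal(unname(fit$coefficients["female"]), log(or), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(5 / 15),
               tolerance = 1e-6)
  # duplicating every row leaves the fitted scores unchanged
  s2 <- rbind(s, transform(s, subject_id = paste0(subject_id, "b")))
  fit2 <- fit_propensity(s2, c(cases, paste0(cases, "b")), covariates = "sex")
  expect_equal(sort(unique(round(fit2$scores, 10))),
               sort(unique(round(fit$scores, 10))))
})

test_that("refitting identical data reproduces coefficients", {
  set.seed(71)
  s <- make_subjects(60)
  s$age <- round(runif(60, 20, 60))
  s$bmi <- round(runif(60, 18, 35), 1)
  cases <- sample(s$subject_id, 30)
  f1 <- fit_propensity(s, cases)
  f2 <- fit_propensity(s, cases)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_true(all(f1$scores > 0 & f1$scores < 1))
})

test_that("degenerate propensity inputs raise informative errors", {
  s <- make_subjects(5)
  expect_error(fit_propensity(s, s$subject_id), "both levels")
  expect_error(fit_propensity(s, s$subject_id[1:2]), "too few subjects")
  sep <- make_subjects(30)
  sep$age <- c(rep(25, 15), rep(55, 15))
  expect_error(fit_propensity(sep, sep$subject_id[1:15], covariates = "age"),
               "separation")
})

test_that("greedy matching handles the elementary cases", {
  m <- greedy_caliper_match(data.frame(id = "A", score = 0.5),
                            data.frame(id = "X", score = 0.5), 0.05)
  expect_equal(m$pairs$control_id, "X")
  expect_equal(m$pairs$distance, 0)

  m2 <- greedy_caliper_match(data.frame(id = "A", score = 0.5),
                             data.frame(id = "X", score = 0.6), 0.05)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_cases, "A")

  m3 <- greedy_caliper_match(data.frame(id = character(), score = numeric()),
                             data.frame(id = "X", score = 0.6), 0.05)
  expect_s3_class(m3, "match_result")
  expect_equal(nrow(m3$pairs), 0)

  expect_error(greedy_caliper_match(data.frame(id = "A", score = 0.5),
                                    data.frame(id = "X", score = 0.5), 0),
               "caliper")
  expect_error(greedy_caliper_match(data.frame(id = "A", score = 1.2),
                                    data.frame(id = "X", score = 0.5), 0.1),
               "strictly in")
})

test_that("equidistant controls go to the lower id and passes accumulate", {
  cases <- data.frame(id = "A", score = 0.50)
  controls <- data.frame(id = c("X2", "X1"), score = c(0.52, 0.48))
  m <- greedy_caliper_match(cases, controls, 0.05)
  # pass 1 takes the tie at the lower id, pass 2 takes the remaining control
  expect_equal(m$pairs$control_id, c("X1", "X2"))
  expect_equal(m$pairs$pass_index, c(1L, 2L))
  m1 <- greedy_caliper_match(cases, controls, 0.05, max_ratio = 1)
  expect_equal(nrow(m1$pairs), 1)
})

test_that("greedy matching agrees with the replay oracle on random instances", {
  set.seed(42)
  for (k in 1:40) {
    nc <- sample(1:6, 1)
    nk <- sample(1:8, 1)
    # coarse grid scores make exact ties common
    cases <- data.frame(id = paste0("c", 1:nc),
                        score = sample(seq(0.30, 0.70, by = 0.02), nc, TRUE))
    controls <- data.frame(id = paste0("k", 1:nk),
                           score = sample(seq(0.30, 0.70, by = 0.02), nk, TRUE))
    caliper <- sample(c(0.02, 0.05, 0.10), 1)
    m <- greedy_caliper_match(cases, controls, caliper)
    o <- greedy_match_oracle(cases, controls, caliper)
    expect_identical(pair_key(m$pairs), pair_key(o))
    # structural invariants
    expect_true(all(m$pairs$distance <= caliper))
    expect_false(anyDuplicated(m$pairs$control_id) > 0)
    expect_true(all(diff(m$pairs$pass_index) >= 0))
  }
})

test_that("matching is invariant to control row order when scores are distinct", {
  set.seed(7)
  cases <- data.frame(id = paste0("c", 1:5), score = runif(5, 0.4, 0.6))
  controls <- data.frame(id = paste0("k", 1:7), score = runif(7, 0.4, 0.6))
  m1 <- greedy_caliper_match(cases, controls, 0.08)
  m2 <- greedy_caliper_match(cases, controls[sample(7), ], 0.08)
  expect_identical(pair_key(m1$pairs), pair_key(m2$pairs))
})

test_that("a non-binding caliper retains every subject in the matched population", {
  set.seed(12)
  n <- 30
  mk <- function(prefix, trial, arm, comp, dose, grp) {
    s <- make_subjects(n, trial_id = trial, arm = arm, compound = comp,
                       dose = dose, group = grp, id_prefix = prefix)
    s$age <- round(runif(n, 20, 60)); s$bmi <- round(runif(n, 19, 33), 1)
    s$baseline_panss_total <- round(runif(n, 75, 115))
    s
  }
  s <- rbind(
    mk("P", "PALI-SCH-303", "paliperidone ER 6 mg/day", "PALI", 6, "PALI_6_12"),
    mk("Q", "PALI-SCH-303", "placebo", "PALI", NA, "PLACEBO_PALI"),
    mk("R", "RIS-INT-3", "risperidone 2 mg/day", "RIS", 2, "RIS_2_4"),
    mk("S", "RIS-INT-3", "placebo", "RIS", NA, "PLACEBO_RIS")
  )
  m <- build_matched_population(s, caliper = 0.999)
  expect_equal(sort(unique(unlist(m$groups))), sort(s$subject_id))
  expect_equal(length(m$groups$RIS_2_4), n)
})

test_that("non-overlapping scores abort with the failing step named", {
  n <- 25
  s <- rbind(
    make_subjects(n, group = "PALI_6_12", id_prefix = "P"),
    make_subjects(n, arm = "placebo", dose = NA, group = "PLACEBO_PALI",
                  id_prefix = "Q"),
    make_subjects(n, trial_id = "RIS-INT-3", arm = "risperidone 2 mg/day",
                  compound = "RIS", dose = 2, group = "RIS_2_4", id_prefix = "R"),
    make_subjects(n, trial_id = "RIS-INT-3", arm = "placebo", compound = "RIS",
                  dose = NA, group = "PLACEBO_RIS", id_prefix = "S")
  )
  set.seed(3)
  # continuous ages give all-distinct scores; a near-zero caliper then
  # admits no pair at all in the first step
  s$age <- runif(nrow(s), 25, 55)
  expect_error(build_matched_population(s, caliper = 1e-9),
               "risperidone vs placebo \\(RIS\\).*no pairs")
})

test_that("balance table: self-comparison and equal means give zero SMD", {
  set.seed(5)
  s <- make_subjects(30)
  s$age <- round(runif(30, 20, 60))
  b <- balance_table(s, groups = list(a = s$subject_id, b = s$subject_id))
  expect_true(all(b$smd$smd == 0))

  x <- make_subjects(20, id_prefix = "X"); y <- make_subjects(20, id_prefix = "Y")
  x$age <- rep(c(30, 50), 10)   # mean 40, some spread
  y$age <- rep(c(20, 60), 10)   # mean 40, larger spread
  b2 <- balance_table(rbind(x, y),
                      groups = list(x = x$subject_id, y = y$subject_id))
  expect_equal(b2$smd$smd[b2$smd$covariate == "age"], 0)
})

test_that("matching shrinks covariate imbalance on confounded assignments", {
  shrunk <- integer(0)
  for (r in 1:5) {
    set.seed(500 + r)
    n <- 300
    s <- make_subjects(n, id_prefix = "Z")
    s$age <- round(rnorm(n, 37, 11)); s$age <- pmin(pmax(s$age, 18), 65)
    s$bmi <- round(rnorm(n, 25, 4), 1)
    s$baseline_panss_total <- round(rnorm(n, 94, 12))
    s$sex <- ifelse(runif(n) < 0.3, "female", "male")
    s$race <- ifelse(runif(n) < 0.7, "white", "other")
    # confounded assignment: older, sicker subjects more often treated
    p <- plogis(-0.5 + 0.06 * (s$age - 37) + 0.04 * (s$baseline_panss_total - 94))
    treated <- runif(n) < p
    t_ids <- s$subject_id[treated]; c_ids <- s$subject_id[!treated]
    pre <- balance_table(s, list(t = t_ids, c = c_ids))$smd
    fit <- fit_propensity(s, t_ids)
    cases <- data.frame(id = t_ids, score = unname(fit$scores[t_ids]))
    ctrls <- data.frame(id = c_ids, score = unname(fit$scores[c_ids]))
    m <- if (length(t_ids) <= length(c_ids)) {
      greedy_caliper_match(cases, ctrls, 0.05)
    } else greedy_caliper_match(ctrls, cases, 0.05)
    keep <- c(m$pairs$case_id, m$pairs$control_id)
    post <- balance_table(s[s$subject_id %in% keep, ],
                          list(t = intersect(t_ids, keep),
                               c = intersect(c_ids, keep)))$smd
    shrunk <- c(shrunk, sum(post$smd <= pre$smd + 1e-9))
  }
  # on average at least 5 of the 6 covariates improve
  expect_gte(mean(shrunk), 5)
})

test_that("placebo poolability pools identical groups and rejects large shifts", {
  co <- generate_cohort(two_arm_suite(-6.5, -6.5, n_a = 0, n_b = 60), 21)
  # a value-identical copy of the placebo group under the other program
  s_r <- co$subjects
  s_r$subject_id <- paste0(s_r$subject_id, "R")
  s_r$compound_program <- "RIS"
  s_r$treatment_group <- "PLACEBO_RIS"
  v_r <- co$visits
  v_r$subject_id <- paste0(v_r$subject_id, "R")
  pp <- placebo_poolability(rbind(co$subjects, s_r), rbind(co$visits, v_r),
                            trial_meta = toy_trial_meta())
  expect_true(pp$pool)
  expect_equal(pp$endpoint$difference, rep(0, nrow(pp$endpoint)))
  expect_equal(pp$endpoint$p_value, rep(1, nrow(pp$endpoint)))

  # two groups 15 PANSS points apart at published scale: decisively not pooled
  suite <- two_arm_suite(-20.4, -5.4, n_a = 95, n_b = 122,
                         completion_a = 0.368, completion_b = 0.516)
  co2 <- generate_cohort(suite, 22)
  s2 <- co2$subjects
  act <- s2$treatment_group == "PALI_6_12"
  s2$modal_dose_mg <- NA
  s2$treatment_group[act] <- "PLACEBO_PALI"
  s2$compound_program[!act] <- "RIS"
  s2$treatment_group[!act] <- "PLACEBO_RIS"
  pp2 <- placebo_poolability(s2, co2$visits, trial_meta = toy_trial_meta())
  expect_false(pp2$pool)
  expect_lt(pp2$endpoint$p_value[pp2$endpoint$measure == "panss_total"], 0.05)
})
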