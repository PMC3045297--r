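test_that("LOCF carries the last pre-endpoint observation and logs exclusions", {
  s <- rbind(make_subjects(1, id_prefix = "C"),          # completer
             make_subjects(1, id_prefix = "D"),          # drops after week 3
             make_subjects(1, id_prefix = "B"))          # baseline only
  v <- rbind(
    do.call(rbind, lapply(0:6, function(w) toy_visit_row("C0001", w, 95 - 3 * w))),
    do.call(rbind, lapply(0:3, function(w) toy_visit_row("D0001", w, 90 - 2 * w))),
    toy_visit_row("B0001", 0, 100),
    toy_visit_row("C0001", 8, 30)     # past the endpoint week: ignored
  )
  ep <- locf_endpoint(s, v, measures = "panss_total")
  cc <- ep[ep$subject_id == "C0001", ]
  expect_equal(cc$endpoint, 95 - 18)
  expect_equal(cc$carried_from_week, 6)
  dd <- ep[ep$subject_id == "D0001", ]
  expect_equal(dd$endpoint, 84)
  expect_equal(dd$carried_from_week, 3)
  expect_equal(dd$change, -6)
  expect_false("B0001" %in% ep$subject_id)
  expect_equal(attr(ep, "excluded")$panss_total, "B0001")
  # idempotence: recomputing from the same visits reproduces the records
  expect_equal(locf_endpoint(s, v, measures = "panss_total"), ep)
})

test_that("endpoint week is trial-specific", {
  s <- rbind(
    make_subjects(1, trial_id = "RIS-USA-72", compound = "RIS", dose = 4,
                  group = "RIS_2_4", arm = "risperidone 4 mg/day", panss = 90,
                  id_prefix = "F"),
    make_subjects(1, trial_id = "RIS-INT-3", compound = "RIS", dose = 6,
                  group = "RIS_4_6", arm = "risperidone 6 mg/day",
                  id_prefix = "E")
  )
  v <- rbind(
    do.call(rbind, lapply(c(0, 2, 4, 6), function(w) toy_visit_row("F0001", w, 90 - w))),
    do.call(rbind, lapply(c(0, 4, 8), function(w) toy_visit_row("E0001", w, 94 - w)))
  )
  ep <- locf_endpoint(s, v, measures = "panss_total")
  expect_equal(ep$carried_from_week[ep$subject_id == "F0001"], 4)  # 4-week trial
  expect_equal(ep$carried_from_week[ep$subject_id == "E0001"], 8)  # 8-week trial
})

test_that("responder rule is an exact 30%-of-baseline boundary", {
  ep <- data.frame(
    subject_id = c("a", "b", "c"), measure = "panss_total",
    baseline = c(100, 94, 90), endpoint = c(70, 66, 95),
    change = c(-30, -28, 5), carried_from_week = 6,
    stringsAsFactors = FALSE
  )
  r <- responder_flags(ep)
  expect_identical(r$flags$responder, c(TRUE, FALSE, FALSE))

  grps <- list(g1 = c("a", "b"), g2 = "c")
  r2 <- responder_flags(ep, groups = grps)
  expect_equal(r2$rates$pct[r2$rates$group == "g1"], 50.0)
  # invariance under subject reordering
  r3 <- responder_flags(ep[3:1, ], groups = grps)
  expect_equal(r3$rates, r2$rates)

  ep$baseline[1] <- 0
  expect_error(responder_flags(ep), "baseline")
})

test_that("ANCOVA matches the normal-equations oracle on toy data", {
  set.seed(33)
  dat <- data.frame(
    group = rep(c("A", "B"), each = 4),
    baseline = c(90, 95, 100, 105, 88, 96, 101, 99),
    change = c(-10, -14, -9, -20, -4, -6, -12, -7)
  )
  cc <- ancova_contrast(dat)
  o <- ancova_oracle(dat$group, dat$baseline, dat$change)
  expect_equal(cc$adjusted_means$adjusted_mean, o$adjusted_means,
               tolerance = 1e-6)
  expect_equal(cc$adjusted_means$se, o$adjusted_se, tolerance = 1e-6)
  expect_equal(cc$differences$estimate, o$differences$estimate,
               tolerance = 1e-6)
  expect_equal(cc$differences$se, o$differences$se, tolerance = 1e-6)
  expect_equal(cc$differences$p_value, o$differences$p_value,
               tolerance = 1e-6)

  # three-group case
  set.seed(34)
  d3 <- data.frame(group = rep(c("A", "B", "C"), each = 6),
                   baseline = round(rnorm(18, 95, 10)),
                   change = round(rnorm(18, -12, 8)))
  c3 <- ancova_contrast(d3)
  o3 <- ancova_oracle(d3$group, d3$baseline, d3$change)
  expect_equal(c3$adjusted_means$adjusted_mean, o3$adjusted_means,
               tolerance = 1e-6)
  expect_equal(c3$differences$estimate, o3$differences$estimate,
               tolerance = 1e-6)
})

test_that("adjusted mean differences are antisymmetric under relabeling", {
  set.seed(35)
  dat <- data.frame(group = rep(c("A", "B"), each = 10),
                    baseline = rnorm(20, 95, 10), change = rnorm(20, -10, 6))
  d_ab <- ancova_contrast(dat)$differences$estimate
  swapped <- dat
  swapped$group <- ifelse(dat$group == "A", "B", "A")
  d_ba <- ancova_contrast(swapped)$differences$estimate
  expect_equal(d_ab, -d_ba, tolerance = 1e-10)
})

test_that("zero-variance baseline drops the covariate and equals one-way ANOVA", {
  dat <- data.frame(group = rep(c("A", "B"), each = 5),
                    baseline = 100,
                    change = c(-8, -12, -10, -9, -11, -3, -5, -4, -6, -2))
  expect_warning(cc <- ancova_contrast(dat), "zero variance")
  expect_true(cc$covariate_dropped)
  o <- ancova_oracle(dat$group, dat$baseline, dat$change, use_baseline = FALSE)
  expect_equal(cc$adjusted_means$adjusted_mean, o$adjusted_means,
               tolerance = 1e-8)
  raw <- tapply(dat$change, dat$group, mean)
  expect_equal(cc$adjusted_means$adjusted_mean,
               as.numeric(raw[cc$adjusted_means$group]))
  expect_equal(cc$differences$p_value, o$differences$p_value, tolerance = 1e-8)
})

test_that("ANCOVA rejects groups that are too small or collinear designs", {
  expect_error(ancova_contrast(data.frame(group = "A", baseline = 1, change = 1)),
               "two groups")
  expect_error(ancova_contrast(data.frame(group = c("A", "A", "B"),
                                          baseline = c(90, 95, 92),
                                          change = c(-1, -2, -3))),
               "at least two subjects")
  # baseline perfectly collinear with the group indicator
  dat <- data.frame(group = rep(c("A", "B"), each = 3),
                    baseline = rep(c(90, 110), each = 3),
                    change = c(-1, -2, -3, -4, -5, -6))
  expect_error(ancova_contrast(dat), "singular|collinear")
})

test_that("chi-square contrast equals the hand formula", {
  flat <- categorical_contrast(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  tab <- rbind(c(30, 70), c(50, 50))
  got <- categorical_contrast(tab)
  want <- chisq_oracle(tab)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  expect_equal(got$df, 1)

  expect_equal(categorical_contrast(rbind(c(5, 6, 7), c(8, 9, 10)))$df, 2)
  expect_error(categorical_contrast(rbind(c(0, 0), c(3, 4))), "zero row")
  expect_error(categorical_contrast(rbind(c(-1, 2), c(3, 4))), "non-negative")
})
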