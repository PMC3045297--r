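# Builders for small in-code fixtures: hand-made subject tables and compact
# scenario suites used across the test files.

make_subjects <- function(n, trial_id = "PALI-SCH-303", arm = "paliperidone ER 6 mg/day",
                          compound = "PALI", dose = 6, group = "PALI_6_12",
                          age = 37, sex = "male", race = "white", bmi = 25,
                          panss = 94, cgi = 5, completed = TRUE,
                          id_prefix = "S") {
  data.frame(
    subject_id = paste0(id_prefix, sprintf("%04d", seq_len(n))),
    trial_id = trial_id, arm = arm, compound_program = compound,
    modal_dose_mg = dose, treatment_group = group,
    age = rep_len(age, n), sex = rep_len(sex, n), race = rep_len(race, n),
    bmi = rep_len(bmi, n), baseline_panss_total = rep_len(panss, n),
    baseline_cgi_s = rep_len(cgi, n), completed = rep_len(completed, n),
    discontinuation_week = ifelse(rep_len(completed, n), NA_integer_, 2L),
    prior_atypical_only = FALSE,
    stringsAsFactors = FALSE
  )
}

toy_trial_meta <- function(trial_id = "T1", weeks = 6, lo = 70, hi = 120) {
  data.frame(
    trial_id = trial_id, program = "PALI", duration_weeks = weeks,
    endpoint_week = weeks, panss_low = lo, panss_high = hi, doses_mg = "6",
    has_factor_scores = TRUE, has_cgi = TRUE, stringsAsFactors = FALSE
  )
}

toy_covariates <- function(group = "G1") {
  data.frame(
    covariate_group = group, age_mean = 37, age_sd = 11, female_p = 0.25,
    white_p = 0.75, bmi_mean = 25, bmi_sd = 4, panss_mean = 94,
    panss_sd = 12, cgi_mean = 4.7, cgi_sd = 0.7, stringsAsFactors = FALSE
  )
}

toy_arm <- function(trial_id = "T1", arm = "paliperidone ER 6 mg/day",
                    program = "PALI", dose = 6, n = 50, cov_group = "G1",
                    effect = -15, effect_sd = 20, cgi_effect = -0.5,
                    completion = 0.8, weight_delta = 0.5) {
  out <- data.frame(
    trial_id = trial_id, arm = arm, compound_program = program,
    modal_dose_mg = dose, n = n, covariate_group = cov_group,
    ae_group = cov_group, endpoint_effect = effect, effect_sd = effect_sd,
    cgi_effect = cgi_effect, completion_rate = completion,
    weight_delta_kg = weight_delta, stringsAsFactors = FALSE
  )
  out[paste0("share_", c("negative", "positive", "anxiety_depression",
                         "disorganized_thoughts", "hostility_excitement"))] <-
    as.list(c(0.25, 0.35, 0.15, 0.15, 0.10))
  out
}

# Two-arm, one-trial suite: an active arm and a placebo arm with the given
# endpoint effects, SDs and completion rates.
two_arm_suite <- function(effect_a, effect_b, sd_a = 22.7, sd_b = 24,
                          n_a = 100, n_b = 100, completion_a = 0.8,
                          completion_b = 0.8, weeks = 6,
                          locf_calibrated = TRUE) {
  arms <- rbind(
    toy_arm("T1", "paliperidone ER 6 mg/day", "PALI", 6, n_a, "G1",
            effect = effect_a, effect_sd = sd_a, completion = completion_a),
    toy_arm("T1", "placebo", "PALI", NA, n_b, "G1",
            effect = effect_b, effect_sd = sd_b, completion = completion_b)
  )
  make_suite(toy_trial_meta("T1", weeks), arms, toy_covariates("G1"),
             locf_calibrated = locf_calibrated)
}

toy_visit_row <- function(subject_id, week, panss, cgi = 4L, weight = 80) {
  data.frame(
    subject_id = subject_id, week = as.integer(week),
    panss_total = as.integer(panss),
    panss_negative = NA_integer_, panss_positive = NA_integer_,
    panss_anxiety_depression = NA_integer_,
    panss_disorganized_thoughts = NA_integer_,
    panss_hostility_excitement = NA_integer_,
    cgi_s = as.integer(cgi), weight_kg = weight, stringsAsFactors = FALSE
  )
}
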