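#' Construct a scenario suite for the synthetic cohort generator
#'
#' A scenario suite bundles everything [generate_cohort()] needs: trial
#' metadata, one row per arm with its size and calibration targets, baseline
#' covariate moments per covariate group, and per-arm adverse-event incidence
#' probabilities. [default_suite()] returns the suite calibrated to the
#' published six-trial analysis; `make_suite()` is the validating constructor
#' used for custom (e.g. toy or stress-test) scenarios.
#'
#' @param trial_meta data.frame as [default_trial_meta()].
#' @param arms data.frame, one row per arm, with columns `trial_id`, `arm`,
#'   `compound_program`, `modal_dose_mg` (NA for placebo), `n`,
#'   `covariate_group`, `ae_group`, `endpoint_effect` (mean PANSS total
#'   change at the protocol endpoint; negative = improvement), `effect_sd`,
#'   `share_negative`, `share_positive`, `share_anxiety_depression`,
#'   `share_disorganized_thoughts`, `share_hostility_excitement`
#'   (non-negative, sum 1: how the total change splits across factors),
#'   `cgi_effect`, `completion_rate` in (0, 1], `weight_delta_kg`.
#' @param covariates data.frame keyed by `covariate_group` with columns
#'   `age_mean`, `age_sd`, `female_p`, `white_p`, `bmi_mean`, `bmi_sd`,
#'   `panss_mean`, `panss_sd`, `cgi_mean`, `cgi_sd`.
#' @param ae_rates data.frame `ae_group`, `preferred_term`, `rate` (per-term
#'   incidence probabilities), or NULL for no adverse events.
#' @param noise list of nuisance scales; see [default_noise()].
#' @param dropout list(mechanism = "mcar" or "mar_improvement", gamma):
#'   dropout is a constant discrete-time hazard solved so survival to the
#'   endpoint equals `completion_rate`; with "mar_improvement" the weekly
#'   hazard additionally depends (logit-linearly, slope `gamma` per 10 PANSS
#'   points of current improvement) on the subject's latent improvement,
#'   for stress-testing LOCF.
#' @param locf_calibrated logical; when TRUE (default) the latent endpoint
#'   improvement is rescaled so the expected LOCF arm mean equals
#'   `endpoint_effect` despite dropout (see the methods vignette).
#' @return object of class `scenario_suite`.
#' @export
make_suite <- function(trial_meta, arms, covariates, ae_rates = NULL,
                       noise = default_noise(),
                       dropout = list(mechanism = "mcar", gamma = 0),
                       locf_calibrated = TRUE) {
  share_cols <- paste0("share_", PANSS_FACTORS)
  need <- c("trial_id", "arm", "compound_program", "modal_dose_mg", "n",
            "covariate_group", "ae_group", "endpoint_effect", "effect_sd",
            share_cols, "cgi_effect", "completion_rate", "weight_delta_kg")
  check_columns(arms, need, "arm scenario")
  bad_trial <- setdiff(arms$trial_id, trial_meta$trial_id)
  if (length(bad_trial) > 0) {
    stop("arm references undeclared trial: ", bad_trial[1])
  }
  sh <- as.matrix(arms[, share_cols])
  if (any(sh < -1e-9)) stop("factor_effect_shares must be non-negative")
  if (any(abs(rowSums(sh) - 1) > 1e-6)) {
    stop("factor_effect_shares must sum to 1 for every arm")
  }
  if (any(arms$completion_rate <= 0 | arms$completion_rate > 1)) {
    stop("completion_rate must be in (0, 1]")
  }
  if (any(covariates$female_p < 0 | covariates$female_p > 1 |
            covariates$white_p < 0 | covariates$white_p > 1)) {
    stop("covariate proportions must be in [0, 1]")
  }
  if (!is.null(ae_rates) && nrow(ae_rates) > 0 &&
        any(ae_rates$rate < 0 | ae_rates$rate > 1)) {
    stop("adverse-event incidence probabilities must be in [0, 1]")
  }
  structure(
    list(trial_meta = trial_meta, arms = arms, covariates = covariates,
         ae_rates = ae_rates, noise = noise, dropout = dropout,
         locf_calibrated = locf_calibrated),
    class = "scenario_suite"
  )
}

#' @rdname make_suite
#' @export
default_noise <- function() {
  list(
    panss_factor_sd = 1.8,   # per-factor visit noise (score points)
    cgi_subject_sd = 0.8,    # between-subject SD of CGI-S change
    cgi_visit_sd = 0.3,
    weight_change_sd = 4.0,  # between-subject SD of endpoint weight change (kg)
    weight_visit_sd = 0.4,
    weight_baseline_mean = 80,
    weight_baseline_sd = 15
  )
}

# Published group-level calibration targets for the five analysis groups.
group_targets <- function() {
  g <- c("PALI_6_12", "RIS_2_4", "RIS_4_6", "PLACEBO_PALI", "PLACEBO_RIS")
  targets <- data.frame(
    group = g,
    endpoint_effect = c(-18.4, -11.6, -18.7, -6.5, -5.4),
    # between-subject SDs recovered from printed SEs at the analysis ns
    effect_sd = c(22.7, 23.4, 22.4, 24.0, 24.2),
    cgi_effect = c(-0.9, 0.0, -0.1, -0.2, -0.2),
    completion_rate = c(0.648, 0.540, 0.667, 0.368, 0.516),
    weight_delta_kg = c(0.7, 1.0, 1.3, 0.0, 0.0),
    stringsAsFactors = FALSE
  )
  # printed mean factor changes; worsening (positive) changes are clamped to a
  # zero share before normalizing, keeping shares non-negative
  fc <- rbind(
    PALI_6_12 = c(-4.7, -6.2, -2.3, -3.5, -1.4),
    RIS_2_4 = c(-2.5, -4.5, -1.7, -2.3, -0.6),
    RIS_4_6 = c(-3.8, -6.3, -2.5, -4.2, -2.0),
    PLACEBO_PALI = c(-1.3, -2.5, -1.3, -1.2, 0.4),
    PLACEBO_RIS = c(-2.3, -1.6, -1.8, -0.6, 0.9)
  )
  colnames(fc) <- PANSS_FACTORS
  sh <- pmax(-fc, 0)
  sh <- sh / rowSums(sh)
  targets[paste0("share_", PANSS_FACTORS)] <- sh[targets$group, ]
  covs <- data.frame(
    group = g,
    age_mean = c(37.4, 37.8, 37.1, 36.7, 38.0),
    age_sd = c(11.3, 10.6, 10.1, 10.9, 10.1),
    female_p = c(0.251, 0.274, 0.248, 0.242, 0.148),
    white_p = c(0.760, 0.735, 0.767, 0.916, 0.936),
    bmi_mean = c(25.2, 25.5, 25.5, 24.9, 25.3),
    bmi_sd = c(4.7, 3.3, 3.4, 5.2, 3.2),
    panss_mean = c(94.3, 94.4, 96.2, 94.5, 92.6),
    panss_sd = c(11.9, 15.2, 16.6, 12.2, 12.3),
    cgi_mean = c(4.8, 4.8, 4.8, 4.6, 4.7),
    cgi_sd = c(0.7, 0.6, 0.7, 0.7, 0.8),
    stringsAsFactors = FALSE
  )
  # per-term incidence (proportions) per group, published safety table
  terms <- c("insomnia", "sinus tachycardia", "tachycardia", "somnolence",
             "restlessness", "nausea", "anxiety", "salivary hypersecretion",
             "akathisia", "dizziness", "nasal congestion")
  ae <- rbind(
    PALI_6_12 = c(.145, .078, .067, .039, .000, .022, .017, .017, .045, .045, .006),
    RIS_2_4 = c(.221, .009, .009, .089, .080, .080, .097, .053, .044, .044, .035),
    RIS_4_6 = c(.171, .016, .023, .070, .054, .085, .109, .039, .047, .062, .054),
    PLACEBO_PALI = c(.095, .042, .032, .053, .000, .042, .021, .000, .032, .032, .000),
    PLACEBO_RIS = c(.189, .000, .000, .016, .008, .033, .057, .000, .008, .025, .025)
  )
  colnames(ae) <- terms
  list(targets = targets, covariates = covs, ae = ae)
}

# Solve dose-level parameters from the two overlapping dose-group targets.
# The 4 mg/day arm (n4 subjects, member of both groups) takes the mean of the
# group targets; the 2 mg and 6 mg levels are solved so the subject-weighted
# group means equal the printed group values.
solve_dose_levels <- function(t24, t46, n24 = 113, n46 = 129, n4 = 63) {
  p4 <- (t24 + t46) / 2
  list(
    d2 = (t24 * n24 - p4 * n4) / (n24 - n4),
    d4 = p4,
    d6 = (t46 * n46 - p4 * n4) / (n46 - n4)
  )
}

#' Default six-trial scenario suite
#'
#' The generator's study conditions: six trials (three per program) with the
#' published arm structures, per-group baseline covariate moments, endpoint
#' effects, completion rates, adverse-event incidences and weight changes.
#' Because the comparator's 4 mg/day subjects (n = 63) belong to both
#' comparator dose groups, dose-level parameters for the flexible-dose arms
#' are solved from the group-level targets (see the methods vignette for the
#' constants table and rationale).
#'
#' @return a `scenario_suite`; see [make_suite()].
#' @export
default_suite <- function() {
  gt <- group_targets()
  tg <- gt$targets
  rownames(tg) <- tg$group
  share_cols <- paste0("share_", PANSS_FACTORS)

  # dose-level parameters for the comparator arms
  num_fields <- c("endpoint_effect", "effect_sd", "cgi_effect",
                  "completion_rate", "weight_delta_kg")
  dose <- lapply(num_fields, function(f) {
    solve_dose_levels(tg["RIS_2_4", f], tg["RIS_4_6", f])
  })
  names(dose) <- num_fields
  dual_shares <- (unlist(tg["RIS_2_4", share_cols]) +
                    unlist(tg["RIS_4_6", share_cols])) / 2
  dual_shares <- dual_shares / sum(dual_shares)

  arm_row <- function(trial, arm, program, dose_mg, n, cov_group, ae_group,
                      eff, eff_sd, shares, cgi, compl, wt) {
    out <- data.frame(
      trial_id = trial, arm = arm, compound_program = program,
      modal_dose_mg = dose_mg, n = n, covariate_group = cov_group,
      ae_group = ae_group, endpoint_effect = eff, effect_sd = eff_sd,
      cgi_effect = cgi, completion_rate = compl, weight_delta_kg = wt,
      stringsAsFactors = FALSE
    )
    out[share_cols] <- as.list(shares)
    out
  }
  grp_row <- function(trial, arm, program, dose_mg, n, group) {
    arm_row(trial, arm, program, dose_mg, n, group, group,
            tg[group, "endpoint_effect"], tg[group, "effect_sd"],
            unlist(tg[group, share_cols]), tg[group, "cgi_effect"],
            tg[group, "completion_rate"], tg[group, "weight_delta_kg"])
  }
  ris_row <- function(trial, arm, dose_mg, n, level, cov_group, ae_group) {
    arm_row(trial, arm, "RIS", dose_mg, n, cov_group, ae_group,
            dose$endpoint_effect[[level]], dose$effect_sd[[level]],
            if (level == "d4") dual_shares else
              unlist(tg[if (level == "d2") "RIS_2_4" else "RIS_4_6", share_cols]),
            dose$cgi_effect[[level]], dose$completion_rate[[level]],
            dose$weight_delta_kg[[level]])
  }

  arms <- rbind(
    grp_row("PALI-SCH-303", "paliperidone ER 6 mg/day", "PALI", 6, 30, "PALI_6_12"),
    grp_row("PALI-SCH-303", "paliperidone ER 12 mg/day", "PALI", 12, 30, "PALI_6_12"),
    grp_row("PALI-SCH-303", "placebo", "PALI", NA, 32, "PLACEBO_PALI"),
    grp_row("PALI-SCH-304", "paliperidone ER 6 mg/day", "PALI", 6, 30, "PALI_6_12"),
    grp_row("PALI-SCH-304", "paliperidone ER 12 mg/day", "PALI", 12, 30, "PALI_6_12"),
    grp_row("PALI-SCH-304", "placebo", "PALI", NA, 32, "PLACEBO_PALI"),
    grp_row("PALI-SCH-305", "paliperidone ER 9 mg/day", "PALI", 9, 59, "PALI_6_12"),
    grp_row("PALI-SCH-305", "placebo", "PALI", NA, 31, "PLACEBO_PALI"),
    ris_row("RIS-USA-1", "risperidone 2 mg/day", 2, 30, "d2", "RIS_2_4", "RIS_D2"),
    ris_row("RIS-USA-1", "risperidone 4 mg/day", 4, 63, "d4", "RIS_4_DUAL", "RIS_D4"),
    ris_row("RIS-USA-1", "risperidone 6 mg/day", 6, 30, "d6", "RIS_4_6", "RIS_D6"),
    grp_row("RIS-USA-1", "placebo", "RIS", NA, 40, "PLACEBO_RIS"),
    ris_row("RIS-INT-3", "risperidone 2 mg/day", 2, 20, "d2", "RIS_2_4", "RIS_D2"),
    ris_row("RIS-INT-3", "risperidone 6 mg/day", 6, 36, "d6", "RIS_4_6", "RIS_D6"),
    grp_row("RIS-INT-3", "placebo", "RIS", NA, 52, "PLACEBO_RIS"),
    # 8 mg/day sits inside the dose cap but outside both defined dose groups
    ris_row("RIS-USA-72", "risperidone 8 mg/day", 8, 12, "d6", "RIS_4_6", "RIS_D6"),
    grp_row("RIS-USA-72", "placebo", "RIS", NA, 30, "PLACEBO_RIS")
  )

  covs <- gt$covariates
  dual_cov <- covs[covs$group == "RIS_2_4", -1] / 2 +
    covs[covs$group == "RIS_4_6", -1] / 2
  covs <- rbind(covs, cbind(group = "RIS_4_DUAL", dual_cov))
  names(covs)[1] <- "covariate_group"

  ae <- gt$ae
  ae_dose <- lapply(colnames(ae), function(term) {
    lv <- solve_dose_levels(ae["RIS_2_4", term], ae["RIS_4_6", term])
    c(RIS_D2 = max(0, min(1, lv$d2)), RIS_D4 = lv$d4,
      RIS_D6 = max(0, min(1, lv$d6)))
  })
  names(ae_dose) <- colnames(ae)
  ae_long <- do.call(rbind, lapply(colnames(ae), function(term) {
    data.frame(
      ae_group = c(rownames(ae), names(ae_dose[[term]])),
      preferred_term = term,
      rate = c(ae[, term], unname(ae_dose[[term]])),
      stringsAsFactors = FALSE
    )
  }))
  rownames(ae_long) <- NULL

  make_suite(default_trial_meta(), arms, covs, ae_long)
}

# Expected carried-forward fraction of the endpoint effect among subjects
# with at least one post-baseline visit, under linear gain f(t) = t/W and a
# constant weekly dropout hazard h. Used to calibrate the latent improvement
# so the LOCF arm mean hits endpoint_effect.
locf_fraction <- function(completion, W) {
  if (completion >= 1) return(1)
  h <- 1 - completion^(1 / W)
  j <- 0:(W - 1)
  ef <- sum((j / W) * (1 - h)^j * h) + completion
  ef / (1 - h)
}

#' Generate a synthetic patient-level cohort
#'
#' Draws baseline covariates from truncated-normal (continuous) and
#' Bernoulli (binary) generators with the suite's moments, simulates a
#' per-subject latent improvement trajectory (linear cumulative fraction of
#' the endpoint effect plus independent visit noise, with PANSS total equal
#' to the sum of the five factor scores at every visit), dropout as a
#' constant discrete-time hazard solved so survival to the protocol endpoint
#' equals the arm's completion rate (post-dropout visits removed), per-term
#' independent adverse events, and weight change normal around the arm's
#' target. A fixed `(suite, seed)` gives byte-identical output.
#'
#' @param suite a `scenario_suite` from [make_suite()] or [default_suite()].
#' @param seed integer RNG seed.
#' @return list with data.frames `subjects`, `visits`, `events`.
#' @export
generate_cohort <- function(suite, seed) {
  stopifnot(inherits(suite, "scenario_suite"))
  set.seed(as.integer(seed))
  noise <- suite$noise
  share_cols <- paste0("share_", PANSS_FACTORS)
  items <- PANSS_FACTOR_ITEMS

  subj_list <- list(); visit_list <- list(); event_list <- list()
  for (a in seq_len(nrow(suite$arms))) {
    arm <- suite$arms[a, ]
    n <- arm$n
    if (n == 0) next
    tm <- suite$trial_meta[suite$trial_meta$trial_id == arm$trial_id, ]
    W <- tm$endpoint_week
    cov <- suite$covariates[suite$covariates$covariate_group == arm$covariate_group, ]
    if (nrow(cov) != 1) stop("missing covariate group ", arm$covariate_group)
    label <- paste(arm$trial_id, arm$arm)

    ids <- sprintf("%s-A%02d-%04d", arm$trial_id, a, seq_len(n))
    age <- round(rtruncnorm(n, cov$age_mean, cov$age_sd, 18, 65, label))
    sex <- ifelse(runif(n) < cov$female_p, "female", "male")
    race <- ifelse(runif(n) < cov$white_p, "white", "other")
    bmi <- round(rtruncnorm(n, cov$bmi_mean, cov$bmi_sd, 15, 60, label), 1)
    panss0 <- as.integer(round(rtruncnorm(n, cov$panss_mean, cov$panss_sd,
                                          tm$panss_low, tm$panss_high, label)))
    panss0 <- pmin(pmax(panss0, tm$panss_low), tm$panss_high)
    cgi0 <- as.integer(pmin(7, pmax(1, round(
      rtruncnorm(n, cov$cgi_mean, cov$cgi_sd, 1, 7, label)))))
    weight0 <- round(rtruncnorm(n, noise$weight_baseline_mean,
                                noise$weight_baseline_sd, 40, 160, label), 1)

    # latent endpoint changes; rescaled so the LOCF mean hits the target
    scale <- if (isTRUE(suite$locf_calibrated)) {
      1 / locf_fraction(arm$completion_rate, W)
    } else 1
    delta <- rnorm(n, arm$endpoint_effect * scale, arm$effect_sd)
    dcgi <- rnorm(n, arm$cgi_effect * scale, noise$cgi_subject_sd)
    dwt <- rnorm(n, arm$weight_delta_kg * scale, noise$weight_change_sd)

    # dropout: last observed week per subject
    h <- 1 - arm$completion_rate^(1 / W)
    if (h <= 0) {
      last_week <- rep.int(W, n)
    } else if (suite$dropout$mechanism == "mar_improvement") {
      gamma <- suite$dropout$gamma %||% 0
      last_week <- vapply(seq_len(n), function(i) {
        for (k in seq_len(W)) {
          hk <- plogis(qlogis(h) + gamma * ((k - 1) / W) * delta[i] / 10)
          if (runif(1) < hk) return(k - 1L)
        }
        W
      }, integer(1))
    } else {
      u <- matrix(runif(n * W) < h, n, W)
      first <- apply(u, 1, function(r) which(r)[1])
      last_week <- ifelse(is.na(first), W, first - 1L)
    }
    completed <- last_week == W

    bmat <- t(vapply(panss0, partition_integer, integer(5), weights = items))
    shares <- unlist(arm[share_cols])

    nv <- last_week + 1L
    idx <- rep.int(seq_len(n), nv)
    wk <- unlist(lapply(last_week, function(l) 0:l), use.names = FALSE)
    f <- wk / W
    post <- wk > 0
    fmat <- matrix(0L, length(idx), 5)
    for (j in 1:5) {
      v <- bmat[idx, j] + shares[j] * f * delta[idx] +
        rnorm(length(idx), 0, noise$panss_factor_sd) * post
      fmat[, j] <- as.integer(pmin(pmax(round(v), items[j]), 7L * items[j]))
    }
    total <- as.integer(rowSums(fmat))
    cgi_v <- as.integer(pmin(7, pmax(1, round(
      cgi0[idx] + f * dcgi[idx] + rnorm(length(idx), 0, noise$cgi_visit_sd) * post))))
    wt_v <- round(weight0[idx] + f * dwt[idx] +
                    rnorm(length(idx), 0, noise$weight_visit_sd) * post, 1)

    vis <- data.frame(
      subject_id = ids[idx], week = wk, panss_total = total,
      panss_negative = fmat[, 1], panss_positive = fmat[, 2],
      panss_anxiety_depression = fmat[, 3],
      panss_disorganized_thoughts = fmat[, 4],
      panss_hostility_excitement = fmat[, 5],
      cgi_s = cgi_v, weight_kg = wt_v,
      stringsAsFactors = FALSE
    )
    if (!tm$has_factor_scores) {
      vis[paste0("panss_", PANSS_FACTORS)] <- NA_integer_
    }
    if (!tm$has_cgi) vis$cgi_s <- NA_integer_
    visit_list[[length(visit_list) + 1L]] <- vis

    if (!is.null(suite$ae_rates)) {
      rates <- suite$ae_rates[suite$ae_rates$ae_group == arm$ae_group, ]
      for (r in seq_len(nrow(rates))) {
        hit <- runif(n) < rates$rate[r]
        onset_u <- runif(n)
        if (any(hit)) {
          onset <- ifelse(last_week >= 1, 1L + floor(onset_u * last_week), 0L)
          event_list[[length(event_list) + 1L]] <- data.frame(
            subject_id = ids[hit],
            preferred_term = rates$preferred_term[r],
            onset_week = as.integer(onset[hit]),
            stringsAsFactors = FALSE
          )
        }
      }
    }

    subj_list[[length(subj_list) + 1L]] <- data.frame(
      subject_id = ids, trial_id = arm$trial_id, arm = arm$arm,
      compound_program = arm$compound_program,
      modal_dose_mg = arm$modal_dose_mg,
      treatment_group = assign_treatment_group(arm$compound_program,
                                               arm$modal_dose_mg),
      age = age, sex = sex, race = race, bmi = bmi,
      baseline_panss_total = panss0, baseline_cgi_s = cgi0,
      completed = completed,
      discontinuation_week = ifelse(completed, NA_integer_, last_week),
      prior_atypical_only = FALSE,
      stringsAsFactors = FALSE
    )
  }

  empty_events <- data.frame(subject_id = character(), preferred_term = character(),
                             onset_week = integer(), stringsAsFactors = FALSE)
  out <- list(
    subjects = do.call(rbind, subj_list),
    visits = do.call(rbind, visit_list),
    events = if (length(event_list)) do.call(rbind, event_list) else empty_events
  )
  if (is.null(out$subjects)) {
    out$subjects <- data.frame(matrix(nrow = 0, ncol = length(SUBJECT_COLUMNS),
                                      dimnames = list(NULL, SUBJECT_COLUMNS)))
    out$visits <- data.frame(matrix(nrow = 0, ncol = length(VISIT_COLUMNS),
                                    dimnames = list(NULL, VISIT_COLUMNS)))
  }
  rownames(out$subjects) <- rownames(out$visits) <- rownames(out$events) <- NULL
  out
}

#' Summarize a cohort by analysis group
#'
#' Per-group sample size, covariate means/SDs, female and white counts with
#' percentages, completion, and the per-term adverse-event incidence table
#' (distinct-subject counting, percentages rounded half away from zero to
#' one decimal — the package's reporting rule throughout).
#'
#' @param subjects,visits,events cohort tables (generated or real).
#' @return list with `demographics` and `ae` data.frames.
#' @export
summarize_cohort <- function(subjects, visits, events) {
  groups <- analysis_groups(subjects)
  rows <- lapply(names(groups), function(g) {
    s <- subjects[subjects$subject_id %in% groups[[g]], ]
    n <- nrow(s)
    if (n == 0) return(NULL)
    pct <- function(k) round_half_away(100 * k / n)
    data.frame(
      group = g, n = n,
      age_mean = mean(s$age), age_sd = if (n > 1) sd(s$age) else NA_real_,
      female_n = sum(s$sex == "female"), female_pct = pct(sum(s$sex == "female")),
      white_n = sum(s$race == "white"), white_pct = pct(sum(s$race == "white")),
      bmi_mean = mean(s$bmi), bmi_sd = if (n > 1) sd(s$bmi) else NA_real_,
      panss_mean = mean(s$baseline_panss_total),
      panss_sd = if (n > 1) sd(s$baseline_panss_total) else NA_real_,
      cgi_mean = mean(s$baseline_cgi_s),
      cgi_sd = if (n > 1) sd(s$baseline_cgi_s) else NA_real_,
      completed_n = sum(s$completed), completion_pct = pct(sum(s$completed)),
      stringsAsFactors = FALSE
    )
  })
  list(
    demographics = do.call(rbind, rows),
    ae = incidence_table(events, subjects)
  )
}
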