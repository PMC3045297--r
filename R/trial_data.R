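#' Trial metadata for the six pooled placebo-controlled studies
#'
#' One row per study: program, double-blind duration, protocol endpoint week
#' (week 4 for the 4-week study, week 8 for the 8-week study, week 6
#' otherwise), the PANSS total entry window, and which assessments the study
#' collected (the earliest comparator study entered patients on BPRS criteria
#' and has no PANSS factor scores; the 4-week study collected no CGI-S).
#'
#' @return data.frame with columns `trial_id`, `program`, `duration_weeks`,
#'   `endpoint_week`, `panss_low`, `panss_high`, `doses_mg`,
#'   `has_factor_scores`, `has_cgi`.
#' @export
default_trial_meta <- function() {
  data.frame(
    trial_id = c("PALI-SCH-303", "PALI-SCH-304", "PALI-SCH-305",
                 "RIS-USA-1", "RIS-INT-3", "RIS-USA-72"),
    program = c("PALI", "PALI", "PALI", "RIS", "RIS", "RIS"),
    duration_weeks = c(6L, 6L, 6L, 6L, 8L, 4L),
    endpoint_week = c(6L, 6L, 6L, 6L, 8L, 4L),
    panss_low = c(70L, 70L, 70L, 60L, 60L, 80L),
    panss_high = c(120L, 120L, 120L, 120L, 120L, 120L),
    doses_mg = c("6,9,12", "6,12", "3,9,15", "1-10", "2,6,10,16", "4,8"),
    has_factor_scores = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    has_cgi = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

SUBJECT_COLUMNS <- c(
  "subject_id", "trial_id", "arm", "compound_program", "modal_dose_mg",
  "treatment_group", "age", "sex", "race", "bmi", "baseline_panss_total",
  "baseline_cgi_s", "completed", "discontinuation_week", "prior_atypical_only"
)

VISIT_COLUMNS <- c(
  "subject_id", "week", "panss_total", "panss_negative", "panss_positive",
  "panss_anxiety_depression", "panss_disorganized_thoughts",
  "panss_hostility_excitement", "cgi_s", "weight_kg"
)

EVENT_COLUMNS <- c("subject_id", "preferred_term", "onset_week")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", what, " table: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

fail_subject <- function(id, field, why) {
  stop("validation error: subject ", id, ", field '", field, "': ", why)
}

#' Validate a subject table
#'
#' Checks the documented schema and the domain invariants: unique non-empty
#' ids, known programs and groups, age inside `age_range`, PANSS total 30-210
#' and (when trial metadata is supplied) inside the originating trial's entry
#' window, CGI-S severity 1-7, and disposition consistency (a discontinuation
#' week is present exactly for non-completers).
#'
#' @param subjects data.frame with the columns in `SUBJECT_COLUMNS`.
#' @param trial_meta trial metadata as from [default_trial_meta()], or NULL
#'   to skip trial-specific checks.
#' @param age_range inclusive age window; default 18-65 years.
#' @return the validated data.frame, invisibly.
#' @export
validate_subjects <- function(subjects, trial_meta = default_trial_meta(),
                              age_range = c(18, 65)) {
  check_columns(subjects, SUBJECT_COLUMNS, "subject")
  if (nrow(subjects) == 0) return(invisible(subjects))
  ids <- subjects$subject_id
  if (any(is.na(ids) | ids == "")) stop("validation error: empty subject_id")
  if (anyDuplicated(ids)) {
    stop("validation error: duplicated subject_id ", ids[duplicated(ids)][1])
  }
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    if (!s$compound_program %in% c("PALI", "RIS")) {
      fail_subject(s$subject_id, "compound_program", "must be PALI or RIS")
    }
    if (!s$treatment_group %in% TREATMENT_GROUPS) {
      fail_subject(s$subject_id, "treatment_group",
                   paste("unknown group", s$treatment_group))
    }
    if (is.na(s$age) || s$age < age_range[1] || s$age > age_range[2]) {
      fail_subject(s$subject_id, "age",
                   sprintf("value %s outside [%s, %s]",
                           s$age, age_range[1], age_range[2]))
    }
    if (!s$sex %in% c("female", "male")) {
      fail_subject(s$subject_id, "sex", "must be female or male")
    }
    if (!s$race %in% c("white", "other")) {
      fail_subject(s$subject_id, "race", "must be white or other")
    }
    if (is.na(s$bmi) || s$bmi <= 10 || s$bmi >= 70) {
      fail_subject(s$subject_id, "bmi", "implausible value")
    }
    p <- s$baseline_panss_total
    if (is.na(p) || p < 30 || p > 210) {
      fail_subject(s$subject_id, "baseline_panss_total", "outside 30-210")
    }
    if (!is.null(trial_meta)) {
      tm <- trial_meta[trial_meta$trial_id == s$trial_id, ]
      if (nrow(tm) == 0) {
        fail_subject(s$subject_id, "trial_id",
                     paste("unknown trial", s$trial_id))
      }
      if (p < tm$panss_low || p > tm$panss_high) {
        fail_subject(s$subject_id, "baseline_panss_total",
                     sprintf("outside trial entry window %d-%d",
                             tm$panss_low, tm$panss_high))
      }
    }
    cg <- s$baseline_cgi_s
    if (is.na(cg) || cg < 1 || cg > 7 || cg != round(cg)) {
      fail_subject(s$subject_id, "baseline_cgi_s", "must be an integer 1-7")
    }
    if (is.na(s$completed)) {
      fail_subject(s$subject_id, "completed", "must be TRUE/FALSE")
    }
    if (s$completed && !is.na(s$discontinuation_week)) {
      fail_subject(s$subject_id, "discontinuation_week",
                   "present for a completer")
    }
    if (!s$completed && is.na(s$discontinuation_week)) {
      fail_subject(s$subject_id, "discontinuation_week",
                   "absent for a non-completer")
    }
  }
  invisible(subjects)
}

#' Validate a visit table
#'
#' Week 0 (baseline) must exist for every subject, weeks are unique,
#' non-negative integers per subject, and — when `subjects` is supplied — no
#' visit falls after a subject's discontinuation week.
#'
#' @param visits data.frame with the columns in `VISIT_COLUMNS`.
#' @param subjects optional subject table for cross-checks.
#' @return the validated data.frame, invisibly.
#' @export
validate_visits <- function(visits, subjects = NULL) {
  check_columns(visits, VISIT_COLUMNS, "visit")
  if (nrow(visits) == 0) return(invisible(visits))
  if (any(is.na(visits$week) | visits$week < 0 | visits$week != round(visits$week))) {
    stop("validation error: visit weeks must be non-negative integers")
  }
  by_subj <- split(visits$week, visits$subject_id)
  for (id in names(by_subj)) {
    w <- by_subj[[id]]
    if (anyDuplicated(w)) fail_subject(id, "week", "duplicated visit week")
    if (!0 %in% w) fail_subject(id, "week", "baseline (week 0) visit missing")
  }
  bad_cgi <- !is.na(visits$cgi_s) &
    (visits$cgi_s < 1 | visits$cgi_s > 7 | visits$cgi_s != round(visits$cgi_s))
  if (any(bad_cgi)) {
    fail_subject(visits$subject_id[bad_cgi][1], "cgi_s", "must be an integer 1-7")
  }
  if (any(!is.na(visits$weight_kg) & visits$weight_kg <= 0)) {
    stop("validation error: non-positive weight_kg")
  }
  if (!is.null(subjects)) {
    unknown <- setdiff(visits$subject_id, subjects$subject_id)
    if (length(unknown) > 0) {
      stop("validation error: visits for unknown subject ", unknown[1])
    }
    last <- vapply(by_subj, max, numeric(1))
    dw <- subjects$discontinuation_week[match(names(by_subj), subjects$subject_id)]
    late <- !is.na(dw) & last > dw
    if (any(late)) {
      fail_subject(names(by_subj)[late][1], "week",
                   "visit after discontinuation week")
    }
  }
  invisible(visits)
}

#' Validate an adverse-event table
#'
#' @param events data.frame with the columns in `EVENT_COLUMNS`.
#' @param subjects optional subject table; events must belong to known subjects.
#' @param visits optional visit table; onset may not postdate the last
#'   observed visit.
#' @return the validated data.frame, invisibly.
#' @export
validate_events <- function(events, subjects = NULL, visits = NULL) {
  check_columns(events, EVENT_COLUMNS, "event")
  if (nrow(events) == 0) return(invisible(events))
  if (any(is.na(events$preferred_term) | events$preferred_term == "")) {
    stop("validation error: empty preferred_term")
  }
  if (any(is.na(events$onset_week) | events$onset_week < 0)) {
    stop("validation error: onset_week must be >= 0")
  }
  if (!is.null(subjects)) {
    unknown <- setdiff(events$subject_id, subjects$subject_id)
    if (length(unknown) > 0) {
      stop("validation error: event for unknown subject ", unknown[1])
    }
  }
  if (!is.null(visits)) {
    last <- tapply(visits$week, visits$subject_id, max)
    lw <- last[events$subject_id]
    bad <- !is.na(lw) & events$onset_week > lw
    if (any(bad)) {
      fail_subject(events$subject_id[bad][1], "onset_week",
                   "after last observed visit")
    }
  }
  invisible(events)
}

read_table_typed <- function(path, char_cols, logical_cols = character(),
                             integer_cols = character(),
                             numeric_cols = character()) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 encoding = "UTF-8", check.names = FALSE)
  for (cc in intersect(char_cols, names(df))) df[[cc]] <- as.character(df[[cc]])
  for (lc in intersect(logical_cols, names(df))) df[[lc]] <- as.logical(df[[lc]])
  for (ic in intersect(integer_cols, names(df))) df[[ic]] <- as.integer(df[[ic]])
  for (nc in intersect(numeric_cols, names(df))) df[[nc]] <- as.numeric(df[[nc]])
  df
}

#' Read / write the patient-level tables
#'
#' Comma-delimited UTF-8 with a fixed header; absent values are empty cells.
#' `read_*` validates against the type invariants (validation can be relaxed
#' with `validate = FALSE` for staging raw data); `write_*` is the exact
#' inverse, so `read_subject_table(write_subject_table(x, p))` reproduces `x`
#' field for field.
#'
#' @param path CSV file path.
#' @param trial_meta trial metadata used for trial-specific validation
#'   (NULL to skip).
#' @param validate run [validate_subjects()] on the result.
#' @param age_range inclusive age window enforced by validation.
#' @return `read_subject_table`: data.frame of subject records in file order.
#' @export
read_subject_table <- function(path, trial_meta = default_trial_meta(),
                               validate = TRUE, age_range = c(18, 65)) {
  df <- read_table_typed(
    path,
    char_cols = c("subject_id", "trial_id", "arm", "compound_program",
                  "treatment_group", "sex", "race"),
    logical_cols = c("completed", "prior_atypical_only"),
    integer_cols = c("baseline_panss_total", "baseline_cgi_s",
                     "discontinuation_week"),
    numeric_cols = c("modal_dose_mg", "age", "bmi")
  )
  check_columns(df, SUBJECT_COLUMNS, "subject")
  df <- df[, SUBJECT_COLUMNS]
  if (validate) validate_subjects(df, trial_meta, age_range)
  df
}

#' @rdname read_subject_table
#' @param subjects,visits,events data.frames to write.
#' @export
write_subject_table <- function(subjects, path) {
  check_columns(subjects, SUBJECT_COLUMNS, "subject")
  write_table_utf8(subjects[, SUBJECT_COLUMNS], path)
}

#' @rdname read_subject_table
#' @export
read_visit_table <- function(path, validate = TRUE) {
  df <- read_table_typed(
    path, char_cols = "subject_id",
    integer_cols = c("week", "panss_total", paste0("panss_", PANSS_FACTORS),
                     "cgi_s"),
    numeric_cols = "weight_kg"
  )
  check_columns(df, VISIT_COLUMNS, "visit")
  df <- df[, VISIT_COLUMNS]
  if (validate) validate_visits(df)
  df
}

#' @rdname read_subject_table
#' @export
write_visit_table <- function(visits, path) {
  check_columns(visits, VISIT_COLUMNS, "visit")
  write_table_utf8(visits[, VISIT_COLUMNS], path)
}

#' @rdname read_subject_table
#' @export
read_event_table <- function(path, validate = TRUE) {
  df <- read_table_typed(path, char_cols = c("subject_id", "preferred_term"),
                         integer_cols = "onset_week")
  check_columns(df, EVENT_COLUMNS, "event")
  df <- df[, EVENT_COLUMNS]
  if (validate) validate_events(df)
  df
}

#' @rdname read_subject_table
#' @export
write_event_table <- function(events, path) {
  check_columns(events, EVENT_COLUMNS, "event")
  write_table_utf8(events[, EVENT_COLUMNS], path)
}

write_table_utf8 <- function(df, path) {
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop("I/O error: cannot write ", path))
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write a whole cohort directory
#'
#' Convenience wrappers around the three table readers/writers using the
#' fixed file names `subjects.csv`, `visits.csv`, `events.csv`.
#'
#' @param dir directory containing (or to receive) the three CSV files.
#' @param trial_meta,validate passed through to the readers.
#' @return `read_cohort`: list with elements `subjects`, `visits`, `events`.
#' @export
read_cohort <- function(dir, trial_meta = default_trial_meta(), validate = TRUE) {
  subjects <- read_subject_table(file.path(dir, "subjects.csv"), trial_meta, validate)
  visits <- read_visit_table(file.path(dir, "visits.csv"), validate)
  events <- read_event_table(file.path(dir, "events.csv"), validate)
  if (validate) {
    validate_visits(visits, subjects)
    validate_events(events, subjects, visits)
  }
  list(subjects = subjects, visits = visits, events = events)
}

#' @rdname read_cohort
#' @param cohort list with `subjects`, `visits`, `events` data.frames.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_subject_table(cohort$subjects, file.path(dir, "subjects.csv"))
  write_visit_table(cohort$visits, file.path(dir, "visits.csv"))
  write_event_table(cohort$events, file.path(dir, "events.csv"))
  invisible(dir)
}

#' Default inclusion/exclusion filter configuration
#'
#' Mirrors the pooled-analysis eligibility rules: age 18-65 inclusive,
#' comparator modal dose capped at 8 mg/day, and (for the study that enrolled
#' while second-generation agents were on the market) exclusion of subjects
#' whose prior treatment was exclusively atypical.
#'
#' @return named list understood by [apply_inclusion_filters()].
#' @export
default_filters <- function() {
  list(
    age_range = c(18, 65),
    max_risperidone_dose = 8,
    prior_atypical_excluded_trials = "RIS-USA-72"
  )
}

# Dose-group assignment ("modal dose" semantics). 4 mg/day belongs to both
# comparator dose groups; the canonical column records RIS_2_4 and the
# dual membership is exposed through group_members().
assign_treatment_group <- function(compound, modal_dose) {
  ifelse(
    is.na(modal_dose),
    ifelse(compound == "PALI", "PLACEBO_PALI", "PLACEBO_RIS"),
    ifelse(compound == "PALI",
           ifelse(modal_dose >= 6 & modal_dose <= 12, "PALI_6_12", "EXCLUDED"),
           ifelse(modal_dose >= 2 & modal_dose <= 4, "RIS_2_4",
                  ifelse(modal_dose > 4 & modal_dose <= 6, "RIS_4_6",
                         "EXCLUDED")))
  )
}

#' Apply eligibility filters and assign modal-dose treatment groups
#'
#' Subjects are screened in rule order (age window, comparator dose cap,
#' prior-atypical screen); each excluded subject is logged with the first
#' rule it triggered. Retained subjects get their `treatment_group`
#' (re)assigned from program and modal dose, and a logical
#' `in_both_ris_groups` marks the 4 mg/day subjects that belong to both
#' comparator dose groups. Filtering is idempotent.
#'
#' @param subjects subject table.
#' @param filters filter configuration as from [default_filters()]; unknown
#'   keys are a configuration error.
#' @return list with `subjects` (retained, regrouped) and `exclusions`
#'   (data.frame `subject_id`, `rule`).
#' @export
apply_inclusion_filters <- function(subjects, filters = default_filters()) {
  known <- c("age_range", "max_risperidone_dose", "prior_atypical_excluded_trials")
  bad <- setdiff(names(filters), known)
  if (length(bad) > 0) stop("config error: unknown filter key(s): ",
                            paste(bad, collapse = ", "))
  filters <- utils::modifyList(default_filters(), filters)
  check_columns(subjects, SUBJECT_COLUMNS, "subject")

  rule <- rep(NA_character_, nrow(subjects))
  lo <- filters$age_range[1]; hi <- filters$age_range[2]
  rule[is.na(rule) & subjects$age < lo] <- paste0("age<", lo)
  rule[is.na(rule) & subjects$age > hi] <- paste0("age>", hi)
  over <- subjects$compound_program == "RIS" &
    !is.na(subjects$modal_dose_mg) &
    subjects$modal_dose_mg > filters$max_risperidone_dose
  rule[is.na(rule) & over] <- paste0("dose>", filters$max_risperidone_dose)
  pa <- subjects$trial_id %in% filters$prior_atypical_excluded_trials &
    subjects$prior_atypical_only
  rule[is.na(rule) & pa] <- "prior_atypical"

  keep <- is.na(rule)
  retained <- subjects[keep, , drop = FALSE]
  retained$treatment_group <- assign_treatment_group(
    retained$compound_program, retained$modal_dose_mg
  )
  retained$in_both_ris_groups <- retained$compound_program == "RIS" &
    !is.na(retained$modal_dose_mg) & retained$modal_dose_mg == 4
  rownames(retained) <- NULL
  list(
    subjects = retained,
    exclusions = data.frame(
      subject_id = subjects$subject_id[!keep],
      rule = rule[!keep],
      stringsAsFactors = FALSE
    )
  )
}

#' Subject ids belonging to an analysis group
#'
#' The two comparator dose groups are overlapping views over one underlying
#' subject set: a modal dose of exactly 4 mg/day places a subject in both
#' `RIS_2_4` and `RIS_4_6` (never as a duplicated row within one contrast).
#'
#' @param subjects subject table with `treatment_group` assigned.
#' @param group one of `PALI_6_12`, `RIS_2_4`, `RIS_4_6`, `PLACEBO_PALI`,
#'   `PLACEBO_RIS`.
#' @return character vector of subject ids.
#' @export
group_members <- function(subjects, group) {
  group <- match.arg(group, setdiff(TREATMENT_GROUPS, "EXCLUDED"))
  active_ris <- subjects$compound_program == "RIS" &
    !is.na(subjects$modal_dose_mg) &
    subjects$treatment_group %in% c("RIS_2_4", "RIS_4_6")
  sel <- switch(
    group,
    RIS_2_4 = active_ris & subjects$modal_dose_mg >= 2 & subjects$modal_dose_mg <= 4,
    RIS_4_6 = active_ris & subjects$modal_dose_mg >= 4 & subjects$modal_dose_mg <= 6,
    subjects$treatment_group == group
  )
  subjects$subject_id[sel]
}

# Named list of the five analysis groups' id vectors.
analysis_groups <- function(subjects) {
  gs <- setdiff(TREATMENT_GROUPS, "EXCLUDED")
  setNames(lapply(gs, function(g) group_members(subjects, g)), gs)
}
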