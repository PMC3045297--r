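#' Treatment-emergent adverse-event incidence table
#'
#' Distinct-subject counting: a subject contributes at most once per
#' preferred term regardless of how many times the event was reported.
#' Percentages use the reporting rule (one decimal, half away from zero).
#'
#' @param events adverse-event table.
#' @param subjects subject table supplying group denominators.
#' @param groups named list of subject-id vectors; defaults to the five
#'   analysis groups found in `subjects`.
#' @return data.frame `preferred_term`, `group`, `n`, `group_n`, `pct`
#'   (terms x groups, zero-filled).
#' @export
incidence_table <- function(events, subjects, groups = NULL) {
  if (is.null(groups)) groups <- analysis_groups(subjects)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  validate_events(events, subjects)
  terms <- sort(unique(events$preferred_term))
  ev <- unique(events[, c("subject_id", "preferred_term")])
  out <- do.call(rbind, lapply(terms, function(term) {
    with_term <- ev$subject_id[ev$preferred_term == term]
    do.call(rbind, lapply(names(groups), function(g) {
      N <- length(groups[[g]])
      n <- length(intersect(with_term, groups[[g]]))
      data.frame(preferred_term = term, group = g, n = n, group_n = N,
                 pct = round_half_away(100 * n / N), stringsAsFactors = FALSE)
    }))
  }))
  out %||% data.frame(preferred_term = character(), group = character(),
                      n = integer(), group_n = integer(), pct = numeric(),
                      stringsAsFactors = FALSE)
}

#' Clamped placebo-adjusted incidence differential
#'
#' Each active rate is first corrected by its own program's placebo rate,
#' with negative corrections set to zero:
#' `d = max(act_a - plc_a, 0) - max(act_b - plc_b, 0)`.
#' The computation runs on percentages already rounded to one decimal (only
#' this order reproduces the published cells) and the result is returned
#' signed, rounded to one decimal; positive means the side-`a` active drug
#' has the larger placebo-corrected rate. Differentials are considered
#' notable when the magnitude is at least 2 percentage points.
#'
#' @param act_a,plc_a active and placebo percentages for side a.
#' @param act_b,plc_b active and placebo percentages for side b.
#' @return signed differential in percentage points, rounded to one decimal.
#'   Vectorized.
#' @export
placebo_adjusted_differential <- function(act_a, plc_a, act_b, plc_b) {
  vals <- c(act_a, plc_a, act_b, plc_b)
  if (any(is.na(vals) | vals < 0 | vals > 100)) {
    stop("validation error: incidence percentages must lie in [0, 100]")
  }
  d <- pmax(act_a - plc_a, 0) - pmax(act_b - plc_b, 0)
  round_half_away(d)
}

#' Flagged adverse-event differential table
#'
#' A term enters the table iff its incidence reaches `incidence_threshold`
#' (default 5%) in any active-treatment or placebo group. For each
#' cross-program comparison the clamped placebo-adjusted differential is
#' reported when its magnitude reaches `differential_threshold` (default
#' 2%), otherwise NA; the direction records which program had the larger
#' placebo-corrected rate (assigned before taking the magnitude). Placebo
#' correction always uses each program's own placebo group, never a pooled
#' one.
#'
#' @param incidence either the long table from [incidence_table()] (columns
#'   `preferred_term`, `group`, `pct`) or a wide percentage table with
#'   columns `preferred_term`, `PALI_6_12`, `PLACEBO_PALI`, `RIS_2_4`,
#'   `RIS_4_6`, `PLACEBO_RIS` (e.g. the published fixture).
#' @param incidence_threshold entry gate on any group's incidence, percent.
#' @param differential_threshold reporting gate on the adjusted
#'   differential's magnitude, percent.
#' @return data.frame per retained term: the five group percentages,
#'   `diff_vs_ris24`, `diff_vs_ris46` (magnitudes or NA) and
#'   `direction_vs_ris24`, `direction_vs_ris46`
#'   (`more_with_pali` / `more_with_ris` / NA).
#' @export
flag_ae_table <- function(incidence, incidence_threshold = 5.0,
                          differential_threshold = 2.0) {
  need <- c("PALI_6_12", "PLACEBO_PALI", "RIS_2_4", "RIS_4_6", "PLACEBO_RIS")
  if ("pct" %in% names(incidence) && "group" %in% names(incidence)) {
    wide <- incidence_to_wide(incidence)
  } else {
    wide <- incidence
  }
  check_columns(wide, c("preferred_term", need), "incidence")
  eps <- 1e-9
  keep <- apply(wide[need], 1, function(r) any(r >= incidence_threshold - eps))
  wide <- wide[keep, , drop = FALSE]
  cell <- function(act_ris, plc_ris, act_pali, plc_pali) {
    d <- placebo_adjusted_differential(act_ris, plc_ris, act_pali, plc_pali)
    mag <- abs(d)
    list(
      diff = ifelse(mag >= differential_threshold - eps, mag, NA_real_),
      dir = ifelse(mag >= differential_threshold - eps,
                   ifelse(d > 0, "more_with_ris", "more_with_pali"),
                   NA_character_)
    )
  }
  c24 <- cell(wide$RIS_2_4, wide$PLACEBO_RIS, wide$PALI_6_12, wide$PLACEBO_PALI)
  c46 <- cell(wide$RIS_4_6, wide$PLACEBO_RIS, wide$PALI_6_12, wide$PLACEBO_PALI)
  out <- data.frame(
    preferred_term = wide$preferred_term,
    wide[need],
    diff_vs_ris24 = c24$diff, direction_vs_ris24 = c24$dir,
    diff_vs_ris46 = c46$diff, direction_vs_ris46 = c46$dir,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

incidence_to_wide <- function(incidence) {
  terms <- unique(incidence$preferred_term)
  groups <- unique(incidence$group)
  wide <- data.frame(preferred_term = terms, stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- incidence[incidence$group == g, ]
    wide[[g]] <- sub$pct[match(terms, sub$preferred_term)]
    wide[[g]][is.na(wide[[g]])] <- 0
  }
  wide
}

#' Weight-change comparison
#'
#' Applies the same baseline-adjusted ANCOVA machinery as the efficacy
#' endpoints to weight change (kg) from baseline to the LOCF endpoint.
#'
#' @param endpoints LOCF endpoint records (the `weight` rows are used).
#' @param groups named list of subject-id vectors defining the comparison.
#' @return an `ancova_contrast` object.
#' @export
weight_contrast <- function(endpoints, groups) {
  endpoint_contrast(endpoints, "weight", groups)
}
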