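#' Fit a propensity model
#'
#' Maximum-likelihood logistic regression of a binary group indicator on the
#' six baseline covariates common to all pooled trials: age, sex, race
#' (white vs all other), baseline BMI, baseline CGI-S and baseline PANSS
#' total. Scores are the fitted probabilities. Subjects with any missing
#' model covariate are dropped before fitting and reported in the result.
#'
#' @param subjects subject table.
#' @param case_ids subject ids forming the indicator's "1" level (e.g. the
#'   active group in an active-vs-placebo step, or one compound program in
#'   the cross-program step).
#' @param covariates covariate names; the default is the fixed six-covariate
#'   model.
#' @return object of class `propensity_fit`: list with `coefficients`,
#'   `scores` (named by subject id, strictly inside (0, 1)), `deviance`,
#'   `converged`, `dropped` (ids lost to missing covariates), `n`.
#' @export
fit_propensity <- function(subjects, case_ids,
                           covariates = c("age", "sex", "race", "bmi",
                                          "baseline_cgi_s",
                                          "baseline_panss_total")) {
  check_columns(subjects, c("subject_id", covariates), "subject")
  y <- subjects$subject_id %in% case_ids
  if (sum(y) < 1 || sum(!y) < 1) {
    stop("both levels of the group indicator need at least one subject")
  }
  X <- propensity_design(subjects, covariates)
  complete <- complete.cases(X)
  dropped <- subjects$subject_id[!complete]
  X <- X[complete, , drop = FALSE]
  y <- y[complete]
  ids <- subjects$subject_id[complete]
  if (length(y) < ncol(X) + 2) {
    stop("too few subjects (", length(y), ") for a ", ncol(X),
         "-covariate propensity model")
  }
  dat <- data.frame(.y = y, X)
  fit <- suppressWarnings(
    glm(.y ~ ., data = dat, family = binomial())
  )
  scores <- fit$fitted.values
  if (any(scores < 1e-8 | scores > 1 - 1e-8)) {
    stop("perfect (or quasi-perfect) separation detected; review the ",
         "propensity model covariates")
  }
  structure(
    list(
      coefficients = coef(fit),
      scores = setNames(as.numeric(scores), ids),
      deviance = fit$deviance,
      null_deviance = fit$null.deviance,
      converged = fit$converged,
      dropped = dropped,
      n = length(y)
    ),
    class = "propensity_fit"
  )
}

# numeric design matrix for the fixed covariate list
propensity_design <- function(subjects, covariates) {
  cols <- lapply(covariates, function(cv) {
    switch(cv,
           sex = as.numeric(subjects$sex == "female"),
           race = as.numeric(subjects$race == "white"),
           as.numeric(subjects[[cv]]))
  })
  names(cols) <- sub("^sex$", "female", sub("^race$", "white", covariates))
  as.data.frame(cols)
}

#' Hierarchical 1-to-many greedy caliper matching
#'
#' Pass-structured greedy matching on the propensity-score (probability)
#' scale. Within each pass, cases are visited in ascending id order and each
#' claims its nearest still-unclaimed control whose absolute score distance
#' is within the caliper ("best" matches first, then "next best" on later
#' passes). Passes repeat — each case may acquire one additional control per
#' pass — until a pass adds no pair. Every control is used at most once.
#' Equidistant controls are broken by the lower control id, making the
#' result deterministic.
#'
#' @param cases data.frame with columns `id`, `score`.
#' @param controls data.frame with columns `id`, `score`.
#' @param caliper maximum |score difference| for a pair (default 0.05).
#' @param max_ratio optional cap on controls per case (default unlimited).
#' @return object of class `match_result`: list with `caliper`, `pairs`
#'   (data.frame `case_id`, `control_id`, `case_score`, `control_score`,
#'   `distance`, `pass_index`), `unmatched_cases`, `unmatched_controls`.
#'   Empty cases or controls give an empty result, not an error.
#' @export
greedy_caliper_match <- function(cases, controls, caliper = 0.05,
                                 max_ratio = Inf) {
  if (!is.numeric(caliper) || length(caliper) != 1 || caliper <= 0) {
    stop("caliper must be a single positive number")
  }
  empty_pairs <- data.frame(
    case_id = character(), control_id = character(), case_score = numeric(),
    control_score = numeric(), distance = numeric(), pass_index = integer(),
    stringsAsFactors = FALSE
  )
  if (nrow(cases) == 0 || nrow(controls) == 0) {
    return(structure(list(caliper = caliper, pairs = empty_pairs,
                          unmatched_cases = cases$id,
                          unmatched_controls = controls$id),
                     class = "match_result"))
  }
  check_columns(cases, c("id", "score"), "cases")
  check_columns(controls, c("id", "score"), "controls")
  if (anyDuplicated(cases$id) || anyDuplicated(controls$id)) {
    stop("ids must be unique within cases and within controls")
  }
  sc <- c(cases$score, controls$score)
  if (any(is.na(sc) | sc <= 0 | sc >= 1)) {
    stop("propensity scores must lie strictly in (0, 1)")
  }

  case_ord <- order_ids(cases$id)
  ctrl_ord <- order_ids(controls$id)       # tie-break: lower control id wins
  ctrl_id <- controls$id[ctrl_ord]
  ctrl_score <- controls$score[ctrl_ord]
  available <- rep(TRUE, length(ctrl_id))
  n_ctrl_per_case <- setNames(integer(nrow(cases)), cases$id)

  pairs <- empty_pairs
  pass <- 0L
  repeat {
    pass <- pass + 1L
    added <- 0L
    for (i in case_ord) {
      cid <- cases$id[i]
      if (n_ctrl_per_case[[cid]] >= max_ratio) next
      d <- abs(ctrl_score - cases$score[i])
      d[!available] <- Inf
      j <- which.min(d)                    # first minimum = lowest control id
      if (!is.finite(d[j]) || d[j] > caliper) next
      available[j] <- FALSE
      n_ctrl_per_case[[cid]] <- n_ctrl_per_case[[cid]] + 1L
      added <- added + 1L
      pairs <- rbind(pairs, data.frame(
        case_id = cid, control_id = ctrl_id[j],
        case_score = cases$score[i], control_score = ctrl_score[j],
        distance = d[j], pass_index = pass, stringsAsFactors = FALSE
      ))
    }
    if (added == 0L) break
  }
  structure(
    list(
      caliper = caliper,
      pairs = pairs,
      unmatched_cases = cases$id[!cases$id %in% pairs$case_id],
      unmatched_controls = ctrl_id[available]
    ),
    class = "match_result"
  )
}

match_two_groups <- function(subjects, ids_a, ids_b, caliper, max_ratio,
                             step_label) {
  sub <- subjects[subjects$subject_id %in% c(ids_a, ids_b), , drop = FALSE]
  fit <- fit_propensity(sub, case_ids = ids_a)
  usable <- names(fit$scores)
  score_of <- function(ids) {
    ids <- intersect(ids, usable)
    data.frame(id = ids, score = unname(fit$scores[ids]),
               stringsAsFactors = FALSE)
  }
  a <- score_of(ids_a); b <- score_of(ids_b)
  # cases = the smaller group (ties anchor on the first-listed group)
  if (nrow(a) <= nrow(b)) {
    m <- greedy_caliper_match(a, b, caliper, max_ratio)
  } else {
    m <- greedy_caliper_match(b, a, caliper, max_ratio)
  }
  if (nrow(m$pairs) == 0) {
    stop("matching step '", step_label, "' produced no pairs ",
         "(check score overlap and caliper)")
  }
  survivors <- unique(c(m$pairs$case_id, m$pairs$control_id))
  list(fit = fit, match = m, survivors = survivors)
}

#' Build the three-step matched analysis population
#'
#' Step 1 matches the comparator program's active subjects (all dose groups
#' pooled) against that program's placebo group; step 2 does the same within
#' the other program; step 3 refits a propensity model on the step-1/step-2
#' active survivors with compound program as the dependent indicator and
#' matches across programs. All subjects in the cross-program matched set
#' enter the final sample; the placebo groups retained in steps 1-2 carry
#' forward unchanged.
#'
#' @param subjects filtered six-trial subject table (treatment groups
#'   assigned, e.g. by [apply_inclusion_filters()]).
#' @param caliper score-scale caliper, default 0.05.
#' @param max_ratio optional cap on controls per case.
#' @return object of class `matched_population`: list with `groups` (named
#'   list of retained ids for the five analysis groups), `pooled_placebo`
#'   (NA until [placebo_poolability()] decides), `steps` (per-step
#'   provenance: fit, match result, sizes) and `caliper`.
#' @export
build_matched_population <- function(subjects, caliper = 0.05, max_ratio = Inf) {
  grp <- analysis_groups(subjects)
  ris_active <- unique(c(grp$RIS_2_4, grp$RIS_4_6))
  for (g in c("PALI_6_12", "PLACEBO_PALI", "PLACEBO_RIS")) {
    if (length(grp[[g]]) == 0) stop("group ", g, " is empty before matching")
  }
  if (length(ris_active) == 0) stop("no active comparator subjects to match")

  s1 <- match_two_groups(subjects, ris_active, grp$PLACEBO_RIS, caliper,
                         max_ratio, "risperidone vs placebo (RIS)")
  s2 <- match_two_groups(subjects, grp$PALI_6_12, grp$PLACEBO_PALI, caliper,
                         max_ratio, "paliperidone ER vs placebo (PALI)")
  ris_surv <- intersect(s1$survivors, ris_active)
  plc_ris_surv <- intersect(s1$survivors, grp$PLACEBO_RIS)
  pali_surv <- intersect(s2$survivors, grp$PALI_6_12)
  plc_pali_surv <- intersect(s2$survivors, grp$PLACEBO_PALI)

  s3 <- match_two_groups(subjects[subjects$subject_id %in%
                                    c(pali_surv, ris_surv), , drop = FALSE],
                         pali_surv, ris_surv, caliper, max_ratio,
                         "paliperidone ER vs risperidone (cross-program)")
  final_active <- s3$survivors

  groups <- list(
    PALI_6_12 = intersect(final_active, pali_surv),
    RIS_2_4 = intersect(final_active, grp$RIS_2_4),
    RIS_4_6 = intersect(final_active, grp$RIS_4_6),
    PLACEBO_PALI = plc_pali_surv,
    PLACEBO_RIS = plc_ris_surv
  )
  input_sizes <- c(PALI_6_12 = length(grp$PALI_6_12),
                   RIS_2_4 = length(grp$RIS_2_4), RIS_4_6 = length(grp$RIS_4_6),
                   PLACEBO_PALI = length(grp$PLACEBO_PALI),
                   PLACEBO_RIS = length(grp$PLACEBO_RIS))
  for (g in names(groups)) {
    if (input_sizes[[g]] > 0 && length(groups[[g]]) == 0) {
      stop("matched population has an empty ", g, " group")
    }
  }
  structure(
    list(
      groups = groups,
      pooled_placebo = NA,
      steps = list(
        ris_vs_placebo = s1, pali_vs_placebo = s2, cross_program = s3
      ),
      caliper = caliper
    ),
    class = "matched_population"
  )
}

#' @export
print.matched_population <- function(x, ...) {
  cat("Matched analysis population (caliper ", x$caliper, ")\n", sep = "")
  sizes <- vapply(x$groups, length, integer(1))
  for (g in names(sizes)) cat(sprintf("  %-13s n = %d\n", g, sizes[[g]]))
  invisible(x)
}

BALANCE_CONTINUOUS <- c("age", "bmi", "baseline_panss_total", "baseline_cgi_s")
BALANCE_BINARY <- c(female = "sex", white = "race")

#' Covariate balance table with standardized mean differences
#'
#' Per group: mean (SD) for continuous covariates and n (%) for binary ones;
#' plus the absolute standardized mean difference for every pairwise group
#' contrast (difference in means over the pooled SD
#' \eqn{\sqrt{(s_1^2 + s_2^2)/2}}; for binary covariates the proportion
#' analogue). A zero numerator gives SMD 0 even when the pooled SD is 0.
#'
#' @param subjects subject table.
#' @param groups named list of subject-id vectors (e.g.
#'   `matched_population$groups`); defaults to the five analysis groups
#'   found in `subjects`.
#' @return list with `stats` (covariate x group summaries) and `smd`
#'   (covariate x group-pair absolute standardized differences).
#' @export
balance_table <- function(subjects, groups = NULL) {
  if (is.null(groups)) groups <- analysis_groups(subjects)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  cov_values <- function(ids) {
    s <- subjects[subjects$subject_id %in% ids, ]
    vals <- lapply(BALANCE_CONTINUOUS, function(cv) s[[cv]])
    names(vals) <- BALANCE_CONTINUOUS
    vals$female <- as.numeric(s$sex == "female")
    vals$white <- as.numeric(s$race == "white")
    vals
  }
  vals <- lapply(groups, cov_values)
  covs <- c(BALANCE_CONTINUOUS, names(BALANCE_BINARY))
  stats <- do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(covs, function(cv) {
      x <- vals[[g]][[cv]]
      binary <- cv %in% names(BALANCE_BINARY)
      data.frame(
        covariate = cv, group = g, n = length(x),
        mean = mean(x),
        sd = if (binary) sqrt(mean(x) * (1 - mean(x))) else
          if (length(x) > 1) sd(x) else NA_real_,
        count = if (binary) sum(x) else NA_integer_,
        pct = if (binary) round_half_away(100 * mean(x)) else NA_real_,
        stringsAsFactors = FALSE
      )
    }))
  }))
  gn <- names(groups)
  pair_rows <- list()
  if (length(gn) >= 2) {
    for (i in seq_len(length(gn) - 1)) for (j in seq(i + 1, length(gn))) {
      for (cv in covs) {
        x <- vals[[gn[i]]][[cv]]; y <- vals[[gn[j]]][[cv]]
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          covariate = cv, group_a = gn[i], group_b = gn[j],
          smd = smd_abs(x, y), stringsAsFactors = FALSE
        )
      }
    }
  }
  list(stats = stats, smd = do.call(rbind, pair_rows))
}

smd_abs <- function(x, y) {
  num <- mean(x) - mean(y)
  if (num == 0) return(0)
  vx <- if (length(x) > 1) var(x) else 0
  vy <- if (length(y) > 1) var(y) else 0
  den <- sqrt((vx + vy) / 2)
  if (den == 0) return(Inf)
  abs(num) / den
}

#' Can the two programs' placebo groups be pooled?
#'
#' Pre-specified comparability check: baseline covariates are compared with
#' two-sample location tests (Welch t) and proportion chi-square tests, and
#' the endpoint LOCF changes (PANSS total and the five factors) with the
#' same baseline-adjusted ANCOVA contrast the efficacy analysis uses.
#' Pooling is allowed iff every endpoint-change p-value exceeds `alpha`.
#'
#' @param subjects,visits cohort tables.
#' @param placebo_pali,placebo_ris subject-id vectors for the two placebo
#'   groups; default to the groups found in `subjects`.
#' @param trial_meta trial metadata (endpoint weeks).
#' @param alpha significance level for the gate, default 0.05.
#' @return list with `pool` (logical), `baseline` (covariate comparison
#'   table) and `endpoint` (per-measure adjusted changes, difference, p).
#' @export
placebo_poolability <- function(subjects, visits,
                                placebo_pali = NULL, placebo_ris = NULL,
                                trial_meta = default_trial_meta(),
                                alpha = 0.05) {
  placebo_pali <- placebo_pali %||% group_members(subjects, "PLACEBO_PALI")
  placebo_ris <- placebo_ris %||% group_members(subjects, "PLACEBO_RIS")
  if (length(placebo_pali) == 0 || length(placebo_ris) == 0) {
    stop("both placebo groups must be non-empty")
  }
  sa <- subjects[subjects$subject_id %in% placebo_pali, ]
  sb <- subjects[subjects$subject_id %in% placebo_ris, ]

  cont_p <- function(x, y) {
    if (length(unique(c(x, y))) < 2) return(1)
    tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
  }
  prop_p <- function(x, y) {
    tab <- rbind(c(sum(x), sum(!x)), c(sum(y), sum(!y)))
    if (any(colSums(tab) == 0)) return(1)
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  baseline <- data.frame(
    covariate = c("age", "bmi", "baseline_panss_total", "baseline_cgi_s",
                  "female", "white"),
    placebo_pali = c(mean(sa$age), mean(sa$bmi), mean(sa$baseline_panss_total),
                     mean(sa$baseline_cgi_s), mean(sa$sex == "female"),
                     mean(sa$race == "white")),
    placebo_ris = c(mean(sb$age), mean(sb$bmi), mean(sb$baseline_panss_total),
                    mean(sb$baseline_cgi_s), mean(sb$sex == "female"),
                    mean(sb$race == "white")),
    p_value = c(
      cont_p(sa$age, sb$age), cont_p(sa$bmi, sb$bmi),
      cont_p(sa$baseline_panss_total, sb$baseline_panss_total),
      cont_p(sa$baseline_cgi_s, sb$baseline_cgi_s),
      prop_p(sa$sex == "female", sb$sex == "female"),
      prop_p(sa$race == "white", sb$race == "white")
    ),
    stringsAsFactors = FALSE
  )

  both <- subjects[subjects$subject_id %in% c(placebo_pali, placebo_ris), ]
  ep <- locf_endpoint(both, visits, trial_meta,
                      measures = c("panss_total", PANSS_FACTORS))
  grp_of <- ifelse(ep$subject_id %in% placebo_pali, "placebo_pali", "placebo_ris")
  endpoint_rows <- list()
  for (m in c("panss_total", PANSS_FACTORS)) {
    em <- ep[ep$measure == m, ]
    gm <- grp_of[ep$measure == m]
    if (length(unique(gm)) < 2 || any(table(gm) < 2)) next
    cc <- ancova_contrast(data.frame(group = gm, baseline = em$baseline,
                                     change = em$change))
    d <- cc$differences[1, ]
    am <- cc$adjusted_means
    endpoint_rows[[m]] <- data.frame(
      measure = m,
      placebo_pali = am$adjusted_mean[am$group == "placebo_pali"],
      placebo_ris = am$adjusted_mean[am$group == "placebo_ris"],
      difference = d$estimate, se = d$se, p_value = d$p_value,
      stringsAsFactors = FALSE
    )
  }
  endpoint <- do.call(rbind, endpoint_rows)
  rownames(endpoint) <- NULL
  pool <- nrow(endpoint) > 0 && all(endpoint$p_value > alpha)
  list(pool = pool, baseline = baseline, endpoint = endpoint, alpha = alpha)
}
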