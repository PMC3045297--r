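measure_column <- function(measure) {
  switch(measure,
         panss_total = "panss_total",
         cgi_s = "cgi_s",
         weight = "weight_kg",
         negative = , positive = , anxiety_depression = ,
         disorganized_thoughts = , hostility_excitement =
           paste0("panss_", measure),
         stop("unknown measure: ", measure))
}

#' LOCF endpoint construction
#'
#' For every subject and measure, the endpoint value is the last observed
#' post-baseline value at or before the subject's trial-specific endpoint
#' week (week 4, 6 or 8 by protocol); completers therefore use the
#' endpoint-week visit itself, dropouts carry their last visit forward, and
#' subjects with no post-baseline observation of a measure are excluded from
#' that measure's change analysis (logged in the `"excluded"` attribute,
#' never an error).
#'
#' @param subjects subject table (only `subject_id` and `trial_id` used).
#' @param visits visit table.
#' @param trial_meta trial metadata supplying `endpoint_week`.
#' @param measures measures to derive; any of `panss_total`, the five factor
#'   names, `cgi_s`, `weight`.
#' @return data.frame with columns `subject_id`, `measure`, `baseline`,
#'   `endpoint`, `change` (endpoint − baseline) and `carried_from_week`;
#'   attribute `"excluded"` lists per-measure exclusions.
#' @export
locf_endpoint <- function(subjects, visits, trial_meta = default_trial_meta(),
                          measures = c("panss_total", PANSS_FACTORS,
                                       "cgi_s", "weight")) {
  check_columns(subjects, c("subject_id", "trial_id"), "subject")
  ew <- setNames(trial_meta$endpoint_week, trial_meta$trial_id)
  v <- visits[visits$subject_id %in% subjects$subject_id, , drop = FALSE]
  v$endpoint_week <- ew[subjects$trial_id[match(v$subject_id, subjects$subject_id)]]
  v <- v[v$week <= v$endpoint_week, , drop = FALSE]

  out <- list(); excluded <- list()
  for (m in measures) {
    col <- measure_column(m)
    vm <- v[!is.na(v[[col]]), c("subject_id", "week", col)]
    base <- vm[vm$week == 0, ]
    post <- vm[vm$week > 0, ]
    post <- post[order(post$subject_id, post$week, method = "radix"), ]
    last <- post[!duplicated(post$subject_id, fromLast = TRUE), ]
    rec <- merge(
      data.frame(subject_id = base$subject_id, baseline = base[[col]]),
      data.frame(subject_id = last$subject_id, endpoint = last[[col]],
                 carried_from_week = last$week),
      by = "subject_id"
    )
    if (nrow(rec) > 0) {
      out[[m]] <- data.frame(
        subject_id = rec$subject_id, measure = m, baseline = rec$baseline,
        endpoint = rec$endpoint, change = rec$endpoint - rec$baseline,
        carried_from_week = rec$carried_from_week, stringsAsFactors = FALSE
      )
    }
    excluded[[m]] <- setdiff(base$subject_id, last$subject_id)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(subject_id = character(), measure = character(),
               baseline = numeric(), endpoint = numeric(), change = numeric(),
               carried_from_week = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Responder derivation (>= 30% PANSS total decrease)
#'
#' A responder shows a decrease from baseline of at least the threshold
#' fraction (default 30%, boundary inclusive) of the baseline PANSS total at
#' the LOCF endpoint. The comparison is done in integer-exact arithmetic
#' (`(baseline - endpoint) / baseline >= f` as
#' `100 (baseline - endpoint) >= 100 f * baseline`), so a decrease of
#' exactly 30% counts.
#'
#' @param endpoints LOCF endpoint records from [locf_endpoint()] (the
#'   `panss_total` rows are used).
#' @param groups optional named list of subject-id vectors; when given,
#'   per-group response percentages (reporting rounding, one decimal) are
#'   returned as well.
#' @param threshold fractional decrease defining response, default 0.30.
#' @return list with `flags` (`subject_id`, `responder`) and, when `groups`
#'   is supplied, `rates` (`group`, `n`, `responders`, `pct`).
#' @export
responder_flags <- function(endpoints, groups = NULL, threshold = 0.30) {
  ep <- endpoints[endpoints$measure == "panss_total", , drop = FALSE]
  if (any(ep$baseline <= 0)) {
    stop("validation error: non-positive baseline PANSS total")
  }
  responder <- 100 * (ep$baseline - ep$endpoint) >=
    round(100 * threshold) * ep$baseline
  flags <- data.frame(subject_id = ep$subject_id, responder = responder,
                      stringsAsFactors = FALSE)
  out <- list(flags = flags)
  if (!is.null(groups)) {
    out$rates <- do.call(rbind, lapply(names(groups), function(g) {
      f <- flags[flags$subject_id %in% groups[[g]], ]
      data.frame(group = g, n = nrow(f), responders = sum(f$responder),
                 pct = if (nrow(f) > 0)
                   round_half_away(100 * sum(f$responder) / nrow(f))
                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Baseline-adjusted ANCOVA contrast
#'
#' Least-squares fit of `change ~ group + baseline` (homogeneous slopes,
#' treatment as the between-group factor and baseline as the covariate).
#' Adjusted (least-squares) means are evaluated at the grand baseline mean;
#' pairwise differences carry model-based standard errors and two-sided
#' p-values from the t distribution on the residual degrees of freedom, with
#' no multiplicity adjustment. A zero-variance baseline drops the covariate
#' with a warning (the adjusted means then equal the raw change means).
#'
#' @param data data.frame with columns `group`, `baseline`, `change`.
#' @return object of class `ancova_contrast`: list with `adjusted_means`
#'   (`group`, `n`, `adjusted_mean`, `se`), `differences` (`group_a`,
#'   `group_b`, `estimate`, `se`, `t`, `df`, `p_value`), `baseline_slope`,
#'   `covariate_dropped`, `residual_df`.
#' @export
ancova_contrast <- function(data) {
  check_columns(data, c("group", "baseline", "change"), "contrast input")
  data <- data[stats::complete.cases(data[c("group", "baseline", "change")]), ]
  g <- factor(data$group)
  if (nlevels(g) < 2) stop("at least two groups are required")
  if (any(table(g) < 2)) stop("every group needs at least two subjects")
  bvar <- var(data$baseline)
  covariate_dropped <- !is.finite(bvar) || bvar < 1e-12
  if (covariate_dropped) {
    warning("baseline covariate has zero variance; dropping it ",
            "(adjusted means equal raw change means)")
    X <- model.matrix(~g)
  } else {
    X <- model.matrix(~ g + data$baseline)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: group factor and baseline covariate are collinear")
  }
  df_fit <- data.frame(change = data$change, g = g, baseline = data$baseline)
  fit <- if (covariate_dropped) lm(change ~ g, data = df_fit) else
    lm(change ~ g + baseline, data = df_fit)
  beta <- coef(fit)
  V <- vcov(fit)
  rdf <- df.residual(fit)
  bbar <- mean(data$baseline)

  lev <- levels(g)
  contrast_row <- function(level) {
    x <- numeric(length(beta))
    names(x) <- names(beta)
    x["(Intercept)"] <- 1
    dn <- paste0("g", level)
    if (dn %in% names(x)) x[dn] <- 1
    if ("baseline" %in% names(x)) x["baseline"] <- bbar
    x
  }
  rows <- t(vapply(lev, contrast_row, numeric(length(beta))))
  adj <- data.frame(
    group = lev,
    n = as.integer(table(g)[lev]),
    adjusted_mean = as.numeric(rows %*% beta),
    se = unname(sqrt(diag(rows %*% V %*% t(rows)))),
    stringsAsFactors = FALSE
  )

  diffs <- list()
  for (i in seq_len(length(lev) - 1)) for (j in seq(i + 1, length(lev))) {
    x <- rows[i, ] - rows[j, ]
    est <- sum(x * beta)
    se <- sqrt(as.numeric(t(x) %*% V %*% x))
    tval <- est / se
    diffs[[length(diffs) + 1L]] <- data.frame(
      group_a = lev[i], group_b = lev[j], estimate = est, se = se,
      t = tval, df = rdf, p_value = 2 * pt(-abs(tval), rdf),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      adjusted_means = adj,
      differences = do.call(rbind, diffs),
      baseline_slope = if (covariate_dropped) 0 else unname(beta["baseline"]),
      covariate_dropped = covariate_dropped,
      residual_df = rdf
    ),
    class = "ancova_contrast"
  )
}

#' @export
print.ancova_contrast <- function(x, ...) {
  cat("Baseline-adjusted ANCOVA contrast\n")
  print(x$adjusted_means, row.names = FALSE)
  cat("Pairwise differences:\n")
  print(x$differences, row.names = FALSE)
  invisible(x)
}

#' Pearson chi-square test for a categorical contingency table
#'
#' Plain Pearson chi-square without continuity correction, as used for
#' categorical baseline variables and endpoint response rates.
#'
#' @param counts matrix of non-negative integer counts (2 x k or r x c).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
categorical_contrast <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero row or column margin")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value),
    expected = ct$expected
  )
}

# Build the ANCOVA input for one measure from endpoint records and a named
# list of group id vectors. Used by the pipeline, poolability and weight
# comparisons. Overlapping groups are fitted per contrast, never as
# duplicated rows within one model.
endpoint_contrast <- function(endpoints, measure, groups) {
  ep <- endpoints[endpoints$measure == measure, , drop = FALSE]
  dat <- do.call(rbind, lapply(names(groups), function(g) {
    e <- ep[ep$subject_id %in% groups[[g]], , drop = FALSE]
    if (nrow(e) == 0) return(NULL)
    data.frame(group = g, baseline = e$baseline, change = e$change,
               stringsAsFactors = FALSE)
  }))
  if (is.null(dat)) stop("no endpoint records for measure ", measure)
  ancova_contrast(dat)
}
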