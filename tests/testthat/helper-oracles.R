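# Independent oracles used to cross-check the package's own implementations.
# These deliberately use plain nested loops / explicit normal equations and
# never call the functions they verify.

# Replay of the pass-structured greedy caliper matching rules: every pass
# visits cases in ascending id order; a case claims the nearest unclaimed
# control within the caliper, ties to the lower control id; passes repeat
# until none adds a pair.
greedy_match_oracle <- function(cases, controls, caliper) {
  ord <- order(cases$id, method = "radix")
  avail <- rep(TRUE, nrow(controls))
  pairs <- data.frame(case_id = character(), control_id = character(),
                      pass_index = integer(), stringsAsFactors = FALSE)
  pass <- 0L
  repeat {
    pass <- pass + 1L
    added <- FALSE
    for (i in ord) {
      best <- NA_integer_
      bestd <- Inf
      for (j in seq_len(nrow(controls))) {
        if (!avail[j]) next
        d <- abs(cases$score[i] - controls$score[j])
        if (d > caliper) next
        take <- d < bestd ||
          (d == bestd && !is.na(best) &&
             isTRUE(controls$id[j] < controls$id[best]))
        if (is.na(best) || take) { best <- j; bestd <- d }
      }
      if (!is.na(best)) {
        avail[best] <- FALSE
        added <- TRUE
        pairs <- rbind(pairs, data.frame(
          case_id = cases$id[i], control_id = controls$id[best],
          pass_index = pass, stringsAsFactors = FALSE
        ))
      }
    }
    if (!added) break
  }
  pairs
}

pair_key <- function(pairs) {
  if (nrow(pairs) == 0) return(character())
  sort(paste(pairs$case_id, pairs$control_id, pairs$pass_index, sep = "|"))
}

# Explicit (X'X)^-1 X'y least-squares oracle for change ~ group + baseline,
# with adjusted means at the grand baseline mean and all pairwise contrasts.
ancova_oracle <- function(group, baseline, change, use_baseline = TRUE) {
  g <- factor(group)
  lev <- levels(g)
  D <- sapply(lev[-1], function(l) as.numeric(g == l))
  X <- cbind(1, D)
  if (use_baseline) X <- cbind(X, baseline)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% change)
  resid <- change - X %*% beta
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  V <- s2 * solve(XtX)
  bbar <- mean(baseline)
  row_for <- function(l) {
    x <- c(1, as.numeric(lev[-1] == l))
    if (use_baseline) x <- c(x, bbar)
    x
  }
  rows <- t(sapply(lev, row_for))
  diffs <- list()
  for (i in seq_len(length(lev) - 1)) for (j in seq(i + 1, length(lev))) {
    x <- rows[i, ] - rows[j, ]
    est <- sum(x * beta)
    se <- sqrt(as.numeric(t(x) %*% V %*% x))
    tval <- est / se
    rdf <- nrow(X) - ncol(X)
    diffs[[length(diffs) + 1]] <- data.frame(
      group_a = lev[i], group_b = lev[j], estimate = est, se = se,
      p_value = 2 * pt(-abs(tval), rdf), stringsAsFactors = FALSE
    )
  }
  list(
    coefficients = as.numeric(beta),
    adjusted_means = as.numeric(rows %*% beta),
    adjusted_se = unname(sqrt(diag(rows %*% V %*% t(rows)))),
    differences = do.call(rbind, diffs)
  )
}

# Pearson chi-square by the textbook formula.
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

# Analytic mean of a normal truncated to [lo, hi]; moment-recovery oracle.
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
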