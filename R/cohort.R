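#' Median and interquartile range
#'
#' Empirical median and quartiles with linear interpolation between order
#' statistics at positions `h = (n - 1) p + 1` (the default quantile
#' definition of mainstream statistical software, which reproduces
#' half-integer medians such as 149.5 from even-sized samples).
#'
#' @param values Non-empty numeric vector; `NA` values are not allowed.
#'
#' @return Named numeric vector `c(median, q1, q3)`.
#'
#' @examples
#' median_iqr(c(1, 2, 3))  # 2, 1.5, 2.5
#'
#' @export
median_iqr <- function(values) {
  if (length(values) == 0L)
    stop("'values' must be non-empty", call. = FALSE)
  if (anyNA(values) || !is.numeric(values))
    stop("'values' must be numeric without NA", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = 7,
                       names = FALSE)
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent groups. U is computed from joint
#' mid-ranks. The p-value is exact (full enumeration of rank splits) when
#' both groups are small (`max(n_x, n_y) <= 8`) and the pooled data contain
#' no ties; otherwise the tie-corrected normal approximation is used, with a
#' 0.5 continuity correction by default.
#'
#' @param x,y Non-empty numeric vectors, the two groups.
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default `TRUE`). Irrelevant when the exact p is used.
#'
#' @return A list with `U` (statistic for the first group), `p_value`
#'   (two-sided), and `exact` (whether full enumeration was used).
#'
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#'
#' @export
mann_whitney_u <- function(x, y, continuity = TRUE) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("groups must not contain NA", call. = FALSE)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    # all observations identical: no evidence either way
    return(list(U = length(x) * length(y) / 2, p_value = 1, exact = FALSE))
  }
  exact <- max(length(x), length(y)) <= 8 && !anyDuplicated(pooled)
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = continuity)
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Kruskal-Wallis test
#'
#' Rank-based comparison of three or more independent groups: the H
#' statistic from joint mid-ranks with tie correction, referred to the
#' chi-square upper tail on `k - 1` degrees of freedom. When every
#' observation is identical across all groups, H = 0 and p = 1.
#'
#' @param groups List of three or more non-empty numeric vectors.
#'
#' @return A list with `H`, `df`, and `p_value`.
#'
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))  # H = 32/7
#'
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("need >= 3 groups; use mann_whitney_u() for two", call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("all groups must be non-empty", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values)) stop("groups must not contain NA", call. = FALSE)
  k <- length(groups)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = k - 1L, p_value = 1))
  g <- factor(rep(seq_len(k), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Spearman rank correlation
#'
#' Spearman's rho computed as the Pearson correlation of joint mid-ranks;
#' the two-sided p-value comes from the t approximation on `n - 2` degrees
#' of freedom. Incomplete pairs (an `NA` in either variable) are dropped
#' pairwise.
#'
#' @param x,y Numeric vectors of equal length with at least 3 complete
#'   pairs.
#' @param x_name,y_name Labels carried into the result.
#'
#' @return An object of class `"correlation_result"`: a list with `x_name`,
#'   `y_name`, `rho`, `p_value`, `n_pairs`, and `n_dropped`.
#'
#' @export
spearman_cor <- function(x, y, x_name = deparse(substitute(x)),
                         y_name = deparse(substitute(y))) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 complete pairs (have ", n, ")", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("a variable is constant after ranking; rho undefined",
            call. = FALSE)
    rho <- NA_real_; p <- NA_real_
  } else {
    rho <- stats::cor(rx, ry)
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  structure(list(x_name = x_name, y_name = y_name, rho = rho, p_value = p,
                 n_pairs = n, n_dropped = n_dropped),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman correlation %s vs %s: rho = %s, p = %s (n = %d%s)\n",
              x$x_name, x$y_name, format(signif(x$rho, 4)),
              format(signif(x$p_value, 4)), x$n_pairs,
              if (x$n_dropped) paste0(", ", x$n_dropped, " pairs dropped")
              else ""))
  invisible(x)
}

#' Cohort-level fragility summary
#'
#' Descriptive statistics of a corpus with fragility columns: trial count,
#' median (IQR) of FI, FQ, and total sample size, the FI histogram, and the
#' headline counts (trials with FI <= 3, FI = 1, and loss to follow-up
#' exceeding FI). Exhausted records are excluded with a message.
#'
#' @param corpus A `trial_corpus` after [attach_fragility()].
#'
#' @return An object of class `"cohort_summary"`.
#'
#' @export
cohort_summary <- function(corpus) {
  stopifnot(inherits(corpus, "trial_corpus"))
  n_excluded <- sum(corpus$fi_exhausted)
  corpus <- drop_exhausted(corpus)
  n <- nrow(corpus)
  if (n == 0L) stop("no usable records in the corpus", call. = FALSE)
  N <- corpus$n_int + corpus$n_ctl
  hist_tab <- table(factor(corpus$fi, levels = 0:max(corpus$fi)))
  structure(list(
    n_trials = n,
    n_excluded = n_excluded,
    fi = median_iqr(corpus$fi),
    fq = median_iqr(corpus$fq),
    sample_size = median_iqr(N),
    total_events = median_iqr(corpus$events_int + corpus$events_ctl),
    fi_histogram = hist_tab,
    n_fi_le3 = sum(corpus$fi <= 3),
    n_fi_eq1 = sum(corpus$fi == 1),
    n_nplfu_gt_fi = sum(corpus$nplfu_gt_fi),
    alpha = attr(corpus, "alpha")
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(m) sprintf("%.2f (IQR: %.2f-%.2f)", m[1], m[2], m[3])
  fmtq <- function(m) sprintf("%.3f (IQR: %.3f-%.3f)", m[1], m[2], m[3])
  cat("Cohort fragility summary:", x$n_trials, "trials",
      if (x$n_excluded) paste0("(", x$n_excluded, " exhausted excluded)"),
      "\n")
  cat("  median FI:", fmt(x$fi), "\n")
  cat("  median FQ:", fmtq(x$fq), "\n")
  cat("  median sample size:", fmt(x$sample_size), "\n")
  cat(sprintf("  FI <= 3: %d/%d (%.1f%%); FI = 1: %d (%.1f%%)\n",
              x$n_fi_le3, x$n_trials, 100 * x$n_fi_le3 / x$n_trials,
              x$n_fi_eq1, 100 * x$n_fi_eq1 / x$n_trials))
  cat(sprintf("  lost to follow-up > FI: %d/%d (%.1f%%)\n",
              x$n_nplfu_gt_fi, x$n_trials,
              100 * x$n_nplfu_gt_fi / x$n_trials))
  invisible(x)
}

# one subgroup comparison: FI split by a grouping factor (all levels kept)
compare_subgroups <- function(fi, group, characteristic, na_iqr_below = 4L) {
  stopifnot(is.factor(group))
  levs <- levels(group)
  rows <- lapply(levs, function(lv) {
    v <- fi[group == lv]
    n <- length(v)
    if (n == 0L)
      return(data.frame(characteristic = characteristic, level = lv, n = 0L,
                        pct = 0, median_fi = NA_real_, q1_fi = NA_real_,
                        q3_fi = NA_real_, stringsAsFactors = FALSE))
    m <- median_iqr(v)
    # quartiles from very few points are unreliable; print them as NA
    data.frame(characteristic = characteristic, level = lv, n = n,
               pct = 100 * n / length(fi), median_fi = m[["median"]],
               q1_fi = if (n >= na_iqr_below) m[["q1"]] else NA_real_,
               q3_fi = if (n >= na_iqr_below) m[["q3"]] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  nonempty <- split(fi, group)
  nonempty <- nonempty[lengths(nonempty) > 0L]
  if (length(nonempty) >= 3L) {
    t <- kruskal_wallis(nonempty)
    out$test <- "kruskal_wallis"; out$statistic <- t$H; out$p_value <- t$p_value
  } else if (length(nonempty) == 2L) {
    t <- mann_whitney_u(nonempty[[1L]], nonempty[[2L]])
    out$test <- "mann_whitney_u"; out$statistic <- t$U; out$p_value <- t$p_value
  } else {
    out$test <- NA_character_; out$statistic <- NA_real_
    out$p_value <- NA_real_
  }
  out
}

#' Subgroup comparison table of the fragility index
#'
#' Builds the characteristics-by-subgroup table: for each trial
#' characteristic (loss-to-follow-up class, publication-year bin,
#' multicenter design, double blinding, registration, intention-to-treat,
#' outcome used, journal group), the group sizes with percentages, the
#' median FI with IQR, and the appropriate rank test (Mann-Whitney U for
#' two occupied groups, Kruskal-Wallis for three or more). Tri-state design
#' flags are pooled to yes versus no-or-unsure. Quartiles of groups with
#' fewer than 4 trials are reported as `NA`. Exhausted records are excluded.
#'
#' @param corpus A `trial_corpus` after [attach_fragility()].
#'
#' @return A data.frame of class `"fi_table1"` with one row per subgroup
#'   level and columns `characteristic`, `level`, `n`, `pct`, `median_fi`,
#'   `q1_fi`, `q3_fi`, `test`, `statistic`, `p_value` (test columns repeated
#'   across the levels of a characteristic).
#'
#' @export
build_table1 <- function(corpus) {
  stopifnot(inherits(corpus, "trial_corpus"))
  corpus <- drop_exhausted(corpus)
  if (nrow(corpus) == 0L) stop("no usable records", call. = FALSE)
  fi <- corpus$fi
  pool <- function(tri, yes = "yes", other = "no_or_unsure")
    factor(ifelse(tri == "yes", yes, other), levels = c(yes, other))
  specs <- list(
    list("nplfu", factor(ifelse(corpus$nplfu_gt_fi, "nplfu_gt_fi",
                                "nplfu_le_fi"),
                         levels = c("nplfu_gt_fi", "nplfu_le_fi"))),
    list("year_bin", derive_year_bin(corpus$year)),
    list("multicenter", pool(corpus$multicenter)),
    list("double_blinded", pool(corpus$double_blinded)),
    list("registered", pool(corpus$registered, other = "no_or_not_reported")),
    list("itt", factor(corpus$itt, levels = c("yes", "no"))),
    list("outcome_used", factor(corpus$outcome_used,
                                levels = c("primary", "secondary"))),
    list("journal", derive_journal_group(corpus$journal)))
  out <- do.call(rbind, lapply(specs, function(s)
    compare_subgroups(fi, s[[2L]], s[[1L]])))
  rownames(out) <- NULL
  class(out) <- c("fi_table1", "data.frame")
  out
}

#' @export
print.fi_table1 <- function(x, ...) {
  cat("Fragility index by subgroup\n")
  df <- as.data.frame(x)
  df$median_fi <- signif(df$median_fi, 4)
  df$pct <- round(df$pct, 1)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Correlations of the fragility index with trial characteristics
#'
#' Spearman correlations of FI against (A) total randomized sample size,
#' (B) total number of events across both arms, and (C) the trial's
#' reported p-value. Pairs with a missing reported p-value are dropped
#' pairwise for panel C with a message; a panel with fewer than 3 usable
#' pairs is omitted with a warning. Exhausted records are excluded.
#'
#' @param corpus A `trial_corpus` after [attach_fragility()].
#'
#' @return A data.frame with one row per computed panel and columns
#'   `x_name`, `y_name`, `rho`, `p_value`, `n_pairs`.
#'
#' @export
correlate_fi <- function(corpus) {
  stopifnot(inherits(corpus, "trial_corpus"))
  corpus <- drop_exhausted(corpus)
  panels <- list(
    sample_size = corpus$n_int + corpus$n_ctl,
    total_events = corpus$events_int + corpus$events_ctl,
    reported_p = corpus$reported_p)
  rows <- list()
  for (nm in names(panels)) {
    y <- panels[[nm]]
    usable <- sum(!is.na(y) & !is.na(corpus$fi))
    if (usable < 3L) {
      warning("panel fi vs ", nm, " omitted: only ", usable,
              " usable pairs", call. = FALSE)
      next
    }
    n_missing <- sum(is.na(y))
    if (n_missing > 0L)
      message("fi vs ", nm, ": dropped ", n_missing,
              " pair(s) with missing values")
    r <- spearman_cor(corpus$fi, y, x_name = "fi", y_name = nm)
    rows[[nm]] <- data.frame(x_name = r$x_name, y_name = r$y_name,
                             rho = r$rho, p_value = r$p_value,
                             n_pairs = r$n_pairs, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
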