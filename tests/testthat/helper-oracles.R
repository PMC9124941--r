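# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths: the exact-test oracle enumerates the conditional
# distribution through stats::dhyper, the fragility oracle rebuilds every
# modified table explicitly, and the rank-test oracles are Monte-Carlo
# permutation estimates.

# minimum-likelihood two-sided exact p by full enumeration via dhyper
oracle_fisher_p <- function(ei, ni, ec, nc, tie_tol = 1e-7) {
  n1 <- ei + ni
  N <- n1 + ec + nc
  K <- ei + ec
  if (K == 0 || K == N) return(1)
  xs <- max(0, n1 + K - N):min(n1, K)
  d <- stats::dhyper(xs, K, N - K, n1)
  min(1, sum(d[d <= d[ei - xs[1] + 1] * (1 + tie_tol)]))
}

# naive fragility oracle: re-derive each incremented table and retest;
# same alpha-boundary guard as the implementation (exact p can equal alpha)
oracle_fragility <- function(ei, ni, ec, nc, alpha = 0.05) {
  nonsig <- function(p) p >= alpha - 1e-12
  p0 <- oracle_fisher_p(ei, ni, ec, nc)
  if (nonsig(p0)) return(list(fi = 0L, exhausted = FALSE))
  arms <- if (ei < ec) "int" else if (ec < ei) "ctl" else c("int", "ctl")
  best <- NULL
  for (a in arms) {
    avail <- if (a == "int") ni else nc
    cand <- NULL
    if (avail > 0) for (k in seq_len(avail)) {
      p <- if (a == "int") oracle_fisher_p(ei + k, ni - k, ec, nc)
           else oracle_fisher_p(ei, ni, ec + k, nc - k)
      if (nonsig(p)) { cand <- list(fi = k, exhausted = FALSE); break }
    }
    if (is.null(cand)) cand <- list(fi = avail, exhausted = TRUE)
    if (is.null(best) ||
        (!cand$exhausted && best$exhausted) ||
        (cand$exhausted == best$exhausted && cand$fi < best$fi))
      best <- cand
  }
  best
}

# Mann-Whitney U from joint mid-ranks (first group)
u_statistic <- function(x, y) {
  sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# two-sided permutation p for the U statistic
perm_p_mwu <- function(x, y, nperm = 10000, seed = 1) {
  set.seed(seed)
  nx <- length(x)
  pooled <- c(x, y)
  mu <- nx * length(y) / 2
  obs <- abs(u_statistic(x, y) - mu)
  hits <- 0L
  for (i in seq_len(nperm)) {
    idx <- sample.int(length(pooled), nx)
    if (abs(u_statistic(pooled[idx], pooled[-idx]) - mu) >= obs - 1e-9)
      hits <- hits + 1L
  }
  hits / nperm
}

# tie-corrected Kruskal-Wallis H computed directly from ranks
h_statistic <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  R <- tapply(r, g, sum)
  n <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(R^2 / n) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

perm_p_kw <- function(groups, nperm = 10000, seed = 1) {
  set.seed(seed)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  obs <- h_statistic(values, g)
  hits <- 0L
  for (i in seq_len(nperm))
    if (h_statistic(values, sample(g)) >= obs - 1e-9) hits <- hits + 1L
  hits / nperm
}

# quantile oracle: sort and interpolate order statistics at h = (n-1)p + 1
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# in-code fixture corpus covering all journal groups, year bins, and flag
# levels; optionally appends a record whose modifiable arm exhausts its
# non-events while still significant
make_fixture_corpus <- function(include_exhausted = FALSE) {
  df <- data.frame(
    trial_id = sprintf("F%02d", 1:12),
    first_author = paste0("Author", 1:12),
    year = c(1995, 1999, 2000, 2005, 2010, 2011, 2015, 2018, 2020, 1997,
             2008, 2021),
    journal = c("New England Journal of Medicine", "Journal of Pediatrics",
                "Neonatology", "Pediatrics", "JAMA", "The Lancet",
                "pediatrics", "NEW ENGLAND JOURNAL OF MEDICINE",
                "Acta Paediatrica", "Neonatology",
                "Journal of Pediatrics", "Archives of Disease in Childhood"),
    multicenter = c("yes", "no", "unsure", "yes", "no", "yes", "no", "yes",
                    "unsure", "no", "yes", "no"),
    double_blinded = c("yes", "no", "no", "unsure", "yes", "no", "yes",
                       "yes", "no", "unsure", "no", "no"),
    registered = c("no", "yes", "unsure", "yes", "no", "yes", "no", "yes",
                   "no", "unsure", "yes", "no"),
    itt = c("yes", "no", "yes", "yes", "no", "yes", "no", "yes", "no",
            "yes", "no", "yes"),
    outcome_used = c("primary", "secondary", "primary", "primary",
                     "secondary", "primary", "primary", "primary",
                     "secondary", "secondary", "primary", "secondary"),
    n_int = c(120, 40, 75, 30, 60, 250, 25, 400, 50, 35, 80, 180),
    n_ctl = c(120, 40, 75, 30, 60, 250, 25, 400, 50, 35, 80, 180),
    events_int = c(10, 2, 5, 1, 4, 30, 0, 45, 3, 2, 6, 22),
    events_ctl = c(28, 11, 17, 9, 15, 60, 7, 80, 13, 10, 18, 48),
    n_lost_followup = c(6, 3, 0, 2, 5, 20, 1, 30, 4, 0, 7, 12),
    reported_p = c(0.002, 0.01, 0.006, 0.009, 0.007, 0.001, 0.004, 0.0005,
                   0.008, 0.012, NA, 0.003),
    stringsAsFactors = FALSE)
  if (include_exhausted) {
    # intervention arm all-events with the smaller event count: the first
    # (only possible) modification is unavailable while p stays below alpha
    df <- rbind(df, data.frame(
      trial_id = "F13", first_author = "Author13", year = 2013,
      journal = "Other Journal", multicenter = "no",
      double_blinded = "no", registered = "no", itt = "no",
      outcome_used = "primary", n_int = 2, n_ctl = 19, events_int = 2,
      events_ctl = 3, n_lost_followup = 0, reported_p = 0.04,
      stringsAsFactors = FALSE))
  }
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  read_corpus(path)
}
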