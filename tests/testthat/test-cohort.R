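test_that("median and quartiles interpolate order statistics", {
  expect_equal(median_iqr(c(1, 2, 3)),
               c(median = 2, q1 = 1.5, q3 = 2.5))
  expect_equal(median_iqr(5), c(median = 5, q1 = 5, q3 = 5))
  set.seed(3)
  x <- rnorm(200)
  m <- median_iqr(x)
  expect_equal(m[["median"]], oracle_quantile(x, 0.5), tolerance = 1e-12)
  expect_equal(m[["q1"]], oracle_quantile(x, 0.25), tolerance = 1e-12)
  expect_equal(m[["q3"]], oracle_quantile(x, 0.75), tolerance = 1e-12)
  expect_true(m[["q1"]] <= m[["median"]] && m[["median"]] <= m[["q3"]])
  expect_error(median_iqr(numeric(0)), "non-empty")
  expect_error(median_iqr(c(1, NA)), "NA")
})

test_that("Mann-Whitney U: exact enumeration on small untied samples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_true(r$exact)
})

test_that("Mann-Whitney U is symmetric under identical groups", {
  x <- c(1, 2, 2, 3, 5)
  r <- mann_whitney_u(x, x)
  expect_equal(r$U, length(x)^2 / 2)
  r2 <- mann_whitney_u(c(2, 2, 2), c(2, 2))
  expect_equal(r2$U, 3)
  expect_equal(r2$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Kruskal-Wallis reproduces the hand-ranked fixture", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$H, 32 / 7, tolerance = 1e-12)
  expect_identical(as.integer(r$df), 2L)
  expect_equal(r$p_value, stats::pchisq(32 / 7, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  r0 <- kruskal_wallis(list(c(2, 2), c(2, 2, 2), c(2)))
  expect_equal(r0$H, 0)
  expect_equal(r0$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, 4:6)), ">= 3 groups")
  expect_error(kruskal_wallis(list(1:3, 4:6, numeric(0))), "non-empty")
})

test_that("Spearman rho is the rank Pearson correlation", {
  x <- c(1, 4, 9, 16, 25)
  r <- spearman_cor(x, sqrt(x))
  expect_equal(r$rho, 1)
  expect_equal(r$p_value, 0)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(8)
  a <- sample(1:5, 40, replace = TRUE)   # heavy ties
  b <- a + sample(0:3, 40, replace = TRUE)
  r2 <- spearman_cor(a, b)
  expect_equal(r2$rho, stats::cor(a, b, method = "spearman"),
               tolerance = 1e-12)
  # missing pairs dropped pairwise
  b[1:3] <- NA
  r3 <- spearman_cor(a, b)
  expect_identical(r3$n_pairs, 37L)
  expect_identical(r3$n_dropped, 3L)
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
  expect_error(spearman_cor(1:4, 1:3), "equal length")
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(17)
  x <- rgamma(30, 2); y <- rgamma(25, 3); z <- rgamma(20, 2.5)
  tr <- function(v) exp(v) + 5   # strictly monotone
  m1 <- mann_whitney_u(x, y); m2 <- mann_whitney_u(tr(x), tr(y))
  expect_equal(m1$U, m2$U); expect_equal(m1$p_value, m2$p_value)
  k1 <- kruskal_wallis(list(x, y, z))
  k2 <- kruskal_wallis(list(tr(x), tr(y), tr(z)))
  expect_equal(k1$H, k2$H)
  s1 <- spearman_cor(x, y[1:30 %% 25 + 1])
  s2 <- spearman_cor(tr(x), tr(y[1:30 %% 25 + 1]))
  expect_equal(s1$rho, s2$rho, tolerance = 1e-12)
})

test_that("two-group Kruskal-Wallis and U test agree asymptotically", {
  set.seed(31)
  x <- round(rnorm(200, 0.0, 1), 1)   # rounding induces ties
  y <- round(rnorm(200, 0.2, 1), 1)
  p_u <- mann_whitney_u(x, y, continuity = FALSE)$p_value
  p_kw <- stats::kruskal.test(c(x, y),
                              factor(rep(1:2, c(200, 200))))$p.value
  expect_lt(abs(p_u - p_kw), 0.01)
})

test_that("cohort summary counts are internally consistent", {
  scored <- attach_fragility(make_fixture_corpus())
  cs <- cohort_summary(scored)
  expect_identical(cs$n_trials, nrow(scored))
  expect_lte(cs$n_fi_eq1, cs$n_fi_le3)
  expect_lte(cs$n_fi_le3, cs$n_trials)
  expect_identical(sum(cs$fi_histogram), cs$n_trials)
  expect_equal(unname(cs$fi["median"]),
               oracle_quantile(scored$fi, 0.5))
  expect_identical(cs$n_nplfu_gt_fi, sum(scored$nplfu_gt_fi))
})

test_that("subgroup table covers every characteristic and trial", {
  scored <- attach_fragility(make_fixture_corpus())
  t1 <- build_table1(scored)
  expect_s3_class(t1, "fi_table1")
  expect_setequal(unique(t1$characteristic),
                  c("nplfu", "year_bin", "multicenter", "double_blinded",
                    "registered", "itt", "outcome_used", "journal"))
  # group counts sum to n for every characteristic
  for (ch in unique(t1$characteristic))
    expect_identical(sum(t1$n[t1$characteristic == ch]), nrow(scored))
  # test routing: >= 3 occupied groups -> Kruskal-Wallis, 2 -> U test
  expect_identical(unique(t1$test[t1$characteristic == "journal"]),
                   "kruskal_wallis")
  expect_identical(unique(t1$test[t1$characteristic == "multicenter"]),
                   "mann_whitney_u")
  expect_identical(unique(t1$test[t1$characteristic == "year_bin"]),
                   "kruskal_wallis")
  # small groups report a median but no quartiles
  small <- t1[t1$n > 0 & t1$n < 4, ]
  expect_true(all(!is.na(small$median_fi)))
  expect_true(all(is.na(small$q1_fi)))
  # empty levels are kept with a zero count and no median
  empty <- t1[t1$n == 0, ]
  expect_true(all(is.na(empty$median_fi)))
  # quartile ordering wherever present
  full <- t1[!is.na(t1$q1_fi), ]
  expect_true(all(full$q1_fi <= full$median_fi &
                  full$median_fi <= full$q3_fi))
})

test_that("correlation panels drop missing reported p pairwise", {
  scored <- attach_fragility(make_fixture_corpus())
  expect_message(cors <- correlate_fi(scored), "dropped 1")
  expect_identical(cors$y_name, c("sample_size", "total_events",
                                  "reported_p"))
  expect_identical(cors$n_pairs[3], nrow(scored) - 1L)
  expect_true(all(cors$rho >= -1 & cors$rho <= 1))
})

test_that("perfectly monotone corpora give rho 1", {
  df <- as.data.frame(make_fixture_corpus())[1:3, ]
  df$n_int <- c(30L, 100L, 400L); df$n_ctl <- df$n_int
  df$events_int <- c(0L, 4L, 30L); df$events_ctl <- c(8L, 20L, 75L)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE, na = "")
  scored <- attach_fragility(read_corpus(p))
  expect_identical(scored$fi, c(2L, 6L, 24L))  # strictly increasing in N
  cors <- suppressMessages(correlate_fi(scored))
  expect_equal(cors$rho[cors$y_name == "sample_size"], 1)
})

test_that("a corpus without reported p omits the p panel with a warning", {
  df <- as.data.frame(make_fixture_corpus())
  df$reported_p <- NA_real_
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE, na = "")
  scored <- attach_fragility(read_corpus(p))
  expect_warning(cors <- correlate_fi(scored), "reported_p omitted")
  expect_identical(cors$y_name, c("sample_size", "total_events"))
})
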