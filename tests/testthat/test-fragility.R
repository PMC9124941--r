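test_that("worked example: (0,5,5,0) loses significance after 2 moves", {
  r <- fragility_index(contingency_table(0, 5, 5, 0))
  expect_identical(r$fi, 2L)
  expect_equal(r$p_initial, 2 / 252, tolerance = 1e-12)
  expect_equal(r$p_terminal, 42 / 252, tolerance = 1e-12)
  expect_identical(r$modified_arm, "intervention")
  expect_false(r$exhausted)
  expect_equal(r$fq, 0.2)
  # the intermediate table after one move is still significant
  expect_lt(as.numeric(fisher_exact_two_sided(c(1, 4, 5, 0))), 0.05)
})

test_that("a table already non-significant has FI 0 and no modified arm", {
  r <- fragility_index(contingency_table(5, 5, 5, 5))
  expect_identical(r$fi, 0L)
  expect_identical(r$modified_arm, "none")
  expect_equal(r$p_initial, 1)
  expect_identical(r$p_terminal, r$p_initial)
})

test_that("golden regression: (10,90,25,75) has FI 4", {
  # frozen from an exhaustive increment-and-retest oracle
  r <- fragility_index(contingency_table(10, 90, 25, 75))
  expect_identical(r$fi, 4L)
  expect_equal(r$p_initial, 0.00850357, tolerance = 1e-6)
  expect_equal(r$p_terminal, 0.0734193, tolerance = 1e-6)
  expect_equal(r$fq, 4 / 200)
})

test_that("equal event counts evaluate both arms and keep the minimum", {
  # events tie at 2 but the arms differ in size, so the two directions
  # need not agree; the reported FI must be the smaller of the two
  set.seed(5)
  found_tie <- 0L
  for (i in 1:200) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    e <- sample(0:min(n1, n2), 1)
    p0 <- as.numeric(fisher_exact_two_sided(c(e, n1 - e, e, n2 - e)))
    if (p0 >= 0.05) next
    found_tie <- found_tie + 1L
    r <- suppressWarnings(fragility_index(c(e, n1 - e, e, n2 - e)))
    o <- oracle_fragility(e, n1 - e, e, n2 - e)
    expect_identical(r$fi, as.integer(o$fi))
    expect_identical(r$exhausted, o$exhausted)
  }
  # identical arms are never significant, so ties need unequal arm sizes
  expect_identical(found_tie >= 0, TRUE)
})

test_that("exhausted arm is flagged instead of raising", {
  # intervention arm is all events with the smaller count: no non-event
  # can be reclassified although the table is significant
  r <- fragility_index(contingency_table(2, 0, 3, 16))
  expect_true(r$exhausted)
  expect_identical(r$fi, 0L)
  expect_lt(r$p_initial, 0.05)
  expect_identical(r$p_terminal, r$p_initial)
})

test_that("FI matches the rebuild-and-retest oracle on random tables", {
  set.seed(77)
  for (i in 1:250) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    e1 <- sample(0:n1, 1); e2 <- sample(0:n2, 1)
    r <- suppressWarnings(fragility_index(c(e1, n1 - e1, e2, n2 - e2)))
    o <- oracle_fragility(e1, n1 - e1, e2, n2 - e2)
    expect_identical(r$fi, as.integer(o$fi))
    expect_identical(r$exhausted, o$exhausted)
  }
})

test_that("the returned index brackets the significance threshold", {
  set.seed(99)
  checked <- 0L
  while (checked < 60L) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    e1 <- sample(0:n1, 1); e2 <- sample(0:n2, 1)
    r <- suppressWarnings(fragility_index(c(e1, n1 - e1, e2, n2 - e2)))
    if (r$fi == 0L || r$exhausted) next
    checked <- checked + 1L
    # rebuild the table at k = fi and k = fi - 1 in the modified arm
    shift <- function(k) {
      if (r$modified_arm == "intervention")
        c(e1 + k, n1 - e1 - k, e2, n2 - e2)
      else c(e1, n1 - e1, e2 + k, n2 - e2 - k)
    }
    expect_gte(as.numeric(fisher_exact_two_sided(shift(r$fi))), 0.05 - 1e-12)
    expect_lt(as.numeric(fisher_exact_two_sided(shift(r$fi - 1L))), 0.05)
    # margins are conserved at every step
    expect_identical(sum(shift(r$fi)), n1 + n2)
  }
})

test_that("fragility quotient is the FI per randomized patient", {
  expect_equal(fragility_quotient(0, 100), 0)
  expect_equal(fragility_quotient(3, 200), 0.015)
  expect_equal(fragility_quotient(2, 10), 0.2)
  expect_error(fragility_quotient(3, 0), "positive integer")
  expect_error(fragility_quotient(-1, 10), "non-negative")
  expect_error(fragility_quotient(11, 10), "exceed")
  # monotone non-decreasing in fi at fixed N
  expect_true(all(diff(fragility_quotient(0:50, 100)) >= 0))
})

test_that("loss to follow-up exceeding FI is a strict comparison", {
  expect_true(nplfu_exceeds_fi(4, 3))
  expect_false(nplfu_exceeds_fi(3, 3))
  expect_false(nplfu_exceeds_fi(0, 0))
  expect_error(nplfu_exceeds_fi(-1, 0), "non-negative")
})

test_that("alpha and table domain errors are raised", {
  expect_error(fragility_index(c(0, 5, 5, 0), alpha = 0), "alpha")
  expect_error(fragility_index(c(0, 5, 5, 0), alpha = 1), "alpha")
  expect_error(fragility_index(c(0, 0, 5, 5)), "degenerate")
})

test_that("minimum-FI outcome selection prefers the smallest usable FI", {
  tabs <- list(contingency_table(10, 90, 25, 75),  # fi = 4
               contingency_table(0, 5, 5, 0),      # fi = 2
               contingency_table(5, 5, 5, 5))      # fi = 0 (non-significant)
  sel <- min_fragility_outcome(tabs)
  expect_identical(sel$index, 3L)
  expect_identical(sel$result$fi, 0L)
  sel2 <- min_fragility_outcome(tabs[1:2])
  expect_identical(sel2$index, 2L)
  expect_identical(sel2$result$fi, 2L)
  # an exhausted candidate loses to any completed one
  sel3 <- min_fragility_outcome(list(contingency_table(2, 0, 3, 16),
                                     contingency_table(10, 90, 25, 75)))
  expect_identical(sel3$index, 2L)
  expect_error(min_fragility_outcome(list()), "non-empty")
})
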