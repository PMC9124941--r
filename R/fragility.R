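#' Fragility index of a significant 2x2 trial result
#'
#' The fragility index (FI) is the minimum number of patients in one arm
#' whose outcome must be reclassified from non-event to event for a
#' statistically significant dichotomous result to lose significance under a
#' two-sided Fisher exact test. Starting from the observed table, the
#' procedure repeatedly adds one event to the arm with the smaller event
#' count while removing one non-event from the same arm -- so arm sizes and
#' the total randomized N never change -- and recomputes the exact two-sided
#' p-value after each step. FI is the smallest number of such moves yielding
#' p >= `alpha`.
#'
#' The arm to modify is fixed from the original table and kept throughout
#' the iteration. If the two arms have equal event counts, both directions
#' are evaluated and the smaller resulting index is returned (the definition
#' asks for the minimum number of reclassified events in either group). A
#' table whose exact p-value is already at or above `alpha` has FI 0: this
#' legitimately occurs for trials whose own reported test was significant
#' while the exact test is not. If the modifiable arm runs out of non-events
#' before significance is lost, the result is flagged `exhausted` and `fi`
#' records the number of non-events consumed.
#'
#' @param table A [contingency_table()] (or anything
#'   [fisher_exact_two_sided()] accepts).
#' @param alpha Significance threshold, strictly between 0 and 1
#'   (default 0.05).
#'
#' @return An object of class `"fragility_result"`: a list with elements
#'   `fi` (the fragility index), `fq` (fragility quotient, `fi / N`),
#'   `p_initial`, `p_terminal` (the exact p after the `fi`-th move),
#'   `modified_arm` (`"intervention"`, `"control"`, or `"none"` when
#'   `fi = 0`), `exhausted`, `alpha`, and `n_total`.
#'
#' @examples
#' fragility_index(contingency_table(0, 5, 5, 0))   # fi = 2
#' fragility_index(contingency_table(5, 5, 5, 5))   # already non-significant
#'
#' @seealso [fragility_quotient()], [attach_fragility()]
#' @export
fragility_index <- function(table, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number strictly between 0 and 1",
         call. = FALSE)
  cells <- as_cells(table)
  if (any(cells < 0))
    stop("cell counts must be non-negative", call. = FALSE)
  ei <- cells[1L]; ni <- cells[2L]; ec <- cells[3L]; nc <- cells[4L]
  if (ei + ni < 1L || ec + nc < 1L)
    stop("degenerate table: each arm must contain at least one patient",
         call. = FALSE)
  n_total <- ei + ni + ec + nc
  p0 <- .fisher_p(ei, ni, ec, nc)

  # Exact p-values are rationals and can equal alpha exactly (e.g. 1/20);
  # a small absolute guard keeps floating-point noise in the enumeration
  # from flipping the p >= alpha decision at the boundary.
  nonsig <- function(p) p >= alpha - 1e-12

  if (nonsig(p0)) {
    return(new_fragility_result(0L, p0, p0, "none", FALSE, alpha, n_total))
  }

  # arm choice frozen from the ORIGINAL table; both directions on a tie
  arms <- if (ei < ec) "intervention" else if (ec < ei) "control"
          else c("intervention", "control")

  run_arm <- function(arm) {
    avail <- if (arm == "intervention") ni else nc
    p_last <- p0
    if (avail >= 1L) for (k in seq_len(avail)) {
      p_k <- if (arm == "intervention") .fisher_p(ei + k, ni - k, ec, nc)
             else                       .fisher_p(ei, ni, ec + k, nc - k)
      if (nonsig(p_k))
        return(list(fi = k, p_terminal = p_k, exhausted = FALSE))
      p_last <- p_k
    }
    list(fi = avail, p_terminal = p_last, exhausted = TRUE)
  }

  paths <- lapply(arms, run_arm)
  ok <- !vapply(paths, `[[`, logical(1), "exhausted")
  pick <- if (any(ok)) {
    cand <- which(ok)
    cand[which.min(vapply(paths[cand], `[[`, integer(1), "fi"))]
  } else {
    which.min(vapply(paths, `[[`, integer(1), "fi"))
  }
  res <- paths[[pick]]
  new_fragility_result(res$fi, p0, res$p_terminal, arms[pick],
                       res$exhausted, alpha, n_total)
}

new_fragility_result <- function(fi, p_initial, p_terminal, modified_arm,
                                 exhausted, alpha, n_total) {
  structure(list(fi = as.integer(fi),
                 fq = fi / n_total,
                 p_initial = as.numeric(p_initial),
                 p_terminal = as.numeric(p_terminal),
                 modified_arm = modified_arm,
                 exhausted = exhausted,
                 alpha = alpha,
                 n_total = as.integer(n_total)),
            class = "fragility_result")
}

#' @export
print.fragility_result <- function(x, ...) {
  cat("Fragility index result (alpha =", format(x$alpha), ")\n")
  cat("  FI:", x$fi, if (x$exhausted) "(non-events exhausted before p >= alpha)",
      "\n")
  cat("  FQ:", format(signif(x$fq, 4)), " (N =", x$n_total, ")\n")
  cat("  p initial:", format(signif(x$p_initial, 4)),
      " p terminal:", format(signif(x$p_terminal, 4)), "\n")
  cat("  modified arm:", x$modified_arm, "\n")
  invisible(x)
}

#' Fragility quotient
#'
#' FI normalized by the trial's total randomized sample size: `fi / n_total`.
#' Expresses fragility per randomized patient, enabling comparison of trials
#' of different sizes.
#'
#' @param fi Fragility index (non-negative integer, at most `n_total`).
#' @param n_total Total randomized sample size (positive integer).
#'
#' @return `fi / n_total`, a fraction in `[0, 1]`.
#'
#' @examples
#' fragility_quotient(3, 200)  # 0.015
#'
#' @export
fragility_quotient <- function(fi, n_total) {
  if (any(is.na(fi)) || any(fi < 0) || any(fi != round(fi)))
    stop("'fi' must be a non-negative integer", call. = FALSE)
  if (any(is.na(n_total)) || any(n_total < 1) || any(n_total != round(n_total)))
    stop("'n_total' must be a positive integer", call. = FALSE)
  if (any(fi > n_total))
    stop("'fi' cannot exceed 'n_total'", call. = FALSE)
  fi / n_total
}

#' Does loss to follow-up exceed the fragility index?
#'
#' Flags trials in which the number of patients lost to follow-up (NPLFU) is
#' strictly greater than the fragility index: in such trials the unobserved
#' outcomes alone could have overturned statistical significance.
#'
#' @param n_lost Number of patients lost to follow-up (non-negative).
#' @param fi Fragility index (non-negative).
#'
#' @return Logical: `TRUE` iff `n_lost > fi` (strict). Vectorized.
#'
#' @examples
#' nplfu_exceeds_fi(4, 3)  # TRUE
#' nplfu_exceeds_fi(3, 3)  # FALSE: strict inequality
#'
#' @export
nplfu_exceeds_fi <- function(n_lost, fi) {
  if (any(is.na(n_lost)) || any(n_lost < 0) || any(is.na(fi)) || any(fi < 0))
    stop("'n_lost' and 'fi' must be non-negative", call. = FALSE)
  n_lost > fi
}

#' Select the minimum-FI outcome among several candidate tables
#'
#' Trials often report several significant dichotomous outcomes; the
#' convention is to analyze only the outcome with the smallest fragility
#' index. Given a list of candidate 2x2 tables for one trial, this helper
#' computes the FI of each and returns the minimizer (non-exhausted results
#' preferred; ties broken by list order).
#'
#' @param tables A non-empty list of tables acceptable to
#'   [fragility_index()].
#' @param alpha Significance threshold passed through to [fragility_index()].
#'
#' @return A list with `index` (position of the selected table), `result`
#'   (its `fragility_result`), and `all` (every candidate's result).
#'
#' @export
min_fragility_outcome <- function(tables, alpha = 0.05) {
  if (!is.list(tables) || length(tables) == 0L)
    stop("'tables' must be a non-empty list of 2x2 tables", call. = FALSE)
  res <- lapply(tables, fragility_index, alpha = alpha)
  exhausted <- vapply(res, `[[`, logical(1), "exhausted")
  fis <- vapply(res, `[[`, integer(1), "fi")
  ord <- order(exhausted, fis)  # non-exhausted first, then smallest FI
  idx <- ord[1L]
  list(index = idx, result = res[[idx]], all = res)
}
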