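#' Construct a 2x2 contingency table of trial outcomes
#'
#' The unit of fragility computation: a cross-tabulation of arm
#' (intervention / control) by outcome (event / non-event) for one
#' dichotomous endpoint of a two-arm trial.
#'
#' @param events_int,nonevents_int Event and non-event counts in the
#'   intervention arm (non-negative integers; the arm must contain at least
#'   one patient).
#' @param events_ctl,nonevents_ctl Event and non-event counts in the control
#'   arm.
#'
#' @return An integer matrix of class `"contingency_table"` with arms as rows
#'   and outcomes as columns.
#'
#' @examples
#' contingency_table(0, 5, 5, 0)
#'
#' @export
contingency_table <- function(events_int, nonevents_int, events_ctl, nonevents_ctl) {
  cells <- c(events_int, nonevents_int, events_ctl, nonevents_ctl)
  if (length(cells) != 4L || anyNA(cells) || !is.numeric(cells))
    stop("all four cell counts must be supplied as single numbers", call. = FALSE)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  cells <- as.integer(round(cells))
  if (cells[1L] + cells[2L] < 1L || cells[3L] + cells[4L] < 1L)
    stop("each arm must contain at least one patient", call. = FALSE)
  x <- matrix(cells, nrow = 2L, byrow = TRUE,
              dimnames = list(arm = c("intervention", "control"),
                              outcome = c("event", "nonevent")))
  class(x) <- c("contingency_table", class(x))
  x
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("2x2 contingency table (N =", sum(x), ")\n")
  print(unclass(x), ...)
  invisible(x)
}

# normalise input into the four cells c(ei, ni, ec, nc)
as_cells <- function(table) {
  if (inherits(table, "contingency_table")) return(as.integer(t(unclass(table))))
  if (is.matrix(table) && all(dim(table) == 2L)) return(as.integer(t(table)))
  if (is.numeric(table) && length(table) == 4L) return(as.integer(table))
  stop("'table' must be a contingency_table, a 2x2 matrix, or 4 cell counts",
       call. = FALSE)
}

#' Hypergeometric point probability
#'
#' Probability of drawing exactly `x` marked items in a sample of size `n`
#' from a population of `N` items of which `K` are marked, computed through
#' log binomial coefficients: C(K, x) C(N - K, n - x) / C(N, n). This is the
#' exact kernel underneath the two-sided Fisher test.
#'
#' @param x Number of marked items drawn.
#' @param N Population size.
#' @param K Number of marked items in the population.
#' @param n Sample size.
#'
#' @return The point probability, a number in `[0, 1]`.
#'
#' @examples
#' hypergeom_pmf(1, 10, 6, 5)  # 6/252
#'
#' @export
hypergeom_pmf <- function(x, N, K, n) {
  vals <- c(x, N, K, n)
  if (anyNA(vals) || any(vals != round(vals)) || any(vals < 0))
    stop("x, N, K, n must be non-negative integers", call. = FALSE)
  if (K > N || n > N || n < 1L)
    stop("need 0 <= K <= N and 1 <= n <= N", call. = FALSE)
  if (x < max(0, n + K - N) || x > min(n, K))
    stop("x = ", x, " outside the hypergeometric support [",
         max(0, n + K - N), ", ", min(n, K), "]", call. = FALSE)
  exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
}

# Fast internal two-sided exact p for cells (ei, ni, ec, nc); no validation.
# Minimum-likelihood rule: sum point probabilities of all margin-preserving
# tables no more probable than the observed one. A relative tie tolerance
# keeps floating-point noise from dropping a tied table out of the sum.
.fisher_p <- function(ei, ni, ec, nc, tie_tol = 1e-7) {
  n1 <- ei + ni            # intervention arm size
  N  <- n1 + ec + nc
  K  <- ei + ec            # total events
  if (K == 0L || K == N) return(1)
  lo <- max(0L, n1 + K - N)
  hi <- min(n1, K)
  xs <- lo:hi
  logd <- lchoose(K, xs) + lchoose(N - K, n1 - xs) - lchoose(N, n1)
  d <- exp(logd - max(logd))           # rescaled; ordering preserved
  d_obs <- d[ei - lo + 1L]
  min(1, sum(d[d <= d_obs * (1 + tie_tol)]) / sum(d))
}

#' Two-sided Fisher exact test p-value
#'
#' Exact conditional test for association in a 2x2 table, two-sided under the
#' minimum-likelihood rule: the p-value sums the hypergeometric probabilities
#' of every table with the observed margins whose point probability does not
#' exceed that of the observed table. The computation enumerates the full
#' conditional support through log binomial coefficients; no large-sample
#' approximation is ever used, since fragility flips hinge on the exact
#' position of p relative to the significance threshold.
#'
#' Tables tied with the observed point probability are included using a
#' relative tolerance of `1e-7`, guarding against floating-point asymmetry in
#' the enumeration. If either margin is degenerate (no events at all, or no
#' non-events at all) the conditional distribution is a point mass and p = 1.
#'
#' @param table A [contingency_table()], a 2x2 matrix (rows = arms,
#'   columns = event/non-event), or a numeric vector of the four cells
#'   `(events_int, nonevents_int, events_ctl, nonevents_ctl)`.
#'
#' @return The two-sided p-value, a number in `(0, 1]`, with attribute
#'   `method = "fisher_exact_two_sided"`.
#'
#' @examples
#' fisher_exact_two_sided(contingency_table(0, 5, 5, 0))  # 2/252
#' fisher_exact_two_sided(c(3, 7, 3, 7))                  # identical arms: 1
#'
#' @export
fisher_exact_two_sided <- function(table) {
  cells <- as_cells(table)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (cells[1L] + cells[2L] < 1L || cells[3L] + cells[4L] < 1L)
    stop("each arm must contain at least one patient", call. = FALSE)
  p <- .fisher_p(cells[1L], cells[2L], cells[3L], cells[4L])
  structure(p, method = "fisher_exact_two_sided")
}
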