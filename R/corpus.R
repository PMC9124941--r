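#' @name corpus-schema
#' @title Trial corpus CSV schema
#'
#' @description
#' A trial corpus is a CSV (UTF-8, comma-separated, header required, free
#' text quoted) with one row per randomized controlled trial and exactly the
#' following columns:
#'
#' \describe{
#'   \item{trial_id}{unique identifier (text)}
#'   \item{first_author}{first author surname (text)}
#'   \item{year}{year of publication (1900--2100)}
#'   \item{journal}{journal name (free text; see [derive_journal_group()])}
#'   \item{multicenter, double_blinded, registered}{tri-state flags:
#'     `yes` / `no` / `unsure`}
#'   \item{itt}{intention-to-treat analysis: `yes` / `no`}
#'   \item{outcome_used}{`primary` / `secondary` -- which outcome the 2x2
#'     counts describe}
#'   \item{n_int, n_ctl}{randomized arm sizes (>= 1)}
#'   \item{events_int, events_ctl}{event counts per arm (<= the arm size)}
#'   \item{n_lost_followup}{patients lost to follow-up (<= total N)}
#'   \item{reported_p}{the trial's reported p-value for this outcome
#'     (in `[0, 1]`; may be empty)}
#' }
#'
#' Each trial carries a single pre-selected outcome: when a trial reported
#' several significant outcomes, the one with the smallest fragility index
#' is chosen at extraction time (see [min_fragility_outcome()]).
NULL

CORPUS_COLUMNS <- c("trial_id", "first_author", "year", "journal",
                    "multicenter", "double_blinded", "registered", "itt",
                    "outcome_used", "n_int", "n_ctl", "events_int",
                    "events_ctl", "n_lost_followup", "reported_p")

TRISTATE_LEVELS <- c("yes", "no", "unsure")
JOURNAL_GROUPS <- c("NEJM", "J_Pediatrics", "Neonatology", "Pediatrics",
                    "JAMA", "Other")
YEAR_BINS <- c("pre2000", "y2000_2010", "y2011_present")

# per-row invariant checks; returns character vector of row-numbered messages
validate_corpus_rows <- function(df) {
  msgs <- character(0)
  bad <- function(cond, rule) {
    idx <- which(cond)
    if (length(idx))
      sprintf("row %d: %s", idx, rule)
    else character(0)
  }
  count_ok <- function(x) !is.na(x) & x >= 0 & x == round(x)
  msgs <- c(msgs,
    bad(is.na(df$trial_id) | !nzchar(df$trial_id), "trial_id must be non-empty"),
    bad(!count_ok(df$n_int) | df$n_int < 1, "n_int must be a positive integer"),
    bad(!count_ok(df$n_ctl) | df$n_ctl < 1, "n_ctl must be a positive integer"),
    bad(!count_ok(df$events_int), "events_int must be a non-negative integer"),
    bad(!count_ok(df$events_ctl), "events_ctl must be a non-negative integer"),
    bad(!count_ok(df$n_lost_followup),
        "n_lost_followup must be a non-negative integer"),
    bad(is.na(df$year) | df$year < 1900 | df$year > 2100,
        "year must lie in 1900-2100"),
    bad(!df$multicenter %in% TRISTATE_LEVELS,
        "multicenter must be yes/no/unsure"),
    bad(!df$double_blinded %in% TRISTATE_LEVELS,
        "double_blinded must be yes/no/unsure"),
    bad(!df$registered %in% TRISTATE_LEVELS,
        "registered must be yes/no/unsure"),
    bad(!df$itt %in% c("yes", "no"), "itt must be yes/no"),
    bad(!df$outcome_used %in% c("primary", "secondary"),
        "outcome_used must be primary/secondary"),
    bad(!is.na(df$reported_p) & (df$reported_p < 0 | df$reported_p > 1),
        "reported_p must lie in [0, 1]"))
  # cross-field invariants only where the fields themselves parsed
  ok <- count_ok(df$n_int) & count_ok(df$n_ctl) &
    count_ok(df$events_int) & count_ok(df$events_ctl) &
    count_ok(df$n_lost_followup)
  msgs <- c(msgs,
    bad(ok & df$events_int > df$n_int, "events_int exceeds n_int"),
    bad(ok & df$events_ctl > df$n_ctl, "events_ctl exceeds n_ctl"),
    bad(ok & df$n_lost_followup > df$n_int + df$n_ctl,
        "n_lost_followup exceeds total sample size"),
    bad(ok & df$n_int + df$n_ctl < 2, "total sample size must be >= 2"))
  dup <- duplicated(df$trial_id) & !is.na(df$trial_id)
  msgs <- c(msgs, if (any(dup))
    sprintf("row %d: duplicated trial_id '%s'", which(dup), df$trial_id[dup]))
  msgs
}

as_trial_corpus <- function(df, provenance) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(CORPUS_COLUMNS, names(df))
  unknown <- setdiff(names(df), CORPUS_COLUMNS)
  if (length(missing) || length(unknown))
    stop("corpus schema mismatch",
         if (length(missing)) paste0("; missing columns: ",
                                     paste(missing, collapse = ", ")),
         if (length(unknown)) paste0("; unknown columns: ",
                                     paste(unknown, collapse = ", ")),
         call. = FALSE)
  df <- df[, CORPUS_COLUMNS]
  for (col in c("trial_id", "first_author", "journal"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("multicenter", "double_blinded", "registered", "itt",
                "outcome_used"))
    df[[col]] <- tolower(trimws(as.character(df[[col]])))
  for (col in c("year", "n_int", "n_ctl", "events_int", "events_ctl",
                "n_lost_followup")) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & v != round(v)))
      stop("column '", col, "' contains non-integer values", call. = FALSE)
    df[[col]] <- as.integer(round(v))
  }
  df$reported_p <- suppressWarnings(as.numeric(df$reported_p))
  msgs <- validate_corpus_rows(df)
  if (length(msgs))
    stop("invalid corpus:\n  ", paste(msgs, collapse = "\n  "), call. = FALSE)
  structure(df, provenance = provenance,
            class = c("trial_corpus", "data.frame"))
}

#' Read a trial corpus from CSV
#'
#' Reads and validates a corpus of trial records (one row per RCT; schema in
#' [corpus-schema]). Every invariant violation is reported with its row
#' number; a corpus with any invalid row is rejected as a whole.
#'
#' @param path Path to a corpus CSV file.
#'
#' @return A validated `trial_corpus` (a `data.frame` subclass) with a
#'   `provenance` attribute recording the source path.
#'
#' @examples
#' path <- system.file("extdata", "example_corpus.csv",
#'                     package = "rctfragility")
#' corp <- read_corpus(path)
#' nrow(corp)
#'
#' @seealso [write_corpus()], [attach_fragility()]
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE,
                        fileEncoding = "UTF-8")
  as_trial_corpus(df, provenance = path)
}

#' Write a trial corpus to CSV
#'
#' Serializes the corpus back to the schema of [corpus-schema];
#' `read_corpus(write_corpus(x, f))` reproduces `x` field for field.
#'
#' @param corpus A `trial_corpus`.
#' @param path Output CSV path.
#'
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "trial_corpus"))
  utils::write.csv(as.data.frame(corpus)[, CORPUS_COLUMNS], path,
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' @export
print.trial_corpus <- function(x, ...) {
  cat("Trial corpus:", nrow(x), "records",
      "(provenance:", attr(x, "provenance"), ")\n")
  print(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Publication-year bins
#'
#' Partitions publication years into the three cohort-analysis bins: before
#' 2000, 2000--2010, and 2011 to present. Every year maps to exactly one bin;
#' 2010 belongs to the middle bin and 2011 onward counts as "present era".
#'
#' @param year Vector of calendar years (1900--2100).
#'
#' @return A factor with levels `pre2000`, `y2000_2010`, `y2011_present`.
#'
#' @examples
#' derive_year_bin(c(1999, 2000, 2010, 2011))
#'
#' @export
derive_year_bin <- function(year) {
  if (any(is.na(year)) || any(year < 1900) || any(year > 2100))
    stop("'year' must lie in 1900-2100", call. = FALSE)
  bins <- ifelse(year < 2000, "pre2000",
                 ifelse(year <= 2010, "y2000_2010", "y2011_present"))
  factor(bins, levels = YEAR_BINS)
}

#' Journal groups
#'
#' Maps journal names onto the six analysis groups: the five named
#' high-volume journals (New England Journal of Medicine, Journal of
#' Pediatrics, Neonatology, Pediatrics, JAMA) and `Other`. Matching is
#' case-insensitive and whitespace-trimmed but otherwise exact.
#'
#' @param journal Character vector of journal names.
#'
#' @return A factor with levels `NEJM`, `J_Pediatrics`, `Neonatology`,
#'   `Pediatrics`, `JAMA`, `Other`.
#'
#' @examples
#' derive_journal_group(c("pediatrics", "The Lancet"))
#'
#' @export
derive_journal_group <- function(journal) {
  key <- tolower(trimws(as.character(journal)))
  map <- c("new england journal of medicine" = "NEJM",
           "journal of pediatrics" = "J_Pediatrics",
           "neonatology" = "Neonatology",
           "pediatrics" = "Pediatrics",
           "jama" = "JAMA")
  grp <- unname(map[key])
  grp[is.na(grp)] <- "Other"
  factor(grp, levels = JOURNAL_GROUPS)
}

#' Compute per-trial fragility over a corpus
#'
#' Runs [fragility_index()] on every record's 2x2 table and appends the
#' results as columns: `fi`, `fq`, `p_initial`, `fi_exhausted`, and
#' `nplfu_gt_fi` (loss to follow-up strictly exceeding FI). Input fields are
#' never modified; the computation is deterministic given the corpus and
#' `alpha`. Records whose modifiable arm exhausts its non-events before
#' significance is lost are flagged and reported with a warning; downstream
#' summaries exclude them.
#'
#' @param corpus A validated `trial_corpus`.
#' @param alpha Significance threshold for the exact test (default 0.05).
#'
#' @return The corpus with fragility columns appended (class preserved) and
#'   attribute `alpha`.
#'
#' @export
attach_fragility <- function(corpus, alpha = 0.05) {
  stopifnot(inherits(corpus, "trial_corpus"))
  n <- nrow(corpus)
  fi <- integer(n); fq <- numeric(n); p0 <- numeric(n); exh <- logical(n)
  for (i in seq_len(n)) {
    r <- fragility_index(c(corpus$events_int[i],
                           corpus$n_int[i] - corpus$events_int[i],
                           corpus$events_ctl[i],
                           corpus$n_ctl[i] - corpus$events_ctl[i]),
                         alpha = alpha)
    fi[i] <- r$fi; fq[i] <- r$fq; p0[i] <- r$p_initial; exh[i] <- r$exhausted
  }
  out <- corpus
  out$fi <- fi
  out$fq <- fq
  out$p_initial <- p0
  out$fi_exhausted <- exh
  out$nplfu_gt_fi <- if (n) nplfu_exceeds_fi(corpus$n_lost_followup, fi)
                     else logical(0)
  if (any(exh))
    warning(sum(exh), " record(s) exhausted their non-events before losing ",
            "significance and will be excluded from summaries: ",
            paste(corpus$trial_id[exh], collapse = ", "), call. = FALSE)
  attr(out, "alpha") <- alpha
  out
}

# drop exhausted records before summarising; warn when any are dropped
drop_exhausted <- function(corpus) {
  if (!("fi" %in% names(corpus)))
    stop("corpus has no fragility columns; run attach_fragility() first",
         call. = FALSE)
  if (any(corpus$fi_exhausted)) {
    message("excluding ", sum(corpus$fi_exhausted),
            " exhausted record(s) from the summary")
    corpus <- corpus[!corpus$fi_exhausted, , drop = FALSE]
  }
  corpus
}
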