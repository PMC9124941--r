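#' Serialize a fragility result as JSON
#'
#' One-record machine-readable form of a [fragility_index()] result, used by
#' the command-line `compute` subcommand. Numbers are rounded to 6
#' significant digits so downstream golden-file comparisons are stable.
#'
#' @param result A `fragility_result`.
#'
#' @return A JSON string (class `json`).
#' @export
fragility_json <- function(result) {
  stopifnot(inherits(result, "fragility_result"))
  out <- unclass(result)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null")
}

# tiny FNV-1a hash over a canonical JSON rendering; identifies a config in
# run logs without pulling in a cryptographic dependency
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  # 32-bit FNV-1a in double arithmetic (the xor only touches the low byte;
  # the multiply is split so intermediates stay exactly representable)
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    lo <- h %% 65536
    hi <- (h %/% 65536) %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

round6 <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}

#' Write the full cohort analysis bundle
#'
#' Runs the complete pipeline on a corpus -- per-trial fragility, cohort
#' summary, subgroup table, FI histogram, correlation panels -- and writes
#' every product to `output_dir`:
#'
#' * `per_trial.csv` -- each record with its `fi`, `fq`, `p_initial`,
#'   `fi_exhausted`, `nplfu_gt_fi`;
#' * `cohort_summary.json` -- the [cohort_summary()] object;
#' * `table1.csv` -- the [build_table1()] subgroup comparisons;
#' * `fi_histogram.csv` -- trials per FI value (histogram-ready);
#' * `fi_scatter.csv` -- per-trial FI against sample size, total events and
#'   reported p (scatter-ready);
#' * `correlations.csv` -- the [correlate_fi()] panels;
#' * `run_log.json` -- package version, input provenance, alpha, config
#'   hash, and the identifiers of any excluded (exhausted) records.
#'
#' All report numbers are rounded to 6 significant digits and are
#' recomputable from `per_trial.csv` alone; rerunning on the same inputs
#' writes an identical bundle.
#'
#' @param corpus A `trial_corpus`, or a path to a corpus CSV.
#' @param output_dir Directory to write into (created if absent).
#' @param alpha Significance threshold (default 0.05).
#'
#' @return Invisibly, a named character vector of the files written.
#'
#' @export
cohort_report <- function(corpus, output_dir, alpha = 0.05) {
  if (is.character(corpus) && length(corpus) == 1L)
    corpus <- read_corpus(corpus)
  stopifnot(inherits(corpus, "trial_corpus"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  scored <- suppressWarnings(attach_fragility(corpus, alpha = alpha))
  excluded <- scored$trial_id[scored$fi_exhausted]
  usable <- suppressMessages(drop_exhausted(scored))

  paths <- c(per_trial = file.path(output_dir, "per_trial.csv"),
             summary = file.path(output_dir, "cohort_summary.json"),
             table1 = file.path(output_dir, "table1.csv"),
             histogram = file.path(output_dir, "fi_histogram.csv"),
             scatter = file.path(output_dir, "fi_scatter.csv"),
             correlations = file.path(output_dir, "correlations.csv"),
             log = file.path(output_dir, "run_log.json"))

  utils::write.csv(round6(as.data.frame(scored)), paths[["per_trial"]],
                   row.names = FALSE, na = "")

  cs <- cohort_summary(scored)
  cs_json <- list(n_trials = cs$n_trials, n_excluded = cs$n_excluded,
                  fi = as.list(signif(cs$fi, 6)),
                  fq = as.list(signif(cs$fq, 6)),
                  sample_size = as.list(signif(cs$sample_size, 6)),
                  total_events = as.list(signif(cs$total_events, 6)),
                  n_fi_le3 = cs$n_fi_le3, n_fi_eq1 = cs$n_fi_eq1,
                  n_nplfu_gt_fi = cs$n_nplfu_gt_fi, alpha = cs$alpha)
  jsonlite::write_json(cs_json, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA)

  t1 <- suppressMessages(build_table1(scored))
  utils::write.csv(round6(as.data.frame(t1)), paths[["table1"]],
                   row.names = FALSE, na = "")

  hist_df <- data.frame(fi = as.integer(names(cs$fi_histogram)),
                        n_trials = as.integer(cs$fi_histogram))
  utils::write.csv(hist_df, paths[["histogram"]], row.names = FALSE)

  scatter <- data.frame(trial_id = usable$trial_id, fi = usable$fi,
                        sample_size = usable$n_int + usable$n_ctl,
                        total_events = usable$events_int + usable$events_ctl,
                        reported_p = usable$reported_p,
                        stringsAsFactors = FALSE)
  utils::write.csv(round6(scatter), paths[["scatter"]], row.names = FALSE,
                   na = "")

  cors <- suppressWarnings(suppressMessages(correlate_fi(scored)))
  utils::write.csv(round6(cors), paths[["correlations"]], row.names = FALSE)

  log <- list(package = "rctfragility",
              version = as.character(utils::packageVersion("rctfragility")),
              input = attr(corpus, "provenance"),
              alpha = alpha,
              config_hash = config_hash(list(input = attr(corpus, "provenance"),
                                             alpha = alpha,
                                             n_records = nrow(corpus))),
              n_records = nrow(corpus),
              excluded_exhausted = as.list(excluded))
  jsonlite::write_json(log, paths[["log"]], auto_unbox = TRUE, digits = NA)

  invisible(paths)
}
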