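#' Run the full differential-structure pipeline
#'
#' Chains the whole analysis for a two-condition dataset: optional
#' reactivity computation from raw counts and coverage filtering, then
#' normalization (winsorize/rescale, within-condition quantile
#' normalization, pivot-anchored robust between-condition transform), then
#' the Monte-Carlo-calibrated scan for structurally variable regions.
#'
#' @param data Reactivity tibble, or `NULL` when `counts` is given.
#' @param counts Optional raw count tibble (see [read_counts()]); when
#'   supplied without `data`, reactivities are computed by enumerating all
#'   case x control replicate pairings, and the coverage filters are
#'   applied.
#' @param pivot Optional pivot tibble forwarded to
#'   [normalize_reactivity()].
#' @param reference Reference condition.
#' @param min_coverage,min_rt Coverage-filter thresholds (used with
#'   `counts`).
#' @param radius,l_min,l_max,alpha,B,seed,null_type,global,cache Scan
#'   parameters, see [scan_svrs()].
#' @param screen_p,max_iter Pivot-screen parameters, see
#'   [select_pivot_set()].
#' @param out_dir Optional directory; when given, the called SVRs,
#'   per-position table, normalized reactivities, resolved configuration
#'   and a log file are written there, so the run is reproducible from the
#'   directory alone.
#' @return List of class `svrscan_run` with elements `norm`
#'   (`reactivity_norm`), `scan` (`svr_scan`) and `config` (named list of
#'   every resolved parameter).
#' @export
run_pipeline <- function(data = NULL, counts = NULL, pivot = NULL,
                         reference = NULL, min_coverage = 10, min_rt = 2,
                         radius = 2, l_min = 1, l_max = 100, alpha = 0.05,
                         B = 1000, seed = 1, screen_p = 0.25, max_iter = 5,
                         null_type = "uniform", global = FALSE,
                         cache = NULL, out_dir = NULL) {
  log_lines <- c(sprintf("svrscan %s | R %s",
                         as.character(utils::packageVersion("svrscan")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed: %d", seed))
  if (is.null(data)) {
    if (is.null(counts)) {
      abort("input stage: supply reactivities or raw counts",
            class = "svrscan_stage_error")
    }
    data <- pair_count_replicates(counts)
    log_lines <- c(log_lines,
                   sprintf("reactivity stage: %d replicate pairings",
                           length(unique(paste(data$condition, data$replicate)))))
  }
  if (!is.null(counts)) {
    masked_before <- sum(is.na(data$reactivity))
    data <- withCallingHandlers(
      apply_coverage_filters(data, counts, min_coverage, min_rt),
      message = function(m) invokeRestart("muffleMessage"))
    log_lines <- c(log_lines,
                   sprintf("filter stage: %d values missing after filters (%d before)",
                           sum(is.na(data$reactivity)), masked_before))
  }
  conds <- tryCatch(condition_pair(data, reference), error = function(e) {
    abort(paste0("input stage: ", conditionMessage(e)),
          class = "svrscan_stage_error")
  })
  norm <- tryCatch(
    normalize_reactivity(data, pivot = pivot, reference = conds[1],
                         screen_p = screen_p, max_iter = max_iter,
                         radius = radius),
    error = function(e) {
      abort(paste0("normalization stage: ", conditionMessage(e)),
            class = "svrscan_stage_error")
    })
  log_lines <- c(log_lines,
                 sprintf("normalization stage: %d transcript(s), median beta %.3f",
                         nrow(norm$model), stats::median(norm$model$beta)))
  scan <- tryCatch(
    scan_svrs(norm, radius = radius, l_min = l_min, l_max = l_max,
              alpha = alpha, B = B, seed = seed, null_type = null_type,
              global = global, cache = cache),
    error = function(e) {
      abort(paste0("scan stage: ", conditionMessage(e)),
            class = "svrscan_stage_error")
    })
  log_lines <- c(log_lines,
                 sprintf("scan stage: %d SVR(s) called; %d untestable position(s)",
                         nrow(scan$svrs), sum(is.na(scan$positions$p))))
  config <- list(reference = conds[1], min_coverage = min_coverage,
                 min_rt = min_rt, radius = radius, l_min = l_min,
                 l_max = l_max, alpha = alpha, B = B, seed = seed,
                 screen_p = screen_p, max_iter = max_iter,
                 null_type = null_type, global = global,
                 pivot_supplied = !is.null(pivot))
  res <- structure(list(norm = norm, scan = scan, config = config,
                        log = log_lines),
                   class = "svrscan_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.svrscan_run <- function(x, ...) {
  cat("Differential-structure pipeline run\n")
  print(x$scan)
  invisible(x)
}

#' Write a pipeline run to a directory
#'
#' Writes `svrs.tsv`, `positions.tsv`, `normalized.tsv`, the resolved
#' `config.tsv` (key-value) and `log.txt`.
#'
#' @param run A `svrscan_run` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "svrscan_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_svrs(run$scan, file.path(dir, "svrs.tsv"))
  readr::write_tsv(run$scan$positions, file.path(dir, "positions.tsv"),
                   na = "NA", progress = FALSE)
  write_reactivity(run$norm$data, file.path(dir, "normalized.tsv"))
  cfg <- tibble(key = names(run$config),
                value = vapply(run$config, function(v) paste(format(v),
                                                             collapse = ","),
                               character(1)))
  readr::write_tsv(cfg, file.path(dir, "config.tsv"), progress = FALSE)
  writeLines(run$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' Simulation study over signal levels and seeds
#'
#' Runs simulate -> normalize -> scan -> evaluate over a seed grid for each
#' requested signal level, and aggregates the evaluation metrics.  With
#' `signal = "null"` both pseudo-conditions share the same mixture weights,
#' so the run estimates the false positive rate and the family-wise error
#' rate (fraction of runs with at least one called SVR), with a binomial
#' standard error on the latter.
#'
#' @param signals Character vector of signal levels (`"low"`, `"medium"`,
#'   `"high"`, `"null"`).
#' @param n_seeds Number of seeded runs per signal level (default 20).
#' @param lengths Transcript length or range, forwarded to
#'   [simulate_reactivity()].
#' @param n_reps Replicates per condition: a scalar, or a length-2 range
#'   from which each run's replicate count is drawn.
#' @param model A `reactivity_model`.
#' @param radius,l_min,l_max,alpha,B Scan parameters.
#' @param seed Root seed; run r of signal s uses a child seed derived from
#'   it, so the whole study is reproducible.
#' @param cache Null-distribution cache shared across runs (created
#'   internally when `NULL`).
#' @return List with `per_run` (one row per run: jaccard, avg distance,
#'   specificity, fpr, any_svr) and `aggregate` (one row per signal level
#'   with means and the FWER estimate +/- binomial SE).
#' @export
run_simulation_study <- function(signals = c("low", "medium", "high"),
                                 n_seeds = 20, lengths = c(100, 300),
                                 n_reps = 4, model = reactivity_model("shape"),
                                 radius = 2, l_min = 1, l_max = 100,
                                 alpha = 0.05, B = 500, seed = 1,
                                 cache = NULL) {
  cache <- cache %||% new_null_cache()
  rows <- purrr::map(signals, function(sg) {
    purrr::map(seq_len(n_seeds), function(r) {
      run_seed <- stage_seed(seed, paste0("study_", sg, "_", r))
      reps <- if (length(n_reps) == 2) {
        with_seed(stage_seed(run_seed, "reps"),
                  sample(seq(n_reps[1], n_reps[2]), 1))
      } else {
        n_reps
      }
      sim <- simulate_reactivity(n_transcripts = 1, lengths = lengths,
                                 signal = sg, model = model, n_reps = reps,
                                 seed = run_seed)
      res <- run_pipeline(sim$data, radius = radius, l_min = l_min,
                          l_max = l_max, alpha = alpha, B = B,
                          seed = run_seed, cache = cache)
      n <- sim$params$lengths[1]
      tx <- sim$data$transcript_id[1]
      truth <- filter(sim$truth, .data$transcript_id == tx)
      ranked <- res$scan$positions %>% arrange(.data$rank) %>%
        pull(.data$position)
      ev <- evaluate_svrs(res$scan$svrs, truth, n, ranked = ranked)
      mutate(ev$summary, signal = sg, run = r, seed = run_seed,
             n_reps = reps, any_svr = .data$n_predicted > 0)
    }) %>% bind_rows()
  }) %>% bind_rows()

  aggregate <- rows %>%
    group_by(.data$signal) %>%
    summarise(
      n_runs = n(),
      mean_jaccard = mean(.data$jaccard),
      mean_avg_distance = mean(.data$avg_distance, na.rm = TRUE),
      mean_specificity = mean(.data$specificity, na.rm = TRUE),
      mean_fpr = mean(.data$fpr),
      fwer = mean(.data$any_svr),
      fwer_se = sqrt(.data$fwer * (1 - .data$fwer) / .data$n_runs),
      .groups = "drop") %>%
    arrange(factor(.data$signal, levels = signals))
  list(per_run = rows, aggregate = aggregate)
}
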