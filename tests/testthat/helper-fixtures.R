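# Build a long reactivity tibble from per-replicate vectors.
# values: named list, e.g. list(A = list(rep1 = c(...), rep2 = c(...)), B = ...)
make_react_tbl <- function(values, transcript_id = "tx1") {
  rows <- list()
  for (cond in names(values)) {
    for (rep in names(values[[cond]])) {
      v <- values[[cond]][[rep]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        transcript_id = transcript_id,
        position = seq_along(v),
        condition = cond,
        replicate = rep,
        reactivity = as.numeric(v))
    }
  }
  dplyr::bind_rows(rows)
}

# Two-condition tibble where both conditions carry identical replicate values.
make_identical_conditions <- function(n = 60, n_reps = 2, seed = 1) {
  set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(i) runif(n))
  names(reps) <- paste0("rep", seq_len(n_reps))
  make_react_tbl(list(A = reps, B = reps))
}

# Brute-force maximal scan-statistic region: double loop over all
# (start, end) pairs.  Independent of the package's enumeration path.
brute_max_region <- function(p, l_min = 1, l_max = length(p)) {
  n <- length(p)
  best <- list(q = -Inf, start = NA, end = NA)
  for (s in seq_len(n)) {
    for (e in s:n) {
      L <- e - s + 1
      if (L < l_min || L > l_max) next
      pp <- p[s:e]
      if (any(is.na(pp))) next
      q <- -sum(log(pp)) / sqrt(L)
      if (q > best$q) best <- list(q = q, start = s, end = e)
    }
  }
  best
}

# Count-table fixture: one transcript, given case/control replicates with
# rt_stop and coverage vectors.
make_counts <- function(case_rt, control_cov, transcript_id = "tx1",
                        condition = NULL) {
  rows <- list()
  for (rep in names(case_rt)) {
    v <- case_rt[[rep]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      transcript_id = transcript_id, position = seq_along(v),
      rt_stop = as.numeric(v), coverage = as.numeric(v) * 0 + 100,
      experiment = "case", replicate = rep)
  }
  for (rep in names(control_cov)) {
    v <- control_cov[[rep]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      transcript_id = transcript_id, position = seq_along(v),
      rt_stop = as.numeric(v) * 0, coverage = as.numeric(v),
      experiment = "control", replicate = rep)
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(condition)) out$condition <- condition
  out
}
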