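#' Read a long-format reactivity table
#'
#' Reads a tab-separated reactivity table with columns `transcript_id`,
#' `position` (1-based), `condition`, `replicate` and `reactivity` (`NA` for
#' missing).  Positions without a row are treated as missing downstream.
#'
#' @param path Path to a tab-separated file.
#' @param lengths Optional transcript lengths: either a path to a two-column
#'   TSV (`transcript_id`, `length`) or a tibble with those columns.  When
#'   absent, each transcript's length is taken as its maximum observed
#'   position.
#' @return A tibble with one row per observed (transcript, position,
#'   condition, replicate) key, carrying a `transcript_lengths` attribute.
#' @export
read_reactivity <- function(path, lengths = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = "NA")
  required <- c("transcript_id", "position", "condition", "replicate", "reactivity")
  if (!all(required %in% names(df))) {
    abort(paste0("malformed header: expected columns ",
                 paste(required, collapse = ", ")),
          class = "svrscan_format_error")
  }
  df <- as_tibble(df[required]) %>%
    mutate(transcript_id = as.character(.data$transcript_id),
           position = as.integer(.data$position),
           condition = as.character(.data$condition),
           replicate = as.character(.data$replicate),
           reactivity = as.numeric(.data$reactivity))
  if (!is.null(lengths) && is.character(lengths)) {
    lengths <- readr::read_tsv(lengths, show_col_types = FALSE, progress = FALSE)
  }
  validate_reactivity(df)
  attr(df, "transcript_lengths") <- resolve_lengths(df, lengths)
  df
}

#' Write a reactivity table
#'
#' Inverse of [read_reactivity()]: writes the long TSV format with `NA` for
#' missing values.
#'
#' @param data A reactivity tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reactivity <- function(data, path) {
  validate_reactivity(data)
  readr::write_tsv(data, path, na = "NA", progress = FALSE)
  invisible(path)
}

validate_reactivity <- function(data) {
  required <- c("transcript_id", "position", "condition", "replicate", "reactivity")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste0("reactivity data lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "svrscan_format_error")
  }
  if (any(!is.finite(data$position) | data$position < 1 |
          data$position != as.integer(data$position))) {
    abort("positions must be positive integers (1-based)",
          class = "svrscan_validation_error")
  }
  key <- paste(data$transcript_id, data$position, data$condition,
               data$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- data[duplicated(key), , drop = FALSE][1, ]
    abort(sprintf("duplicate key: (%s, %d, %s, %s)", dup$transcript_id,
                  dup$position, dup$condition, dup$replicate),
          class = "svrscan_validation_error")
  }
  invisible(data)
}

resolve_lengths <- function(data, lengths = NULL) {
  observed <- data %>%
    group_by(.data$transcript_id) %>%
    summarise(length = max(.data$position), .groups = "drop")
  if (is.null(lengths)) return(observed)
  lengths <- as_tibble(lengths)
  out <- observed %>%
    left_join(rename(lengths, supplied = "length"), by = "transcript_id") %>%
    mutate(length = if_else(is.na(.data$supplied), .data$length,
                            as.numeric(.data$supplied))) %>%
    select("transcript_id", "length")
  if (any(out$length < observed$length)) {
    abort("supplied transcript length shorter than maximum observed position",
          class = "svrscan_validation_error")
  }
  mutate(out, length = as.integer(.data$length))
}

#' Transcript lengths of a reactivity table
#'
#' @param data A reactivity tibble.
#' @param lengths Optional tibble (`transcript_id`, `length`) overriding both
#'   the attached attribute and the observed maxima.
#' @return Tibble with columns `transcript_id`, `length`.
#' @export
transcript_lengths <- function(data, lengths = NULL) {
  if (!is.null(lengths)) return(resolve_lengths(data, lengths))
  attr(data, "transcript_lengths") %||% resolve_lengths(data)
}

#' Read a raw count table
#'
#' Reads RT-stop and coverage counts per position, one row per position of
#' one sequencing replicate.  Columns: `transcript_id`, `position`,
#' `rt_stop`, `coverage`, `experiment` (`case` or `control`), `replicate`,
#' and optionally `condition`.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, na = "NA")
  required <- c("transcript_id", "position", "rt_stop", "coverage",
                "experiment", "replicate")
  if (!all(required %in% names(df))) {
    abort(paste0("malformed count header: expected columns ",
                 paste(required, collapse = ", ")),
          class = "svrscan_format_error")
  }
  validate_counts(df)
  as_tibble(df)
}

validate_counts <- function(counts) {
  if (any(counts$rt_stop < 0, na.rm = TRUE) ||
      any(counts$coverage < 0, na.rm = TRUE)) {
    abort("counts must be nonnegative", class = "svrscan_validation_error")
  }
  if (!all(counts$experiment %in% c("case", "control"))) {
    abort("experiment must be 'case' or 'control'",
          class = "svrscan_validation_error")
  }
  invisible(counts)
}

#' Reactivity from one case/control replicate pair
#'
#' The per-position reactivity is the case-experiment RT-stop count divided
#' by the control-experiment coverage, the maximum-likelihood modification
#' rate when control coverage is proportional to probe exposure.  Positions
#' with zero (or missing) control coverage carry no exposure information and
#' become missing.
#'
#' @param case,control Count tibbles for a single replicate each (columns
#'   `transcript_id`, `position`, plus `rt_stop` for `case` and `coverage`
#'   for `control`).
#' @return A tibble `transcript_id`, `position`, `reactivity`.
#' @export
reactivity_from_counts <- function(case, control) {
  ct <- case %>% group_by(.data$transcript_id) %>%
    summarise(length = max(.data$position), .groups = "drop")
  kt <- control %>% group_by(.data$transcript_id) %>%
    summarise(length = max(.data$position), .groups = "drop")
  cmp <- inner_join(ct, kt, by = "transcript_id", suffix = c(".case", ".ctrl"))
  if (!setequal(ct$transcript_id, kt$transcript_id) ||
      any(cmp$length.case != cmp$length.ctrl)) {
    abort("case and control profiles must share transcripts and lengths",
          class = "svrscan_validation_error")
  }
  full_join(select(case, "transcript_id", "position", "rt_stop"),
            select(control, "transcript_id", "position", "coverage"),
            by = c("transcript_id", "position")) %>%
    mutate(reactivity = if_else(
      is.na(.data$coverage) | .data$coverage == 0,
      NA_real_, .data$rt_stop / .data$coverage)) %>%
    select("transcript_id", "position", "reactivity") %>%
    arrange(.data$transcript_id, .data$position)
}

#' Enumerate case x control replicate pairings
#'
#' Truncation-based protocols sequence the case (probe-treated) and control
#' experiments in separate replicates; every case replicate can be paired
#' with every control replicate, so `m` case and `k` control replicates yield
#' `m * k` reactivity replicates.  The replicate id of each output encodes
#' its pairing as `"<case>.<control>"`.
#'
#' @param counts Count tibble (see [read_counts()]); if a `condition` column
#'   is present, pairing is done within each condition.
#' @return A reactivity tibble (`condition` column retained when present,
#'   otherwise set to `"A"`).
#' @export
pair_count_replicates <- function(counts) {
  validate_counts(counts)
  if (!"condition" %in% names(counts)) counts$condition <- "A"
  out <- counts %>%
    group_by(.data$condition) %>%
    group_split() %>%
    purrr::map(function(cc) {
      cond <- cc$condition[1]
      case <- filter(cc, .data$experiment == "case")
      ctrl <- filter(cc, .data$experiment == "control")
      case_ids <- unique(case$replicate)
      ctrl_ids <- unique(ctrl$replicate)
      if (!length(case_ids) || !length(ctrl_ids)) {
        abort("need at least one case and one control replicate",
              class = "svrscan_validation_error")
      }
      grid <- tidyr::expand_grid(case_id = case_ids, ctrl_id = ctrl_ids)
      purrr::pmap(grid, function(case_id, ctrl_id) {
        reactivity_from_counts(filter(case, .data$replicate == case_id),
                               filter(ctrl, .data$replicate == ctrl_id)) %>%
          mutate(condition = cond,
                 replicate = paste0(case_id, ".", ctrl_id))
      }) %>% bind_rows()
    }) %>%
    bind_rows() %>%
    select("transcript_id", "position", "condition", "replicate", "reactivity")
  attr(out, "transcript_lengths") <- resolve_lengths(out)
  out
}

#' Coverage and RT-stop quality filters
#'
#' Applies the standard pre-filters for truncation-based structure probing:
#' transcripts whose RT stop count is below `min_rt` at every position (in
#' every case replicate) are dropped outright, and positions whose control
#' coverage falls below `min_coverage` in any control replicate of a
#' condition are set to missing in all profiles of that condition.
#'
#' @param data Reactivity tibble.
#' @param counts Matching count tibble (see [read_counts()]).
#' @param min_coverage Minimum control coverage to keep a position (default 10).
#' @param min_rt Minimum RT stop for a transcript to be retained (default 2).
#' @return The filtered reactivity tibble; the number of dropped transcripts
#'   and masked positions is reported via `message()`.
#' @export
apply_coverage_filters <- function(data, counts, min_coverage = 10, min_rt = 2) {
  validate_reactivity(data)
  validate_counts(counts)
  if (!"condition" %in% names(counts)) counts$condition <- NA_character_

  max_rt <- counts %>%
    filter(.data$experiment == "case") %>%
    group_by(.data$transcript_id) %>%
    summarise(max_rt = max(.data$rt_stop, na.rm = TRUE), .groups = "drop")
  drop_tx <- max_rt$transcript_id[max_rt$max_rt < min_rt]

  low_cov <- counts %>%
    filter(.data$experiment == "control",
           .data$coverage < min_coverage) %>%
    distinct(.data$transcript_id, .data$position, .data$condition)

  out <- filter(data, !.data$transcript_id %in% drop_tx)
  if (nrow(low_cov)) {
    if (all(is.na(low_cov$condition))) {
      mask_key <- paste(low_cov$transcript_id, low_cov$position)
      hit <- paste(out$transcript_id, out$position) %in% mask_key
    } else {
      mask_key <- paste(low_cov$transcript_id, low_cov$position, low_cov$condition)
      hit <- paste(out$transcript_id, out$position, out$condition) %in% mask_key
    }
    out$reactivity[hit] <- NA_real_
  } else {
    hit <- logical(0)
  }
  message(sprintf("coverage filters: dropped %d transcript(s), masked %d value(s)",
                  length(drop_tx), sum(hit)))
  attr(out, "transcript_lengths") <-
    filter(transcript_lengths(data), !.data$transcript_id %in% drop_tx)
  out
}
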