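intervals_to_positions <- function(intervals) {
  if (!nrow(intervals)) return(integer(0))
  unique(unlist(purrr::map2(intervals$start, intervals$end, seq.int)))
}

#' Jaccard index between two nucleotide position sets
#'
#' |A intersect B| / |A union B|; defined as 0 when both sets are empty.
#'
#' @param predicted,truth Integer vectors of positions (or tibbles with
#'   `start`/`end` interval columns).
#' @return A scalar in \[0, 1\].
#' @export
jaccard_index <- function(predicted, truth) {
  if (is.data.frame(predicted)) predicted <- intervals_to_positions(predicted)
  if (is.data.frame(truth)) truth <- intervals_to_positions(truth)
  u <- length(union(predicted, truth))
  if (u == 0) return(0)
  length(intersect(predicted, truth)) / u
}

#' Average distance from predicted SVRs to true SVRs
#'
#' For each nucleotide in a predicted SVR, the distance to the nearest
#' nucleotide of any true SVR (0 inside a true SVR).  Reported both per
#' predicted nucleotide (the headline value, length-weighted across
#' predicted regions) and as the mean of per-region averages.
#'
#' @param predicted Tibble of predicted intervals (`start`, `end`).
#' @param truth Tibble of true intervals (`start`, `end`); must be
#'   nonempty.
#' @return List with `per_nucleotide` and `per_region` mean distances;
#'   both `NA` (not applicable) when no region was predicted.
#' @export
average_distance <- function(predicted, truth) {
  truth_pos <- intervals_to_positions(truth)
  if (!length(truth_pos)) {
    abort("average distance is undefined with empty truth",
          class = "svrscan_validation_error")
  }
  if (!nrow(predicted)) {
    return(list(per_nucleotide = NA_real_, per_region = NA_real_))
  }
  truth_sorted <- sort(truth_pos)
  dist_to_truth <- function(pos) {
    i <- findInterval(pos, truth_sorted)
    lo <- ifelse(i >= 1, pos - truth_sorted[pmax(i, 1)], Inf)
    hi <- ifelse(i < length(truth_sorted),
                 truth_sorted[pmin(i + 1, length(truth_sorted))] - pos, Inf)
    pmin(lo, hi)
  }
  per_region <- purrr::map2_dbl(predicted$start, predicted$end, function(s, e) {
    mean(dist_to_truth(seq.int(s, e)))
  })
  all_pos <- unlist(purrr::map2(predicted$start, predicted$end, seq.int))
  list(per_nucleotide = mean(dist_to_truth(all_pos)),
       per_region = mean(per_region))
}

#' Precision-recall curve over top-k ranked nucleotides
#'
#' At each cutoff k, precision = |top-k intersect truth| / k and
#' recall = |top-k intersect truth| / |truth|.
#'
#' @param ranked Integer vector of positions ordered by decreasing evidence
#'   (rank 1 first).
#' @param truth Integer vector of true SVR positions (nonempty).
#' @param cutoffs Cutoff grid; default 5, 10, 20, 40, ... up to
#'   3 x |truth| (capped at `length(ranked)`).
#' @return Tibble `k`, `precision`, `recall`.
#' @export
precision_recall <- function(ranked, truth, cutoffs = NULL) {
  stopifnot(length(truth) >= 1)
  if (is.null(cutoffs)) {
    cutoffs <- 5 * 2^(0:12)
    cutoffs <- cutoffs[cutoffs <= 3 * length(truth)]
    if (!length(cutoffs)) cutoffs <- length(truth)
  }
  cutoffs <- sort(unique(pmin(cutoffs, length(ranked))))
  hits <- cumsum(ranked %in% truth)
  tibble(k = cutoffs,
         precision = hits[cutoffs] / cutoffs,
         recall = hits[cutoffs] / length(truth))
}

#' Specificity and position-level false positive rate
#'
#' Specificity is the fraction of true non-SVR positions not predicted;
#' the position-level FPR (the negative-control metric, where truth is
#' empty) is the number of predicted positions divided by the transcript
#' length.
#'
#' @param predicted Integer vector of predicted positions.
#' @param truth Integer vector of true SVR positions (may be empty).
#' @param n Transcript length.
#' @return List with `specificity` and `fpr`.
#' @export
specificity_and_fpr <- function(predicted, truth, n) {
  stopifnot(n >= 1)
  all_pos <- seq_len(n)
  non_truth <- setdiff(all_pos, truth)
  spec <- if (length(non_truth)) {
    length(setdiff(non_truth, predicted)) / length(non_truth)
  } else {
    NA_real_
  }
  list(specificity = spec, fpr = length(unique(predicted)) / n)
}

#' Annotated SVRs of the fluoride riboswitch benchmark
#'
#' The curated benchmark annotation for the *Bacillus cereus* crcB fluoride
#' riboswitch (100 nt), probed with and without fluoride: five SVR
#' intervals at positions 12-17, 22-27, 38-40, 48 and 67-74 (1-based
#' inclusive), 24 nucleotides in total.
#'
#' @return Tibble `transcript_id`, `start`, `end` with attribute
#'   `transcript_length` (100).
#' @export
flu_annotation <- function() {
  out <- tibble(transcript_id = "crcB_fluoride_riboswitch",
                start = c(12L, 22L, 38L, 48L, 67L),
                end = c(17L, 27L, 40L, 48L, 74L))
  attr(out, "transcript_length") <- 100L
  out
}

#' Evaluate predicted SVRs against a truth annotation
#'
#' Computes the full metric panel for one transcript (or one pooled
#' coordinate space): Jaccard index of the called positions, average
#' distance (per nucleotide and per region), specificity, position-level
#' FPR, and — when a ranking is supplied — the top-k precision/recall
#' curve and top-k Jaccard values.
#'
#' @param predicted Tibble of predicted intervals (`start`, `end`).
#' @param truth Tibble of true intervals (`start`, `end`); may have zero
#'   rows (negative-control evaluation).
#' @param n Transcript length.
#' @param ranked Optional integer vector of positions ordered by decreasing
#'   evidence (see [rank_nucleotides()]).
#' @param cutoffs Optional top-k cutoff grid.
#' @return List with `summary` (one-row tibble) and `curve` (tibble, empty
#'   without a ranking).
#' @export
evaluate_svrs <- function(predicted, truth, n, ranked = NULL, cutoffs = NULL) {
  pred_pos <- intervals_to_positions(predicted)
  truth_pos <- intervals_to_positions(truth)
  sf <- specificity_and_fpr(pred_pos, truth_pos, n)
  dist <- if (length(truth_pos)) {
    average_distance(predicted, truth)
  } else {
    list(per_nucleotide = NA_real_, per_region = NA_real_)
  }
  curve <- tibble(k = integer(0), precision = numeric(0), recall = numeric(0),
                  jaccard = numeric(0))
  if (!is.null(ranked) && length(truth_pos)) {
    curve <- precision_recall(ranked, truth_pos, cutoffs) %>%
      mutate(jaccard = purrr::map_dbl(.data$k, function(k) {
        jaccard_index(head(ranked, k), truth_pos)
      }))
  }
  list(summary = tibble(
    n = n,
    n_predicted = length(pred_pos),
    n_truth = length(truth_pos),
    jaccard = jaccard_index(pred_pos, truth_pos),
    avg_distance = dist$per_nucleotide,
    avg_distance_region = dist$per_region,
    specificity = sf$specificity,
    fpr = sf$fpr),
    curve = curve)
}
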