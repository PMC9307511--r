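# Two-sided Wilcoxon rank-sum p-value.
# Exact (via the null Mann-Whitney distribution) when both samples have at
# most `exact_max` values and no ties; otherwise normal approximation with
# tie correction and continuity correction — the same conventions as
# stats::wilcox.test, reimplemented without htest overhead because the scan
# calls this once per nucleotide position.
rank_sum_p <- function(x, y, exact_max = 10) {
  m <- length(x); k <- length(y)
  if (!m || !k) return(NA_real_)
  z <- c(x, y)
  r <- rank(z)
  W <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(z) > 0
  if (!ties && m <= exact_max && k <= exact_max) {
    p <- if (W > m * k / 2) {
      pwilcox(W - 1, m, k, lower.tail = FALSE)
    } else {
      pwilcox(W, m, k)
    }
    return(min(2 * p, 1))
  }
  mu <- m * k / 2
  tt <- table(r)
  sigma2 <- (m * k / 12) * ((m + k + 1) - sum(tt^3 - tt) / ((m + k) * (m + k - 1)))
  if (sigma2 <= 0) return(1)
  d <- W - mu
  d <- sign(d) * max(0, abs(d) - 0.5)  # continuity correction
  2 * pnorm(-abs(d) / sqrt(sigma2))
}

# Positional p-values from position x replicate matrices of the two
# conditions.  Window C_j = [j - radius, j + radius] truncated at the
# transcript ends; values of all replicates in the window are pooled per
# condition.  Positions with fewer than min_obs pooled values in either
# condition are untestable (NA).
positional_pvalue_vec <- function(A, B, radius = 2, min_obs = 3) {
  n <- nrow(A)
  p <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    win <- max(1, j - radius):min(n, j + radius)
    a <- A[win, , drop = FALSE]; a <- a[!is.na(a)]
    b <- B[win, , drop = FALSE]; b <- b[!is.na(b)]
    if (length(a) >= min_obs && length(b) >= min_obs) {
      p[j] <- rank_sum_p(a, b)
    }
  }
  p
}

#' Positional differential p-values
#'
#' For each nucleotide position j, pools the normalized reactivities of all
#' replicates over a window of radius `radius` centred at j (truncated at
#' transcript ends) in each condition, and computes a two-sided Wilcoxon
#' rank-sum p-value contrasting the two pooled samples.
#'
#' @param data Normalized reactivity tibble (or a `reactivity_norm` object).
#' @param radius Window radius in nucleotides (default 2, i.e. a 5-nt
#'   window).
#' @param min_obs Minimum pooled non-missing values per condition for a
#'   position to be testable (default 3).
#' @param reference Reference condition (first sorted when `NULL`).
#' @return Tibble `transcript_id`, `position`, `p` (`NA` where untestable).
#' @export
positional_pvalues <- function(data, radius = 2, min_obs = 3, reference = NULL) {
  if (inherits(data, "reactivity_norm")) data <- data$data
  validate_reactivity(data)
  lens <- transcript_lengths(data)
  conds <- condition_pair(data, reference)
  purrr::map(split(data, data$transcript_id), function(tx_data) {
    tx <- tx_data$transcript_id[1]
    n <- lens$length[lens$transcript_id == tx]
    mats <- reactivity_matrices(tx_data, n, conds)
    tibble(transcript_id = tx, position = seq_len(n),
           p = positional_pvalue_vec(mats$A, mats$B, radius, min_obs))
  }) %>% bind_rows()
}

#' Scan statistic of a candidate region
#'
#' Aggregates positional p-values over a region R as
#' Q(R) = (-sum log p_j) / sqrt(|R|): the numerator accumulates evidence,
#' the square-root length penalty stops a region from growing past its true
#' boundaries.
#'
#' @param p Vector of positional p-values, all in (0, 1\].
#' @return The scan statistic, a nonnegative scalar.
#' @export
scan_statistic <- function(p) {
  if (!length(p)) {
    abort("empty region", class = "svrscan_validation_error")
  }
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("positional p-values must lie in (0, 1]",
          class = "svrscan_validation_error")
  }
  -sum(log(p)) / sqrt(length(p))
}

#' Enumerate candidate regions with their scan statistics
#'
#' Slides windows of every length between `l_min` and `l_max` (stride 1)
#' across the transcript; a window qualifies only if every member position
#' has a non-missing p-value.  `l_max` is clamped to the transcript length.
#'
#' @param p Vector of positional p-values for one transcript (`NA` where
#'   untestable), indexed 1..n.
#' @param l_min,l_max Minimum and maximum region length (defaults 1, 100).
#' @return Tibble `start`, `end`, `length`, `q`.
#' @export
enumerate_regions <- function(p, l_min = 1, l_max = 100) {
  stopifnot(l_min >= 1, l_max >= l_min)
  n <- length(p)
  l_max <- min(l_max, n)
  bad <- is.na(p) | p <= 0 | p > 1
  if (any(p[!is.na(p)] <= 0 | p[!is.na(p)] > 1)) {
    abort("positional p-values must lie in (0, 1]",
          class = "svrscan_validation_error")
  }
  nlp <- ifelse(bad, 0, -log(p))
  cs <- c(0, cumsum(nlp))
  csna <- c(0, cumsum(bad))
  out <- vector("list", l_max - l_min + 1)
  for (L in l_min:l_max) {
    s <- seq_len(n - L + 1)
    e <- s + L - 1
    ok <- (csna[e + 1] - csna[s]) == 0
    if (!any(ok)) next
    out[[L - l_min + 1]] <- tibble(
      start = as.integer(s[ok]), end = as.integer(e[ok]),
      length = as.integer(L),
      q = (cs[e + 1] - cs[s])[ok] / sqrt(L))
  }
  bind_rows(out)
}

# Maximum scan statistic over all candidate regions of a -log p vector.
max_scan_stat <- function(nlp, l_min, l_max) {
  n <- length(nlp)
  l_max <- min(l_max, n)
  if (l_min > n) return(0)
  cs <- c(0, cumsum(nlp))
  best <- 0
  for (L in l_min:l_max) {
    s <- seq_len(n - L + 1)
    m <- max(cs[s + L] - cs[s]) / sqrt(L)
    if (m > best) best <- m
  }
  best
}

#' Monte-Carlo null distribution of the maximal scan statistic
#'
#' Simulates the global null in which positional p-values are i.i.d.
#' Uniform(0, 1): for each of `B` draws, an n-vector of uniform p-values is
#' generated and the maximum scan statistic over all candidate regions is
#' recorded.  Region significance is later assessed against these maxima,
#' which controls the family-wise error rate across the overlapping
#' candidate regions of a transcript.
#'
#' @param n Transcript length.
#' @param l_min,l_max Candidate region length bounds.
#' @param B Number of Monte-Carlo draws (default 1000, minimum 100).
#' @param alpha Target family-wise error level (default 0.05).
#' @param seed Integer seed; the simulation is reproducible given the seed.
#' @return An object of class `scan_null`: list with `samples` (the B
#'   maxima), `threshold` (empirical (1 - alpha) quantile), and the
#'   parameters.
#' @export
simulate_null_distribution <- function(n, l_min = 1, l_max = 100, B = 1000,
                                       alpha = 0.05, seed) {
  if (B < 100) {
    abort("B must be at least 100", class = "svrscan_validation_error")
  }
  samples <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      max_scan_stat(-log(runif(n)), l_min, l_max)
    }, numeric(1))
  })
  structure(list(samples = samples, sorted = sort(samples),
                 threshold = unname(quantile(samples, 1 - alpha, type = 7)),
                 n = n, l_min = l_min, l_max = min(l_max, n), B = B,
                 alpha = alpha, seed = seed),
            class = "scan_null")
}

#' @export
print.scan_null <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo scan null: n = %d, lengths %d-%d, B = %d, threshold(%.2f) = %.3f\n",
    x$n, x$l_min, x$l_max, x$B, 1 - x$alpha, x$threshold))
  invisible(x)
}

#' Create a cache for Monte-Carlo null distributions
#'
#' Null distributions are keyed by transcript-length bin (lengths are
#' rounded up to a 5% geometric grid, so one null serves all lengths in a
#' bin; simulating at the bin's upper edge errs conservative because a
#' longer transcript has more candidate regions).  Pass the cache to
#' [scan_svrs()], [run_pipeline()] or [run_simulation_study()] to reuse
#' nulls across transcripts and across runs.
#'
#' @return An environment used as a key-value store.
#' @export
new_null_cache <- function() new.env(parent = emptyenv())

bin_length <- function(n, rel = 0.05) {
  if (n <= 1) return(as.integer(n))
  as.integer(ceiling((1 + rel)^(ceiling(log(n) / log(1 + rel)))))
}

cached_null <- function(cache, n, l_min, l_max, B, alpha, seed) {
  nb <- max(bin_length(n), n)
  key <- sprintf("n%d_l%d_%d_B%d", nb, l_min, min(l_max, nb), B)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  null <- simulate_null_distribution(nb, l_min, l_max, B, alpha,
                                     seed = stage_seed(seed, key))
  if (!is.null(cache)) cache[[key]] <- null
  null
}

#' Call structurally variable regions against a Monte-Carlo null
#'
#' Each candidate region receives the add-one Monte-Carlo p-value
#' (1 + #\{T_b >= Q\}) / (B + 1); regions with p <= alpha are significant.
#' Reported SVRs are a greedy non-overlapping subset of the significant
#' regions, chosen in order of decreasing Q (ties broken toward the longer
#' region, then the smaller start).
#'
#' @param regions Tibble from [enumerate_regions()].
#' @param null A `scan_null` object whose `n` is at least the transcript
#'   length and whose length bounds match.
#' @param alpha Significance level (default: the null's alpha).
#' @param n Transcript length (default: the null's n).
#' @return Tibble `start`, `end`, `length`, `q`, `p_value` of the called,
#'   mutually non-overlapping SVRs.
#' @export
call_svrs <- function(regions, null, alpha = NULL, n = NULL) {
  if (!inherits(null, "scan_null")) {
    abort("`null` must be a scan_null object", class = "svrscan_validation_error")
  }
  alpha <- alpha %||% null$alpha
  n <- n %||% null$n
  if (n > null$n || (nrow(regions) && max(regions$length) > null$l_max)) {
    abort("null distribution parameters do not cover these regions",
          class = "svrscan_validation_error")
  }
  empty <- tibble(start = integer(0), end = integer(0), length = integer(0),
                  q = numeric(0), p_value = numeric(0))
  if (!nrow(regions)) return(empty)
  B <- null$B
  # #{T_b >= q} = B - #{T_b < q}; findInterval with left.open counts T_b < q
  ge_count <- B - findInterval(regions$q, null$sorted, left.open = TRUE)
  regions$p_value <- (1 + ge_count) / (B + 1)
  sig <- regions[regions$p_value <= alpha, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  sig <- arrange(sig, desc(.data$q), desc(.data$length), .data$start)
  taken <- logical(n)
  keep <- logical(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    span <- sig$start[i]:sig$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  arrange(sig[keep, c("start", "end", "length", "q", "p_value")], .data$start)
}

#' Scan a normalized dataset for structurally variable regions
#'
#' The full Scan stage: positional Wilcoxon p-values, enumeration of all
#' candidate regions with lengths in \[`l_min`, `l_max`\], Monte-Carlo
#' calibration of the maximal scan statistic under the i.i.d. uniform null,
#' and greedy non-overlapping SVR calling at family-wise level `alpha`.
#' Null distributions are simulated per transcript-length bin (5% geometric
#' binning, rounded up) and reused; pass a shared `cache` to reuse them
#' across calls.
#'
#' @param data Normalized reactivity tibble or a `reactivity_norm` object.
#' @param radius Window radius of the positional test (default 2 nt).
#' @param l_min,l_max Candidate region length bounds (defaults 1 and 100).
#' @param alpha Family-wise error level (default 0.05).
#' @param B Monte-Carlo draws per null distribution (default 1000).
#' @param seed Integer seed for the Monte-Carlo null (and the permutation
#'   null if selected).
#' @param min_obs Minimum pooled values per condition per position.
#' @param null_type `"uniform"` (the i.i.d. U(0,1) null, default) or
#'   `"permutation"` (condition labels of replicates are permuted and the
#'   positional tests recomputed; a sensitivity-analysis mode).
#' @param global When `TRUE`, Bonferroni-corrects `alpha` across transcripts
#'   so the family-wise error is controlled over the whole dataset rather
#'   than per transcript.
#' @param cache Optional environment from `new_null_cache()` for null reuse
#'   across calls.
#' @param reference Reference condition label.
#' @return An object of class `svr_scan`: list with `svrs` (called regions),
#'   `positions` (per-position p-values and ranking), `params`, and the
#'   per-transcript nulls.
#' @examples
#' sim <- simulate_reactivity(lengths = 80, signal = "high",
#'                            n_reps = 3, seed = 2)
#' res <- sim$data |> normalize_reactivity() |> scan_svrs(B = 200, seed = 2)
#' tidy(res)
#' @export
scan_svrs <- function(data, radius = 2, l_min = 1, l_max = 100, alpha = 0.05,
                      B = 1000, seed = 1, min_obs = 3,
                      null_type = c("uniform", "permutation"),
                      global = FALSE, cache = NULL, reference = NULL) {
  null_type <- match.arg(null_type)
  if (inherits(data, "reactivity_norm")) {
    reference <- reference %||% data$reference
    data <- data$data
  }
  validate_reactivity(data)
  lens <- transcript_lengths(data)
  conds <- condition_pair(data, reference)
  n_tx <- nrow(lens)
  alpha_eff <- if (global) alpha / n_tx else alpha

  nulls <- list()
  pieces <- purrr::map(split(data, data$transcript_id), function(tx_data) {
    tx <- tx_data$transcript_id[1]
    n <- lens$length[lens$transcript_id == tx]
    mats <- reactivity_matrices(tx_data, n, conds)
    p <- positional_pvalue_vec(mats$A, mats$B, radius, min_obs)
    regions <- enumerate_regions(p, l_min, l_max)
    null <- if (null_type == "uniform") {
      cached_null(cache, n, l_min, l_max, B, alpha_eff, seed)
    } else {
      permutation_null(mats$A, mats$B, radius, min_obs, l_min, l_max, B,
                       alpha_eff, seed = stage_seed(seed, paste0("perm_", tx)))
    }
    svrs <- call_svrs(regions, null, alpha = alpha_eff, n = n)
    pos <- tibble(transcript_id = tx, position = seq_len(n), p = p)
    list(svrs = if (nrow(svrs)) mutate(svrs, transcript_id = tx) else svrs,
         pos = pos, null = null, tx = tx)
  })

  svrs <- bind_rows(purrr::map(pieces, "svrs"))
  if (nrow(svrs)) {
    svrs <- select(svrs, "transcript_id", "start", "end", "length", "q",
                   "p_value")
  } else {
    svrs <- tibble(transcript_id = character(0), start = integer(0),
                   end = integer(0), length = integer(0), q = numeric(0),
                   p_value = numeric(0))
  }
  positions <- bind_rows(purrr::map(pieces, "pos"))
  res <- structure(list(
    svrs = svrs,
    positions = positions,
    nulls = setNames(purrr::map(pieces, "null"), purrr::map_chr(pieces, "tx")),
    params = list(radius = radius, l_min = l_min, l_max = l_max,
                  alpha = alpha, alpha_effective = alpha_eff, B = B,
                  seed = seed, min_obs = min_obs, null_type = null_type,
                  global = global, reference = conds[1]),
    lengths = lens
  ), class = "svr_scan")
  res$positions <- rank_nucleotides(res)
  res
}

# Permutation null: permute replicate condition labels, recompute positional
# p-values, record the max scan statistic.  Sensitivity-analysis mode that
# preserves the window-induced dependence between neighbouring p-values.
permutation_null <- function(A, B, radius, min_obs, l_min, l_max, B_draws,
                             alpha, seed) {
  all_mat <- cbind(A, B)
  nA <- ncol(A)
  nrep <- ncol(all_mat)
  samples <- with_seed(seed, {
    vapply(seq_len(B_draws), function(b) {
      idx <- sample.int(nrep, nA)
      p <- positional_pvalue_vec(all_mat[, idx, drop = FALSE],
                                 all_mat[, -idx, drop = FALSE],
                                 radius, min_obs)
      nlp <- -log(p[!is.na(p)])
      if (!length(nlp)) return(0)
      max_scan_stat(nlp, l_min, l_max)
    }, numeric(1))
  })
  structure(list(samples = samples, sorted = sort(samples),
                 threshold = unname(quantile(samples, 1 - alpha, type = 7)),
                 n = nrow(A), l_min = l_min, l_max = min(l_max, nrow(A)),
                 B = B_draws, alpha = alpha, seed = seed,
                 type = "permutation"),
            class = "scan_null")
}

#' Rank nucleotide positions by differential evidence
#'
#' Produces the total order used for top-k evaluation curves: positions
#' inside called SVRs come first, ordered by the scan statistic of their
#' covering region (descending) and then by their positional p-value; all
#' remaining positions follow, ordered by positional p-value (untestable
#' positions last).
#'
#' @param result An `svr_scan` object.
#' @return The `positions` tibble with columns `in_svr`, `svr_q` and `rank`
#'   (1 = strongest evidence), ranked within each transcript.
#' @export
rank_nucleotides <- function(result) {
  stopifnot(inherits(result, "svr_scan"))
  pos <- result$positions[c("transcript_id", "position", "p")]
  svrs <- result$svrs
  pos$in_svr <- FALSE
  pos$svr_q <- NA_real_
  if (nrow(svrs)) {
    for (i in seq_len(nrow(svrs))) {
      hit <- pos$transcript_id == svrs$transcript_id[i] &
        pos$position >= svrs$start[i] & pos$position <= svrs$end[i]
      pos$in_svr[hit] <- TRUE
      pos$svr_q[hit] <- svrs$q[i]
    }
  }
  pos %>%
    group_by(.data$transcript_id) %>%
    mutate(rank = order(order(!.data$in_svr,
                              if_else(.data$in_svr, -.data$svr_q, 0),
                              if_else(is.na(.data$p), Inf, .data$p),
                              .data$position))) %>%
    ungroup()
}

#' @export
print.svr_scan <- function(x, ...) {
  cat("SVR scan result\n")
  cat(sprintf("  transcripts scanned: %d   SVRs called: %d (alpha = %g, B = %d)\n",
              nrow(x$lengths), nrow(x$svrs), x$params$alpha, x$params$B))
  if (nrow(x$svrs)) print(x$svrs, n = 10)
  invisible(x)
}

#' @rdname scan_svrs
#' @param x,object An `svr_scan` object.
#' @param ... Unused.
#' @export
tidy.svr_scan <- function(x, ...) x$svrs

#' @rdname scan_svrs
#' @export
glance.svr_scan <- function(x, ...) {
  tibble(n_transcripts = nrow(x$lengths),
         n_svrs = nrow(x$svrs),
         n_positions_called = sum(x$positions$in_svr),
         frac_positions_called = sum(x$positions$in_svr) /
           sum(x$lengths$length),
         alpha = x$params$alpha, B = x$params$B,
         null_type = x$params$null_type)
}

#' @rdname scan_svrs
#' @export
autoplot.svr_scan <- function(object, ...) {
  pos <- mutate(object$positions,
                neglogp = -log10(if_else(is.na(.data$p), 1, .data$p)))
  gg <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$position,
                                          y = .data$neglogp)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::facet_wrap(~transcript_id, scales = "free_x") +
    ggplot2::labs(x = "position (nt)", y = expression(-log[10] ~ p[j])) +
    ggplot2::theme_minimal()
  if (nrow(object$svrs)) {
    gg <- gg + ggplot2::geom_rect(
      data = object$svrs,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.2)
  }
  gg
}

#' Write called SVRs to a tab-separated file
#'
#' Coordinates are 1-based inclusive (unlike 0-based half-open BED).
#'
#' @param result An `svr_scan` object (or its `svrs` tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svrs <- function(result, path) {
  svrs <- if (inherits(result, "svr_scan")) result$svrs else result
  readr::write_tsv(svrs, path, na = "NA", progress = FALSE)
  invisible(path)
}
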