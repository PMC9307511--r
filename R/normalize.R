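#' Winsorize and rescale a reactivity vector
#'
#' 90% winsorization (by default) followed by affine rescaling onto
#' \[0, 1\]: values below the `lower_pct` percentile are set to that
#' percentile and values above the `upper_pct` percentile to that
#' percentile; the clipped vector is then min-subtracted and divided by its
#' new maximum.  Percentiles use the empirical quantile with linear
#' interpolation (R type 7).  A constant (or constant-after-clipping) vector
#' maps to all zeros: it carries no structural signal, so there is nothing
#' to rescale.
#'
#' @param x Numeric vector, `NA` allowed (preserved in the output).
#' @param lower_pct,upper_pct Winsorization percentiles in \[0, 100\]
#'   (defaults 5 and 95).
#' @return Numeric vector of the same length with non-missing values in
#'   \[0, 1\].
#' @export
winsorize_rescale <- function(x, lower_pct = 5, upper_pct = 95) {
  obs <- !is.na(x)
  if (!any(obs)) {
    abort("all values missing: nothing to winsorize",
          class = "svrscan_validation_error")
  }
  q <- quantile(x[obs], c(lower_pct, upper_pct) / 100, names = FALSE, type = 7)
  y <- pmin(pmax(x, q[1]), q[2])
  lo <- min(y, na.rm = TRUE)
  y <- y - lo
  hi <- max(y, na.rm = TRUE)
  if (hi > 0) y <- y / hi else y[obs] <- 0
  y
}

#' Quantile normalization of within-condition replicates
#'
#' Matches the value distributions of replicate profiles: with equal
#' non-missing counts, each replicate's k-th order statistic is replaced by
#' the mean of the k-th order statistics across replicates.  With unequal
#' counts (missing data), each replicate's empirical quantile function is
#' interpolated onto a common probability grid, averaged, and the mean
#' quantile function is read back at each replicate's own plotting
#' positions, so ranks within a replicate are always preserved.  Missing
#' positions stay missing.
#'
#' @param mat Numeric matrix, positions in rows, replicates in columns
#'   (`NA` allowed).
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) return(mat)
  counts <- colSums(!is.na(mat))
  if (any(counts == 0)) {
    abort("replicate with no observed values cannot be quantile normalized",
          class = "svrscan_validation_error")
  }
  m_ref <- max(counts)
  probs_ref <- (seq_len(m_ref) - 0.5) / m_ref
  qmat <- vapply(seq_len(ncol(mat)), function(i) {
    v <- sort(mat[, i])
    m <- length(v)
    if (m == m_ref) return(v)
    approx((seq_len(m) - 0.5) / m, v, xout = probs_ref, rule = 2)$y
  }, numeric(m_ref))
  ref <- rowMeans(qmat)
  out <- mat
  for (i in seq_len(ncol(mat))) {
    obs <- !is.na(mat[, i])
    r <- rank(mat[obs, i], ties.method = "average")
    p <- (r - 0.5) / counts[i]
    out[obs, i] <- approx(probs_ref, ref, xout = p, rule = 2)$y
  }
  out
}

# Huber M-estimate simple linear regression by IRLS.
# k: tuning constant in units of the MAD-based robust residual scale.
huber_irls <- function(x, y, k = 1.345, tol = 1e-8, max_iter = 50) {
  X <- cbind(1, x)
  beta <- qr.coef(qr(X), y)
  converged <- FALSE
  iter <- 0L
  scale <- NA_real_
  w <- rep(1, length(y))
  for (iter in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    scale <- mad(r, center = 0)
    if (scale < 1e-12) { converged <- TRUE; break }
    w <- pmin(1, k * scale / pmax(abs(r), 1e-300))
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * y))
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       iterations = iter, converged = converged, scale = scale, weights = w)
}

# Huber M-estimate of location (intercept of a fixed-slope line).
huber_location <- function(r, k = 1.345, tol = 1e-8, max_iter = 50) {
  mu <- stats::median(r)
  s <- mad(r)
  if (s < 1e-12) return(mu)
  for (i in seq_len(max_iter)) {
    w <- pmin(1, k * s / pmax(abs(r - mu), 1e-300))
    mu_new <- sum(w * r) / sum(w)
    if (abs(mu_new - mu) < tol) return(mu_new)
    mu <- mu_new
  }
  mu
}

# Robust symmetric line fit (reweighted standardized major axis).  Both
# condition log-means carry comparable sampling noise, so the plain y-on-x
# Huber regression is attenuated toward zero (regression dilution); the
# symmetric slope sqrt(b_yx / b_xy) is consistent under equal error
# variances.  The reverse-direction slope is computed under the forward
# fit's final Huber weights, so gross y-outliers — which would act as
# leverage points in the reverse regression — stay downweighted in both
# directions.  With a noiseless predictor the fit reduces to the forward
# Huber IRLS estimate.
robust_line <- function(x, y, k = 1.345, tol = 1e-8, max_iter = 50) {
  f1 <- huber_irls(x, y, k, tol, max_iter)
  w <- f1$weights
  sw <- sum(w)
  xm <- sum(w * x) / sw; ym <- sum(w * y) / sw
  vy <- sum(w * (y - ym)^2)
  b2 <- if (vy > 0) sum(w * (y - ym) * (x - xm)) / vy else NA_real_
  slope <- if (is.finite(b2) && abs(b2) > 1e-12 &&
               sign(f1$slope) == sign(b2)) {
    sign(f1$slope) * sqrt(abs(f1$slope / b2))
  } else {
    f1$slope
  }
  intercept <- huber_location(y - slope * x, k, tol, max_iter)
  list(intercept = intercept, slope = slope,
       iterations = f1$iterations, converged = f1$converged,
       scale = f1$scale)
}

# Per-transcript, per-condition position x replicate matrix of reactivities.
# Returns list(A = matrix, B = matrix, reps_A, reps_B) on the full 1..n grid.
reactivity_matrices <- function(tx_data, n, conditions) {
  build <- function(cond) {
    sub <- filter(tx_data, .data$condition == cond)
    reps <- sort(unique(sub$replicate))
    m <- matrix(NA_real_, nrow = n, ncol = length(reps),
                dimnames = list(NULL, reps))
    m[cbind(sub$position, match(sub$replicate, reps))] <- sub$reactivity
    m
  }
  list(A = build(conditions[1]), B = build(conditions[2]))
}

matrices_to_long <- function(tx, mats, conditions) {
  one <- function(m, cond) {
    tibble(transcript_id = tx,
           position = rep(seq_len(nrow(m)), ncol(m)),
           condition = cond,
           replicate = rep(colnames(m), each = nrow(m)),
           reactivity = as.vector(m))
  }
  bind_rows(one(mats$A, conditions[1]), one(mats$B, conditions[2]))
}

#' Select a structurally invariant pivot set
#'
#' Determines, per transcript, the set of positions used to anchor
#' between-condition normalization.  An iterative screen is used: positional
#' Wilcoxon p-values are computed on the current data, positions with
#' p < `screen_p` are removed, the between-condition log-linear model is
#' refitted on the remainder and condition B re-transformed, and the screen
#' repeats until the set stabilizes or `max_iter` iterations.  The input is
#' expected to already be winsorized/rescaled and quantile normalized.
#'
#' @param data Reactivity tibble after the within-condition steps.
#' @param screen_p Positions with positional p-value below this loose
#'   threshold are excluded from the pivot (default 0.25).
#' @param max_iter Maximum screen/refit rounds (default 5).
#' @param radius Window radius for the positional test (default 2 nt).
#' @param reference Condition treated as reference (default: first sorted).
#' @return Tibble `transcript_id`, `position` of pivot positions.
#' @export
select_pivot_set <- function(data, screen_p = 0.25, max_iter = 5, radius = 2,
                             reference = NULL) {
  validate_reactivity(data)
  lens <- transcript_lengths(data)
  conds <- condition_pair(data, reference)
  out <- purrr::map(split(data, data$transcript_id), function(tx_data) {
    tx <- tx_data$transcript_id[1]
    n <- lens$length[lens$transcript_id == tx]
    mats <- reactivity_matrices(tx_data, n, conds)
    pivot <- pivot_screen(mats$A, mats$B, screen_p, max_iter, radius)
    tibble(transcript_id = tx, position = pivot)
  }) %>% bind_rows()
  if (!nrow(out)) {
    abort("pivot screening removed all positions; supply a pivot set explicitly",
          class = "svrscan_pivot_error")
  }
  out
}

pivot_screen <- function(A, B, screen_p, max_iter, radius) {
  n <- nrow(A)
  B_cur <- B
  pivot <- integer(0)
  for (it in seq_len(max_iter)) {
    p <- positional_pvalue_vec(A, B_cur, radius = radius)
    new_pivot <- which(!is.na(p) & p >= screen_p)
    if (identical(new_pivot, pivot) && it > 1) break
    pivot <- new_pivot
    if (!length(pivot)) break
    fit <- try(fit_loglinear(A, B, pivot), silent = TRUE)
    if (inherits(fit, "try-error")) break
    B_cur <- transform_B(B, fit$log_alpha, fit$beta)
  }
  pivot
}

# Fit log mean(A) ~ log alpha + beta log mean(B) over the pivot positions,
# dropping positions whose condition mean is at or below the positivity floor.
fit_loglinear <- function(A, B, pivot, floor = 1e-3) {
  mA <- rowMeans(A, na.rm = TRUE)[pivot]
  mB <- rowMeans(B, na.rm = TRUE)[pivot]
  ok <- is.finite(mA) & is.finite(mB) & mA > floor & mB > floor
  if (sum(ok) < 3) {
    abort("fewer than 3 usable pivot positions for the between-condition fit",
          class = "svrscan_fit_error")
  }
  fit <- robust_line(log(mB[ok]), log(mA[ok]))
  list(log_alpha = fit$intercept, beta = fit$slope,
       n_pivot_used = sum(ok), iterations = fit$iterations,
       converged = fit$converged, scale = fit$scale)
}

# Extrapolate the fitted transform to all positions.  Values at or below the
# positivity floor pass through unchanged: they sit outside the log-linear
# fit's support and carry no signal either way.
transform_B <- function(B, log_alpha, beta, floor = 1e-3) {
  out <- B
  idx <- which(!is.na(B) & B > floor)
  out[idx] <- exp(log_alpha + beta * log(B[idx]))
  out
}

#' Fit the between-condition log-linear normalization model
#'
#' Regresses the log of the position-wise mean reactivity in the reference
#' condition on the log mean in the other condition over the pivot
#' positions, with Huber's M-estimate fitted by iteratively reweighted least
#' squares (tuning constant 1.345 robust-scale units, MAD residual scale).
#' The intercept (`log_alpha`) absorbs sequencing-depth differences and the
#' slope (`beta`) signal-to-noise differences.
#'
#' @inheritParams select_pivot_set
#' @param pivot Tibble `transcript_id`, `position` of assumed structurally
#'   invariant positions.
#' @return Tibble with one row per transcript: `transcript_id`, `log_alpha`,
#'   `beta`, `n_pivot`, `n_pivot_used`, `iterations`, `converged`, `scale`.
#' @export
fit_between_condition_model <- function(data, pivot, reference = NULL) {
  validate_reactivity(data)
  lens <- transcript_lengths(data)
  conds <- condition_pair(data, reference)
  purrr::map(split(data, data$transcript_id), function(tx_data) {
    tx <- tx_data$transcript_id[1]
    n <- lens$length[lens$transcript_id == tx]
    piv <- pivot$position[pivot$transcript_id == tx]
    if (!length(piv)) {
      abort(sprintf("no pivot positions supplied for transcript %s", tx),
            class = "svrscan_fit_error")
    }
    mats <- reactivity_matrices(tx_data, n, conds)
    fit <- fit_loglinear(mats$A, mats$B, piv)
    tibble(transcript_id = tx, log_alpha = fit$log_alpha, beta = fit$beta,
           n_pivot = length(piv), n_pivot_used = fit$n_pivot_used,
           iterations = fit$iterations, converged = fit$converged,
           scale = fit$scale)
  }) %>% bind_rows()
}

condition_pair <- function(data, reference = NULL) {
  conds <- sort(unique(data$condition))
  if (length(conds) != 2) {
    abort(sprintf("expected exactly 2 conditions, found %d", length(conds)),
          class = "svrscan_validation_error")
  }
  if (!is.null(reference)) {
    if (!reference %in% conds) {
      abort(sprintf("reference condition '%s' not present", reference),
            class = "svrscan_validation_error")
    }
    conds <- c(reference, setdiff(conds, reference))
  }
  conds
}

#' Normalize a two-condition reactivity dataset
#'
#' Runs the full normalization pipeline per transcript: (1) 90%
#' winsorization and rescaling onto \[0, 1\] per replicate; (2) quantile
#' normalization of within-condition replicates; (3) between-condition
#' anchoring — a structurally invariant pivot set is selected (or supplied),
#' a robust log-linear transform is fitted on it, and the transform is
#' extrapolated to every position of the non-reference condition.  The
#' reference condition passes through steps 1–2 unchanged.
#'
#' @inheritParams select_pivot_set
#' @param pivot Optional pivot tibble (`transcript_id`, `position`); when
#'   `NULL` the iterative screen of [select_pivot_set()] is used.
#' @param lower_pct,upper_pct Winsorization percentiles (defaults 5, 95).
#' @return An object of class `reactivity_norm`: a list with `data` (the
#'   normalized reactivity tibble), `model` (per-transcript fit
#'   coefficients), `pivot`, `reference`, and the parameters used.
#' @examples
#' sim <- simulate_reactivity(lengths = 80, signal = "medium",
#'                            n_reps = 2, seed = 1)
#' norm <- normalize_reactivity(sim$data)
#' tidy(norm)
#' @export
normalize_reactivity <- function(data, pivot = NULL, reference = NULL,
                                 screen_p = 0.25, max_iter = 5, radius = 2,
                                 lower_pct = 5, upper_pct = 95) {
  validate_reactivity(data)
  lens <- transcript_lengths(data)
  conds <- condition_pair(data, reference)

  pieces <- purrr::map(split(data, data$transcript_id), function(tx_data) {
    tx <- tx_data$transcript_id[1]
    n <- lens$length[lens$transcript_id == tx]
    mats <- reactivity_matrices(tx_data, n, conds)

    # Step 1: winsorize + rescale each replicate separately
    for (nm in c("A", "B")) {
      m <- mats[[nm]]
      keep <- colSums(!is.na(m)) > 0
      m[, keep] <- apply(m[, keep, drop = FALSE], 2, winsorize_rescale,
                         lower_pct = lower_pct, upper_pct = upper_pct)
      mats[[nm]] <- m
    }
    # Step 2: within-condition quantile normalization
    mats$A <- quantile_normalize(mats$A)
    mats$B <- quantile_normalize(mats$B)

    # Step 3: pivot + robust log-linear between-condition transform
    if (is.null(pivot)) {
      piv <- pivot_screen(mats$A, mats$B, screen_p, max_iter, radius)
      if (!length(piv)) {
        abort(sprintf(
          "pivot screening removed all positions of transcript %s; supply a pivot set",
          tx), class = "svrscan_pivot_error")
      }
    } else {
      piv <- pivot$position[pivot$transcript_id == tx]
    }
    fit <- fit_loglinear(mats$A, mats$B, piv)
    mats$B <- transform_B(mats$B, fit$log_alpha, fit$beta)

    list(data = matrices_to_long(tx, mats, conds),
         model = tibble(transcript_id = tx, log_alpha = fit$log_alpha,
                        beta = fit$beta, n_pivot = length(piv),
                        n_pivot_used = fit$n_pivot_used,
                        iterations = fit$iterations,
                        converged = fit$converged, scale = fit$scale),
         pivot = tibble(transcript_id = tx, position = piv))
  })

  norm_data <- bind_rows(purrr::map(pieces, "data"))
  attr(norm_data, "transcript_lengths") <- lens
  structure(list(
    data = norm_data,
    model = bind_rows(purrr::map(pieces, "model")),
    pivot = bind_rows(purrr::map(pieces, "pivot")),
    reference = conds[1],
    conditions = conds,
    params = list(screen_p = screen_p, max_iter = max_iter, radius = radius,
                  lower_pct = lower_pct, upper_pct = upper_pct,
                  pivot_supplied = !is.null(pivot))
  ), class = "reactivity_norm")
}

#' @export
print.reactivity_norm <- function(x, ...) {
  cat("Normalized reactivity dataset\n")
  cat(sprintf("  transcripts: %d   reference condition: %s\n",
              nrow(x$model), x$reference))
  cat(sprintf("  median log_alpha: %.4f   median beta: %.4f\n",
              stats::median(x$model$log_alpha), stats::median(x$model$beta)))
  invisible(x)
}

#' @rdname normalize_reactivity
#' @param x A `reactivity_norm` object.
#' @param ... Unused.
#' @export
tidy.reactivity_norm <- function(x, ...) x$model

#' @rdname normalize_reactivity
#' @export
glance.reactivity_norm <- function(x, ...) {
  tibble(n_transcripts = nrow(x$model),
         median_log_alpha = stats::median(x$model$log_alpha),
         median_beta = stats::median(x$model$beta),
         all_converged = all(x$model$converged),
         reference = x$reference)
}

#' @rdname normalize_reactivity
#' @param object A `reactivity_norm` object.
#' @export
autoplot.reactivity_norm <- function(object, ...) {
  conds <- object$conditions
  means <- object$data %>%
    group_by(.data$transcript_id, .data$position, .data$condition) %>%
    summarise(mean_r = mean(.data$reactivity, na.rm = TRUE), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_r") %>%
    left_join(mutate(object$pivot, pivot = TRUE),
              by = c("transcript_id", "position")) %>%
    mutate(pivot = !is.na(.data$pivot))
  ggplot2::ggplot(means, ggplot2::aes(x = .data[[conds[2]]],
                                      y = .data[[conds[1]]],
                                      colour = .data$pivot)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~transcript_id) +
    ggplot2::labs(x = paste("mean normalized reactivity,", conds[2]),
                  y = paste("mean normalized reactivity,", conds[1]),
                  colour = "pivot") +
    ggplot2::theme_minimal()
}
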