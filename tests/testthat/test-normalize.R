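test_that("winsorize-rescale matches a sort-based percentile oracle", {
  oracle <- function(x, lo = 0.05, hi = 0.95) {
    q <- quantile(x, c(lo, hi), type = 7, names = FALSE)
    y <- pmin(pmax(x, q[1]), q[2])
    (y - min(y)) / (max(y) - min(y))
  }
  x <- as.numeric(1:100)
  expect_equal(winsorize_rescale(x), oracle(x))
  expect_equal(min(winsorize_rescale(x)), 0)
  expect_equal(max(winsorize_rescale(x)), 1)
  set.seed(11)
  for (i in 1:5) {
    x <- rgamma(50, 1, 1)
    expect_equal(winsorize_rescale(x), oracle(x))
  }
})

test_that("winsorize-rescale is monotone, bounded, and handles degenerate input", {
  set.seed(3)
  x <- rnorm(80)
  y <- winsorize_rescale(x)
  expect_true(all(y >= 0 & y <= 1))
  ord <- order(x)
  expect_true(all(diff(y[ord]) >= 0))  # order-preserving up to ties
  expect_equal(winsorize_rescale(rep(2.5, 10)), rep(0, 10))
  x_na <- c(0.5, NA, 1.5)
  expect_true(is.na(winsorize_rescale(x_na)[2]))
  expect_error(winsorize_rescale(c(NA_real_, NA_real_)),
               class = "svrscan_validation_error")
})

test_that("quantile normalization matches the hand-computed order-statistic means", {
  m <- cbind(c(0, 2, 4), c(1, 3, 5))
  out <- quantile_normalize(m)
  expect_equal(out[, 1], c(0.5, 2.5, 4.5))
  expect_equal(out[, 2], c(0.5, 2.5, 4.5))
  # identical value multisets are a fixed point
  m2 <- cbind(c(1, 2, 3), c(3, 1, 2))
  expect_equal(quantile_normalize(m2), m2)
  # single replicate is the identity
  expect_equal(quantile_normalize(cbind(c(5, 1, 3))), cbind(c(5, 1, 3)))
})

test_that("quantile normalization agrees with limma on complete data", {
  skip_if_not_installed("limma")
  set.seed(21)
  for (i in 1:3) {
    m <- matrix(rgamma(300, 1), ncol = 3)
    expect_equal(unname(quantile_normalize(m)),
                 unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
  }
})

test_that("quantile normalization equalizes distributions and restores missingness", {
  set.seed(5)
  m <- matrix(runif(200), ncol = 2)
  m[sample(200, 30)] <- NA
  out <- quantile_normalize(m)
  expect_equal(is.na(out), is.na(m))
  # ranks preserved within each replicate
  for (i in 1:2) {
    obs <- !is.na(m[, i])
    expect_equal(rank(out[obs, i]), rank(m[obs, i]))
  }
  # with equal counts the sorted multisets coincide exactly
  me <- matrix(rnorm(120), ncol = 2)
  oute <- quantile_normalize(me)
  expect_equal(sort(oute[, 1]), sort(oute[, 2]))
})

test_that("the robust log-linear fit recovers exact and noiseless parameters", {
  df_id <- make_identical_conditions(n = 80, n_reps = 2, seed = 2)
  pivot <- tibble::tibble(transcript_id = "tx1", position = 1:80)
  fit <- fit_between_condition_model(df_id, pivot)
  expect_equal(fit$log_alpha, 0, tolerance = 1e-6)
  expect_equal(fit$beta, 1, tolerance = 1e-6)

  set.seed(9)
  rB <- runif(100, 0.05, 1)
  rA <- exp(0.3 + 0.8 * log(rB))
  df <- make_react_tbl(list(A = list(r1 = rA), B = list(r1 = rB)))
  fit2 <- fit_between_condition_model(
    df, tibble::tibble(transcript_id = "tx1", position = 1:100))
  expect_equal(fit2$log_alpha, 0.3, tolerance = 1e-4)
  expect_equal(fit2$beta, 0.8, tolerance = 1e-4)

  expect_error(fit_between_condition_model(
    df, tibble::tibble(transcript_id = "tx1", position = 1:2)),
    class = "svrscan_fit_error")
})

test_that("the Huber IRLS fit agrees with MASS::rlm on noisy data", {
  skip_if_not_installed("MASS")
  set.seed(13)
  x <- runif(150, -1, 1)
  y <- 0.2 + 0.9 * x + rnorm(150, 0, 0.1)
  y[1:10] <- y[1:10] + 3
  mine <- svrscan:::huber_irls(x, y)
  ref <- MASS::rlm(y ~ x, k = 1.345, maxit = 50)
  expect_equal(mine$intercept, unname(coef(ref)[1]), tolerance = 5e-3)
  expect_equal(mine$slope, unname(coef(ref)[2]), tolerance = 5e-3)
  expect_true(mine$converged)
})

test_that("Huber fit recovers parameters across seeded simulations, robust to pivot contamination", {
  set.seed(31)
  n_sims <- 20
  err <- matrix(NA_real_, n_sims, 2)
  beta_shift <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    la <- runif(1, -0.5, 0.5); be <- runif(1, 0.5, 1.5)
    x <- log(runif(200, 0.05, 1))
    y <- la + be * x + rnorm(200, 0, 0.05)
    fit <- svrscan:::huber_irls(x, y)
    err[s, ] <- abs(c(fit$intercept - la, fit$slope - be))
    # contaminate 20% of the pivot with differential (shifted) positions
    y2 <- y
    idx <- sample(200, 40)
    y2[idx] <- y2[idx] + 0.5
    fit2 <- svrscan:::huber_irls(x, y2)
    beta_shift[s] <- abs(fit2$slope - fit$slope)
  }
  expect_lt(mean(err[, 1]), 0.05)
  expect_lt(mean(err[, 2]), 0.05)
  expect_true(all(beta_shift < 0.1))
})

test_that("pivot screening keeps invariant positions and excludes a shifted block", {
  df <- make_identical_conditions(n = 60, n_reps = 2, seed = 4)
  piv <- select_pivot_set(df)
  # identical conditions: every testable position is structurally invariant
  expect_equal(piv$position, 1:60)

  excl <- numeric(5)
  for (s in 1:5) {
    set.seed(100 + s)
    base <- lapply(1:2, function(i) runif(100, 0.2, 0.6))
    shifted <- lapply(base, function(v) {
      w <- v + rnorm(100, 0, 0.02)
      w[10:20] <- w[10:20] + 0.35
      pmin(w, 1)
    })
    names(base) <- names(shifted) <- c("r1", "r2")
    df2 <- make_react_tbl(list(A = base, B = shifted))
    piv2 <- select_pivot_set(df2)
    excl[s] <- mean(!(10:20) %in% piv2$position)
  }
  expect_gte(mean(excl), 0.8)
})

test_that("a supplied pivot set bypasses screening verbatim", {
  df <- make_identical_conditions(n = 40, n_reps = 2, seed = 6)
  pivot <- tibble::tibble(transcript_id = "tx1", position = 5:25)
  norm <- normalize_reactivity(df, pivot = pivot)
  expect_equal(norm$pivot$position, 5:25)
  expect_equal(norm$model$n_pivot, 21L)
})

test_that("normalizing identical conditions is a no-op between conditions", {
  df <- make_identical_conditions(n = 70, n_reps = 2, seed = 8)
  norm <- normalize_reactivity(df)
  wide <- tidyr::pivot_wider(norm$data,
                             names_from = "condition",
                             values_from = "reactivity")
  expect_true(all(abs(wide$A - wide$B) < 1e-6))
  # step-1 contract: everything in [0, 1] for the reference condition
  a_vals <- norm$data$reactivity[norm$data$condition == "A"]
  expect_true(all(a_vals >= 0 & a_vals <= 1))
})

test_that("normalization removes a known depth/power distortion", {
  meds <- numeric(3)
  for (s in 1:3) {
    set.seed(40 + s)
    n <- 200
    a1 <- runif(n, 0.05, 1); a2 <- a1 + rnorm(n, 0, 0.02)
    # B = depth-scaled, power-distorted copy of A (alpha, beta known)
    distort <- function(v) exp(-0.3 + 1.2 * log(pmax(v, 1e-6)))
    df <- make_react_tbl(list(A = list(r1 = a1, r2 = a2),
                              B = list(r1 = distort(a1),
                                       r2 = distort(a2))))
    # invariant 90%: positions 1..180; inject differences elsewhere
    df$reactivity[df$condition == "B" & df$position > 180] <-
      df$reactivity[df$condition == "B" & df$position > 180] + 0.4
    norm <- normalize_reactivity(df)
    wide <- tidyr::pivot_wider(
      dplyr::summarise(dplyr::group_by(norm$data, position, condition),
                       r = mean(reactivity), .groups = "drop"),
      names_from = "condition", values_from = "r")
    inv <- wide$position <= 180
    meds[s] <- median(abs(wide$A[inv] - wide$B[inv]))
  }
  expect_lt(max(meds), 0.02)
})

test_that("single-replicate conditions pass through the pipeline", {
  set.seed(15)
  v <- runif(50, 0.1, 0.9)
  df <- make_react_tbl(list(A = list(r1 = v),
                            B = list(r1 = v + rnorm(50, 0, 0.01))))
  norm <- normalize_reactivity(df)
  expect_s3_class(norm, "reactivity_norm")
  expect_equal(nrow(norm$model), 1)
})

test_that("normalization is invariant to replicate relabeling and consistent position permutation", {
  df <- make_identical_conditions(n = 50, n_reps = 2, seed = 17)
  df$reactivity[df$condition == "B"] <-
    df$reactivity[df$condition == "B"] * 1.3
  norm1 <- normalize_reactivity(df)

  relab <- dplyr::mutate(df, replicate = paste0("other_", replicate))
  norm2 <- normalize_reactivity(relab)
  expect_equal(norm1$data$reactivity, norm2$data$reactivity)

  set.seed(18)
  perm <- sample(50)
  permuted <- dplyr::mutate(df, position = perm[position])
  norm3 <- normalize_reactivity(permuted)
  key1 <- dplyr::arrange(dplyr::mutate(norm1$data, position = perm[position]),
                         condition, replicate, position)
  key3 <- dplyr::arrange(norm3$data, condition, replicate, position)
  expect_equal(key1$reactivity, key3$reactivity, tolerance = 1e-10)
})

test_that("tidy and glance summarize the fitted normalization", {
  df <- make_identical_conditions(n = 40, n_reps = 2, seed = 20)
  norm <- normalize_reactivity(df)
  td <- tidy(norm)
  expect_true(all(c("transcript_id", "log_alpha", "beta") %in% names(td)))
  gl <- glance(norm)
  expect_equal(gl$n_transcripts, 1L)
  expect_true(gl$all_converged)
  expect_s3_class(autoplot(norm), "ggplot")
})
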