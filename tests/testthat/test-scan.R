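test_that("rank-sum p-values match stats::wilcox.test across regimes", {
  set.seed(2)
  for (i in 1:30) {
    m <- sample(3:15, 1); k <- sample(3:15, 1)
    x <- rnorm(m); y <- rnorm(k, mean = runif(1, -1, 1))
    if (i %% 3 == 0) { # induce ties
      x <- round(x, 1); y <- round(y, 1)
    }
    use_exact <- m <= 10 && k <= 10 && !anyDuplicated(c(x, y))
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                               exact = use_exact))$p.value
    expect_equal(svrscan:::rank_sum_p(x, y), ref, tolerance = 1e-12)
  }
})

test_that("fully separated small samples give the exact enumeration p-value", {
  # all C(10,5) rank assignments: the two extreme orderings out of 252
  expect_equal(svrscan:::rank_sum_p(1:5, 6:10), 2 / 252)
  expect_equal(svrscan:::rank_sum_p(6:10, 1:5), 2 / 252)
  expect_equal(svrscan:::rank_sum_p(c(1, 2, 3), c(1, 2, 3)), 1)
})

test_that("windows are truncated at transcript ends", {
  set.seed(23)
  a <- list(r1 = runif(10)); b <- list(r1 = runif(10))
  df <- make_react_tbl(list(A = a, B = b))
  pv <- positional_pvalues(df, radius = 2, min_obs = 1)
  manual <- svrscan:::rank_sum_p(a$r1[1:3], b$r1[1:3])
  expect_equal(pv$p[1], manual)
  manual_end <- svrscan:::rank_sum_p(a$r1[8:10], b$r1[8:10])
  expect_equal(pv$p[10], manual_end)
})

test_that("positions with too few pooled observations are untestable", {
  a <- list(r1 = c(0.1, NA, NA, NA, 0.5, 0.6, 0.7))
  b <- list(r1 = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8))
  df <- make_react_tbl(list(A = a, B = b))
  pv <- positional_pvalues(df, radius = 1, min_obs = 3)
  expect_true(is.na(pv$p[2]))  # pooled A over positions 1-3 has 1 value
  expect_false(is.na(pv$p[6]))
})

test_that("the scan statistic follows its closed forms and invariances", {
  expect_equal(scan_statistic(c(1, 1, 1)), 0)
  expect_equal(scan_statistic(0.05), 2.9957, tolerance = 1e-4)
  expect_equal(scan_statistic(c(0.01, 0.01)), 6.5127, tolerance = 1e-4)
  set.seed(5)
  p <- runif(12)
  expect_equal(scan_statistic(p), scan_statistic(sample(p)))
  # m copies of p give sqrt(m) * (-log p)
  expect_equal(scan_statistic(rep(0.1, 9)), 3 * -log(0.1))
  # strictly decreasing in each p_j
  p2 <- p; p2[4] <- p2[4] / 2
  expect_gt(scan_statistic(p2), scan_statistic(p))
  expect_error(scan_statistic(numeric(0)), class = "svrscan_validation_error")
  expect_error(scan_statistic(c(0.5, 0)), class = "svrscan_validation_error")
})

test_that("candidate region enumeration counts, skips missing, and clamps", {
  p <- c(0.5, 0.2, 0.8)
  regs <- enumerate_regions(p, l_min = 1, l_max = 3)
  expect_equal(nrow(regs), 6)  # 3 + 2 + 1
  expect_equal(sum(regs$length == 1), 3)

  p_na <- c(0.5, 0.4, NA, 0.2, 0.1)
  regs_na <- enumerate_regions(p_na, l_min = 1, l_max = 5)
  expect_true(all(regs_na$end < 3 | regs_na$start > 3))

  regs_clamp <- enumerate_regions(p, l_min = 1, l_max = 100)
  expect_equal(max(regs_clamp$length), 3)
})

test_that("enumeration plus argmax equals the brute-force double-loop oracle", {
  set.seed(29)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    p <- runif(n)
    if (i %% 4 == 0) p[sample(n, 2)] <- NA
    regs <- enumerate_regions(p, l_min = 1, l_max = n)
    if (!nrow(regs)) next
    best <- regs[which.max(regs$q), ]
    oracle <- brute_max_region(p)
    expect_equal(best$q, oracle$q, tolerance = 1e-12)
    expect_equal(c(best$start, best$end), c(oracle$start, oracle$end))
  }
})

test_that("the Monte-Carlo null is reproducible and matches the single-position closed form", {
  n1 <- simulate_null_distribution(50, 1, 10, B = 200, seed = 42)
  n2 <- simulate_null_distribution(50, 1, 10, B = 200, seed = 42)
  expect_identical(n1$samples, n2$samples)
  expect_error(simulate_null_distribution(50, 1, 10, B = 50, seed = 1),
               class = "svrscan_validation_error")

  # n = 1, L = 1: T_b = -log U, so P(T > -log 0.05) = 0.05
  B <- 4000
  null1 <- simulate_null_distribution(1, 1, 1, B = B, seed = 7)
  frac <- mean(null1$samples > -log(0.05))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / B))
})

test_that("region p-values use the add-one estimator and respect its bounds", {
  null <- simulate_null_distribution(20, 1, 20, B = 200, seed = 3)
  regs <- enumerate_regions(rep(1e-8, 20), 1, 20)
  called <- call_svrs(regs, null, alpha = 0.05, n = 20)
  expect_true(all(called$p_value >= 1 / 201 & called$p_value <= 1))
  # observed Q above every null maximum gets exactly 1/(B+1)
  expect_equal(min(called$p_value), 1 / 201)
  # mismatched null parameters are rejected
  expect_error(call_svrs(regs, null, n = 50),
               class = "svrscan_validation_error")
})

test_that("greedy selection reports the higher-Q region among overlaps", {
  null <- structure(list(samples = rep(1, 100), sorted = rep(1, 100),
                         threshold = 1, n = 30, l_min = 1, l_max = 30,
                         B = 100, alpha = 0.05, seed = 1),
                    class = "scan_null")
  regs <- tibble::tibble(start = c(5L, 8L), end = c(12L, 15L),
                         length = c(8L, 8L), q = c(9, 7))
  called <- call_svrs(regs, null, alpha = 0.05, n = 30)
  expect_equal(nrow(called), 1)
  expect_equal(called$start, 5)
})

test_that("a strong block yields exactly one SVR covering it; pure null yields none", {
  p <- rep(0.5, 100); p[11:20] <- 1e-6
  regs <- enumerate_regions(p, 1, 100)
  null <- simulate_null_distribution(100, 1, 100, B = 500, seed = 11)
  called <- call_svrs(regs, null, alpha = 0.05, n = 100)
  expect_equal(nrow(called), 1)
  expect_gte(length(intersect(called$start:called$end, 11:20)), 8)

  flat <- enumerate_regions(rep(0.5, 100), 1, 100)
  expect_equal(nrow(call_svrs(flat, null, alpha = 0.05, n = 100)), 0)
})

test_that("nucleotide ranking is consistent with calls and falls back to p-values", {
  sim <- simulate_reactivity(lengths = 100, signal = "high", n_reps = 3,
                             seed = 19)
  res <- scan_svrs(normalize_reactivity(sim$data), B = 200, seed = 19)
  pos <- res$positions
  k <- sum(pos$in_svr)
  if (k > 0) {
    topk <- pos$position[pos$rank <= k]
    expect_setequal(topk, pos$position[pos$in_svr])
  }
  # two called SVRs: all positions of the higher-Q one rank first
  if (nrow(res$svrs) >= 2) {
    qs <- dplyr::arrange(res$svrs, dplyr::desc(q))
    r1 <- pos$rank[pos$position %in% qs$start[1]:qs$end[1]]
    r2 <- pos$rank[pos$position %in% qs$start[2]:qs$end[2]]
    expect_lt(max(r1), min(r2))
  }
  # no calls: ranking is ascending positional p
  null_res <- scan_svrs(normalize_reactivity(
    make_identical_conditions(n = 60, n_reps = 2, seed = 21)),
    B = 200, seed = 21)
  expect_equal(nrow(null_res$svrs), 0)
  pp <- null_res$positions
  ord <- pp$position[order(pp$rank)]
  expect_equal(ord, pp$position[order(ifelse(is.na(pp$p), Inf, pp$p),
                                      pp$position)])
})

test_that("the permutation null mode runs and is seed-reproducible", {
  sim <- simulate_reactivity(lengths = 60, signal = "null", n_reps = 3,
                             seed = 23)
  norm <- normalize_reactivity(sim$data)
  r1 <- scan_svrs(norm, B = 100, seed = 5, null_type = "permutation")
  r2 <- scan_svrs(norm, B = 100, seed = 5, null_type = "permutation")
  expect_identical(r1$nulls[[1]]$samples, r2$nulls[[1]]$samples)
  expect_equal(r1$svrs, r2$svrs)
})

test_that("scan results expose tidy, glance, autoplot and TSV output", {
  sim <- simulate_reactivity(lengths = 80, signal = "high", n_reps = 3,
                             seed = 27)
  res <- scan_svrs(normalize_reactivity(sim$data), B = 200, seed = 27)
  expect_equal(tidy(res), res$svrs)
  gl <- glance(res)
  expect_equal(gl$n_svrs, nrow(res$svrs))
  expect_s3_class(autoplot(res), "ggplot")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_svrs(res, path)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)),
               nrow(res$svrs))
})
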