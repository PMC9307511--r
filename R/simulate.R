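# Two-state (paired/unpaired) Markov chain along the sequence: stationary
# 50/50 start, self-transition probability 1 - 1/mean_run, so runs of equal
# pairing status have geometric length with mean mean_run — helix-like
# blocks.
markov_pairing <- function(n, mean_run) {
  stay <- 1 - 1 / max(mean_run, 1)
  s <- integer(n)
  s[1] <- rbinom(1, 1, 0.5)
  if (n > 1) {
    flips <- runif(n - 1) > stay
    s[-1] <- flips
    s <- cumsum(s) %% 2L
  }
  s
}

#' Sample a synthetic conformation ensemble
#'
#' Generates K binary pairing-status vectors standing in for conformations
#' drawn from an RNA's thermodynamic structure ensemble.  Conformation 1 is
#' a two-state Markov chain with mean run length `mean_run` (helix-like
#' blocks); each further conformation copies conformation 1 and resamples
#' geometric-length blocks with probability `p_var` from a fresh chain, so
#' conformations agree over most of the sequence but differ in localized
#' blocks.  With the defaults, conformations 1 and 2 disagree at roughly
#' 20% of positions — those positions are the ground-truth structurally
#' variable regions.
#'
#' @param n Transcript length (>= 10).
#' @param K Number of conformations (default 10).
#' @param mean_run Mean pairing-status run length in nt (default 6).
#' @param p_var Probability that a block is resampled in a non-reference
#'   conformation (default 0.4).
#' @param seed Integer seed.
#' @return An object of class `conformation_ensemble`: list with `status`
#'   (K x n 0/1 matrix), `n`, `K` and the sampler parameters.
#' @export
sample_conformation_ensemble <- function(n, K = 10, mean_run = 6, p_var = 0.4,
                                         seed) {
  stopifnot(n >= 10, K >= 2)
  status <- with_seed(seed, {
    m <- matrix(0L, nrow = K, ncol = n)
    m[1, ] <- markov_pairing(n, mean_run)
    for (c in 2:K) {
      v <- m[1, ]
      # segment into geometric-length blocks; resample a fixed fraction
      # p_var of them (stratified, not Bernoulli, so the disagreement rate
      # between conformations concentrates around p_var / 2)
      starts <- integer(0)
      j <- 1L
      while (j <= n) {
        starts <- c(starts, j)
        j <- j + min(n - j + 1L, 1L + stats::rgeom(1, 1 / max(mean_run, 1)))
      }
      ends <- c(starts[-1] - 1L, n)
      n_blocks <- length(starts)
      # take shuffled blocks until they cover a fraction p_var of positions,
      # so the resampled fraction (hence the ~p_var/2 disagreement rate with
      # conformation 1) is pinned rather than left to Bernoulli variance
      ord <- sample.int(n_blocks)
      covered <- cumsum((ends - starts + 1L)[ord])
      pick <- ord[seq_len(which(covered >= p_var * n)[1])]
      for (b in pick) {
        v[starts[b]:ends[b]] <- markov_pairing(ends[b] - starts[b] + 1L,
                                               mean_run)
      }
      m[c, ] <- v
    }
    m
  })
  structure(list(status = status, n = n, K = K, mean_run = mean_run,
                 p_var = p_var, seed = seed),
            class = "conformation_ensemble")
}

#' Ground-truth SVR intervals of an ensemble
#'
#' The true structurally variable regions are the maximal runs of positions
#' where conformations 1 and 2 — the two that receive nearly all the
#' mixture weight — differ in pairing status.
#'
#' @param ensemble A `conformation_ensemble` (or a K x n 0/1 matrix).
#' @return Tibble `start`, `end` of 1-based inclusive intervals.
#' @export
true_svrs_from_ensemble <- function(ensemble) {
  status <- if (inherits(ensemble, "conformation_ensemble")) {
    ensemble$status
  } else {
    ensemble
  }
  stopifnot(nrow(status) >= 2)
  diff_pos <- status[1, ] != status[2, ]
  runs <- rle(diff_pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  tibble(start = starts[runs$values], end = ends[runs$values])
}

signal_base_weights <- function(signal) {
  switch(signal,
    low    = list(A = c(0.4, 0.5), B = c(0.5, 0.4)),
    medium = list(A = c(0.3, 0.6), B = c(0.6, 0.3)),
    high   = list(A = c(0.0, 0.9), B = c(0.9, 0.0)),
    null   = list(A = c(0.4, 0.5), B = c(0.4, 0.5)),
    abort(sprintf("unknown signal level '%s'", signal),
          class = "svrscan_validation_error")
  )
}

#' Assign conformation mixture weights
#'
#' 90% of the mixture weight goes to conformations 1 and 2 with the
#' condition-specific base split determined by `signal`; the remaining 10%
#' is split uniformly at random over conformations 3..K, shared between
#' conditions.  Each replicate perturbs the first two weights with
#' N(0, `noise_sd`^2) noise; negative components are clipped to 0 and the
#' whole vector renormalized to sum to 1.
#'
#' Signal levels set the base weights of (conformation 1, conformation 2)
#' to (0.4, 0.5) vs (0.5, 0.4) (`"low"`), (0.3, 0.6) vs (0.6, 0.3)
#' (`"medium"`), (0, 0.9) vs (0.9, 0) (`"high"`); `"null"` gives both
#' conditions (0.4, 0.5), i.e. no structural difference.
#'
#' @param K Number of conformations.
#' @param signal `"low"`, `"medium"`, `"high"` or `"null"`.
#' @param n_reps Replicates per condition (scalar, or length-2 for A and B).
#' @param noise_sd Replicate weight noise standard deviation (default 0.1).
#' @param seed Integer seed.
#' @return List with matrices `A` and `B` (replicates x K), rows summing
#'   to 1.
#' @export
assign_weights <- function(K, signal = c("low", "medium", "high", "null"),
                           n_reps, noise_sd = 0.1, seed) {
  signal <- match.arg(signal)
  stopifnot(K >= 2)
  if (length(n_reps) == 1) n_reps <- c(n_reps, n_reps)
  base <- signal_base_weights(signal)
  with_seed(seed, {
    rest <- if (K > 2) {
      u <- runif(K - 2)
      0.1 * u / sum(u)
    } else {
      numeric(0)
    }
    make <- function(w12, m) {
      t(vapply(seq_len(m), function(i) {
        w <- c(pmax(w12 + rnorm(2, 0, noise_sd), 0), rest)
        w / sum(w)
      }, numeric(K)))
    }
    list(A = make(base$A, n_reps[1]), B = make(base$B, n_reps[2]))
  })
}

#' Status-conditional reactivity models
#'
#' Parametric stand-ins for platform-specific reactivity distributions,
#' conditional on pairing status; in every model the unpaired distribution
#' stochastically dominates the paired one (unpaired nucleotides are more
#' reactive).  These are synthetic parameterizations chosen to mimic the
#' qualitative shape of each platform's reactivities, not fits to any
#' published training data:
#' * `"shape"` — Gamma pair on the nonnegative reals: paired
#'   Gamma(shape 0.8, scale 0.1) (mean 0.08), unpaired
#'   Gamma(shape 1.2, scale 0.6) (mean 0.72).
#' * `"icshape"` — zero-inflated Beta pair on \[0, 1\]: paired 0 w.p. 0.4
#'   else Beta(1, 4); unpaired 0 w.p. 0.1 else Beta(2, 2).
#' * `"point"` — degenerate: paired and unpaired are fixed values
#'   (`paired`, `unpaired` arguments); useful for closed-form checks of the
#'   mixture construction.
#'
#' @param platform One of `"shape"`, `"icshape"`, `"point"`.
#' @param paired,unpaired Fixed values for the `"point"` model (defaults
#'   0.1 and 0.9).
#' @return An object of class `reactivity_model` with a vectorized `draw`
#'   function over pairing-status vectors.
#' @export
reactivity_model <- function(platform = c("shape", "icshape", "point"),
                             paired = 0.1, unpaired = 0.9) {
  platform <- match.arg(platform)
  draw <- switch(platform,
    shape = function(status) {
      m <- length(status)
      ifelse(status == 1,
             rgamma(m, shape = 0.8, scale = 0.1),
             rgamma(m, shape = 1.2, scale = 0.6))
    },
    icshape = function(status) {
      m <- length(status)
      zero_p <- ifelse(status == 1, 0.4, 0.1)
      x <- ifelse(status == 1, rbeta(m, 1, 4), rbeta(m, 2, 2))
      x * (runif(m) >= zero_p)
    },
    point = function(status) {
      ifelse(status == 1, paired, unpaired)
    })
  structure(list(platform = platform, draw = draw,
                 params = if (platform == "point") {
                   list(paired = paired, unpaired = unpaired)
                 } else {
                   NULL
                 }),
            class = "reactivity_model")
}

#' Draw status-conditional reactivities
#'
#' @param status Pairing-status vector (1 = paired, 0 = unpaired).
#' @param model A `reactivity_model`.
#' @return Nonnegative reactivity draws, one per element of `status`.
#' @export
draw_reactivity <- function(status, model) {
  stopifnot(inherits(model, "reactivity_model"))
  model$draw(status)
}

#' Simulate a two-condition structure-probing dataset
#'
#' Implements the conformation-mixture generative model: each transcript is
#' given a K-conformation ensemble; each condition mixes the conformations
#' with weights concentrated (90%) on the first two; each replicate
#' perturbs those weights with Gaussian noise; and the observed reactivity
#' at a position is the weighted combination of fresh status-conditional
#' draws, one per conformation.  Positions where conformations 1 and 2
#' differ in pairing status are the ground-truth SVRs.
#'
#' @param n_transcripts Number of transcripts (default 1).
#' @param lengths Transcript length(s): a scalar, a vector of per-transcript
#'   lengths, or a length-2 range `c(min, max)` sampled uniformly when
#'   `n_transcripts > 2` or `sample_lengths = TRUE`.
#' @param signal Signal strength: `"low"`, `"medium"`, `"high"` or
#'   `"null"` (identical base weights in both conditions).
#' @param model A `reactivity_model` (default `reactivity_model("shape")`).
#' @param n_reps Replicates per condition (scalar or length-2).
#' @param K Conformations per transcript (default 10).
#' @param mean_run Mean pairing run length of the sampler (default 6 nt).
#' @param noise_sd Replicate weight noise (default 0.1).
#' @param seed Integer seed; output is fully reproducible given the seed.
#' @param sample_lengths Force uniform sampling from `range(lengths)`.
#' @return An object of class `sp_sim`: list with `data` (long reactivity
#'   tibble), `truth` (tibble `transcript_id`, `start`, `end`),
#'   `ensembles`, `weights` and `params`.
#' @export
simulate_reactivity <- function(n_transcripts = 1, lengths = c(100, 300),
                                signal = c("low", "medium", "high", "null"),
                                model = reactivity_model("shape"),
                                n_reps = 2, K = 10, mean_run = 6,
                                noise_sd = 0.1, seed,
                                sample_lengths = NULL) {
  signal <- match.arg(signal)
  stopifnot(inherits(model, "reactivity_model"))
  if (length(n_reps) == 1) n_reps <- c(n_reps, n_reps)
  sample_lengths <- sample_lengths %||%
    (length(lengths) == 2 && n_transcripts != 2)
  tx_lengths <- if (length(lengths) == n_transcripts && !sample_lengths) {
    as.integer(lengths)
  } else {
    with_seed(stage_seed(seed, "lengths"),
              sample(seq(min(lengths), max(lengths)), n_transcripts,
                     replace = TRUE))
  }
  tx_ids <- sprintf("tx%03d", seq_len(n_transcripts))

  ens_list <- list(); w_list <- list()
  data_list <- list(); truth_list <- list()
  for (t in seq_len(n_transcripts)) {
    n <- tx_lengths[t]
    ens <- sample_conformation_ensemble(
      n, K = K, mean_run = mean_run,
      seed = stage_seed(seed, paste0("ensemble_", t)))
    w <- assign_weights(K, signal, n_reps, noise_sd,
                        seed = stage_seed(seed, paste0("weights_", t)))
    truth <- true_svrs_from_ensemble(ens)
    reacts <- with_seed(stage_seed(seed, paste0("reactivity_", t)), {
      draw_cond <- function(wm, cond) {
        purrr::map(seq_len(nrow(wm)), function(i) {
          # fresh conformation-level draws per replicate and position
          X <- t(vapply(seq_len(K), function(c) model$draw(ens$status[c, ]),
                        numeric(n)))
          tibble(transcript_id = tx_ids[t], position = seq_len(n),
                 condition = cond, replicate = paste0(cond, "_rep", i),
                 reactivity = drop(wm[i, ] %*% X))
        }) %>% bind_rows()
      }
      bind_rows(draw_cond(w$A, "A"), draw_cond(w$B, "B"))
    })
    ens_list[[t]] <- ens; w_list[[t]] <- w
    data_list[[t]] <- reacts
    if (nrow(truth)) truth_list[[t]] <- mutate(truth, transcript_id = tx_ids[t])
  }
  data <- bind_rows(data_list)
  attr(data, "transcript_lengths") <- tibble(transcript_id = tx_ids,
                                             length = tx_lengths)
  truth <- bind_rows(truth_list)
  if (!nrow(truth)) {
    truth <- tibble(transcript_id = character(0), start = integer(0),
                    end = integer(0))
  } else {
    truth <- select(truth, "transcript_id", "start", "end")
  }
  structure(list(data = data, truth = truth,
                 ensembles = setNames(ens_list, tx_ids),
                 weights = setNames(w_list, tx_ids),
                 params = list(n_transcripts = n_transcripts,
                               lengths = tx_lengths, signal = signal,
                               platform = model$platform, n_reps = n_reps,
                               K = K, mean_run = mean_run,
                               noise_sd = noise_sd, seed = seed)),
            class = "sp_sim")
}

#' @export
print.sp_sim <- function(x, ...) {
  cat("Simulated structure-probing dataset\n")
  cat(sprintf("  %d transcript(s), lengths %s; signal = %s, model = %s\n",
              x$params$n_transcripts,
              paste(range(x$params$lengths), collapse = "-"),
              x$params$signal, x$params$platform))
  cat(sprintf("  true SVRs: %d intervals covering %d nt\n", nrow(x$truth),
              if (nrow(x$truth)) sum(x$truth$end - x$truth$start + 1) else 0L))
  invisible(x)
}

#' @rdname simulate_reactivity
#' @param object An `sp_sim` object.
#' @param ... Unused.
#' @export
autoplot.sp_sim <- function(object, ...) {
  means <- object$data %>%
    group_by(.data$transcript_id, .data$position, .data$condition) %>%
    summarise(mean_r = mean(.data$reactivity, na.rm = TRUE), .groups = "drop")
  gg <- ggplot2::ggplot(means, ggplot2::aes(x = .data$position,
                                            y = .data$mean_r,
                                            colour = .data$condition)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~transcript_id, scales = "free") +
    ggplot2::labs(x = "position (nt)", y = "mean reactivity") +
    ggplot2::theme_minimal()
  if (nrow(object$truth)) {
    gg <- gg + ggplot2::geom_rect(
      data = object$truth,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2)
  }
  gg
}

#' Construct a negative-control dataset by replicate splitting
#'
#' Randomly splits the replicates of a single condition into two
#' pseudo-conditions of sizes ceiling(m/2) and floor(m/2).  The two groups
#' are exchangeable, so any SVR called between them is a false positive by
#' construction.
#'
#' @param data Reactivity tibble.
#' @param condition Which condition to split (default: the first present).
#' @param seed Integer seed for the split.
#' @return A reactivity tibble with conditions `"pseudoA"` and `"pseudoB"`.
#' @export
make_negative_control <- function(data, condition = NULL, seed) {
  validate_reactivity(data)
  condition <- condition %||% sort(unique(data$condition))[1]
  sub <- filter(data, .data$condition == !!condition)
  reps <- sort(unique(sub$replicate))
  if (length(reps) < 2) {
    abort("need at least 2 replicates to build a negative control",
          class = "svrscan_validation_error")
  }
  shuffled <- with_seed(seed, sample(reps))
  g1 <- shuffled[seq_len(ceiling(length(reps) / 2))]
  out <- mutate(sub, condition = if_else(.data$replicate %in% g1,
                                         "pseudoA", "pseudoB"))
  attr(out, "transcript_lengths") <- transcript_lengths(data)
  out
}
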