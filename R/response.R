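#' Per-electrode conditional response statistics and preference labels
#'
#' For every electrode and trial, computes the conditional mean evoked count
#' `x_i^u` for each of the four source states `u` in `{(0,0),(1,0),(0,1),
#' (1,1)}` (the maximum-likelihood Poisson mean), the all-trial averages, an
#' availability mask, and a source-preference label.
#'
#' Availability requires the average of the four all-trial conditional means
#' to reach 1 spike/event. Among available electrodes, the label is `G1`
#' (source-1 preferring) when `xbar^{1,0} - xbar^{0,1} >= 0.5` spike/event,
#' `G2` when `<= -0.5`, and `G0` otherwise.
#'
#' @param counts `n_elec x n_trials x n_events` array of evoked counts.
#' @param u `2 x n_events` binary source matrix (the same schedule is
#'   delivered on every trial).
#' @return An object of class `"cond_stats"`: list with
#'   \describe{
#'     \item{x_u}{`n_elec x n_trials x 4` conditional means (`NA` where a
#'       state has no events in a trial; missing cells are excluded from
#'       averages, not zero-filled).}
#'     \item{x_u_bar}{`n_elec x 4` all-trial averages.}
#'     \item{available}{Logical vector.}
#'     \item{label}{Factor with levels `G0`, `G1`, `G2`, `unavailable`.}
#'   }
#' @export
conditional_stats <- function(counts, u) {
  stopifnot(length(dim(counts)) == 3L)
  n_elec <- dim(counts)[1L]
  n_trials <- dim(counts)[2L]
  n_events <- dim(counts)[3L]
  if (!is.matrix(u) || nrow(u) != 2L || ncol(u) != n_events) {
    stop("`u` must be 2 x n_events, aligned with `counts`", call. = FALSE)
  }
  st <- state_index(u)
  x_u <- array(NA_real_, c(n_elec, n_trials, 4L),
               dimnames = list(NULL, NULL, state_labels()))
  for (m in 1:4) {
    idx <- which(st == m)
    if (length(idx) > 0L) {
      x_u[, , m] <- apply(counts[, , idx, drop = FALSE], c(1L, 2L), mean)
    }
  }
  x_u_bar <- apply(x_u, c(1L, 3L), mean, na.rm = TRUE)
  x_u_bar[is.nan(x_u_bar)] <- NA_real_
  avail <- rowMeans(x_u_bar) >= 1
  avail[is.na(avail)] <- FALSE
  diff10 <- x_u_bar[, "u10"] - x_u_bar[, "u01"]
  label <- rep("G0", n_elec)
  label[!is.na(diff10) & diff10 >= 0.5] <- "G1"
  label[!is.na(diff10) & diff10 <= -0.5] <- "G2"
  label[!avail] <- "unavailable"
  structure(
    list(x_u = x_u, x_u_bar = x_u_bar, available = avail,
         label = factor(label, levels = c("G0", "G1", "G2", "unavailable")),
         n_trials = n_trials, n_events = n_events),
    class = "cond_stats"
  )
}

#' @export
print.cond_stats <- function(x, ...) {
  cat("Conditional response statistics\n")
  cat(sprintf("  %d electrodes, %d trials\n", nrow(x$x_u_bar), x$n_trials))
  print(table(x$label))
  invisible(x)
}

#' Kullback-Leibler divergence between two Poisson distributions
#'
#' Closed form `(log l1 - log l2) * l1 - l1 + l2` in nats. Limit conventions:
#' `l1 = 0` gives `l2` (the limit of the closed form); `l1 > 0, l2 = 0` gives
#' `Inf`. Vectorized over both arguments.
#'
#' @param lambda1,lambda2 Non-negative Poisson means.
#' @return KLD in nats (non-negative; 0 iff the means are equal).
#' @export
#' @examples
#' kld_poisson(2, 1)  # 2*log(2) - 1
kld_poisson <- function(lambda1, lambda2) {
  if (any(lambda1 < 0, na.rm = TRUE) || any(lambda2 < 0, na.rm = TRUE)) {
    stop("Poisson means must be non-negative", call. = FALSE)
  }
  out <- ifelse(lambda1 == 0, lambda2,
                (log(lambda1) - log(lambda2)) * lambda1 - lambda1 + lambda2)
  out[lambda1 > 0 & lambda2 == 0] <- Inf
  out
}

#' Per-electrode KLD trajectories across trials
#'
#' Evaluates, for every available electrode and trial, the Poisson KLD between
#' the response distributions conditioned on the two pure source states,
#' `D_KL(x_i^{1,0}(l) || x_i^{0,1}(l))`. Where `x_i^{0,1}` is exactly zero it
#' is floored at one pseudo-count over the whole recording
#' (`1 / (n_events * n_trials)`) so trajectories stay finite while the
#' ordering of divergences is preserved.
#'
#' @param stats A [conditional_stats()] object.
#' @param clip Clipping bound applied by [kld_change()] to
#'   change-from-trial-1 summaries.
#' @return Object of class `"kld_transition"`: list with `D_KL`
#'   (`n_avail x n_trials`, rows named by electrode index), `electrodes`, and
#'   `clip`.
#' @export
kld_transition <- function(stats, clip = 10) {
  stopifnot(inherits(stats, "cond_stats"))
  keep <- which(stats$available)
  floor2 <- 1 / (stats$n_events * stats$n_trials)
  l1 <- stats$x_u[keep, , "u10", drop = FALSE]
  l2 <- stats$x_u[keep, , "u01", drop = FALSE]
  l2 <- pmax(l2, floor2)
  D <- matrix(kld_poisson(l1, l2), nrow = length(keep),
              dimnames = list(keep, NULL))
  structure(list(D_KL = D, electrodes = keep, clip = clip),
            class = "kld_transition")
}

#' Clipped change in KLD from trial 1
#'
#' @param kt A [kld_transition()] object.
#' @return Matrix of `D_KL(l) - D_KL(1)` with values clipped to
#'   `[-clip, clip]`.
#' @export
kld_change <- function(kt) {
  stopifnot(inherits(kt, "kld_transition"))
  delta <- kt$D_KL - kt$D_KL[, 1L]
  pmin(pmax(delta, -kt$clip), kt$clip)
}

#' Fraction of source-coding electrodes
#'
#' An electrode responding only to one channel of group 1 has an expected
#' conditional-mean ratio `xbar^{1,0}/xbar^{0,1}` of exactly
#' `a/(1-a)` (3 under the default mixing balance), so a strictly larger ratio
#' indicates coding of the hidden source rather than of the nearest channel.
#' Computes, among `G1` electrodes, the fraction with `xbar^{1,0} > 3
#' xbar^{0,1}` (and symmetrically for `G2`), both as all-trial averages and
#' per trial.
#'
#' @param stats A [conditional_stats()] object.
#' @param ratio Threshold ratio (default 3).
#' @return List with `fraction_g1`, `fraction_g2` (all-trial; `NA` when the
#'   group is empty) and `per_trial` (matrix `2 x n_trials`).
#' @export
source_coding_fraction <- function(stats, ratio = 3) {
  stopifnot(inherits(stats, "cond_stats"))
  g1 <- stats$label == "G1"
  g2 <- stats$label == "G2"
  frac <- function(num, den, grp) {
    if (!any(grp)) return(NA_real_)
    mean(num[grp] > ratio * den[grp], na.rm = TRUE)
  }
  fraction_g1 <- frac(stats$x_u_bar[, "u10"], stats$x_u_bar[, "u01"], g1)
  fraction_g2 <- frac(stats$x_u_bar[, "u01"], stats$x_u_bar[, "u10"], g2)
  per_trial <- sapply(seq_len(stats$n_trials), function(l) {
    c(frac(stats$x_u[, l, "u10"], stats$x_u[, l, "u01"], g1),
      frac(stats$x_u[, l, "u01"], stats$x_u[, l, "u10"], g2))
  })
  rownames(per_trial) <- c("G1", "G2")
  list(fraction_g1 = fraction_g1, fraction_g2 = fraction_g2,
       per_trial = per_trial)
}

#' State-coding vs error-coding correlation diagnostics
#'
#' Correlates each electrode's evoked-count series (events concatenated over
#' all trials) with the hidden sources and with the population error signals
#' `e_k(t) = x~_k(t) - (sum_t x~_k(t) / sum_t u_k(t)) u_k(t)`. An electrode is
#' state-coding when `corr(x_i, u_1) > 0.4` or `corr(x_i, u_2) > 0.4`, and
#' error-coding when `|corr(x_i, e_1)| > 0.4` or `|corr(x_i, e_2)| > 0.4`.
#'
#' @param counts `n_elec x n_trials x n_events` array.
#' @param u `2 x n_events` binary source matrix.
#' @param population `2 x n_trials x n_events` (or `2 x n_events x n_trials`)
#'   population series from [build_population()]; defaults to group means of
#'   the supplied counts via [conditional_stats()] labels.
#' @param stats Optional precomputed [conditional_stats()] (used when
#'   `population` is `NULL`).
#' @param threshold Correlation threshold (default 0.4).
#' @return Object of class `"coding_diag"`: per-electrode correlation matrix
#'   `corr_u` (`n_elec x 2`), `corr_e`, logical `state_coding` /
#'   `error_coding` (NA where a series has zero variance, with the electrode
#'   flagged in `degenerate`), and the fractions among available electrodes.
#' @export
coding_correlations <- function(counts, u, population = NULL, stats = NULL,
                                threshold = 0.4) {
  n_elec <- dim(counts)[1L]
  n_trials <- dim(counts)[2L]
  n_events <- dim(counts)[3L]
  st_u <- u
  # event series concatenated over trials: electrode x (trials*events)
  xmat <- matrix(aperm(counts, c(1L, 3L, 2L)), nrow = n_elec)
  u_series <- st_u[, rep(seq_len(n_events), times = n_trials), drop = FALSE]

  if (is.null(population)) {
    if (is.null(stats)) stats <- conditional_stats(counts, u)
    pop <- build_population(counts, stats, u = u)
    pop_series <- pop$x_series_flat
  } else {
    pop_series <- matrix(population, nrow = 2L)
  }

  etot <- rowSums(pop_series)
  utot <- rowSums(u_series)
  scale_k <- ifelse(utot > 0, etot / utot, 0)
  e_series <- pop_series - scale_k * u_series

  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  corr_u <- t(apply(xmat, 1L, function(x) {
    c(safe_cor(x, u_series[1L, ]), safe_cor(x, u_series[2L, ]))
  }))
  corr_e <- t(apply(xmat, 1L, function(x) {
    c(safe_cor(x, e_series[1L, ]), safe_cor(x, e_series[2L, ]))
  }))
  colnames(corr_u) <- c("u1", "u2")
  colnames(corr_e) <- c("e1", "e2")
  state_coding <- corr_u[, 1L] > threshold | corr_u[, 2L] > threshold
  error_coding <- abs(corr_e[, 1L]) > threshold | abs(corr_e[, 2L]) > threshold
  degenerate <- apply(xmat, 1L, function(x) stats::sd(x) == 0)
  structure(
    list(corr_u = corr_u, corr_e = corr_e, state_coding = state_coding,
         error_coding = error_coding, degenerate = degenerate,
         fraction_state = mean(state_coding, na.rm = TRUE),
         fraction_error = mean(error_coding, na.rm = TRUE),
         threshold = threshold),
    class = "coding_diag"
  )
}
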