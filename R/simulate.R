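#' Culture simulator configuration
#'
#' Parameters of the synthetic culture's generative model. The two-dimensional
#' population response on each event is `x~(t) = W s~(t) + xi(t)` with
#' Gaussian background noise `xi`; each electrode's expected evoked count is a
#' rectified sum of a spontaneous baseline, a nearest-channel direct term and
#' its group's population component, and counts are Poisson. Between trials,
#' `W` is updated by a state-dependent Hebbian rule with efficacies `beta`.
#'
#' Defaults emulate the trained (TRN) condition: responses of order 1--3
#' spike/event, connectivity of order 1--2 spike/event, and a ground-truth
#' efficacy ratio `beta2/beta1` of 27.1% so that within-group connections
#' strengthen while between-group connections weaken over 100 trials.
#'
#' @param W0 Initial `2 x 2` population connectivity (spike/event).
#' @param beta1 Plasticity efficacy for the single-source states `(1,0)` and
#'   `(0,1)`.
#' @param beta2 Plasticity efficacy for the joint state `(1,1)`. The
#'   efficacy of `(0,0)` is fixed at 0: without activation there is no
#'   activity-dependent plasticity.
#' @param eta Plasticity step scale multiplying the per-trial update.
#' @param noise_cov `2 x 2` symmetric PSD background-noise covariance
#'   ((spike/event)^2).
#' @param baseline Spontaneous rate added to every electrode (spike/event).
#' @param local_gain Direct-response gain from each stimulated electrode's own
#'   channel (electrode i listens to channel i for i <= n_stim); scalar or
#'   length-`n_stim` vector.
#' @param unstim_gain Coupling of non-stimulated electrodes to the mean
#'   population rate.
#' @param d_d,d_s Direct and synaptic response latencies (ms); used only when
#'   synthesizing raw voltage traces.
#' @param apv_mode Logical; if `TRUE` all plasticity efficacies are zeroed
#'   (NMDA-receptor blockade analogue), so `W` stays constant.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(W0 = matrix(c(1.5, 0.25, 0.25, 1.5), 2L, 2L),
                       beta1 = 4e-4, beta2 = 0.271 * beta1, eta = 1,
                       noise_cov = diag(0.1, 2L), baseline = 0.3,
                       local_gain = 1, unstim_gain = 0.25,
                       d_d = 5, d_s = 15, apv_mode = FALSE) {
  if (!is.matrix(W0) || any(dim(W0) != 2L)) stop("`W0` must be 2 x 2", call. = FALSE)
  check_psd(noise_cov, "noise_cov")
  if (baseline < 0) stop("`baseline` must be non-negative", call. = FALSE)
  structure(
    list(W0 = W0, beta1 = beta1, beta2 = beta2, eta = eta,
         noise_cov = noise_cov, baseline = baseline, local_gain = local_gain,
         unstim_gain = unstim_gain, d_d = d_d, d_s = d_s,
         apv_mode = isTRUE(apv_mode)),
    class = "sim_config"
  )
}

# Efficacy per source state, ordered (0,0), (1,0), (0,1), (1,1).
# The (0,0) efficacy is identically zero.
efficacy_vector <- function(config) {
  if (config$apv_mode) rep(0, 4L) else c(0, config$beta1, config$beta1, config$beta2)
}

#' One plasticity step of the state-dependent Hebbian rule
#'
#' Applies `W' = W + eta * sum_u efficacy[u] * z^u`, where `z^u` is the
#' within-trial centered cross-product statistic of the population response
#' and input for source state `u`. The noise term of the plasticity model is
#' not simulated; it is what the efficacy estimators absorb as residual.
#'
#' @param W Current `2 x 2` connectivity.
#' @param z_stats List of four `2 x 2` matrices named `u00`, `u10`, `u01`,
#'   `u11` (the `u00` entry is ignored: its efficacy is fixed at 0).
#' @param efficacies Numeric length-4 vector of efficacies in state order
#'   `(0,0), (1,0), (0,1), (1,1)`; the first entry is forced to 0.
#' @param eta Step scale.
#' @return The updated `2 x 2` connectivity matrix.
#' @export
apply_plasticity <- function(W, z_stats, efficacies, eta = 1) {
  stopifnot(is.matrix(W), all(dim(W) == 2L), length(efficacies) == 4L)
  efficacies[1L] <- 0
  dW <- matrix(0, 2L, 2L)
  for (m in 2:4) {
    if (efficacies[m] != 0) dW <- dW + efficacies[m] * z_stats[[state_labels()[m]]]
  }
  W + eta * dW
}

# Centered cross-product statistics z^u for one trial.
# x_pop: 2 x T population response, s_pop: 2 x T population input,
# st: state index per event. Centering means are within-trial empirical means.
trial_z_stats <- function(x_pop, s_pop, st) {
  xc <- x_pop - rowMeans(x_pop)
  sc <- s_pop - rowMeans(s_pop)
  out <- vector("list", 4L)
  names(out) <- state_labels()
  for (m in 1:4) {
    idx <- which(st == m)
    out[[m]] <- if (length(idx) == 0L) {
      matrix(0, 2L, 2L)          # empty sum: state absent in this trial
    } else {
      tcrossprod(xc[, idx, drop = FALSE], sc[, idx, drop = FALSE])
    }
  }
  out
}

#' Simulate a synthetic culture
#'
#' Runs the generative model forward over all trials: per event the population
#' rate is `x~ = W s~ + xi`; each electrode's expected count is
#' `max(0, baseline + local_gain * s_nearest + group population component)`
#' and the emitted count is Poisson. After each trial's events, `W` is updated
#' by [apply_plasticity()] using that trial's centered statistics, so the
#' connectivity trajectory carries the plasticity ground truth.
#'
#' Electrode groups: electrodes `1..n_stim/2` receive population component
#' `x~_1` (source-1 driven), `n_stim/2+1..n_stim` receive `x~_2`, and
#' electrodes above `n_stim` are unstimulated (`local_gain` 0, coupled to the
#' mean population rate by `unstim_gain`).
#'
#' @param schedule A [stim_schedule()] object.
#' @param config A [sim_config()] object.
#' @param seed Master seed; `noise` and `counts` substreams are derived from
#'   it.
#' @param emit_counts If `FALSE`, skip the electrode-level Poisson stage and
#'   return only the population-level ground truth (faster for parameter
#'   recovery studies).
#' @param active_trials Trials during which stimulation is delivered (default
#'   all). Inactive trials model a resting period: no events, no counts, no
#'   plasticity; the connectivity holds its last value.
#' @return A list of class `"culture_sim"` with elements
#'   \describe{
#'     \item{counts}{`n_elec x n_trials x n_events` integer array (or `NULL`).}
#'     \item{truth}{Ground truth: `W_trajectory` (`2 x 2 x n_trials`, the
#'       connectivity in force during each trial), `x_pop` (`2 x n_events x
#'       n_trials` latent population response), `s_pop` (`2 x n_events`),
#'       `efficacies`, `electrode_group` (1, 2 or 0 for unstimulated), and the
#'       seeds used.}
#'     \item{schedule, config}{The inputs.}
#'   }
#' @export
#' @examples
#' sched <- stim_schedule(stim_params(n_trials = 5, seed = 1))
#' sim <- simulate_culture(sched, sim_config(), seed = 1)
#' dim(sim$counts)
simulate_culture <- function(schedule, config = sim_config(), seed = NULL,
                             emit_counts = TRUE, active_trials = NULL) {
  stopifnot(inherits(schedule, "stim_schedule"), inherits(config, "sim_config"))
  check_psd(config$noise_cov, "noise_cov")
  p <- schedule$params
  Tev <- p$n_events
  L <- p$n_trials
  s_pop <- input_population(schedule)
  st <- state_index(schedule$u)
  eff <- efficacy_vector(config)

  half <- p$n_stim %/% 2L
  group <- c(rep(1L, half), rep(2L, half), rep(0L, p$n_elec - p$n_stim))
  lg <- rep(config$local_gain, length.out = p$n_stim)

  # background-noise Cholesky factor (PSD-safe via eigen for rank-deficient cov)
  ev <- eigen(config$noise_cov, symmetric = TRUE)
  Lchol <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2L)

  W <- config$W0
  W_traj <- array(NA_real_, c(2L, 2L, L))
  x_pop <- array(NA_real_, c(2L, Tev, L))
  counts <- if (emit_counts) array(NA_integer_, c(p$n_elec, L, Tev)) else NULL

  noise_seed <- sub_seed(seed, "noise")
  count_seed <- sub_seed(seed, "counts")

  xi_all <- with_seed(noise_seed, {
    array(stats::rnorm(2L * Tev * L), c(2L, Tev, L))
  })

  # electrode-level expected rates depend on W through x~; draw Poisson per trial
  count_rng <- function(rate_mat) matrix(
    stats::rpois(length(rate_mat), lambda = rate_mat), nrow = nrow(rate_mat)
  )

  do_counts <- function(xt) {
    # xt: 2 x Tev population response of the current trial
    rate <- matrix(config$baseline, p$n_elec, Tev)
    rate[seq_len(p$n_stim), ] <- rate[seq_len(p$n_stim), ] +
      lg * schedule$s + xt[group[seq_len(p$n_stim)], , drop = FALSE]
    if (p$n_elec > p$n_stim) {
      idx <- (p$n_stim + 1L):p$n_elec
      rate[idx, ] <- rate[idx, ] +
        config$unstim_gain * matrix(colMeans(xt), length(idx), Tev, byrow = TRUE)
    }
    pmax(rate, 0)
  }

  active <- active_trials %||% seq_len(L)
  with_seed(count_seed, {
    for (l in seq_len(L)) {
      W_traj[, , l] <- W
      if (!(l %in% active)) next  # resting period: no stimulation, W frozen
      xi <- Lchol %*% xi_all[, , l]
      xt <- W %*% s_pop + xi
      x_pop[, , l] <- xt
      if (emit_counts) counts[, l, ] <- count_rng(do_counts(xt))
      z <- trial_z_stats(xt, s_pop, st)
      W <- apply_plasticity(W, z, eff, eta = config$eta)
    }
  })

  truth <- list(W_trajectory = W_traj, x_pop = x_pop, s_pop = s_pop,
                efficacies = eff, electrode_group = group,
                seeds = list(master = seed, noise = noise_seed,
                             counts = count_seed))
  structure(list(counts = counts, truth = truth, schedule = schedule,
                 config = config),
            class = "culture_sim")
}

#' @export
print.culture_sim <- function(x, ...) {
  p <- x$schedule$params
  cat("Synthetic culture simulation\n")
  cat(sprintf("  %d electrodes, %d trials x %d events\n",
              p$n_elec, p$n_trials, p$n_events))
  cat(sprintf("  plasticity: beta1 = %.3g, beta2 = %.3g%s\n",
              x$config$beta1, x$config$beta2,
              if (x$config$apv_mode) " (APV mode: disabled)" else ""))
  W1 <- x$truth$W_trajectory[, , 1]
  WL <- x$truth$W_trajectory[, , p$n_trials]
  cat(sprintf("  W diag: %.2f -> %.2f; off-diag: %.2f -> %.2f\n",
              mean(diag(W1)), mean(diag(WL)),
              mean(W1[c(2, 3)]), mean(WL[c(2, 3)])))
  invisible(x)
}
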