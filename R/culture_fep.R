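#' Per-culture free-energy analysis
#'
#' Runs the population recognition analysis for one culture: builds the
#' population series from preference-labelled electrodes, then per trial
#' estimates the connectivity `mu_W` and residual covariance, the expected
#' internal energy, the plug-in entropy of the four-component Gaussian
#' recognition density, the free energy `F = <U> - H`, and gamma-norms of
#' `mu_W`.
#'
#' @param counts `n_elec x n_trials x n_events` evoked-count array, or a
#'   `"culture_sim"` object (its counts are used).
#' @param schedule A [stim_schedule()]. Taken from the simulation object when
#'   `counts` is a `"culture_sim"`.
#' @param stats Optional precomputed [conditional_stats()].
#' @param population Optional precomputed `2 x n_events x n_trials` population
#'   response array (bypasses electrode grouping; used for population-level
#'   simulations).
#' @param gammas Gamma-norm exponents to track.
#' @return Object of class `"culture_fep"`: per-trial data frame `trials`
#'   (`W11, W12, W21, W22`, `U_mean`, `H`, `F`, `sigma_det`, one `gnorm_*`
#'   column per exponent, `ok` flag for trials with sparse states), the
#'   `W` array (`2 x 2 x n_trials`), `sigma_xi` array, the population series,
#'   and the inputs' metadata.
#' @export
#' @examples
#' sched <- stim_schedule(stim_params(n_trials = 4, seed = 2))
#' sim <- simulate_culture(sched, sim_config(), seed = 2)
#' fit <- culture_fep(sim)
#' head(fit$trials)
culture_fep <- function(counts, schedule = NULL, stats = NULL,
                        population = NULL, gammas = c(1, 2, 4)) {
  if (inherits(counts, "culture_sim")) {
    schedule <- counts$schedule
    counts <- counts$counts
  }
  if (is.null(schedule)) stop("`schedule` is required", call. = FALSE)
  st <- state_index(schedule$u)
  s_series <- input_population(schedule)

  if (is.null(population)) {
    if (is.null(stats)) stats <- conditional_stats(counts, schedule$u)
    pop <- build_population(counts, stats, schedule = schedule)
    x_series <- pop$x_series
  } else {
    pop <- NULL
    x_series <- population
  }
  L <- dim(x_series)[3L]

  W <- array(NA_real_, c(2L, 2L, L))
  Sx <- array(NA_real_, c(2L, 2L, L))
  cols <- c("trial", "W11", "W12", "W21", "W22", "U_mean", "H", "F",
            "sigma_det", paste0("gnorm_", gammas), "ok")
  tab <- as.data.frame(matrix(NA_real_, L, length(cols)))
  names(tab) <- cols
  tab$trial <- seq_len(L)
  tab$ok <- FALSE

  for (l in seq_len(L)) {
    xt <- x_series[, , l]
    if (anyNA(xt)) next  # trial not recorded (e.g. resting period)
    fit <- estimate_connectivity(xt, s_series, trial = l)
    W[, , l] <- fit$mu_W
    Sx[, , l] <- fit$sigma_xi
    tab[l, c("W11", "W12", "W21", "W22")] <-
      c(fit$mu_W[1, 1], fit$mu_W[1, 2], fit$mu_W[2, 1], fit$mu_W[2, 2])
    sreg <- regularize_cov(fit$sigma_xi)
    U_mean <- expected_energy(sreg)
    gmm <- fit_recognition(xt, st)
    if (isTRUE(gmm$ok)) {
      H <- entropy_plugin(xt, gmm)
      fe <- free_energy(U_mean, H)
      tab[l, c("U_mean", "H", "F")] <- c(fe$U_mean, fe$H, fe$F)
      tab$ok[l] <- TRUE
    } else {
      tab[l, "U_mean"] <- U_mean
    }
    tab[l, "sigma_det"] <- det(fit$sigma_xi)
    for (g in gammas) tab[l, paste0("gnorm_", g)] <- gamma_norm(fit$mu_W, g)
  }

  structure(
    list(trials = tab, W = W, sigma_xi = Sx, population = pop,
         x_series = x_series, s_series = s_series, u = schedule$u,
         stats = stats, gammas = gammas),
    class = "culture_fep"
  )
}

#' @export
print.culture_fep <- function(x, ...) {
  L <- nrow(x$trials)
  cat("Per-culture free-energy analysis\n")
  cat(sprintf("  %d trials%s\n", L,
              if (!is.null(x$population))
                sprintf(" (G1: %d, G2: %d electrodes)",
                        x$population$n_g1, x$population$n_g2) else ""))
  first <- x$trials[1L, ]
  last <- x$trials[L, ]
  cat(sprintf("  W diag  : %.3f -> %.3f\n",
              mean(c(first$W11, first$W22)), mean(c(last$W11, last$W22))))
  cat(sprintf("  W offdiag: %.3f -> %.3f\n",
              mean(c(first$W12, first$W21)), mean(c(last$W12, last$W21))))
  cat(sprintf("  F: %.3f -> %.3f  (<U>: %.3f -> %.3f, H: %.3f -> %.3f)\n",
              first$F, last$F, first$U_mean, last$U_mean, first$H, last$H))
  invisible(x)
}

#' @export
summary.culture_fep <- function(object, ...) {
  tab <- object$trials
  L <- nrow(tab)
  out <- data.frame(
    quantity = c("W11", "W22", "W12", "W21", "U_mean", "H", "F"),
    trial_1 = unlist(tab[1L, c("W11", "W22", "W12", "W21", "U_mean", "H", "F")]),
    trial_last = unlist(tab[L, c("W11", "W22", "W12", "W21", "U_mean", "H", "F")])
  )
  out$change <- out$trial_last - out$trial_1
  rownames(out) <- NULL
  out
}

#' @export
plot.culture_fep <- function(x, which = c("connectivity", "free_energy"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  tab <- x$trials
  old <- graphics::par(mfrow = c(length(which), 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  if ("connectivity" %in% which) {
    graphics::matplot(tab$trial, tab[, c("W11", "W22", "W12", "W21")],
                      type = "l", lty = c(1, 1, 2, 2),
                      col = c("black", "grey30", "grey60", "grey70"),
                      xlab = "trial", ylab = "connection strength (spike/event)",
                      main = "Estimated connectivity")
    graphics::legend("topleft", c("W11", "W22", "W12", "W21"),
                     lty = c(1, 1, 2, 2),
                     col = c("black", "grey30", "grey60", "grey70"), bty = "n")
  }
  if ("free_energy" %in% which) {
    graphics::matplot(tab$trial, tab[, c("U_mean", "H", "F")],
                      type = "l", lty = 1, col = c("grey60", "black", "red"),
                      xlab = "trial", ylab = "nats",
                      main = "Free-energy decomposition")
    graphics::legend("topleft", c("<U>", "H", "F"), lty = 1,
                     col = c("grey60", "black", "red"), bty = "n")
  }
  invisible(x)
}
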