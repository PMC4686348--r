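#' Build the two-dimensional population series
#'
#' Collapses electrode counts to the population response `x~(t) =
#' (mean over G1 electrodes, mean over G2 electrodes)` per event and trial,
#' and the population input `s~(t)` as channel-group means of the schedule.
#' Defined only when both preference groups are non-empty.
#'
#' @param counts `n_elec x n_trials x n_events` array.
#' @param stats A [conditional_stats()] object supplying the `G1`/`G2`
#'   labels (only available electrodes carry labels).
#' @param schedule A [stim_schedule()] (for `s~`), or pass `u` alone when the
#'   input series is not needed.
#' @param u Optional `2 x n_events` source matrix (kept alongside).
#' @return Object of class `"population_series"`: `x_series`
#'   (`2 x n_events x n_trials`), `x_series_flat` (`2 x (n_events*n_trials)`),
#'   `s_series` (`2 x n_events` or `NULL`), `u`, and the group sizes.
#' @export
build_population <- function(counts, stats, schedule = NULL, u = NULL) {
  stopifnot(inherits(stats, "cond_stats"))
  g1 <- which(stats$label == "G1")
  g2 <- which(stats$label == "G2")
  if (length(g1) == 0L || length(g2) == 0L) {
    stop(sprintf(
      "population undefined: preference group %s is empty for this culture",
      if (length(g1) == 0L) "G1" else "G2"), call. = FALSE)
  }
  n_trials <- dim(counts)[2L]
  n_events <- dim(counts)[3L]
  grp_mean <- function(idx) {
    m <- apply(counts[idx, , , drop = FALSE], c(2L, 3L), mean)  # trials x events
    t(m)                                                        # events x trials
  }
  x1 <- grp_mean(g1)
  x2 <- grp_mean(g2)
  x_series <- array(NA_real_, c(2L, n_events, n_trials))
  x_series[1L, , ] <- x1
  x_series[2L, , ] <- x2
  s_series <- if (!is.null(schedule)) input_population(schedule) else NULL
  if (is.null(u) && !is.null(schedule)) u <- schedule$u
  structure(
    list(x_series = x_series,
         x_series_flat = matrix(x_series, nrow = 2L),
         s_series = s_series, u = u,
         n_g1 = length(g1), n_g2 = length(g2),
         g1 = g1, g2 = g2),
    class = "population_series"
  )
}

#' Maximum-likelihood population connectivity for one trial
#'
#' Closed-form estimator `mu_W = (sum_t x~ s~^T)(sum_t s~ s~^T)^{-1}`, the
#' minimizer of the internal action (summed prediction-error energy) of the
#' linear recognition model `x~ = W s~ + xi`. The residual covariance is the
#' pooled second moment of `x~ - mu_W s~` over the trial's events.
#'
#' @param x `2 x T` population response for one trial.
#' @param s `2 x T` population input.
#' @param max_condition Condition-number bound above which the input moment
#'   matrix is declared singular.
#' @param trial Optional trial index used in error messages.
#' @return List with `mu_W` (`2 x 2`), `sigma_xi` (`2 x 2` pooled residual
#'   covariance), and `n` (events used).
#' @export
estimate_connectivity <- function(x, s, max_condition = 1e8, trial = NULL) {
  stopifnot(is.matrix(x), is.matrix(s), nrow(x) == 2L, nrow(s) == 2L,
            ncol(x) == ncol(s))
  Sxs <- tcrossprod(x, s)
  Sss <- tcrossprod(s, s)
  if (!is.finite(kappa(Sss, exact = TRUE)) ||
      kappa(Sss, exact = TRUE) > max_condition) {
    stop(sprintf("input moment matrix is singular or ill-conditioned%s",
                 if (is.null(trial)) "" else sprintf(" at trial %d", trial)),
         call. = FALSE)
  }
  mu_W <- Sxs %*% solve(Sss)
  resid <- x - mu_W %*% s
  sigma_xi <- tcrossprod(resid) / ncol(x)
  list(mu_W = mu_W, sigma_xi = sigma_xi, n = ncol(x))
}

#' Internal energy of one event
#'
#' Prediction-error energy of the Gaussian noise model,
#' `U = 1/2 xi^T Sigma^-1 xi + 1/2 log((2 pi)^N |Sigma|)` with
#' `xi = x~ - W s~` and `N = 2`.
#'
#' @param s,x Length-2 input and response vectors for the event.
#' @param W `2 x 2` connectivity.
#' @param sigma_xi `2 x 2` positive-definite noise covariance.
#' @return Energy in nats.
#' @export
internal_energy <- function(s, x, W, sigma_xi) {
  d <- det(sigma_xi)
  if (!is.finite(d) || d <= 0) stop("`sigma_xi` must be positive definite", call. = FALSE)
  xi <- as.numeric(x - W %*% s)
  0.5 * sum(xi * solve(sigma_xi, xi)) + 0.5 * log((2 * pi)^2 * d)
}

#' Expected internal energy under the recognition density
#'
#' Closed form of the Gaussian expectation of the event energy:
#' `<U> = 1 + log(2 pi) + 1/2 log |Sigma_xi|` (nats).
#'
#' @param sigma_xi `2 x 2` positive-definite residual covariance.
#' @return Expected energy in nats.
#' @export
expected_energy <- function(sigma_xi) {
  d <- det(sigma_xi)
  if (!is.finite(d) || d <= 0) stop("`sigma_xi` must be positive definite", call. = FALSE)
  1 + log(2 * pi) + 0.5 * log(d)
}

#' Four-component Gaussian recognition density for one trial
#'
#' The recognition density of the population response is a Gaussian mixture
#' with one component per source state and equal weights 1/4. Components are
#' labelled by the known state sequence (no EM): each component's mean and
#' covariance are the conditional sample moments of `x~` over the trial's
#' events in that state.
#'
#' @param x `2 x T` population response for one trial.
#' @param st Integer state index per event (1..4 for states
#'   `(0,0),(1,0),(0,1),(1,1)`).
#' @param min_events Minimum events per state required (default 2).
#' @return Object of class `"gmm_recognition"`: list with `means` (`2 x 4`),
#'   `covs` (`2 x 2 x 4`), `weights` (all 1/4), or an error marker when a
#'   state is too sparse (`ok = FALSE`, `missing_state` set).
#' @export
fit_recognition <- function(x, st, min_events = 2L) {
  stopifnot(is.matrix(x), nrow(x) == 2L, length(st) == ncol(x))
  means <- matrix(NA_real_, 2L, 4L, dimnames = list(NULL, state_labels()))
  covs <- array(NA_real_, c(2L, 2L, 4L), dimnames = list(NULL, NULL, state_labels()))
  for (m in 1:4) {
    idx <- which(st == m)
    if (length(idx) < min_events) {
      return(structure(list(ok = FALSE, missing_state = state_labels()[m]),
                       class = "gmm_recognition"))
    }
    xm <- x[, idx, drop = FALSE]
    means[, m] <- rowMeans(xm)
    xc <- xm - means[, m]
    covs[, , m] <- tcrossprod(xc) / length(idx)  # ML (1/n) moments
  }
  structure(list(ok = TRUE, means = means, covs = covs, weights = rep(1 / 4, 4L)),
            class = "gmm_recognition")
}

# Regularize a component covariance to be safely positive definite.
regularize_cov <- function(S, rel = 1e-9) {
  S + diag(rel * max(sum(diag(S)) / 2, .Machine$double.eps), nrow(S))
}

#' Plug-in entropy of the recognition density
#'
#' Approximates `H[q(x~)] = <-log q(x~)>` by the sample average of
#' `-log q` over the trial's observed population responses. Component
#' covariances are regularized by adding `1e-9 * trace/2` to the diagonal
#' before inversion so that trials with (near-)constant responses remain
#' evaluable.
#'
#' @param x `2 x T` population response the mixture was fitted on.
#' @param gmm A [fit_recognition()] object with `ok = TRUE`.
#' @return Entropy estimate in nats.
#' @export
entropy_plugin <- function(x, gmm) {
  stopifnot(inherits(gmm, "gmm_recognition"))
  if (!isTRUE(gmm$ok)) stop("recognition density was not fitted (sparse state)", call. = FALSE)
  Tn <- ncol(x)
  log_comp <- matrix(NA_real_, 4L, Tn)
  for (m in 1:4) {
    S <- regularize_cov(gmm$covs[, , m])
    d <- det(S)
    if (!is.finite(d) || d <= 0) {
      stop("component covariance not positive definite after regularization",
           call. = FALSE)
    }
    Sinv <- solve(S)
    xc <- x - gmm$means[, m]
    quad <- colSums(xc * (Sinv %*% xc))
    log_comp[m, ] <- -0.5 * quad - log(2 * pi) - 0.5 * log(d)
  }
  # log q = log( 1/4 sum_m N_m ) via log-sum-exp
  mx <- apply(log_comp, 2L, max)
  logq <- mx + log(colSums(exp(sweep(log_comp, 2L, mx)))) + log(1 / 4)
  -mean(logq)
}

#' Free-energy decomposition
#'
#' Assembles `F = <U> - H` (nats); the parameter-entropy term of the full
#' variational bound is constant over trials and omitted.
#'
#' @param U_mean Expected internal energy (nats).
#' @param H Plug-in entropy (nats).
#' @return List with `U_mean`, `H`, and `F` (exact identity `F = U_mean - H`).
#' @export
free_energy <- function(U_mean, H) {
  list(U_mean = U_mean, H = H, F = U_mean - H)
}

#' Gamma-norm of a connectivity matrix
#'
#' `(sum_ij |W_ij|^gamma)^{1/gamma}`, probing constraints on total synaptic
#' strength.
#'
#' @param W Numeric matrix.
#' @param gamma Positive exponent.
#' @return The norm value.
#' @export
#' @examples
#' gamma_norm(diag(2), 2)  # sqrt(2)
gamma_norm <- function(W, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("`gamma` must be a positive scalar", call. = FALSE)
  }
  sum(abs(W)^gamma)^(1 / gamma)
}
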