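#' Centered Hebbian cross-product statistics per trial and source state
#'
#' For each trial `l` and source state `u`, computes the `2 x 2` statistic
#' `z_ij^u(l) = sum_{t: u(t)=u} (x~_i(t) - <x~_i>)(s~_j(t) - <s~_j>)`, the
#' regressor of the plasticity models. Centering means are per-trial
#' empirical means by default (the sums defining `z` run within one trial);
#' all-trial centering is available behind `centering = "all"`. The per-trial
#' connectivity change is taken as the endpoint slope
#' `dW_ij(l) = (W_ij(L) - W_ij(1)) / L` for all `l`, since trial-to-trial
#' differences of `mu_W` are noisy and saturate late in training.
#'
#' @param x_series `2 x n_events x n_trials` population response array (e.g.
#'   `culture_fep()$x_series` or a simulation's `truth$x_pop`).
#' @param s_series `2 x n_events` population input.
#' @param u `2 x n_events` binary source matrix.
#' @param W `2 x 2 x n_trials` connectivity trajectory (typically the
#'   per-trial `mu_W` estimates).
#' @param centering `"trial"` (default) or `"all"`.
#' @return Object of class `"hebb_stats"`: list of arrays `z10`, `z01`, `z11`
#'   (`2 x 2 x n_trials`; a state absent from a trial contributes a zero
#'   matrix), `dW` (`2 x 2`, constant across trials by construction), and
#'   `n_trials`. The `(0,0)` statistic is excluded throughout: its efficacy
#'   is fixed at zero.
#' @export
hebbian_statistics <- function(x_series, s_series, u, W,
                               centering = c("trial", "all")) {
  centering <- match.arg(centering)
  stopifnot(length(dim(x_series)) == 3L, dim(x_series)[1L] == 2L)
  L <- dim(x_series)[3L]
  st <- state_index(u)
  if (!is.null(W)) stopifnot(length(dim(W)) == 3L, dim(W)[3L] == L)

  xbar_all <- if (centering == "all") {
    apply(x_series, 1L, mean, na.rm = TRUE)
  } else NULL
  z <- list(u10 = array(0, c(2L, 2L, L)), u01 = array(0, c(2L, 2L, L)),
            u11 = array(0, c(2L, 2L, L)))
  sc_trial <- s_series - rowMeans(s_series)
  for (l in seq_len(L)) {
    xt <- x_series[, , l]
    if (anyNA(xt)) next  # unrecorded trial contributes empty (zero) sums
    xc <- if (centering == "trial") xt - rowMeans(xt) else xt - xbar_all
    for (m in 2:4) {
      idx <- which(st == m)
      if (length(idx) > 0L) {
        zl <- tcrossprod(xc[, idx, drop = FALSE], sc_trial[, idx, drop = FALSE])
        z[[state_labels()[m]]][, , l] <- zl
      }
    }
  }
  dW <- if (is.null(W)) NULL else (W[, , L] - W[, , 1L]) / L
  structure(list(z10 = z$u10, z01 = z$u01, z11 = z$u11, dW = dW,
                 n_trials = L, centering = centering),
            class = "hebb_stats")
}

#' Fit a plasticity-efficacy model to a connectivity trajectory
#'
#' Estimates learning efficacies from the Hebbian statistics by closed-form
#' least squares on the Gaussian residual model
#' `dW_ij(l) = sum_u efficacy_u z_ij^u(l) + eps`, with the residual variance
#' shared across all matrix entries.
#'
#' Two nested models are available: the plain Hebbian `alpha`-model
#' (one efficacy for all active states, `dW = alpha (z^{10} + z^{01} +
#' z^{11})`) and the state-dependent `beta`-model (`beta1` for the
#' single-source states, which are symmetric, and `beta2` for the joint
#' state). Both fix the `(0,0)` efficacy at zero.
#'
#' @param stats A [hebbian_statistics()] object (with `dW` present), or a
#'   `"culture_fep"` object, in which case the statistics are computed from
#'   its population series and estimated connectivity trajectory.
#' @param model `"beta"` (default) or `"alpha"`.
#' @param dW Optional `2 x 2` connectivity-change matrix overriding
#'   `stats$dW`.
#' @return An object of class `"efficacy_fit"` with components
#'   `coefficients` (named `alpha` or `beta1`, `beta2`), `sigma2` (ML residual
#'   variance), `nll` (negative log-likelihood at the optimum), `bic`,
#'   `n_params` (efficacies + variance), `n_residuals`, `residuals`,
#'   `fitted`, and the model name. Standard methods `print`, `summary`,
#'   `coef`, `logLik`, `BIC`, `residuals`, `fitted` and `predict` apply.
#' @export
#' @examples
#' sched <- stim_schedule(stim_params(n_trials = 20, seed = 3))
#' sim <- simulate_culture(sched, sim_config(), seed = 3, emit_counts = FALSE)
#' hs <- hebbian_statistics(sim$truth$x_pop, sim$truth$s_pop, sched$u,
#'                          sim$truth$W_trajectory)
#' fit_efficacy(hs, model = "beta")
fit_efficacy <- function(stats, model = c("beta", "alpha"), dW = NULL) {
  model <- match.arg(model)
  if (inherits(stats, "culture_fep")) {
    stats <- hebbian_statistics(stats$x_series, stats$s_series, stats$u,
                                stats$W)
  }
  stopifnot(inherits(stats, "hebb_stats"))
  dW <- dW %||% stats$dW
  if (is.null(dW)) stop("a connectivity change `dW` is required", call. = FALSE)
  L <- stats$n_trials

  # flatten to residual vectors: one entry per (trial, i, j)
  y <- rep(as.numeric(dW), times = L)              # constant target
  r1 <- as.numeric(stats$z10 + stats$z01)          # single-source regressor
  r2 <- as.numeric(stats$z11)                      # joint-state regressor
  n <- length(y)

  if (model == "alpha") {
    rs <- r1 + r2
    den <- sum(rs^2)
    if (den == 0) stop("degenerate data: all z statistics are zero", call. = FALSE)
    est <- c(alpha = sum(y * rs) / den)
    fitted <- est[[1L]] * rs
  } else {
    M <- matrix(c(sum(r1^2), sum(r1 * r2), sum(r1 * r2), sum(r2^2)), 2L, 2L)
    if (!is.finite(kappa(M, exact = TRUE)) || kappa(M, exact = TRUE) > 1e12) {
      stop("singular normal matrix: beta-model unidentifiable", call. = FALSE)
    }
    est <- solve(M, c(sum(y * r1), sum(y * r2)))
    names(est) <- c("beta1", "beta2")
    fitted <- est[[1L]] * r1 + est[[2L]] * r2
  }
  resid <- y - fitted
  sigma2 <- mean(resid^2)                          # ML plug-in variance
  nll <- if (sigma2 > 0) n / 2 * (1 + log(2 * pi * sigma2)) else -Inf
  k <- length(est) + 1L                            # efficacies + variance
  structure(
    list(coefficients = est, sigma2 = sigma2, nll = nll,
         bic = model_bic(nll, k, n), n_params = k, n_residuals = n,
         residuals = resid, fitted = fitted, model = model, stats = stats,
         dW = dW),
    class = "efficacy_fit"
  )
}

#' Bayesian information criterion on the residual likelihood
#'
#' Schwarz criterion `BIC = k ln(n) + 2 NLL` with `n` the number of residual
#' entries (trials times the four matrix entries) and `k` the parameter
#' count (efficacies plus the shared residual variance).
#'
#' @param nll Negative log-likelihood at the optimum (or an `"efficacy_fit"`).
#' @param k Number of parameters.
#' @param n Number of residuals.
#' @return The BIC value.
#' @export
model_bic <- function(nll, k = NULL, n = NULL) {
  if (inherits(nll, "efficacy_fit")) return(nll$bic)
  if (n <= k) stop("more parameters than residuals", call. = FALSE)
  k * log(n) + 2 * nll
}

#' Predict the total connectivity change implied by a fitted efficacy model
#'
#' Accumulates the model-implied per-trial updates over the whole training
#' period: `sum_l sum_u efficacy_u z^u(l)` entrywise. Contrasting the two
#' models, a plain Hebbian fit predicts growth of the between-group
#' connections `W12`/`W21`, while a state-dependent fit with `beta2 < beta1`
#' predicts their decline.
#'
#' @param object An `"efficacy_fit"`.
#' @param stats Optional [hebbian_statistics()] to predict for (defaults to
#'   the fitting statistics).
#' @param ... Unused.
#' @return A `2 x 2` matrix of predicted total change in `W`.
#' @export
predict.efficacy_fit <- function(object, stats = NULL, ...) {
  stats <- stats %||% object$stats
  R1 <- apply(stats$z10 + stats$z01, c(1L, 2L), sum)
  R2 <- apply(stats$z11, c(1L, 2L), sum)
  cf <- object$coefficients
  if (object$model == "alpha") cf[[1L]] * (R1 + R2) else cf[[1L]] * R1 + cf[[2L]] * R2
}

#' @export
print.efficacy_fit <- function(x, ...) {
  cat(sprintf("%s-model plasticity-efficacy fit\n",
              if (x$model == "alpha") "Hebbian (alpha)" else
                "state-dependent Hebbian (beta)"))
  print(signif(x$coefficients, 4))
  if (x$model == "beta") {
    cat(sprintf("  efficacy ratio beta2/beta1: %.1f%%\n",
                100 * x$coefficients[["beta2"]] / x$coefficients[["beta1"]]))
  }
  cat(sprintf("  residual sd: %.3g;  BIC: %.2f  (n = %d, k = %d)\n",
              sqrt(x$sigma2), x$bic, x$n_residuals, x$n_params))
  invisible(x)
}

#' @export
summary.efficacy_fit <- function(object, ...) {
  out <- list(model = object$model, coefficients = object$coefficients,
              sigma2 = object$sigma2, nll = object$nll, bic = object$bic,
              n = object$n_residuals, k = object$n_params,
              predicted_dW_total = predict(object))
  class(out) <- "summary.efficacy_fit"
  out
}

#' @export
print.summary.efficacy_fit <- function(x, ...) {
  cat(sprintf("Plasticity model: %s\n", x$model))
  print(signif(x$coefficients, 4))
  cat(sprintf("sigma2 = %.3g, NLL = %.2f, BIC = %.2f (n = %d, k = %d)\n",
              x$sigma2, x$nll, x$bic, x$n, x$k))
  cat("Predicted total change in W:\n")
  print(signif(x$predicted_dW_total, 3))
  invisible(x)
}

#' @export
coef.efficacy_fit <- function(object, ...) object$coefficients

#' @export
logLik.efficacy_fit <- function(object, ...) {
  structure(-object$nll, df = object$n_params, nobs = object$n_residuals,
            class = "logLik")
}

#' @export
residuals.efficacy_fit <- function(object, ...) object$residuals

#' @export
fitted.efficacy_fit <- function(object, ...) object$fitted
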