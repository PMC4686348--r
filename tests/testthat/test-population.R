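test_that("population series are group means and inherit single-electrode counts", {
  u <- all_states_u(32)
  n_trials <- 2
  counts <- array(stats::rpois(6 * n_trials * 32, 3), c(6, n_trials, 32))
  # force labels: electrode 1 -> G1, electrode 2 -> G2, rest unavailable
  counts[1, , ] <- counts[1, , ] + 5 * matrix(u[1, ], n_trials, 32, byrow = TRUE)
  counts[2, , ] <- counts[2, , ] + 5 * matrix(u[2, ], n_trials, 32, byrow = TRUE)
  counts[3:6, , ] <- 0
  st <- conditional_stats(counts, u)
  expect_equal(as.character(st$label[1:2]), c("G1", "G2"))
  pop <- build_population(counts, st)
  expect_equal(pop$x_series[1, , 1], counts[1, 1, ])
  expect_equal(pop$x_series[2, , 2], counts[2, 2, ])

  # all-ones input: population input is (1, 1) on every event
  sched <- list(s = matrix(1L, 32, 10))
  expect_true(all(input_population(sched$s) == 1))

  # empty group: culture excluded with a diagnostic
  counts2 <- counts
  counts2[2, , ] <- 0
  st2 <- conditional_stats(counts2, u)
  expect_error(build_population(counts2, st2), "G2")
})

test_that("mixing balance sets the expected population input under pure states", {
  p <- stim_params(a = 3 / 4, n_events = 4000L, seed = 41)
  sched <- stim_schedule(p)
  sp <- input_population(sched)
  idx <- which(sched$u[1, ] == 1 & sched$u[2, ] == 0)
  expect_lt(abs(mean(sp[1, idx]) - 0.75), 0.02)
  expect_lt(abs(mean(sp[2, idx]) - 0.25), 0.02)
})

test_that("connectivity estimator is exact on noiseless data and matches least squares", {
  set.seed(42)
  W0 <- matrix(c(1.2, 0.3, 0.4, 0.9), 2, 2)
  s <- matrix(stats::runif(2 * 64), 2)
  x <- W0 %*% s
  fit <- estimate_connectivity(x, s)
  expect_equal(fit$mu_W, W0, tolerance = 1e-12)
  expect_equal(max(abs(fit$sigma_xi)), 0, tolerance = 1e-20)

  # random noisy instance: equals the numerical least-squares minimizer
  x2 <- W0 %*% s + matrix(stats::rnorm(2 * 64, sd = 0.5), 2)
  fit2 <- estimate_connectivity(x2, s)
  obj <- function(w) sum((x2 - matrix(w, 2, 2) %*% s)^2)
  num <- stats::optim(as.numeric(W0), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  expect_lt(max(abs(fit2$mu_W - matrix(num$par, 2, 2))) / max(abs(fit2$mu_W)),
            1e-6)

  # gradient of the internal action vanishes at the estimator
  act <- function(w) {
    W <- matrix(w, 2, 2)
    sum(vapply(seq_len(ncol(s)), function(t) {
      internal_energy(s[, t], x2[, t], W, fit2$sigma_xi)
    }, numeric(1)))
  }
  g <- numDeriv_grad(act, as.numeric(fit2$mu_W))
  expect_lt(max(abs(g)) / act(as.numeric(fit2$mu_W)), 1e-6)

  # rank-deficient input: constant s across events
  s_const <- matrix(c(0.5, 0.5), 2, 64)
  expect_error(estimate_connectivity(x, s_const), "singular")
})

test_that("internal energy matches its closed form and a quadratic-form oracle", {
  expect_equal(internal_energy(c(0, 0), c(0, 0), diag(2), diag(2)), log(2 * pi))
  expect_equal(internal_energy(c(0, 0), c(1, 0), diag(0, 2), diag(2)),
               0.5 + log(2 * pi))
  set.seed(43)
  S <- crossprod(matrix(stats::rnorm(4), 2)) + diag(0.5, 2)
  s <- stats::rnorm(2); x <- stats::rnorm(2)
  W <- matrix(stats::rnorm(4), 2)
  xi <- x - W %*% s
  # explicit 2x2 inverse
  Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2) /
    (S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1])
  oracle <- 0.5 * t(xi) %*% Sinv %*% xi + 0.5 * log((2 * pi)^2 * det(S))
  expect_equal(internal_energy(s, x, W, S), as.numeric(oracle))
  expect_error(internal_energy(s, x, W, diag(0, 2)), "positive definite")
})

test_that("expected energy agrees with the Monte-Carlo mean of the event energy", {
  expect_equal(expected_energy(diag(2)), 1 + log(2 * pi))
  expect_equal(expected_energy(diag(exp(2), 2)), 3 + log(2 * pi))
  set.seed(44)
  S <- crossprod(matrix(stats::rnorm(4), 2)) + diag(0.3, 2)
  n <- 1e5
  ch <- chol(S)
  xi <- t(ch) %*% matrix(stats::rnorm(2 * n), 2)
  en <- 0.5 * colSums(xi * solve(S, xi)) + 0.5 * log((2 * pi)^2 * det(S))
  se <- stats::sd(en) / sqrt(n)
  expect_lt(abs(expected_energy(S) - mean(en)), 3 * se)
  expect_error(expected_energy(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("recognition density recovers known component moments", {
  # degenerate: constant response per state
  st_idx <- rep(1:4, each = 8)
  x <- rbind(c(0, 1, 2, 3)[st_idx], c(3, 2, 1, 0)[st_idx])
  gmm <- fit_recognition(x, st_idx)
  expect_true(gmm$ok)
  expect_equal(unname(gmm$means[, "u10"]), c(1, 2))
  expect_true(all(abs(gmm$covs) < 1e-14))
  expect_equal(sum(gmm$weights), 1)

  # sampled Gaussian mixture with known moments
  set.seed(45)
  mu <- list(c(0, 0), c(4, 0), c(0, 4), c(4, 4))
  n_per <- 400
  st2 <- rep(1:4, each = n_per)
  x2 <- sapply(st2, function(m) mu[[m]] + stats::rnorm(2, sd = 0.5))
  gmm2 <- fit_recognition(x2, st2)
  for (m in 1:4) {
    expect_lt(max(abs(gmm2$means[, m] - mu[[m]])), 4 * 0.5 / sqrt(n_per) * 3)
    expect_lt(max(abs(gmm2$covs[, , m] - diag(0.25, 2))), 0.05)
  }

  # sparse state: flagged, not fitted (only one event of state (1,0) here)
  gmm3 <- fit_recognition(x[, 1:9, drop = FALSE], st_idx[1:9])
  expect_false(gmm3$ok)
  expect_equal(gmm3$missing_state, "u10")
})

test_that("plug-in entropy matches the well-separated mixture closed form", {
  # equal spherical components far apart: H ~ log 4 + Gaussian entropy
  set.seed(46)
  mu <- list(c(0, 0), c(50, 0), c(0, 50), c(50, 50))
  sd0 <- 0.8
  n_per <- 256
  st <- rep(1:4, each = n_per)
  x <- sapply(st, function(m) mu[[m]] + stats::rnorm(2, sd = sd0))
  gmm <- fit_recognition(x, st)
  H <- entropy_plugin(x, gmm)
  # closed-form for an isolated Gaussian + mixture weight term
  H_ref <- log(4) + 0.5 * log((2 * pi * exp(1))^2 * det(diag(sd0^2, 2)))
  expect_lt(abs(H - H_ref), 0.05)

  # single effective component: all states identical
  x1 <- sapply(st, function(m) c(0, 0) + stats::rnorm(2, sd = sd0))
  gmm1 <- fit_recognition(x1, st)
  H1 <- entropy_plugin(x1, gmm1)
  Sig <- tcrossprod(x1 - rowMeans(x1)) / ncol(x1)
  expect_lt(abs(H1 - 0.5 * log((2 * pi * exp(1))^2 * det(Sig))), 0.1)

  # widening all covariances increases the entropy
  gmm_wide <- gmm
  gmm_wide$covs <- gmm$covs * 4
  expect_gt(entropy_plugin(x, gmm_wide), H)
})

test_that("free energy is the exact energy-entropy difference and norms evaluate", {
  fe <- free_energy(2.5, 2.5)
  expect_identical(fe$F, 0)
  set.seed(47)
  for (i in 1:20) {
    U <- stats::rnorm(1); H <- stats::rnorm(1)
    expect_identical(free_energy(U, H)$F, U - H)
  }
  expect_equal(gamma_norm(diag(2), 2), sqrt(2))
  expect_equal(gamma_norm(diag(2), 1), 2)
  W <- matrix(c(-1.3, 0.2, 2, 0.7), 2)
  expect_equal(gamma_norm(W, 4), sum(abs(W)^4)^(1 / 4))
  expect_error(gamma_norm(W, 0), "positive")
})

test_that("per-culture analysis keeps the free-energy identity on every trial", {
  fx <- small_sim(seed = 48, n_trials = 6)
  fep <- culture_fep(fx$sim)
  ok <- fep$trials$ok
  expect_true(any(ok))
  expect_equal(fep$trials$F[ok],
               fep$trials$U_mean[ok] - fep$trials$H[ok])
  expect_s3_class(summary(fep), "data.frame")
})
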