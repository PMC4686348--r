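test_that("Hebbian statistics match hand arithmetic on a four-event toy trial", {
  # 2 x 4 toy: one event per source state
  u <- cbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  x <- matrix(c(1, 0,
                3, 1,
                1, 3,
                4, 4), 2, 4)
  s <- matrix(c(0, 0,
                0.75, 0.25,
                0.25, 0.75,
                1, 1), 2, 4)
  xc <- x - rowMeans(x)
  sc <- s - rowMeans(s)
  hs <- hebbian_statistics(array(x, c(2, 4, 1)), s, u, W = NULL)
  for (m in 2:4) {
    expect_equal(hs[[c("z10", "z01", "z11")[m - 1]]][, , 1],
                 tcrossprod(xc[, m], sc[, m]))
  }
  # constant response: centering annihilates every statistic
  x_const <- matrix(2, 2, 4)
  hs0 <- hebbian_statistics(array(x_const, c(2, 4, 1)), s, u, W = NULL)
  expect_true(all(hs0$z10 == 0) && all(hs0$z01 == 0) && all(hs0$z11 == 0))
})

# build a hebb_stats object with constant-per-trial z matrices so that the
# model-implied dW is exactly constant across trials
make_stats <- function(z10, z01, z11, L = 50) {
  structure(list(z10 = array(z10, c(2, 2, L)), z01 = array(z01, c(2, 2, L)),
                 z11 = array(z11, c(2, 2, L)), dW = NULL, n_trials = L,
                 centering = "trial"),
            class = "hebb_stats")
}

test_that("efficacy estimators are exact on noiseless data and respect nesting", {
  set.seed(51)
  z10 <- matrix(stats::rnorm(4), 2)
  z01 <- matrix(stats::rnorm(4), 2)
  z11 <- matrix(stats::rnorm(4), 2)
  st <- make_stats(z10, z01, z11)

  # alpha-model generated data
  alpha_true <- 0.01
  dW <- alpha_true * (z10 + z01 + z11)
  fa <- fit_efficacy(st, model = "alpha", dW = dW)
  expect_equal(unname(coef(fa)), alpha_true, tolerance = 1e-12)
  expect_equal(fa$sigma2, 0, tolerance = 1e-24)

  # beta-model generated data with distinct efficacies
  b <- c(0.01, 0.0027)
  dWb <- b[1] * (z10 + z01) + b[2] * z11
  fb <- fit_efficacy(st, model = "beta", dW = dWb)
  expect_equal(unname(coef(fb)), b, tolerance = 1e-10)

  # nesting: beta fit on alpha-generated data returns equal efficacies and
  # the same predicted connectivity change as the alpha fit
  fb_on_a <- fit_efficacy(st, model = "beta", dW = dW)
  expect_equal(unname(coef(fb_on_a)), c(alpha_true, alpha_true),
               tolerance = 1e-10)
  expect_equal(predict(fb_on_a), predict(fa), tolerance = 1e-10)

  # degenerate inputs error out
  st0 <- make_stats(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  expect_error(fit_efficacy(st0, model = "alpha", dW = dW), "degenerate")
  st_sing <- make_stats(z10, z01, matrix(0, 2, 2))
  expect_error(fit_efficacy(st_sing, model = "beta", dW = dW), "singular")
})

test_that("closed-form estimators equal direct numerical likelihood minimization", {
  set.seed(52)
  L <- 30
  st <- structure(list(z10 = array(stats::rnorm(4 * L), c(2, 2, L)),
                       z01 = array(stats::rnorm(4 * L), c(2, 2, L)),
                       z11 = array(stats::rnorm(4 * L), c(2, 2, L)),
                       dW = NULL, n_trials = L, centering = "trial"),
                  class = "hebb_stats")
  dW <- matrix(stats::rnorm(4, sd = 0.5), 2)

  y <- rep(as.numeric(dW), L)
  rA <- as.numeric(st$z10 + st$z01 + st$z11)
  r1 <- as.numeric(st$z10 + st$z01)
  r2 <- as.numeric(st$z11)

  fa <- fit_efficacy(st, model = "alpha", dW = dW)
  opt_a <- stats::optim(0, fn = function(a) sum((y - a * rA)^2),
                        gr = function(a) -2 * sum(rA * (y - a * rA)),
                        method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 2000))
  expect_lt(abs(coef(fa)[[1]] - opt_a$par) / abs(opt_a$par), 1e-8)

  fb <- fit_efficacy(st, model = "beta", dW = dW)
  rss_b <- function(bb) sum((y - bb[1] * r1 - bb[2] * r2)^2)
  gr_b <- function(bb) {
    e <- y - bb[1] * r1 - bb[2] * r2
    c(-2 * sum(r1 * e), -2 * sum(r2 * e))
  }
  opt_b <- stats::optim(c(0, 0), rss_b, gr = gr_b, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 2000))
  par_b <- newton_polish(opt_b$par, gr_b)
  expect_lt(max(abs(coef(fb) - par_b)) / max(abs(coef(fb))), 1e-8)

  # the minimized residual sum matches the ML variance times n
  expect_equal(fb$sigma2 * fb$n_residuals, rss_b(coef(fb)), tolerance = 1e-10)
})

test_that("noisy efficacy estimates are unbiased within Monte-Carlo error", {
  set.seed(53)
  alpha_true <- 0.01
  reps <- 100
  est <- numeric(reps)
  z10 <- matrix(stats::rnorm(4), 2)
  z01 <- matrix(stats::rnorm(4), 2)
  z11 <- matrix(stats::rnorm(4), 2)
  st <- make_stats(z10, z01, z11)
  S <- z10 + z01 + z11
  for (r in seq_len(reps)) {
    dW <- alpha_true * S + matrix(stats::rnorm(4, sd = 0.002), 2)
    est[r] <- coef(fit_efficacy(st, model = "alpha", dW = dW))[[1]]
  }
  se <- stats::sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - alpha_true), 3 * se)
})

test_that("efficacy-ratio recovery bias on synthetic cultures is below 10%", {
  # replicate beta-model cultures at a reduced size and recover the ratio
  reps <- 60
  ratios <- numeric(reps)
  cfg <- sim_config()
  true_ratio <- cfg$beta2 / cfg$beta1
  for (r in seq_len(reps)) {
    fit <- pop_level_fit(seed = 6000 + r, config = cfg,
                         params = stim_params(n_trials = 60))
    cf <- coef(fit_efficacy(fit$stats, model = "beta"))
    ratios[r] <- cf[["beta2"]] / cf[["beta1"]]
  }
  bias <- mean(ratios) - true_ratio
  expect_lt(abs(bias), 0.1 * true_ratio)
})

test_that("BIC penalizes the extra efficacy parameter and selects the generator", {
  nll <- 100
  expect_equal(model_bic(nll, 3, 400) - model_bic(nll, 2, 400), log(400))
  expect_error(model_bic(nll, 5, 4), "parameters")

  # model-selection consistency on simulated cultures: the generating rule
  # is recovered, and the plain Hebbian rule is recovered reliably once the
  # background noise (which perturbs both the connectivity trajectory and
  # the regressors) is small
  sel_rate <- function(cfg, gen, n = 15, base = 54000) {
    hits <- 0
    for (k in seq_len(n)) {
      fit <- pop_level_fit(seed = base + k, config = cfg,
                           params = stim_params(n_trials = 60))
      fa <- fit_efficacy(fit$stats, model = "alpha")
      fb <- fit_efficacy(fit$stats, model = "beta")
      chosen <- if (fa$bic < fb$bic) "alpha" else "beta"
      hits <- hits + (chosen == gen)
    }
    hits / n
  }
  expect_gte(sel_rate(sim_config(), "beta"), 0.9)
  expect_gte(sel_rate(sim_config(beta2 = 4e-4, noise_cov = diag(1e-4, 2)),
                      "alpha", base = 54100), 0.9)
})

test_that("model predictions separate the two plasticity rules and vanish at zero", {
  set.seed(55)
  fit <- pop_level_fit(seed = 55, params = stim_params(n_trials = 40))
  fb <- fit_efficacy(fit$stats, model = "beta")
  fa <- fit_efficacy(fit$stats, model = "alpha")
  pred_b <- predict(fb)
  pred_a <- predict(fa)
  # beta-model predicts declining between-group connections on a
  # source-coding culture; the plain Hebbian model predicts growth
  expect_lt(mean(pred_b[c(2, 3)]), 0)
  expect_gt(mean(pred_a[c(2, 3)]), 0)
  # zero efficacies predict zero change
  f0 <- fb
  f0$coefficients[] <- 0
  expect_true(all(predict(f0) == 0))
})
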