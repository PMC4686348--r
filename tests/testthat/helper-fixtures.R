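# Shared fixtures, built in code at test time.

# A small training-condition simulation (fewer trials/events than the full
# design, same structure).
small_sim <- function(seed = 42, n_trials = 10, n_events = 128, ...) {
  params <- stim_params(n_trials = n_trials, n_events = n_events, seed = seed)
  sched <- stim_schedule(params)
  sim <- simulate_culture(sched, sim_config(...), seed = seed)
  list(params = params, sched = sched, sim = sim)
}

# Counts array whose value is a pure function of the source state:
# counts[i, l, t] = values[state(t)] for every electrode and trial.
state_counts <- function(u, values, n_elec = 4, n_trials = 3) {
  st <- 1L + u[1L, ] + 2L * u[2L, ]
  n_events <- ncol(u)
  counts <- array(0, c(n_elec, n_trials, n_events))
  for (t in seq_len(n_events)) counts[, , t] <- values[st[t]]
  counts
}

# A source matrix that visits all four states cyclically.
all_states_u <- function(n_events = 64) {
  base <- cbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  base[, rep(1:4, length.out = n_events)]
}

# Polish a numerical minimum with Newton steps on an exact gradient and a
# finite-difference Hessian (keeps optimizer-based oracles at ~1e-12
# precision without using the closed form under test).
newton_polish <- function(par, gr, steps = 6, h = 1e-7) {
  for (s in seq_len(steps)) {
    g <- gr(par)
    H <- matrix(0, length(par), length(par))
    for (j in seq_along(par)) {
      pp <- par; pm <- par
      pp[j] <- pp[j] + h
      pm[j] <- pm[j] - h
      H[, j] <- (gr(pp) - gr(pm)) / (2 * h)
    }
    par <- par - solve(H, g)
  }
  par
}

# Central finite-difference gradient.
numDeriv_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Population-level beta-model culture analysis: per-trial ML connectivity from
# the latent population series, then Hebbian statistics. Used by recovery
# studies.
pop_level_fit <- function(seed, config = sim_config(), params = stim_params()) {
  params$seed <- seed
  sched <- stim_schedule(params)
  sim <- simulate_culture(sched, config, seed = seed, emit_counts = FALSE)
  L <- params$n_trials
  West <- array(NA_real_, c(2, 2, L))
  for (l in seq_len(L)) {
    West[, , l] <- estimate_connectivity(sim$truth$x_pop[, , l],
                                         sim$truth$s_pop)$mu_W
  }
  hs <- hebbian_statistics(sim$truth$x_pop, sim$truth$s_pop, sched$u, West)
  list(sim = sim, sched = sched, stats = hs)
}
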