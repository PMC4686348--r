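#' Stimulation design parameters
#'
#' Bundles the constants of the stimulation generative process: two hidden
#' binary sources drive 32 stimulation channels through a probabilistic mixing
#' matrix, for 256 one-second events per trial and 100 trials.
#'
#' @param rho Per-event firing probability of each hidden source, in `[0, 1]`.
#' @param a Mixing balance in `[0, 1]`: channels 1--16 copy source 1 with
#'   probability `a` (source 2 otherwise); channels 17--32 have the roles
#'   swapped.
#' @param n_events Stimulation events per trial.
#' @param n_trials Number of trials.
#' @param n_stim Number of stimulation channels.
#' @param n_elec Number of recording electrodes (`n_stim <= n_elec`).
#' @param seed Optional master seed for schedule generation.
#'
#' @return An object of class `"stim_params"` (a named list).
#' @export
#' @examples
#' stim_params(rho = 1/2, a = 3/4)
stim_params <- function(rho = 1 / 2, a = 3 / 4, n_events = 256L, n_trials = 100L,
                        n_stim = 32L, n_elec = 64L, seed = NULL) {
  stopif_not_prob(rho, "rho")
  stopif_not_prob(a, "a")
  stopif_not_count(n_events, "n_events")
  stopif_not_count(n_trials, "n_trials")
  stopif_not_count(n_stim, "n_stim", min = 2L)
  stopif_not_count(n_elec, "n_elec")
  if (n_stim > n_elec) stop("`n_stim` must not exceed `n_elec`", call. = FALSE)
  if (n_stim %% 2L != 0L) stop("`n_stim` must be even (two channel groups)", call. = FALSE)
  structure(
    list(rho = rho, a = a, n_events = as.integer(n_events),
         n_trials = as.integer(n_trials), n_stim = as.integer(n_stim),
         n_elec = as.integer(n_elec), seed = seed),
    class = "stim_params"
  )
}

#' Draw the hidden binary sources
#'
#' Generates the two hidden sources as independent Bernoulli(`rho`) trains of
#' length `n_events`: `u_k(t) = 1` when an independent uniform draw falls
#' below `rho`.
#'
#' @param params A [stim_params()] object.
#' @param seed Optional seed (defaults to the `sources` substream of
#'   `params$seed`).
#' @return An integer matrix `u` of dimension `2 x n_events` with entries in
#'   `{0, 1}`.
#' @export
generate_sources <- function(params, seed = sub_seed(params$seed, "sources")) {
  stopifnot(inherits(params, "stim_params"))
  with_seed(seed, {
    matrix(as.integer(stats::runif(2L * params$n_events) < params$rho),
           nrow = 2L, dimnames = list(c("u1", "u2"), NULL))
  })
}

#' Mix hidden sources into stimulation channels
#'
#' Each channel independently copies one of the two sources at every event:
#' channels `1..n_stim/2` take source 1 with probability `a` (source 2
#' otherwise), channels `n_stim/2+1..n_stim` take source 1 with probability
#' `1 - a`. Equivalently, `s(t)` follows a binary process with intensity
#' `A u(t)` for the mixing matrix `A` with rows `(a, 1-a)` and `(1-a, a)`.
#'
#' @param u `2 x n_events` binary source matrix from [generate_sources()].
#' @param params A [stim_params()] object.
#' @param seed Optional seed (defaults to the `mixing` substream).
#' @return An integer matrix `s` of dimension `n_stim x n_events`.
#' @export
mix_inputs <- function(u, params, seed = sub_seed(params$seed, "mixing")) {
  stopifnot(inherits(params, "stim_params"))
  if (!is.matrix(u) || nrow(u) != 2L || ncol(u) != params$n_events) {
    stop("`u` must be a 2 x n_events matrix matching `params`", call. = FALSE)
  }
  half <- params$n_stim %/% 2L
  with_seed(seed, {
    omega <- matrix(stats::runif(params$n_stim * params$n_events),
                    nrow = params$n_stim)
    take_u1 <- omega < rbind(
      matrix(params$a, half, params$n_events),
      matrix(1 - params$a, half, params$n_events)
    )
    s <- matrix(0L, params$n_stim, params$n_events)
    s[take_u1] <- matrix(u[1L, ], params$n_stim, params$n_events, byrow = TRUE)[take_u1]
    s[!take_u1] <- matrix(u[2L, ], params$n_stim, params$n_events, byrow = TRUE)[!take_u1]
    rownames(s) <- paste0("s", seq_len(params$n_stim))
    s
  })
}

#' Build a complete stimulation schedule
#'
#' Draws the hidden sources and mixed channel inputs once; the same pattern is
#' delivered on every trial, so the schedule stores a single `n_events`-long
#' realization together with the mixing matrix `A`.
#'
#' @param params A [stim_params()] object.
#' @return An object of class `"stim_schedule"`: list with `u` (`2 x
#'   n_events`), `s` (`n_stim x n_events`), `A` (`n_stim x 2`), and `params`.
#' @export
#' @examples
#' sched <- stim_schedule(stim_params(seed = 1))
#' dim(sched$s)
stim_schedule <- function(params = stim_params()) {
  u <- generate_sources(params)
  s <- mix_inputs(u, params)
  half <- params$n_stim %/% 2L
  A <- rbind(
    matrix(c(params$a, 1 - params$a), half, 2L, byrow = TRUE),
    matrix(c(1 - params$a, params$a), half, 2L, byrow = TRUE)
  )
  colnames(A) <- c("u1", "u2")
  structure(list(u = u, s = s, A = A, params = params), class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  p <- x$params
  cat("Stimulation schedule\n")
  cat(sprintf("  %d events/trial x %d trials, %d channels (of %d electrodes)\n",
              p$n_events, p$n_trials, p$n_stim, p$n_elec))
  cat(sprintf("  source rate rho = %.3g, mixing balance a = %.3g\n", p$rho, p$a))
  cat(sprintf("  realized source rates: %.3f, %.3f\n",
              mean(x$u[1, ]), mean(x$u[2, ])))
  invisible(x)
}

#' Channel-group mean input series
#'
#' Collapses the binary channel inputs to the two-dimensional population input
#' `s~(t) = (mean of channels 1..n/2, mean of channels n/2+1..n)`.
#'
#' @param schedule A [stim_schedule()] object (or a bare `n_stim x n_events`
#'   binary matrix).
#' @return A `2 x n_events` numeric matrix.
#' @export
input_population <- function(schedule) {
  s <- if (inherits(schedule, "stim_schedule")) schedule$s else schedule
  half <- nrow(s) %/% 2L
  rbind(s1 = colMeans(s[seq_len(half), , drop = FALSE]),
        s2 = colMeans(s[half + seq_len(half), , drop = FALSE]))
}
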