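# Dataset I/O in the layout of the published summary dataset:
# per-culture evoked-count trains "x(t)_<label>_<k>.csv" with one row per
# (trial, event) and columns trial, event, x1..x<n_elec>, u1, u2;
# "x_u_<cond>.csv" conditional-expectation transients; "kld_<cond>.csv"
# per-electrode KLD transients.

#' Write an evoked-count train as CSV
#'
#' @param counts `n_elec x n_trials x n_events` array.
#' @param u `2 x n_events` source matrix.
#' @param path Output file path.
#' @param trials Trials to write (default all; the published trains cover
#'   every tenth trial).
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, u, path, trials = NULL) {
  n_elec <- dim(counts)[1L]
  n_events <- dim(counts)[3L]
  trials <- trials %||% seq_len(dim(counts)[2L])
  rows <- do.call(rbind, lapply(trials, function(l) {
    cbind(trial = l, event = seq_len(n_events), t(counts[, l, ]),
          u1 = u[1L, ], u2 = u[2L, ])
  }))
  colnames(rows) <- c("trial", "event", paste0("x", seq_len(n_elec)), "u1", "u2")
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}

#' Read an evoked-count train CSV
#'
#' Accepts the schema written by [write_counts_csv()]; trials absent from the
#' file (e.g. trains covering trials 1, 11, ..., 91 only) come back as `NA`
#' slices.
#'
#' @param path CSV path.
#' @param n_trials Total number of trials in the design (default: the largest
#'   trial index present).
#' @return List with `counts` (`n_elec x n_trials x n_events`), `u`
#'   (`2 x n_events`), and `trials_present`.
#' @export
read_counts_csv <- function(path, n_trials = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("trial", "event", "u1", "u2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("count CSV schema violation: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  if (length(xcols) == 0L) {
    stop("count CSV schema violation: no electrode columns x1..xN", call. = FALSE)
  }
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  n_elec <- length(xcols)
  trials_present <- sort(unique(df$trial))
  n_trials <- n_trials %||% max(trials_present)
  n_events <- max(df$event)
  counts <- array(NA_integer_, c(n_elec, n_trials, n_events))
  u <- matrix(NA_integer_, 2L, n_events, dimnames = list(c("u1", "u2"), NULL))
  for (l in trials_present) {
    sub <- df[df$trial == l, ]
    sub <- sub[order(sub$event), ]
    counts[, l, sub$event] <- t(as.matrix(sub[, xcols]))
    u[1L, sub$event] <- sub$u1
    u[2L, sub$event] <- sub$u2
  }
  list(counts = counts, u = u, trials_present = trials_present)
}

#' Write conditional-expectation transients as CSV
#'
#' One row per (electrode, trial), columns `electrode`, `trial`, `x00`,
#' `x10`, `x01`, `x11`, `label`.
#'
#' @param stats A [conditional_stats()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xu_csv <- function(stats, path) {
  stopifnot(inherits(stats, "cond_stats"))
  n_elec <- dim(stats$x_u)[1L]
  rows <- do.call(rbind, lapply(seq_len(stats$n_trials), function(l) {
    data.frame(electrode = seq_len(n_elec), trial = l,
               x00 = stats$x_u[, l, "u00"], x10 = stats$x_u[, l, "u10"],
               x01 = stats$x_u[, l, "u01"], x11 = stats$x_u[, l, "u11"],
               label = as.character(stats$label))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write per-electrode KLD transients as CSV
#'
#' @param kt A [kld_transition()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kld_csv <- function(kt, path) {
  stopifnot(inherits(kt, "kld_transition"))
  df <- data.frame(electrode = kt$electrodes, kt$D_KL, check.names = FALSE)
  names(df) <- c("electrode", paste0("trial", seq_len(ncol(kt$D_KL))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a run configuration file
#'
#' Configurations are YAML with keys matching the [stim_params()] and
#' [sim_config()] field names plus the run-level settings of
#' [run_experiment()].
#'
#' @param path File path.
#' @param config For writing: a list as accepted by [run_experiment()].
#' @return For `read_run_config`, the configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
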