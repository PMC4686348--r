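#' Dispatch the study's standard statistical tests
#'
#' Paired comparisons use the Wilcoxon signed-rank test, unpaired comparisons
#' the Mann-Whitney U test, and correlations the Spearman rank test,
#' mirroring the analysis conventions of the experimental design.
#'
#' @param x,y Numeric samples (for `"spearman"`, the two series to
#'   correlate).
#' @param type `"paired"`, `"unpaired"`, or `"spearman"`.
#' @param alternative Alternative hypothesis passed to the underlying test.
#' @return A one-row data frame: `test`, `statistic`, `p_value`, `n`, and
#'   `degenerate` (`TRUE` when ties make the test uninformative, e.g. all
#'   paired differences zero).
#' @export
group_tests <- function(x, y, type = c("paired", "unpaired", "spearman"),
                        alternative = "two.sided") {
  type <- match.arg(type)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  degenerate <- FALSE
  res <- switch(type,
    paired = {
      d <- x - y
      if (all(d == 0)) {
        degenerate <- TRUE
        list(statistic = 0, p.value = 1, method = "Wilcoxon signed-rank")
      } else {
        suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            alternative = alternative))
      }
    },
    unpaired = suppressWarnings(
      stats::wilcox.test(x, y, paired = FALSE, alternative = alternative)),
    spearman = suppressWarnings(
      stats::cor.test(x, y, method = "spearman", alternative = alternative))
  )
  name <- switch(type, paired = "Wilcoxon signed-rank",
                 unpaired = "Mann-Whitney U", spearman = "Spearman")
  data.frame(test = name, statistic = unname(res$statistic[1] %||% NA_real_),
             p_value = res$p.value, n = length(x), degenerate = degenerate,
             stringsAsFactors = FALSE)
}

# Condition taxonomy: training (trn), NMDA blockade (apv), partial training
# (prt), and alternative (a, rho) settings alt1..alt4.
condition_settings <- function(condition) {
  alt <- list(alt1 = c(a = 1 / 2, rho = 1 / 2), alt2 = c(a = 3 / 4, rho = 1 / 4),
              alt3 = c(a = 3 / 4, rho = 3 / 4), alt4 = c(a = 1, rho = 1 / 2))
  if (condition %in% names(alt)) {
    list(a = alt[[condition]][["a"]], rho = alt[[condition]][["rho"]],
         apv = FALSE, prt = FALSE)
  } else if (condition == "apv") {
    list(a = 3 / 4, rho = 1 / 2, apv = TRUE, prt = FALSE)
  } else if (condition == "prt") {
    list(a = 3 / 4, rho = 1 / 2, apv = FALSE, prt = TRUE)
  } else if (condition == "trn") {
    list(a = 3 / 4, rho = 1 / 2, apv = FALSE, prt = FALSE)
  } else {
    stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
  }
}

#' Run a full simulate-and-analyse experiment
#'
#' Simulates `n_cultures` synthetic cultures under a named condition, runs the
#' complete analysis chain (conditional statistics, KLD transitions,
#' per-culture free-energy analysis, efficacy-model comparison), applies the
#' group-level statistical tests, and (optionally) writes all tables to
#' `outdir` in the documented CSV layout. Deterministic under a fixed seed.
#'
#' In the partially-trained (`prt`) condition, plasticity operates only during
#' trials 1--10 and 91--100; the connectivity is frozen in between,
#' representing the unstimulated resting period.
#'
#' @param config A list (or path to a YAML file) with entries `condition`
#'   (`"trn"`, `"apv"`, `"prt"`, `"alt1"`..`"alt4"`), `n_cultures`, `seed`,
#'   optional overrides for [stim_params()] / [sim_config()] fields, optional
#'   `outdir`, and `verbose`.
#' @return Object of class `"run_report"`: per-culture results (`cultures`),
#'   group-level summary tables and test results (`tests`), excluded-culture
#'   log, and provenance (seed, condition, config echo).
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  condition <- config$condition %||% "trn"
  n_cultures <- config$n_cultures %||% 5L
  seed <- config$seed %||% 1L
  verbose <- isTRUE(config$verbose)
  cs <- condition_settings(condition)

  params0 <- stim_params(
    rho = config$rho %||% cs$rho, a = config$a %||% cs$a,
    n_events = config$n_events %||% 256L, n_trials = config$n_trials %||% 100L,
    n_stim = config$n_stim %||% 32L, n_elec = config$n_elec %||% 64L
  )
  cfg_args <- config[intersect(names(config),
                               c("beta1", "beta2", "eta", "baseline",
                                 "local_gain", "unstim_gain"))]
  cfg_args$apv_mode <- cs$apv
  sim_cfg <- do.call(sim_config, cfg_args)

  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  cultures <- vector("list", n_cultures)
  excluded <- character()
  for (k in seq_len(n_cultures)) {
    k_seed <- sub_seed(seed, paste0("culture", k))
    params <- params0
    params$seed <- sub_seed(k_seed, "schedule")
    sched <- stim_schedule(params)
    L <- params$n_trials
    active <- if (cs$prt) {
      # partial training: first and last 10 trials delivered, resting between
      intersect(c(seq_len(min(10L, L)), seq(max(1L, L - 9L), L)), seq_len(L))
    } else NULL
    sim <- simulate_culture(sched, sim_cfg, seed = k_seed,
                            active_trials = active)
    stats <- conditional_stats(sim$counts, sched$u)
    kt <- kld_transition(stats)
    fep <- tryCatch(culture_fep(sim$counts, sched, stats = stats),
                    error = function(e) e)
    if (inherits(fep, "error")) {
      excluded <- c(excluded, sprintf("culture %d: %s", k, conditionMessage(fep)))
      cultures[[k]] <- list(stats = stats, kld = kt, fep = NULL)
      next
    }
    fit_b <- fit_efficacy(fep, model = "beta")
    fit_a <- fit_efficacy(fep, model = "alpha")
    cultures[[k]] <- list(stats = stats, kld = kt, fep = fep,
                          fit_beta = fit_b, fit_alpha = fit_a)
    if (!is.null(outdir)) {
      write_counts_csv(sim$counts, sched$u,
                       file.path(outdir, sprintf("x(t)_%s_%d.csv", condition, k)))
      write_xu_csv(stats, file.path(outdir, sprintf("x_u_%s_%d.csv", condition, k)))
      write_kld_csv(kt, file.path(outdir, sprintf("kld_%s_%d.csv", condition, k)))
      utils::write.csv(fep$trials,
                       file.path(outdir, sprintf("fep_%s_%d.csv", condition, k)),
                       row.names = FALSE)
    }
    if (verbose) {
      message(sprintf("culture %d/%d analysed (%d/%d electrodes available)",
                      k, n_cultures, sum(stats$available),
                      length(stats$available)))
    }
  }

  ok <- !vapply(cultures, function(cu) is.null(cu$fep), logical(1))
  get_trial <- function(cu, col, l) cu$fep$trials[[col]][l]
  L <- params0$n_trials
  summarize <- function(col) {
    data.frame(
      culture = which(ok),
      trial_1 = vapply(cultures[ok], get_trial, numeric(1), col = col, l = 1L),
      trial_L = vapply(cultures[ok], get_trial, numeric(1), col = col, l = L)
    )
  }
  tests <- list()
  if (sum(ok) >= 2L) {
    for (col in c("F", "U_mean", "H")) {
      sm <- summarize(col)
      tests[[col]] <- cbind(quantity = col,
                            group_tests(sm$trial_L, sm$trial_1, "paired"))
    }
    kld_first <- vapply(cultures[ok], function(cu) mean(cu$kld$D_KL[, 1L]),
                        numeric(1))
    kld_last <- vapply(cultures[ok], function(cu) mean(cu$kld$D_KL[, L]),
                       numeric(1))
    tests$KLD <- cbind(quantity = "KLD",
                       group_tests(kld_last, kld_first, "paired"))
  }
  tests <- do.call(rbind, tests)

  efficacy <- if (sum(ok) > 0L) {
    do.call(rbind, lapply(which(ok), function(k) {
      cu <- cultures[[k]]
      data.frame(culture = k,
                 mu_beta1 = coef(cu$fit_beta)[["beta1"]],
                 mu_beta2 = coef(cu$fit_beta)[["beta2"]],
                 ratio = coef(cu$fit_beta)[["beta2"]] / coef(cu$fit_beta)[["beta1"]],
                 mu_alpha = coef(cu$fit_alpha)[["alpha"]],
                 bic_beta = cu$fit_beta$bic, bic_alpha = cu$fit_alpha$bic)
    }))
  } else NULL
  if (!is.null(outdir) && !is.null(efficacy)) {
    utils::write.csv(efficacy, file.path(outdir, sprintf("efficacy_%s.csv", condition)),
                     row.names = FALSE)
  }

  report <- structure(
    list(condition = condition, n_cultures = n_cultures, seed = seed,
         cultures = cultures, tests = tests, efficacy = efficacy,
         excluded = excluded, params = params0, sim_config = sim_cfg,
         config_hash = config_hash(config)),
    class = "run_report"
  )
  if (!is.null(outdir)) write_report_md(report, file.path(outdir, "report.md"))
  report
}

# Small deterministic hash of the configuration for provenance lines.
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

write_report_md <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# Run report: condition %s", report$condition),
    sprintf("- cultures: %d (excluded: %d)", report$n_cultures,
            length(report$excluded)),
    sprintf("- seed: %s; config hash: %s", report$seed, report$config_hash),
    ""), con)
  if (!is.null(report$tests)) {
    writeLines("## Group tests (trial 1 vs final trial)", con)
    writeLines(utils::capture.output(print(report$tests, row.names = FALSE)), con)
  }
  if (length(report$excluded) > 0L) {
    writeLines(c("", "## Exclusions", paste0("- ", report$excluded)), con)
  }
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Experiment run: condition %s, %d cultures (seed %s)\n",
              x$condition, x$n_cultures, x$seed))
  if (length(x$excluded) > 0L) {
    cat(sprintf("  excluded: %d culture(s)\n", length(x$excluded)))
  }
  if (!is.null(x$tests)) {
    cat("  group tests (final vs first trial):\n")
    print(x$tests, row.names = FALSE)
  }
  if (!is.null(x$efficacy)) {
    cat(sprintf("  mean efficacy ratio beta2/beta1: %.1f%%\n",
                100 * mean(x$efficacy$mu_beta2) / mean(x$efficacy$mu_beta1)))
  }
  invisible(x)
}
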