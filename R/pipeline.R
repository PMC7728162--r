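#' Run the full simulation-to-statistics experiment
#'
#' Simulates both arms of a cohort, decodes every condition with the
#' clean-template classifier, assembles the trial outcome table with spectral
#' covariates, fits the full and per-level logistic models, summarises firing
#' rates and runs the non-parametric comparisons.
#'
#' @param config a [cohort_config()] (its `seed` is the master seed).
#' @param hhl an [hhl_params()] for the exposed arm.
#' @param spectral_profile optional token energy profile.
#' @param out_dir optional directory; when given, tables, the configuration
#'   and a checksum manifest are written there.
#' @param keep_cohort retain the simulated rasters in the returned bundle
#'   (memory-heavy; default FALSE).
#' @return an `ic_experiment` bundle: `performance` (mean percent correct and
#'   SEM per arm/level/SNR), `classification`, `outcomes`, `fits` (full model
#'   and per-level models or the error that prevented them), `rate_summary`,
#'   `comparisons`, `tokens`, `neurons`, `config`, `hhl`.
#' @export
run_experiment <- function(config = cohort_config(), hhl = hhl_params(),
                           spectral_profile = NULL, out_dir = NULL,
                           keep_cohort = FALSE) {
  cohort <- simulate_cohort(config, hhl, spectral_profile = spectral_profile)
  clsf <- classify_experiment(cohort)
  outcomes <- trial_outcome_table(clsf, cohort$tokens)
  performance <- purrr::pmap(clsf, function(arm, level_db, snr_db, overall_pc,
                                            result) {
    tibble(arm = arm, level_db = level_db, snr_db = snr_db,
           mean_pc = overall_pc,
           sem_pc = sd(result$trial_pc$percent_correct) /
             sqrt(nrow(result$trial_pc)))
  }) %>% bind_rows()
  rates <- neuron_rates(cohort)
  fits <- list(
    full = tryCatch(fit_correctness_model(outcomes),
                    error = function(e) conditionMessage(e)),
    per_level = tryCatch(fit_per_level_logistic(outcomes),
                         error = function(e) conditionMessage(e))
  )
  bundle <- structure(list(
    config = config, hhl = hhl,
    tokens = cohort$tokens, neurons = cohort$neurons,
    classification = clsf, outcomes = outcomes, performance = performance,
    rate_summary = mean_rate_summary(rates),
    comparisons = compare_groups(rates, cohort$neurons, cohort$neurons),
    fits = fits,
    cohort = if (keep_cohort) cohort else NULL
  ), class = "ic_experiment")
  if (!is.null(out_dir)) write_experiment(bundle, out_dir)
  bundle
}

#' @export
print.ic_experiment <- function(x, ...) {
  cat("<ic_experiment> ", x$config$n_neurons, " neurons, ",
      x$config$n_trials, " trials, seed ", x$config$seed, "\n", sep = "")
  print(x$performance, n = Inf)
  invisible(x)
}

#' Percent-correct-versus-SNR curves
#'
#' Mean percent correct per condition with +/- SEM error bars, one curve per
#' arm, faceted by level. The quiet (SNR = Inf) condition is drawn at the
#' right edge of the axis.
#'
#' @param x an `ic_experiment` or the `performance` tibble itself.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_performance <- function(x, ...) {
  perf <- if (inherits(x, "ic_experiment")) x$performance else x
  quiet_x <- max(perf$snr_db[is.finite(perf$snr_db)], 0) + 8
  df <- perf %>% mutate(
    snr_x = ifelse(is.finite(.data$snr_db), .data$snr_db, quiet_x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snr_x, y = .data$mean_pc,
                                   colour = .data$arm, group = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pc - .data$sem_pc,
                                        ymax = .data$mean_pc + .data$sem_pc),
                           width = 1.2) +
    ggplot2::facet_wrap(~level_db, labeller = ggplot2::label_both) +
    ggplot2::scale_x_continuous(
      breaks = c(sort(unique(df$snr_x[is.finite(perf$snr_db)])), quiet_x),
      labels = function(b) ifelse(b == quiet_x, "quiet", b)) +
    ggplot2::labs(x = "SNR (dB)", y = "percent correct", colour = "arm") +
    ggplot2::ylim(0, 100)
}

#' @method autoplot ic_experiment
#' @export
autoplot.ic_experiment <- function(object, ...) plot_performance(object, ...)

#' Write an experiment bundle to disk with a manifest
#'
#' Writes the trial outcomes, performance summary, rate summary, group
#' comparisons, per-term regression tables, confusion matrices, neuron
#' metadata and the run configuration as CSV/YAML, plus `manifest.csv` with
#' an MD5 checksum per file.
#'
#' @param bundle an `ic_experiment`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest tibble.
#' @export
write_experiment <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(bundle$outcomes, "trial_outcomes.csv")
  wr(bundle$performance, "performance.csv")
  wr(bundle$rate_summary, "rate_summary.csv")
  wr(bundle$comparisons, "group_comparisons.csv")
  if (inherits(bundle$fits$full, "correctness_fit")) {
    wr(bundle$fits$full$lrt, "logistic_full_lrt.csv")
  }
  if (inherits(bundle$fits$per_level, "level_fits")) {
    wr(as_tibble(bundle$fits$per_level), "logistic_per_level.csv")
  }
  for (i in seq_len(nrow(bundle$classification))) {
    r <- bundle$classification[i, ]
    cm <- as.data.frame(r$result[[1]]$confusion)
    names(cm) <- c("true", "predicted", "count")
    wr(cm, sprintf("confusion_%s_%gdB_snr%s.csv", r$arm, r$level_db,
                   ifelse(is.finite(r$snr_db), r$snr_db, "quiet")))
  }
  wr(bundle$neurons, "neurons.csv")
  write_run_config(run_config(bundle$config, bundle$hhl, out_dir),
                   file.path(out_dir, "run_config.yaml"))
  paths <- c(paths, file.path(out_dir, "run_config.yaml"))
  manifest <- tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths))
  )
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Figures and a markdown summary for an experiment
#'
#' @param bundle an `ic_experiment` (a partial bundle produces a partial
#'   report with warnings).
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (is.null(bundle$performance) || nrow(bundle$performance) == 0) {
    warning("empty bundle: no performance table; no figure written")
  } else {
    p <- file.path(out_dir, "performance.png")
    ggplot2::ggsave(p, plot_performance(bundle), width = 7, height = 4, dpi = 150)
    paths <- c(paths, p)
  }
  md <- file.path(out_dir, "summary.md")
  lines <- c("# Experiment summary", "",
             sprintf("- neurons: %d, trials: %d, master seed: %d",
                     bundle$config$n_neurons, bundle$config$n_trials,
                     bundle$config$seed),
             sprintf("- HHL params: p_max = %g, gain = %g, knee = %g",
                     bundle$hhl$p_max, bundle$hhl$gain, bundle$hhl$p_sat), "",
             "## Percent correct by condition", "",
             paste(utils::capture.output(as.data.frame(bundle$performance)),
                   collapse = "\n"))
  if (inherits(bundle$fits$full, "correctness_fit")) {
    lines <- c(lines, "", "## Likelihood-ratio tests (full model)", "",
               paste(utils::capture.output(
                 as.data.frame(bundle$fits$full$lrt)), collapse = "\n"))
  } else if (!is.null(bundle$fits$full)) {
    warning("full model unavailable: ", bundle$fits$full)
  }
  writeLines(lines, md)
  invisible(c(paths, md))
}

#' Serializable run configuration
#'
#' @param cohort a [cohort_config()].
#' @param hhl an [hhl_params()].
#' @param output_dir optional output directory recorded in the config.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), hhl = hhl_params(),
                       output_dir = NULL) {
  structure(list(
    cohort = unclass(cohort), hhl = hhl,
    output_dir = output_dir, master_seed = cohort$seed
  ), class = "run_config")
}

#' @rdname run_config
#' @param rc a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(rc, path) {
  y <- unclass(rc)
  y$hhl <- unclass(y$hhl)[c("p_max", "gain")]
  yaml::write_yaml(lapply(y, function(x) {
    if (is.list(x)) lapply(x, identity) else x
  }), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  co <- y$cohort
  snrs <- as.numeric(unlist(co$snrs))
  run_config(
    cohort = cohort_config(
      n_neurons = co$n_neurons, n_trials = co$n_trials, bin_s = co$bin_s,
      window_s = co$window_s, fs = co$fs, levels = unlist(co$levels),
      snrs = snrs, cf_range = unlist(co$cf_range), seed = co$seed
    ),
    hhl = hhl_params(y$hhl$p_max, y$hhl$gain),
    output_dir = y$output_dir
  )
}
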