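#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-term likelihood-ratio table of a correctness model
#'
#' @param x a `correctness_fit`.
#' @param ... unused.
#' @return tibble: `term`, `estimate`, `z_wald`, `chisq`, `df`, `p_value`.
#' @method tidy correctness_fit
#' @export
tidy.correctness_fit <- function(x, ...) x$lrt

#' @method glance correctness_fit
#' @export
glance.correctness_fit <- function(x, ...) {
  tibble(
    n = x$n,
    null_deviance = x$model$null.deviance,
    deviance = x$model$deviance,
    df_residual = x$model$df.residual,
    aic = x$model$aic,
    hf_covariate = x$hf
  )
}

#' Tidy per-trial predictions of a classification result
#'
#' @param x a `classification_result`.
#' @param ... unused.
#' @return tibble with one row per classification event.
#' @method tidy classification_result
#' @export
tidy.classification_result <- function(x, ...) {
  x$predictions %>%
    mutate(arm = x$arm, level_db = x$level_db, snr_db = x$snr_db, .before = 1)
}

#' @method glance classification_result
#' @export
glance.classification_result <- function(x, ...) {
  tibble(arm = x$arm, level_db = x$level_db, snr_db = x$snr_db,
         overall_pc = x$overall_pc,
         n_trials = nrow(x$trial_pc),
         n_classifications = nrow(x$predictions),
         leave_one_out = x$exclude_self)
}

#' @method tidy classification_set
#' @export
tidy.classification_set <- function(x, ...) {
  purrr::map(x$result, glance) %>% bind_rows()
}

#' @method autoplot classification_set
#' @export
autoplot.classification_set <- function(object, ...) {
  perf <- purrr::pmap(object, function(arm, level_db, snr_db, overall_pc,
                                       result) {
    tibble(arm = arm, level_db = level_db, snr_db = snr_db,
           mean_pc = overall_pc,
           sem_pc = sd(result$trial_pc$percent_correct) /
             sqrt(nrow(result$trial_pc)))
  }) %>% bind_rows()
  plot_performance(perf)
}

#' Confusion-matrix heatmap
#'
#' @param object a `classification_result`.
#' @param ... unused.
#' @return a ggplot of true-by-predicted counts.
#' @method autoplot classification_result
#' @export
autoplot.classification_result <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("%s, %g dB SPL, SNR %g dB", object$arm,
                                  object$level_db, object$snr_db))
}
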