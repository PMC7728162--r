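#' Build clean-speech templates for the PSTH classifier
#'
#' One template per token: the mean over trials of the concatenated
#' neurons-by-bins single-trial response vectors, computed from the clean
#' (SNR = Inf) condition of one arm at one level. Templates are arm- and
#' level-specific; cross-group decoding is never performed.
#'
#' @param cr a `condition_response` for the clean condition.
#' @return a `vcv_templates` object: `values` (S x N*B matrix, rownames =
#'   token ids) plus metadata (`neuron_id`, `n_bins`, `n_trials`, `arm`,
#'   `level_db`).
#' @export
build_templates <- function(cr) {
  stopifnot(inherits(cr, "condition_response"))
  if (!is.infinite(cr$snr_db)) {
    stop("templates must be built from the clean (SNR = Inf) condition")
  }
  toks <- unique(cr$rows$token_id)
  vals <- t(vapply(toks, function(tk) {
    keep <- cr$rows$token_id == tk
    Matrix::colMeans(cr$m[keep, , drop = FALSE])
  }, numeric(ncol(cr$m))))
  rownames(vals) <- toks
  structure(list(
    values = vals, token_ids = toks,
    neuron_id = cr$neuron_id, n_bins = cr$n_bins, n_trials = cr$n_trials,
    arm = cr$arm, level_db = cr$level_db
  ), class = "vcv_templates")
}

#' @export
print.vcv_templates <- function(x, ...) {
  cat("<vcv_templates> ", nrow(x$values), " tokens x ", ncol(x$values),
      " features (", length(x$neuron_id), " neurons x ", x$n_bins,
      " bins); arm=", x$arm, ", ", x$level_db, " dB SPL\n", sep = "")
  invisible(x)
}

#' Euclidean distance between a trial vector and a template
#'
#' The square root of the summed squared elementwise differences. The
#' classifier's argmin is unaffected by the monotone square root.
#'
#' @param x,y numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch between trial and template")
  sqrt(sum((as.numeric(x) - as.numeric(y))^2))
}

#' Classify a single trial against the templates
#'
#' Nearest template by Euclidean distance. With `exclude_self = TRUE` the
#' template of `true_token` is recomputed as the mean of the remaining
#' T - 1 trials (leave-one-out), the rule used for clean-condition decoding.
#' Ties are broken deterministically by the lowest token index, with a
#' warning.
#'
#' @param trial numeric vector of length N*B (single-trial spike counts).
#' @param templates a `vcv_templates`.
#' @param exclude_self logical; leave-one-out adjustment of the matching
#'   template.
#' @param true_token token id whose template contains this trial (required
#'   when `exclude_self = TRUE`).
#' @return predicted token id (character).
#' @export
classify_trial <- function(trial, templates, exclude_self = FALSE,
                           true_token = NULL) {
  M <- templates$values
  if (length(trial) != ncol(M)) stop("length mismatch between trial and template")
  d2 <- rowSums(sweep(M, 2, as.numeric(trial))^2)
  if (exclude_self) {
    if (is.null(true_token)) stop("`true_token` required for exclude_self")
    Tn <- templates$n_trials
    if (Tn < 2) stop("leave-one-out requires at least 2 trials")
    loo <- (Tn * M[true_token, ] - as.numeric(trial)) / (Tn - 1)
    d2[true_token] <- sum((as.numeric(trial) - loo)^2)
  }
  best <- which(d2 == min(d2))
  if (length(best) > 1) {
    warning("distance tie between templates {",
            paste(rownames(M)[best], collapse = ", "),
            "}; choosing the lowest token index")
    best <- best[1]
  }
  rownames(M)[best]
}

# squared distances of every row of a sparse binary trial matrix X to every
# template row of M, with optional leave-one-out correction for the trial's
# own token (clean condition). Returns the n_rows x S matrix of d^2.
trial_template_dist2 <- function(X, M, rows = NULL, loo = FALSE, n_trials = NULL) {
  rn <- Matrix::rowSums(X) # = ||x||^2 for 0/1 entries
  mm <- rowSums(M^2)
  XM <- as.matrix(X %*% t(M)) # inner products <x_i, m_s>
  D2 <- outer(rn, mm, "+") - 2 * XM
  if (loo) {
    stopifnot(!is.null(rows), !is.null(n_trials), n_trials >= 2)
    Tn <- n_trials
    s_idx <- match(rows$token_id, rownames(M))
    for (i in seq_len(nrow(X))) {
      s <- s_idx[i]
      ip_loo <- (Tn * XM[i, s] - rn[i]) / (Tn - 1)
      mm_loo <- (Tn^2 * mm[s] - 2 * Tn * XM[i, s] + rn[i]) / (Tn - 1)^2
      D2[i, s] <- rn[i] - 2 * ip_loo + mm_loo
    }
  }
  D2
}

#' Classify all trials of one condition
#'
#' Every single trial of every token at one (arm, level, SNR) condition is
#' assigned to the nearest template. Trial t's percent correct is the fraction
#' of the 11 tokens' t-th presentations classified correctly, times 100; the
#' confusion matrix accumulates all token-by-trial classifications. For the
#' clean condition the trial under test is excluded from its own template
#' (leave-one-out), unless overridden.
#'
#' @param cr a `condition_response`.
#' @param templates a `vcv_templates` from the same arm and level.
#' @param exclude_self leave-one-out flag; defaults to TRUE exactly when `cr`
#'   is the clean condition that the templates were built from.
#' @return a `classification_result`: `predictions` tibble (`token_id`,
#'   `trial`, `predicted`, `correct`), `trial_pc` tibble (percent correct per
#'   trial), `overall_pc`, `confusion` (S x S true-by-predicted counts), and
#'   the condition coordinates.
#' @export
classify_condition <- function(cr, templates, exclude_self = NULL) {
  stopifnot(inherits(cr, "condition_response"),
            inherits(templates, "vcv_templates"))
  if (!identical(cr$arm, templates$arm) ||
      !identical(cr$level_db, templates$level_db)) {
    stop("templates and trials must come from the same arm and level")
  }
  toks <- templates$token_ids
  cnt <- table(cr$rows$token_id)
  if (!all(toks %in% names(cnt)) || length(unique(cnt)) != 1) {
    stop("incomplete condition: every token needs the same full set of trials")
  }
  if (is.null(exclude_self)) exclude_self <- is.infinite(cr$snr_db)
  D2 <- trial_template_dist2(cr$m, templates$values, cr$rows,
                             loo = exclude_self, n_trials = templates$n_trials)
  ties <- apply(D2, 1, function(d) sum(d == min(d)))
  if (any(ties > 1)) {
    warning(sum(ties > 1), " trial(s) with tied template distances; ",
            "lowest token index chosen")
  }
  pred <- toks[apply(D2, 1, which.min)]
  predictions <- cr$rows %>%
    mutate(predicted = pred, correct = as.integer(pred == .data$token_id))
  trial_pc <- predictions %>%
    group_by(trial = .data$trial) %>%
    summarise(percent_correct = 100 * mean(.data$correct), .groups = "drop")
  confusion <- table(
    factor(predictions$token_id, levels = toks),
    factor(predictions$predicted, levels = toks)
  )
  structure(list(
    predictions = predictions, trial_pc = trial_pc,
    overall_pc = mean(trial_pc$percent_correct),
    confusion = unclass(confusion),
    arm = cr$arm, level_db = cr$level_db, snr_db = cr$snr_db,
    exclude_self = exclude_self
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> arm=", x$arm, ", ", x$level_db, " dB SPL, SNR ",
      x$snr_db, " dB: ", round(x$overall_pc, 1), "% correct (",
      nrow(x$predictions), " classifications)\n", sep = "")
  invisible(x)
}

#' Decode every condition of a simulated cohort
#'
#' Builds clean-speech templates per (arm, level) and classifies all
#' conditions of the cohort against the matching templates; the clean
#' condition itself is decoded leave-one-out.
#'
#' @param cohort an `ic_cohort` whose `snrs` include `Inf` (the template
#'   condition).
#' @return a `classification_set`: tibble with one row per (arm, level, SNR)
#'   carrying `overall_pc` and the full `classification_result` in `result`.
#' @export
classify_experiment <- function(cohort) {
  stopifnot(inherits(cohort, "ic_cohort"))
  if (!any(is.infinite(cohort$responses$snr_db))) {
    stop("cohort lacks the clean (SNR = Inf) template condition")
  }
  tpl_key <- function(arm, level) paste(arm, level, sep = "|")
  clean <- cohort$responses %>% filter(is.infinite(.data$snr_db))
  templates <- setNames(
    lapply(clean$data, build_templates),
    tpl_key(clean$arm, clean$level_db)
  )
  out <- purrr::pmap(cohort$responses, function(arm, level_db, snr_db, data) {
    res <- classify_condition(data, templates[[tpl_key(arm, level_db)]])
    tibble(arm = arm, level_db = level_db, snr_db = snr_db,
           overall_pc = res$overall_pc, result = list(res))
  }) %>% bind_rows()
  class(out) <- c("classification_set", class(out))
  out
}
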