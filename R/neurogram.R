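#' Compute a PSTH (per-bin mean spike count across trials)
#'
#' The peri-stimulus time histogram is the arithmetic mean, over trials, of
#' the per-bin spike counts; at 1-ms Bernoulli bins this is the empirical
#' firing probability per bin.
#'
#' @param x a trials-by-bins numeric matrix (one neuron), a [sample_spikes()]
#'   `spike_raster`, or a `condition_response` (then `token_id` is required).
#' @param token_id token to extract when `x` is a `condition_response`.
#' @return for a matrix, a numeric vector of per-bin means; otherwise an
#'   N-by-B matrix with one row per neuron (rownames = neuron ids).
#' @export
#' @examples
#' compute_psth(rbind(c(0, 1), c(1, 1))) # 0.5, 1.0
compute_psth <- function(x, token_id = NULL) {
  if (inherits(x, "condition_response")) {
    if (is.null(token_id)) stop("`token_id` required for a condition_response")
    keep <- x$rows$token_id == token_id
    if (!any(keep)) stop("token '", token_id, "' not present")
    v <- Matrix::colMeans(x$m[keep, , drop = FALSE])
    return(matrix(v, nrow = length(x$neuron_id), byrow = TRUE,
                  dimnames = list(x$neuron_id, NULL)))
  }
  if (inherits(x, "spike_raster")) {
    if (x$n_trials < 1) stop("empty raster")
    v <- Matrix::colMeans(x$m)
    return(matrix(v, nrow = length(x$neuron_id), byrow = TRUE,
                  dimnames = list(x$neuron_id, NULL)))
  }
  m <- as.matrix(x)
  if (nrow(m) < 1) stop("empty raster")
  colMeans(m)
}

#' All PSTHs of one condition
#'
#' @param cr a `condition_response`.
#' @return named list (by token id) of N-by-B PSTH matrices.
#' @export
psth_set <- function(cr) {
  stopifnot(inherits(cr, "condition_response"))
  toks <- unique(cr$rows$token_id)
  setNames(lapply(toks, function(tk) compute_psth(cr, tk)), toks)
}

#' Assemble a CF-ordered population neurogram
#'
#' Stacks per-neuron PSTHs in order of ascending characteristic frequency
#' (ties broken by neuron id), the conventional tonotopic layout with low CFs
#' at the bottom.
#'
#' @param psths N-by-B matrix of PSTHs with rownames = neuron ids (as returned
#'   by [compute_psth()] on a `condition_response`).
#' @param neuron_meta tibble with `neuron_id` and `cf` (Hz).
#' @return a `neurogram`: list with `values` (rows sorted by ascending CF),
#'   `cf_order` (Hz) and `neuron_id`.
#' @export
assemble_neurogram <- function(psths, neuron_meta) {
  stopifnot(is.matrix(psths), !is.null(rownames(psths)))
  if (anyDuplicated(neuron_meta$neuron_id)) stop("duplicate neuron_id")
  if (!all(rownames(psths) %in% neuron_meta$neuron_id)) {
    stop("PSTH rows missing from `neuron_meta`")
  }
  meta <- neuron_meta[match(rownames(psths), neuron_meta$neuron_id), ]
  ord <- order(meta$cf, meta$neuron_id)
  structure(list(
    values = psths[ord, , drop = FALSE],
    cf_order = meta$cf[ord],
    neuron_id = meta$neuron_id[ord]
  ), class = "neurogram")
}

#' @export
print.neurogram <- function(x, ...) {
  cat("<neurogram> ", nrow(x$values), " neurons (CF ",
      round(min(x$cf_order)), "-", round(max(x$cf_order)), " Hz) x ",
      ncol(x$values), " bins\n", sep = "")
  invisible(x)
}

#' Heatmap of a neurogram
#'
#' @param object a `neurogram`.
#' @param ... unused.
#' @return a ggplot: time on the x axis, CF rank on the y axis (low CFs at the
#'   bottom), firing probability as fill.
#' @method autoplot neurogram
#' @export
autoplot.neurogram <- function(object, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$values)),
    bin = seq_len(ncol(object$values))
  )
  df$p <- as.numeric(t(object$values))[
    (df$row - 1) * ncol(object$values) + df$bin]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$row,
                                   fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "P(spike)") +
    ggplot2::labs(x = "time (ms)", y = "neuron (ascending CF)")
}

#' Match two populations one-to-one by characteristic frequency
#'
#' Greedy matching without replacement: control units are processed in a
#' seeded random order; each takes the nearest still-available exposed unit in
#' log-frequency (octave) distance, with exact ties resolved at random.
#' The same scheme with linear distance is available for response thresholds
#' via `by = "threshold"`.
#'
#' @param control_meta,exposed_meta tibbles with `neuron_id` and the matching
#'   variable (`cf` in Hz or `threshold` in dB SPL).
#' @param seed integer seed controlling processing order and tie breaks.
#' @param by `"cf"` (log2 distance) or `"threshold"` (linear distance).
#' @return tibble with one row per control unit: `control_id`, `exposed_id`,
#'   the matched values and the distance used; `|control|` rows, no exposed
#'   unit reused.
#' @export
match_populations_by_cf <- function(control_meta, exposed_meta, seed = 1,
                                    by = c("cf", "threshold")) {
  by <- match.arg(by)
  if (nrow(exposed_meta) < nrow(control_meta)) {
    stop("exposed population smaller than control population")
  }
  xv <- control_meta[[by]]
  yv <- exposed_meta[[by]]
  tx <- if (by == "cf") log2(xv) else xv
  ty <- if (by == "cf") log2(yv) else yv
  withr::with_seed(derive_seed(seed, "cf-match"), {
    ord <- sample(nrow(control_meta))
    avail <- rep(TRUE, length(ty))
    pick <- integer(length(tx))
    for (i in ord) {
      d <- abs(ty - tx[i])
      d[!avail] <- Inf
      best <- which(d == min(d))
      j <- if (length(best) > 1) sample(best, 1) else best
      pick[i] <- j
      avail[j] <- FALSE
    }
    tibble(
      control_id = control_meta$neuron_id,
      exposed_id = exposed_meta$neuron_id[pick],
      control_value = xv, exposed_value = yv[pick],
      distance = abs(tx - ty[pick]),
      by = by
    )
  })
}

#' Per-neuron firing rates by condition
#'
#' Rates in spikes/s over the full analysis window (including the post-token
#' tail), per neuron and (arm, level, SNR) condition, pooled across tokens and
#' trials.
#'
#' @param cohort an `ic_cohort`.
#' @return tibble: `arm`, `level_db`, `snr_db`, `neuron_id`, `rate_hz`.
#' @export
neuron_rates <- function(cohort) {
  stopifnot(inherits(cohort, "ic_cohort"))
  win <- cohort$config$window_s
  purrr::pmap(cohort$responses, function(arm, level_db, snr_db, data) {
    tot <- Matrix::colSums(data$m) # spikes per feature over all rows
    per_neuron <- rowsum(tot, rep(seq_along(data$neuron_id),
                                  each = data$n_bins))
    tibble(
      arm = arm, level_db = level_db, snr_db = snr_db,
      neuron_id = data$neuron_id,
      rate_hz = as.numeric(per_neuron) / (nrow(data$m) * win)
    )
  }) %>% bind_rows()
}

#' Mean and median firing rates per condition, with group differences
#'
#' @param cohort an `ic_cohort` (or a tibble from [neuron_rates()]).
#' @return tibble with one row per (level, SNR): per-arm mean and median rate
#'   in spikes/s and, when both arms are present, the exposed-minus-control
#'   mean difference and the exposed/control mean ratio.
#' @export
mean_rate_summary <- function(cohort) {
  rates <- if (inherits(cohort, "ic_cohort")) neuron_rates(cohort) else cohort
  smry <- rates %>%
    group_by(.data$arm, .data$level_db, .data$snr_db) %>%
    summarise(mean_rate = mean(.data$rate_hz),
              median_rate = median(.data$rate_hz), .groups = "drop")
  if (length(unique(smry$arm)) < 2) return(smry)
  wide <- tidyr::pivot_wider(smry, names_from = "arm",
                             values_from = c("mean_rate", "median_rate"))
  wide %>% mutate(
    diff_mean = .data$mean_rate_exposed - .data$mean_rate_control,
    ratio_mean = .data$mean_rate_exposed / .data$mean_rate_control
  )
}
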