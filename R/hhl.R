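#' Hidden-hearing-loss model parameters
#'
#' The phenomenological model of cochlear synaptopathy with compensatory
#' central gain is a broken-stick transform of per-bin firing probability:
#' probabilities saturate at a knee `p_sat` (loss of high-threshold
#' auditory-nerve input truncates the top of the dynamic range) and are then
#' multiplied by `gain`, restoring the pre-exposure maximum since
#' `p_sat = p_max / gain`.
#'
#' With the default constants (maximum firing probability 0.127 per 1-ms bin,
#' gain 1.40) the knee is 0.127 / 1.40 = 0.0907, i.e. 0.09 to two decimals.
#'
#' @param p_max maximum firing probability per bin (default 0.127).
#' @param gain multiplicative central gain, >= 1 (default 1.40).
#' @return an `hhl_params` object with fields `p_max`, `gain`, `p_sat`.
#' @export
#' @examples
#' hhl_params()$p_sat # 0.0907...
hhl_params <- function(p_max = 0.127, gain = 1.40) {
  if (!is.numeric(p_max) || length(p_max) != 1 || p_max <= 0 || p_max > 1) {
    stop("`p_max` must be a probability in (0, 1]")
  }
  if (!is.numeric(gain) || length(gain) != 1 || gain < 1) {
    stop("`gain` must be >= 1")
  }
  structure(list(p_max = p_max, gain = gain, p_sat = p_max / gain),
            class = "hhl_params")
}

#' @export
print.hhl_params <- function(x, ...) {
  cat("<hhl_params> p_max=", x$p_max, ", gain=", x$gain,
      ", knee p_sat=", signif(x$p_sat, 4), "\n", sep = "")
  invisible(x)
}

#' Apply the saturation-plus-gain transform to firing probabilities
#'
#' `p' = gain * min(p, p_sat)`, clamped to \[0, 1\]. Below the knee the
#' transform is linear with slope `gain`; at and above the knee the output is
#' pinned to `gain * p_sat = p_max`, so the output never exceeds `p_max`
#' (nor 1, for other parameterizations).
#'
#' @param p numeric vector or matrix of probabilities in \[0, 1\].
#' @param params an [hhl_params()].
#' @return transformed probabilities, same shape as `p`.
#' @export
#' @examples
#' apply_hhl_gain(c(0, 0.05, 0.127), hhl_params()) # 0, 0.07, 0.127
apply_hhl_gain <- function(p, params = hhl_params()) {
  stopifnot(inherits(params, "hhl_params"))
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  out <- pmin(pmin(p, params$p_sat) * params$gain, 1)
  dim(out) <- dim(p)
  dimnames(out) <- dimnames(p)
  out
}

# moving-average smoothing along bins (columns) of an N x B matrix
smooth_bins <- function(m, w) {
  if (w <= 1) return(m)
  k <- rep(1 / w, w)
  t(apply(m, 1, function(r) {
    as.numeric(stats::filter(c(rep(r[1], w), r, rep(r[length(r)], w)),
                             k, sides = 2))[w + seq_along(r)]
  }))
}

#' Estimate the population maximum firing probability
#'
#' The model's `p_max` is the mean, across neurons, of each neuron's maximum
#' firing probability over all its PSTHs at the reference level (75 dB SPL,
#' control arm, all tokens and SNRs pooled). Raw 1-ms PSTH bins at finite
#' trial counts overestimate the maximum (the largest of many noisy binomial
#' bins). Firing probability is maximal in the unadapted onset response,
#' which holds the ceiling for tens of milliseconds, so the default
#' `"split"` method reads the mean PSTH value in a short post-onset window
#' (default 12 ms): one half of the trials selects each neuron's
#' best-driving stimulus condition, the held-out half is read there, making
#' the reading unbiased. Conditions with intense broadband drive (loud
#' masking noise) guarantee every characteristic frequency is driven to its
#' ceiling at onset. `"max"` is the plain smoothed maximum (upward-biased at
#' small trial counts).
#'
#' @param x an `ic_cohort`, or a list of N-by-B PSTH matrices (then the plain
#'   smoothed maximum is used).
#' @param level_db reference level (default 75).
#' @param smooth_ms onset-window / smoothing length in ms (default 12).
#' @param method `"split"` (cross-validated, cohort input only) or `"max"`.
#' @return estimated `p_max` (scalar probability per bin).
#' @export
estimate_pmax <- function(x, level_db = 75, smooth_ms = 12,
                          method = c("split", "max")) {
  method <- match.arg(method)
  if (inherits(x, "ic_cohort")) {
    rows <- x$responses %>%
      filter(.data$arm == "control", .data$level_db == !!level_db)
    if (nrow(rows) == 0) stop("no control responses at ", level_db, " dB SPL")
    n_neuron <- x$config$n_neurons
    if (method == "max") {
      w <- max(1L, round(smooth_ms / (x$config$bin_s * 1000)))
      maxima <- rep(-Inf, n_neuron)
      for (cr in rows$data) {
        for (tk in unique(cr$rows$token_id)) {
          sel <- cr$rows$token_id == tk
          sm <- smooth_bins(feature_to_matrix(
            Matrix::colMeans(cr$m[sel, , drop = FALSE]), n_neuron), w)
          maxima <- pmax(maxima, apply(sm, 1, max))
        }
      }
      return(mean(maxima))
    }
    # split method: the onset response (the first ~25 ms, where firing
    # probability is maximal and holds its ceiling) is read per PSTH; one
    # half of the trials selects each neuron's best PSTH, the held-out half
    # is read there, so the reading is unbiased (the halves are independent)
    w <- max(2L, round(smooth_ms / (x$config$bin_s * 1000)))
    onset <- 2 + seq_len(min(w, x$config$n_bins - 2)) # skip the rise bins
    a_read <- list()
    b_read <- list()
    for (cr in rows$data) {
      half_a <- cr$rows$trial %% 2 == 1
      if (cr$n_trials < 2) stop("split estimation requires >= 2 trials")
      for (tk in unique(cr$rows$token_id)) {
        sel <- cr$rows$token_id == tk
        pa <- feature_to_matrix(
          Matrix::colMeans(cr$m[sel & half_a, , drop = FALSE]), n_neuron)
        pb <- feature_to_matrix(
          Matrix::colMeans(cr$m[sel & !half_a, , drop = FALSE]), n_neuron)
        a_read[[length(a_read) + 1]] <- rowMeans(pa[, onset, drop = FALSE])
        b_read[[length(b_read) + 1]] <- rowMeans(pb[, onset, drop = FALSE])
      }
    }
    A <- do.call(cbind, a_read)
    B <- do.call(cbind, b_read)
    # read the held-out half at each neuron's best PSTH under the selection half
    per_neuron <- B[cbind(seq_len(n_neuron), max.col(A, ties.method = "first"))]
    return(mean(per_neuron))
  }
  if (!is.list(x) || length(x) == 0) stop("empty input")
  w_bins <- NULL
  maxima <- NULL
  for (m in x) {
    m <- as.matrix(m)
    w <- max(1L, round(smooth_ms)) # PSTH input: bins assumed 1 ms
    sm <- smooth_bins(m, min(w, ncol(m)))
    mx <- apply(sm, 1, max)
    maxima <- if (is.null(maxima)) mx else pmax(maxima, mx)
  }
  mean(maxima)
}

#' Estimate the central gain from firing rates
#'
#' The ratio of the mean exposed to the mean control firing rate, pooled over
#' all SNR conditions (including quiet) at the moderate level (60 dB SPL),
#' where responses stay below the saturation knee.
#'
#' @param x an `ic_cohort` with both arms, or a [neuron_rates()] tibble.
#' @param level_db pooling level (default 60).
#' @return estimated gain (dimensionless).
#' @export
estimate_gain <- function(x, level_db = 60) {
  rates <- if (inherits(x, "ic_cohort")) neuron_rates(x) else x
  sub <- rates %>% filter(.data$level_db == !!level_db)
  if (!all(c("control", "exposed") %in% sub$arm)) {
    stop("both arms required at ", level_db, " dB SPL")
  }
  mc <- mean(sub$rate_hz[sub$arm == "control"])
  me <- mean(sub$rate_hz[sub$arm == "exposed"])
  if (mc <= 0) stop("zero control firing rate; gain undefined")
  me / mc
}

# reshape a length-N*B feature vector back to an N x B matrix (neuron-major)
feature_to_matrix <- function(v, n_neurons) {
  matrix(v, nrow = n_neurons, byrow = TRUE)
}

#' Regenerate paired control and HL-model rasters from control PSTHs
#'
#' The saturation-plus-gain transform is applied bin-wise to each control
#' PSTH to give the HL-model PSTH; Bernoulli-per-bin spike trains are then
#' regenerated for BOTH arms (the control PSTHs are resampled too, keeping
#' the comparison model-vs-model on equal sampling footing). Templates for
#' each arm are later rebuilt from that arm's clean-condition simulations.
#'
#' @param psths named list (token id -> N x B matrix) of control PSTHs for
#'   one condition.
#' @param params an [hhl_params()].
#' @param n_trials trials to regenerate per token (default 32).
#' @param seed integer seed.
#' @param level_db,snr_db condition coordinates stamped on the output.
#' @return list with `condition_response` elements `control` and `hl`.
#' @export
make_hl_model_rasters <- function(psths, params = hhl_params(), n_trials = 32,
                                  seed = 1, level_db = NA_real_,
                                  snr_db = NA_real_) {
  stopifnot(is.list(psths), length(psths) > 0, !is.null(names(psths)))
  build_arm <- function(arm_name, transform) {
    mats <- lapply(names(psths), function(tk) {
      p <- as.matrix(psths[[tk]])
      if (transform) p <- apply_hhl_gain(p, params)
      sample_spikes(p, n_trials,
                    seed = derive_seed(seed, paste("hl-model", arm_name, tk,
                                                   sep = "|")))$m
    })
    n_neuron <- nrow(as.matrix(psths[[1]]))
    structure(list(
      m = do.call(rbind, mats),
      rows = tibble(token_id = rep(names(psths), each = n_trials),
                    trial = rep(seq_len(n_trials), length(psths))),
      neuron_id = rownames(as.matrix(psths[[1]])) %||%
        sprintf("n%03d", seq_len(n_neuron)),
      n_bins = ncol(as.matrix(psths[[1]])), n_trials = n_trials,
      arm = arm_name, level_db = level_db, snr_db = snr_db
    ), class = "condition_response")
  }
  list(control = build_arm("control", FALSE),
       hl = build_arm("hl", TRUE))
}
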