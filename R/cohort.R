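#' Simulate a synthetic IC cohort
#'
#' Generates VCV tokens, speech-shaped noise, a neuron population, per-neuron
#' driving probabilities for every requested stimulus condition, and
#' Bernoulli-per-bin spike rasters. The exposed arm is not simulated
#' independently: its driving probabilities are the control probabilities
#' passed through the hidden-hearing-loss transform ([apply_hhl_gain()]),
#' mirroring how the phenomenological model constructs the comparison
#' (both arms are then resampled on equal footing).
#'
#' All randomness derives from `config$seed` via [derive_seed()]; identical
#' configurations give bit-identical stimuli and rasters.
#'
#' @param config a [cohort_config()].
#' @param hhl an [hhl_params()] object used for the exposed arm (default
#'   `hhl_params()`, i.e. p_max 0.127 and gain 1.40).
#' @param arms which arms to simulate: subset of `c("control", "exposed")`.
#' @param levels,snrs condition grid; defaults from `config`.
#' @param spectral_profile optional per-token high-frequency energy profile
#'   passed to [generate_token_set()].
#' @param neurons optional neuron metadata tibble (defaults to
#'   [neuron_population()] drawn from the config seed); pass one to vary the
#'   population's parameter distributions.
#' @param keep_drive keep the control driving-probability matrices in the
#'   result (memory-heavy at full size; default FALSE).
#' @return an `ic_cohort` list: `config`, `hhl`, `tokens`, `neurons`, and
#'   `responses`, a tibble with one row per (arm, level, snr) whose `data`
#'   column holds `condition_response` objects (sparse trial-by-feature
#'   matrices with row metadata).
#' @export
#' @examples
#' co <- simulate_cohort(cohort_config(n_neurons = 5, n_trials = 2, seed = 1,
#'                                     snrs = c(0, Inf)),
#'                       arms = "control")
#' co$responses
simulate_cohort <- function(config = cohort_config(), hhl = hhl_params(),
                            arms = c("control", "exposed"),
                            levels = config$levels, snrs = config$snrs,
                            spectral_profile = NULL, neurons = NULL,
                            keep_drive = FALSE) {
  arms <- match.arg(arms, c("control", "exposed"), several.ok = TRUE)
  tokens <- generate_token_set(config, spectral_profile)
  if (is.null(neurons)) neurons <- neuron_population(config)
  stopifnot(nrow(neurons) == config$n_neurons)
  ref_level <- 60 # in-band powers computed once here, then shifted per level

  # per-neuron in-band power matrices per (token, snr, noise realization) at
  # the reference level; the clean condition needs a single realization
  energies <- list()
  for (ti in seq_len(nrow(tokens))) {
    tok <- tokens[ti, ]
    for (snr in snrs) {
      n_pool <- if (is.finite(snr)) config$noise_pool else 1L
      energies[[paste(tok$token_id, snr, sep = "|")]] <-
        lapply(seq_len(n_pool), function(k) {
          nz <- if (is.finite(snr)) {
            make_speech_shaped_noise(
              tokens, config$window_s,
              seed = derive_seed(config$seed,
                                 paste("noise", tok$token_id, snr, k, sep = "|"))
            )
          } else NULL
          wave <- mix_at_snr(tok, nz, ref_level, snr)
          stim_neuron_meansq(wave, neurons, config$fs, config$n_bins,
                             config$window_s)
        })
    }
  }

  drive_ctrl <- list()
  grid <- tidyr::expand_grid(level_db = levels, snr_db = snrs)
  for (gi in seq_len(nrow(grid))) {
    lv <- grid$level_db[gi]; snr <- grid$snr_db[gi]
    for (tid in tokens$token_id) {
      drive_ctrl[[paste(lv, snr, tid, sep = "|")]] <-
        lapply(energies[[paste(tid, snr, sep = "|")]], function(ms) {
          drive_from_meansq(neurons, ms * 10^((lv - ref_level) / 10),
                            bin_s = config$bin_s)
        })
    }
  }

  responses <- purrr::pmap(
    tidyr::expand_grid(arm = arms, level_db = levels, snr_db = snrs),
    function(arm, level_db, snr_db) {
      mats <- lapply(tokens$token_id, function(tid) {
        ps <- drive_ctrl[[paste(level_db, snr_db, tid, sep = "|")]]
        if (arm == "exposed") ps <- lapply(ps, apply_hhl_gain, params = hhl)
        # trial t is driven by noise realization ((t - 1) mod pool) + 1
        sub <- lapply(seq_along(ps), function(k) {
          n_k <- length(seq(k, config$n_trials, by = length(ps)))
          if (n_k == 0) return(NULL)
          sample_spikes(
            ps[[k]], n_k,
            seed = derive_seed(config$seed,
                               paste("raster", arm, level_db, snr_db, tid, k,
                                     sep = "|"))
          )$m
        })
        # interleave the per-realization trial blocks back into trial order
        m <- do.call(rbind, sub[!vapply(sub, is.null, logical(1))])
        ord <- order(unlist(lapply(seq_along(ps), function(k) {
          seq(k, config$n_trials, by = length(ps))
        })))
        m[ord, , drop = FALSE]
      })
      cr <- structure(list(
        m = do.call(rbind, mats),
        rows = tibble(
          token_id = rep(tokens$token_id, each = config$n_trials),
          trial = rep(seq_len(config$n_trials), nrow(tokens))
        ),
        neuron_id = neurons$neuron_id, n_bins = config$n_bins,
        n_trials = config$n_trials,
        arm = arm, level_db = level_db, snr_db = snr_db
      ), class = "condition_response")
      tibble(arm = arm, level_db = level_db, snr_db = snr_db, data = list(cr))
    }
  ) %>% bind_rows()

  out <- list(config = config, hhl = if ("exposed" %in% arms) hhl else NULL,
              tokens = tokens, neurons = neurons, responses = responses)
  if (keep_drive) out$drive <- drive_ctrl
  structure(out, class = "ic_cohort")
}

#' @export
print.ic_cohort <- function(x, ...) {
  cat("<ic_cohort> ", x$config$n_neurons, " neurons, ",
      nrow(x$tokens), " tokens, ", x$config$n_trials, " trials; ",
      nrow(x$responses), " (arm x level x SNR) conditions\n", sep = "")
  invisible(x)
}

#' Extract one condition's responses from a cohort
#'
#' @param cohort an `ic_cohort`.
#' @param arm `"control"` or `"exposed"`.
#' @param level_db,snr_db condition coordinates.
#' @return a `condition_response` object.
#' @export
condition_response <- function(cohort, arm, level_db, snr_db) {
  r <- cohort$responses
  hit <- r$arm == arm & r$level_db == level_db &
    (r$snr_db == snr_db | (is.infinite(snr_db) & is.infinite(r$snr_db)))
  if (!any(hit)) stop("condition not present in cohort: ", arm, " ",
                      level_db, " dB, SNR ", snr_db)
  r$data[[which(hit)[1]]]
}

#' @export
print.condition_response <- function(x, ...) {
  cat("<condition_response> arm=", x$arm, ", ", x$level_db, " dB SPL, SNR ",
      x$snr_db, " dB: ", nrow(x$m), " trials x ", ncol(x$m), " features\n",
      sep = "")
  invisible(x)
}
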