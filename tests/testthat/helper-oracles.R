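# Independent brute-force oracles and small fixture builders.

# plain-loop Euclidean distance
bf_distance <- function(x, y) {
  s <- 0
  for (j in seq_along(x)) s <- s + (x[j] - y[j])^2
  sqrt(s)
}

# exhaustive nearest-template classification, lowest index on ties
bf_classify <- function(trial, template_matrix) {
  d <- rep(NA_real_, nrow(template_matrix))
  for (s in seq_len(nrow(template_matrix))) {
    d[s] <- bf_distance(trial, template_matrix[s, ])
  }
  rownames(template_matrix)[which.min(d)]
}

# build a condition_response from a dense trials x (neurons*bins) matrix
make_cr <- function(m, token_ids, n_trials, n_bins,
                    arm = "control", level_db = 60, snr_db = Inf,
                    neuron_ids = NULL) {
  n_neurons <- ncol(m) / n_bins
  structure(list(
    m = Matrix::Matrix(m, sparse = TRUE),
    rows = tibble::tibble(
      token_id = rep(token_ids, each = n_trials),
      trial = rep(seq_len(n_trials), length(token_ids))
    ),
    neuron_id = neuron_ids %||% sprintf("n%03d", seq_len(n_neurons)),
    n_bins = n_bins, n_trials = n_trials,
    arm = arm, level_db = level_db, snr_db = snr_db
  ), class = "condition_response")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small decoding instance: returns trials, template matrix, rows
random_instance <- function(seed) {
  withr::with_seed(seed, {
    N <- sample(1:3, 1); B <- sample(2:10, 1); S <- sample(2:4, 1)
    toks <- paste0("tok", seq_len(S))
    M <- matrix(runif(S * N * B), S, N * B, dimnames = list(toks, NULL))
    trial <- as.numeric(runif(N * B) < 0.4)
    list(trial = trial, M = M, toks = toks)
  })
}

# one-row fake token tibble with a given waveform, for spectral tests
fake_token <- function(wave, fs, token_id = "TST",
                       bounds = c(0, 0.3, 0.6, 0.9)) {
  tk <- tibble::tibble(
    token_id = token_id, vowel = "A", consonant = "X",
    prop_hf_target = NA_real_,
    formants = list(c(850, 1220)),
    segments = list(tibble::tibble(
      segment = c("V1", "C", "V2"),
      t0 = bounds[1:3], t1 = bounds[2:4]
    )),
    waveform = list(wave), duration = bounds[4]
  )
  attr(tk, "fs") <- fs
  attr(tk, "window_s") <- 1.0
  class(tk) <- c("vcv_tokens", class(tk))
  tk
}
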