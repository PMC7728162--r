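cfg <- cohort_config(n_neurons = 2, n_trials = 2, seed = 11)

test_that("token set honours the requested spectral profile", {
  toks <- generate_token_set(cfg)
  expect_equal(nrow(toks), 11)
  expect_setequal(toks$token_id, vcv_token_ids())
  meas <- compute_hf_energy_proportion(toks, "consonant")
  expect_true(all(abs(meas$prop_hf - toks$prop_hf_target) < 0.05))
  # measured proportions track the requested profile tightly and monotonically
  expect_gt(cor(meas$prop_hf, toks$prop_hf_target), 0.99)
  # strict monotonicity across strictly increasing targets (ties excluded)
  ord <- order(toks$prop_hf_target)
  tgt <- toks$prop_hf_target[ord]
  got <- meas$prop_hf[ord]
  for (i in 1:(length(tgt) - 1)) for (j in (i + 1):length(tgt)) {
    if (tgt[j] - tgt[i] >= 0.05) expect_gt(got[j], got[i])
  }
})

test_that("degenerate all-low profile yields no energy above the cutoff", {
  prof <- setNames(rep(0, 3), c("AMA", "ASA", "ITI"))
  toks <- generate_token_set(cfg, spectral_profile = prof)
  meas <- compute_hf_energy_proportion(toks, "consonant")
  expect_true(all(meas$prop_hf < 0.05))
})

test_that("token generation is deterministic and validates the profile", {
  t1 <- generate_token_set(cfg)
  t2 <- generate_token_set(cfg)
  expect_identical(t1$waveform, t2$waveform)
  # a different seed changes the waveforms
  t3 <- generate_token_set(cohort_config(n_neurons = 2, n_trials = 2, seed = 12))
  expect_false(identical(t1$waveform, t3$waveform))
  expect_error(generate_token_set(cfg, spectral_profile = c(AMA = 1.2)),
               "\\[0, 1\\]")
  expect_error(generate_token_set(cfg, spectral_profile = c(-0.1)), "named")
})

test_that("tokens are 0.9 s, ramped, and tiled by the three segments", {
  toks <- generate_token_set(cfg)
  fs <- attr(toks, "fs")
  for (i in seq_len(nrow(toks))) {
    w <- toks$waveform[[i]]
    expect_equal(length(w), round(0.9 * fs))
    segs <- toks$segments[[i]]
    expect_equal(segs$t0[1], 0)
    expect_equal(segs$t1[3], 0.9)
    expect_equal(segs$t0[-1], segs$t1[-3]) # segments tile without overlap
    # ramped edges: first and last samples small relative to overall RMS
    expect_lt(max(abs(w[1:10])), 0.5 * sqrt(mean(w^2)))
  }
})

test_that("speech-shaped noise matches the token long-term spectrum", {
  toks <- generate_token_set(cfg)
  nz <- make_speech_shaped_noise(toks, 1, seed = 5)
  expect_equal(sqrt(mean(nz^2)), 1, tolerance = 1e-6)
  # reproducible given seed
  expect_identical(as.numeric(nz), as.numeric(make_speech_shaped_noise(toks, 1, seed = 5)))
  expect_error(make_speech_shaped_noise(toks, 0, seed = 1), "positive")

  # low-pass token set -> above-cutoff noise power below 10% of total
  fs <- attr(toks, "fs")
  t <- seq_len(round(0.9 * fs)) / fs
  lp <- fake_token(sin(2 * pi * 500 * t) + 0.5 * sin(2 * pi * 900 * t), fs)
  nlp <- make_speech_shaped_noise(lp, 1, seed = 2)
  P <- Mod(fft(as.numeric(nlp)))^2
  f <- (seq_along(P) - 1) * fs / length(P)
  keep <- f <= fs / 2
  expect_lt(sum(P[keep & f > 2000]) / sum(P[keep]), 0.10)

  # near-white token set -> roughly flat shaped noise (no band dominates)
  set.seed(3)
  wt <- fake_token(rnorm(round(0.9 * fs)), fs)
  nw <- make_speech_shaped_noise(wt, 1, seed = 2)
  Pw <- Mod(fft(as.numeric(nw)))^2
  lo <- sum(Pw[keep & f <= 6000]); hi <- sum(Pw[keep & f > 6000])
  expect_gt(hi / (lo + hi), 0.2)
})

test_that("mixing respects the level and SNR calibration", {
  toks <- generate_token_set(cfg)
  nz <- make_speech_shaped_noise(toks, 1, seed = 7)
  tok <- toks[1, ]
  rms_of <- function(x) sqrt(mean(x^2))
  tgt <- synaptogain:::spl_to_rms(60)

  clean <- mix_at_snr(tok, NULL, 60, Inf)
  expect_equal(rms_of(clean), tgt, tolerance = 1e-9)

  m0 <- mix_at_snr(tok, nz, 60, 0)
  sig <- c(clean, numeric(length(m0) - length(clean)))
  noise_part <- m0 - sig
  expect_equal(rms_of(noise_part), tgt, tolerance = 1e-6)

  m12 <- mix_at_snr(tok, nz, 60, -12)
  noise12 <- m12 - sig
  expect_equal(rms_of(noise12) / rms_of(clean), 10^(12 / 20), tolerance = 1e-6)

  expect_error(mix_at_snr(tok, NULL, 60, 0), "noise")
})
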