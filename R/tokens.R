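#' @section Synthetic VCV tokens:
#' Tokens are synthetic stand-ins for recorded vowel-consonant-vowel utterances.
#' Each token is 0.9 s long inside a 1.0 s analysis window, with a 5-ms
#' raised-cosine onset/offset ramp, and tiles into three half-open segments:
#' initial vowel, consonant, final vowel. Vowels are harmonic complexes with
#' formant-shaped spectral envelopes; consonants are band-limited noise bursts
#' (preceded by a short token-specific closure) whose proportion of energy
#' above a cutoff frequency is directly controllable. Only the envelope
#' structure and the spectral energy split matter downstream, which is what
#' these stimuli reproduce.
#' @name vcv-tokens
NULL

# default per-token target proportion of consonant energy above the 2-kHz
# cutoff; the three x=T tokens share the same consonant and hence one value
.default_hf_profile <- c(
  AMA = 0.08, ANA = 0.12, AGA = 0.20, AKA = 0.30, AZA = 0.40,
  ATA = 0.50, ITI = 0.50, UTU = 0.50, AFA = 0.60, ASHA = 0.75, ASA = 0.85
)

.vowel_formants <- list(
  A = c(850, 1220, 2810, 3800),
  I = c(300, 2300, 3000, 4100),
  U = c(350, 900, 2250, 3700)
)

# fixed per-token fundamental frequency (Hz): one speaker, distinct
# utterances; the three same-consonant tokens are spaced 30 Hz apart so the
# periodicity cue separates them the way their recordings would differ
.token_f0 <- c(
  AMA = 198, ANA = 228, AGA = 210, AKA = 240, AZA = 204, ATA = 192,
  ITI = 222, UTU = 252, AFA = 234, ASHA = 216, ASA = 246
)

# intrinsic vowel duration: high front vowels are shorter, back rounded
# vowels longer; sets the initial-vowel length before per-token jitter
.vowel_v1 <- c(A = 0.35, I = 0.29, U = 0.41)

#' Default VCV token identifiers
#'
#' Nine tokens of the form AxA plus ITI and UTU, giving three tokens (ATA,
#' ITI, UTU) that share the consonant T.
#' @return character vector of 11 token ids.
#' @export
vcv_token_ids <- function() names(.default_hf_profile)

# raised-cosine ramp applied in place at both ends of a segment
ramp_ends <- function(x, fs, ramp_s = 0.005) {
  n <- max(2L, round(ramp_s * fs))
  if (2 * n >= length(x)) return(x)
  w <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = n))
  x[seq_len(n)] <- x[seq_len(n)] * w
  x[length(x) - n + seq_len(n)] <- x[length(x) - n + seq_len(n)] * rev(w)
  x
}

# deterministic per-label draw in [0, 1) from the token-set seed
label_unit <- function(seed, what, label) {
  (derive_seed(seed, paste0(what, "|", label)) %% 9973) / 9973
}

# band-limited Gaussian noise via FFT masking with raised-cosine edges
band_noise <- function(n, fs, f_lo, f_hi, edge_hz = 100) {
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # mirror for the negative-frequency half
  m <- numeric(n)
  m[f >= f_lo & f <= f_hi] <- 1
  lo_edge <- f >= f_lo - edge_hz & f < f_lo
  m[lo_edge] <- 0.5 - 0.5 * cos(pi * (f[lo_edge] - (f_lo - edge_hz)) / edge_hz)
  hi_edge <- f > f_hi & f <= f_hi + edge_hz
  m[hi_edge] <- 0.5 + 0.5 * cos(pi * (f[hi_edge] - f_hi) / edge_hz)
  y <- Re(fft(X * m, inverse = TRUE)) / n
  y / max(rms(y), .Machine$double.eps)
}

# amplitudes/phases of a formant-shaped harmonic complex; the spectral
# envelope rolls off gently above F1, the natural vowel tilt
harmonic_amps <- function(fk, formants) {
  env <- rowSums(sapply(formants, function(F) {
    bw <- 80 + 0.08 * F
    1 / (1 + ((fk - F) / bw)^2)
  }))
  tilt <- pmin(1, (formants[1] / fk)^0.5)
  sqrt(env * tilt^2)
}

# harmonic complex with a formant-shaped spectral envelope; when `to_formants`
# is given, the spectrum crossfades towards it over the final `trans_s`
# seconds (a formant transition towards a consonant locus)
vowel_segment <- function(n, fs, f0, formants, phase_seed,
                          to_formants = NULL, trans_s = 0.10,
                          reverse = FALSE) {
  t <- seq_len(n) / fs
  kmax <- floor((fs / 2 - 500) / f0)
  fk <- f0 * seq_len(kmax)
  # near-coherent harmonic phases approximate the glottal pulse train, giving
  # the deep pitch-rate envelope modulation that midbrain neurons follow
  ph <- withr::with_seed(phase_seed, runif(kmax, 0, 0.4))
  synth <- function(amp) {
    y <- numeric(n)
    for (k in seq_len(kmax)) y <- y + amp[k] * sin(2 * pi * fk[k] * t + ph[k])
    y
  }
  y <- synth(harmonic_amps(fk, formants))
  if (!is.null(to_formants)) {
    y2 <- synth(harmonic_amps(fk, to_formants))
    ntr <- min(n, round(trans_s * fs))
    fade <- numeric(n)
    fade[(n - ntr + 1):n] <- seq(0, 1, length.out = ntr)
    if (reverse) fade <- rev(fade)
    y <- (1 - fade) * y + fade * y2
  }
  y / rms(y)
}

# consonant-specific formant loci that the flanking vowels transition towards;
# F1 drops for closures (nasals/plosives), F2/F3 depend on place
consonant_loci <- function(seed, cons) {
  tr <- consonant_traits(seed, cons)
  f1 <- switch(tr$manner, nasal = 250, plosive = 350, 450)
  c(f1, tr$locus2, tr$locus3, 3800)
}

# per-consonant spectral and temporal signatures, phonetically motivated:
# band centres (Hz) of the low and high noise components, manner class, and
# voicing. Fricative centroids rise from SH to S; nasals are murmur-like.
.consonant_traits <- list(
  M  = list(lo = 400,  hi = 2700, manner = "nasal",     voiced = TRUE,  amp = 0.55, locus2 = 900,  locus3 = 2300),
  N  = list(lo = 1100, hi = 3900, manner = "nasal",     voiced = TRUE,  amp = 0.75, locus2 = 1700, locus3 = 2900),
  G  = list(lo = 650,  hi = 2500, manner = "plosive",   voiced = TRUE,  amp = 1,    locus2 = 1300, locus3 = 2500),
  K  = list(lo = 1100, hi = 3400, manner = "plosive",   voiced = FALSE, amp = 1,    locus2 = 2300, locus3 = 3300),
  Z  = list(lo = 750,  hi = 4500, manner = "fricative", voiced = TRUE,  amp = 1,    locus2 = 1500, locus3 = 2700),
  T  = list(lo = 1550, hi = 5200, manner = "plosive",   voiced = FALSE, amp = 1,    locus2 = 1900, locus3 = 3100),
  F  = list(lo = 950,  hi = 6800, manner = "fricative", voiced = FALSE, amp = 1,    locus2 = 1100, locus3 = 2400),
  S  = list(lo = 1250, hi = 7800, manner = "fricative", voiced = FALSE, amp = 1,    locus2 = 2100, locus3 = 3500),
  SH = list(lo = 600,  hi = 2900, manner = "fricative", voiced = FALSE, amp = 1,    locus2 = 2500, locus3 = 2200)
)

consonant_traits <- function(seed, cons) {
  tr <- .consonant_traits[[toupper(cons)]]
  if (is.null(tr)) {
    tr <- list(lo = 500 * (1400 / 500)^label_unit(seed, "band_lo", cons),
               hi = 2900 * (6500 / 2900)^label_unit(seed, "band_hi", cons),
               manner = "fricative", voiced = FALSE, amp = 1,
               locus2 = 600 + 2200 * label_unit(seed, "locus2", cons),
               locus3 = 2200 + 1200 * label_unit(seed, "locus3", cons))
  }
  tr
}

# consonant: a manner-specific temporal envelope imposed on a two-band noise
# mixture whose power fraction above `cutoff` equals prop_hf. Nasals are a
# sustained low-amplitude murmur; plosives a closure gap, a sharp 60-ms burst
# and weak aspiration; fricatives sustained noise after a brief onset.
# Voiced closures carry a weak harmonic voice bar.
consonant_segment <- function(n, fs, prop_hf, closure_s, cutoff = 2000,
                              noise_seed, seed, cons, f0 = 220) {
  tr <- consonant_traits(seed, cons)
  half_bw <- 2^0.35 # ~0.7-octave bands
  mix <- withr::with_seed(noise_seed, {
    lo <- band_noise(n, fs, max(250, tr$lo / half_bw),
                     min(tr$lo * half_bw, cutoff - 150))
    hi <- band_noise(n, fs, max(tr$hi / half_bw, cutoff + 150),
                     min(tr$hi * half_bw, fs / 2 - 800))
    sqrt(1 - prop_hf) * lo + sqrt(prop_hf) * hi
  })
  mix <- mix / rms(mix)
  env <- rep(1, n)
  n_cl <- round(closure_s * fs)
  if (tr$manner == "nasal") {
    env[] <- tr$amp
  } else if (tr$manner == "plosive") {
    n_b <- round(0.08 * fs)
    env[seq_len(n_cl)] <- 0
    env[n_cl + seq_len(min(n_b, n - n_cl))] <- 2.0
    if (n_cl + n_b < n) env[(n_cl + n_b + 1):n] <- 0.45
  } else { # fricative: brief onset then sustained
    n_on <- round(0.015 * fs)
    env[seq_len(n_on)] <- seq(0, 1, length.out = n_on)
  }
  # smooth envelope steps (3 ms) so they do not splatter energy across bands
  ks <- round(0.003 * fs)
  env <- as.numeric(stats::filter(c(rep(env[1], ks), env, rep(env[n], ks)),
                                  rep(1 / ks, ks), sides = 2))[ks + seq_len(n)]
  out <- mix * env
  if (isTRUE(tr$voiced) && tr$manner == "plosive" && n_cl > 8) {
    t <- seq_len(n_cl) / fs
    mur <- sin(2 * pi * f0 * t) + 0.5 * sin(2 * pi * 2 * f0 * t)
    out[seq_len(n_cl)] <- 0.15 * ramp_ends(mur / rms(mur), fs, 0.003)
  }
  ramp_ends(out, fs, 0.003)
}

#' Generate a synthetic VCV token set
#'
#' Builds the 11 default VCV tokens (or a custom subset via the names of
#' `spectral_profile`). Each token's consonant segment is a band-limited noise
#' burst whose proportion of energy above `cutoff_hz` is set by the profile;
#' tokens sharing a consonant letter share the same burst realization.
#' Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param spectral_profile named numeric vector in \[0, 1\]: target proportion
#'   of consonant energy above `cutoff_hz`, one entry per token id. Defaults to
#'   a fixed profile spanning 0.08-0.85 across the 11 tokens.
#' @param cutoff_hz spectral cutoff for the energy split (default 2000 Hz).
#' @return a `vcv_tokens` tibble with one row per token: `token_id`, `vowel`,
#'   `consonant`, `prop_hf_target`, `formants` (list), `segments` (list of
#'   tibbles with `segment`, `t0`, `t1` in seconds), `waveform` (list),
#'   `duration`. Attributes `fs` and `window_s` carry the sample rate and
#'   analysis window.
#' @export
#' @examples
#' toks <- generate_token_set(cohort_config(seed = 1))
#' toks$token_id
generate_token_set <- function(config = cohort_config(),
                               spectral_profile = NULL,
                               cutoff_hz = 2000) {
  if (is.null(spectral_profile)) spectral_profile <- .default_hf_profile
  if (is.null(names(spectral_profile)) || any(names(spectral_profile) == "")) {
    stop("`spectral_profile` must be a named vector of token ids")
  }
  if (any(spectral_profile < 0 | spectral_profile > 1)) {
    stop("`spectral_profile` values must lie in [0, 1]")
  }
  fs <- config$fs
  dur <- 0.9
  ids <- names(spectral_profile)
  vowel_of <- function(id) substr(id, 1, 1)
  consonant_of <- function(id) substr(id, 2, nchar(id) - 1)

  rows <- purrr::imap(spectral_profile, function(prop, id) {
    v <- vowel_of(id)
    cons <- consonant_of(id)
    if (!v %in% names(.vowel_formants)) {
      stop("no formant definition for vowel '", v, "'")
    }
    # utterance-to-utterance timing variation: segment boundaries start from
    # the vowel's intrinsic duration and shift by up to +/-25 ms per token,
    # as in separately recorded productions
    b1 <- .vowel_v1[[v]] + 0.03 * (label_unit(config$seed, "t1", id) - 0.5)
    b2 <- b1 + 0.20 + 0.05 * (label_unit(config$seed, "t2", id) - 0.5)
    seg_t <- c(0, b1, b2, dur)
    n_seg <- diff(round(seg_t * fs)) # exact sample-aligned boundaries
    f0 <- if (id %in% names(.token_f0)) .token_f0[[id]] else
      190 + 60 * label_unit(config$seed, "f0", id)
    vseed <- derive_seed(config$seed, paste0("vowel|", v))
    cseed <- derive_seed(config$seed, paste0("consonant|", cons))
    loci <- consonant_loci(config$seed, cons)
    # formant transitions into and out of the consonant carry its place cue
    v1 <- ramp_ends(vowel_segment(n_seg[1], fs, f0, .vowel_formants[[v]],
                                  vseed, to_formants = loci), fs, 0.003)
    # closure length is consonant-specific (30-70 ms), a deterministic
    # temporal signature that aids discrimination
    closure <- 0.03 + 0.04 * label_unit(config$seed, "closure", cons)
    cc <- consonant_segment(n_seg[2], fs, prop, closure, cutoff_hz, cseed,
                            config$seed, cons, f0)
    v2 <- ramp_ends(vowel_segment(n_seg[3], fs, f0, .vowel_formants[[v]],
                                  vseed + 1, to_formants = loci,
                                  reverse = TRUE), fs, 0.003)
    w <- ramp_ends(c(v1, cc, v2), fs, 0.005)
    tibble(
      token_id = id, vowel = v, consonant = cons, prop_hf_target = prop,
      formants = list(.vowel_formants[[v]]),
      segments = list(tibble(
        segment = c("V1", "C", "V2"),
        t0 = seg_t[1:3], t1 = seg_t[2:4]
      )),
      waveform = list(w / rms(w)),
      duration = dur
    )
  })
  out <- bind_rows(rows)
  attr(out, "fs") <- fs
  attr(out, "window_s") <- config$window_s
  attr(out, "cutoff_hz") <- cutoff_hz
  class(out) <- c("vcv_tokens", class(out))
  out
}

#' Speech-shaped background noise
#'
#' Gaussian noise whose long-term power spectrum matches the average spectrum
#' of the supplied token set (smoothed with a running mean of stated
#' bandwidth). The waveform spans the full `duration` and is normalized to
#' unit RMS; [mix_at_snr()] applies level scaling.
#'
#' @param tokens a `vcv_tokens` tibble from [generate_token_set()].
#' @param duration noise duration in seconds (default 1.0).
#' @param seed integer seed for the random phases.
#' @param smooth_hz smoothing bandwidth of the spectral target in Hz
#'   (default 100).
#' @return numeric waveform of length `duration * fs` with attribute `fs`.
#' @export
make_speech_shaped_noise <- function(tokens, duration = 1.0, seed = 1,
                                     smooth_hz = 100) {
  stopifnot(inherits(tokens, "vcv_tokens"))
  if (nrow(tokens) == 0) stop("empty token set")
  if (duration <= 0) stop("`duration` must be positive")
  fs <- attr(tokens, "fs")
  n <- round(duration * fs)
  # average token power spectrum on the output frequency grid
  pows <- sapply(tokens$waveform, function(w) {
    wp <- c(w, numeric(max(0, n - length(w))))[seq_len(n)]
    Mod(fft(wp))^2
  })
  target <- rowMeans(pows)
  k <- max(1L, round(smooth_hz * duration)) # bins per smoothing bandwidth
  kern <- rep(1 / (2 * k + 1), 2 * k + 1)
  sm <- stats::filter(c(rev(target[seq_len(k)]), target, rev(target)[seq_len(k)]),
                      kern, sides = 2)
  target <- as.numeric(sm[k + seq_len(n)])
  target[is.na(target)] <- 0
  mag <- sqrt(pmax(target, 0))
  y <- withr::with_seed(seed, {
    half <- floor(n / 2)
    ph <- runif(half - 1, 0, 2 * pi)
    X <- complex(modulus = mag, argument = 0)
    X[2:half] <- complex(modulus = mag[2:half], argument = ph)
    X[n:(n - half + 2)] <- Conj(X[2:half])
    Re(fft(X, inverse = TRUE)) / n
  })
  y <- y / rms(y)
  attr(y, "fs") <- fs
  y
}

#' Mix a token with noise at a given level and SNR
#'
#' The token RMS (over its 0.9-s extent) is scaled to `level_db` dB SPL; the
#' noise RMS is scaled to `level_db - snr_db`. `snr_db = Inf` encodes the
#' clean condition and returns the scaled token alone. The token is placed at
#' the start of the window; the noise runs continuously over the full window.
#'
#' @param token one row of a `vcv_tokens` tibble, or a numeric waveform.
#' @param noise numeric noise waveform (from [make_speech_shaped_noise()]);
#'   ignored when `snr_db = Inf`.
#' @param level_db presentation level in dB SPL (e.g. 60 or 75).
#' @param snr_db signal-to-noise ratio in dB, or `Inf` for clean.
#' @return numeric waveform of the mixture, padded to the noise length (or
#'   token length if clean), with attribute `fs` when available.
#' @export
mix_at_snr <- function(token, noise = NULL, level_db, snr_db) {
  w <- if (is.data.frame(token)) token$waveform[[1]] else as.numeric(token)
  fs <- if (is.data.frame(token)) attr(token, "fs") else attr(token, "fs")
  stopifnot(is.finite(level_db))
  if (!(is.finite(snr_db) || is.infinite(snr_db) && snr_db > 0)) {
    stop("`snr_db` must be finite or +Inf")
  }
  sig <- w * spl_to_rms(level_db) / rms(w)
  if (is.infinite(snr_db)) {
    out <- sig
  } else {
    if (is.null(noise)) stop("noise waveform required for finite SNR")
    nz <- as.numeric(noise) * spl_to_rms(level_db - snr_db) / rms(noise)
    n <- max(length(sig), length(nz))
    out <- c(sig, numeric(n - length(sig))) + c(nz, numeric(n - length(nz)))
  }
  if (!is.null(fs)) attr(out, "fs") <- fs
  out
}
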