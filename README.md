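# synaptogain

Simulation and decoding of auditory-midbrain population responses to speech
in noise, under cochlear synaptopathy ("hidden hearing loss") with
compensatory central gain.

## The problem

Loud-noise exposure can destroy synapses between inner hair cells and
high-threshold auditory-nerve fibers while leaving audiometric thresholds
normal. Downstream, inferior-colliculus (IC) neurons then lose input mainly
at high sound levels, and the central auditory system compensates with
multiplicative gain. The perceptual signature is level-dependent: speech in
noise becomes *harder* to discriminate at high sound levels, and can even
become *easier* at moderate levels where the extra gain boosts an
undamaged, unsaturated response.

`synaptogain` is for auditory and computational neuroscientists who want a
tested, fully synthetic implementation of that analysis chain:

1. **Cohort simulation** — vowel-consonant-vowel (VCV) tokens with
   controllable spectral energy above a cutoff, speech-shaped noise mixed at
   calibrated dB SPL levels and SNRs, characteristic-frequency-tuned IC
   neurons with sigmoid rate-level functions, and Bernoulli-per-bin spike
   sampling at 1-ms resolution.
2. **PSTH template-matching classifier** — a single trial's population
   response vector `v_i` (length *N* neurons x *B* bins) is assigned to the
   clean-speech template with minimum Euclidean distance, where template
   `v̄^s_j = (1/T) Σ_i v^s_ij` is the trial-mean response to token *s*; the
   clean condition is decoded leave-one-out.
3. **The HHL + central-gain model** — the broken-stick transform
   `p' = g · min(p, p_sat)` with knee `p_sat = p_max / g`; with the
   population maximum `p_max = 0.127` (probability per 1-ms bin) and gain
   `g = 1.40`, the knee is `0.09`. Applied to control firing probabilities
   it produces the "exposed" arm; both arms are resampled and decoded on
   equal footing.
4. **Trial-level statistics** — binomial logistic regression of correctness
   on exposure x level x SNR x high-frequency energy proportion with
   interactions to order 4, per-term likelihood-ratio tests, per-level fits
   with Bonferroni correction, and non-parametric group comparisons
   (Fisher's exact test on octave-binned CFs, Wilcoxon rank-sum thresholds,
   Kruskal-Wallis across levels, Friedman across arms, Shapiro-Wilk screen).

## A worked example

```r
library(synaptogain)

cfg <- cohort_config(n_neurons = 60, n_trials = 16, seed = 1)
bundle <- run_experiment(cfg, hhl = hhl_params(p_max = 0.127, gain = 1.40))
bundle$performance %>% tidyr::pivot_wider(id_cols = c(arm, level_db),
                                          names_from = snr_db,
                                          values_from = mean_pc)
```

```
  arm     level_db `-12`  `-6`   `0`   `6`  `12` `Inf`
1 control       60 21.6   82.4 100     100   100   100
2 control       75 13.6   34.1  96.0   100   100   100
3 exposed       60 22.7   88.1 100     100   100   100
4 exposed       75  9.09  12.5  57.4   100   100   100
```

Reading the table: each number is the mean percent correct over 16 trials of
11-way token classification (chance ≈ 9.1%). Clean speech (`Inf`) decodes
perfectly in every arm; performance falls monotonically as the masker grows;
and the hidden-hearing-loss arm is *better* than control at 60 dB SPL
(88.1 vs 82.4 at −6 dB SNR — the central gain boosts an unsaturated
response) but *worse* at 75 dB SPL (57.4 vs 96.0 at 0 dB SNR — saturation
above the knee erases between-token differences).

The trial-level logistic regression recovers the same pattern.
`tidy(bundle$fits$full)` gives the per-term likelihood-ratio table — on this
run the exposure main effect (chi-square(1) = 39.3, p = 3.6e-10) and the
exposure x level interaction (chi-square(1) = 26.0, p = 3.5e-7) are both
significant — and the per-level fits resolve the interaction's direction:

```
  level_db     term estimate     chisq df      p_value p_bonferroni
1       60 exposure    0.631  1.407438  1 2.354821e-01 4.709643e-01
2       75 exposure   -1.583 81.840477  1 1.475261e-19 2.950522e-19
```

`plot_performance(bundle)` draws the percent-correct-versus-SNR curves with
SEM bars; `bundle$rate_summary` shows the exposed arm firing ~1.4x faster at
60 dB SPL; `bundle$comparisons` holds the non-parametric battery (the
CF-matched populations give Fisher's exact p = 1.000).

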