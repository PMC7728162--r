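fs <- 24000
tt <- seq_len(round(0.9 * fs)) / fs

test_that("high-frequency energy proportion integrates the periodogram", {
  tone4k <- fake_token(sin(2 * pi * 4000 * tt), fs)
  expect_gt(compute_hf_energy_proportion(tone4k[1, ], "consonant"), 0.99)
  tone500 <- fake_token(sin(2 * pi * 500 * tt), fs)
  expect_lt(compute_hf_energy_proportion(tone500[1, ], "consonant"), 0.01)
  # equal-power two-line spectrum splits 50/50 (Parseval)
  mix <- fake_token(sin(2 * pi * 1000 * tt) + sin(2 * pi * 3000 * tt), fs)
  expect_equal(compute_hf_energy_proportion(mix[1, ], "consonant"), 0.5,
               tolerance = 0.01)
  # the ear filter reweights the spectrum before integration
  hp_gain <- function(f) ifelse(f > 2000, 2, 1)
  expect_equal(
    compute_hf_energy_proportion(mix[1, ], "consonant", ear_filter = hp_gain),
    4 / 5, tolerance = 0.01)
  # vowel segment selector concatenates both vowels
  expect_equal(compute_hf_energy_proportion(mix[1, ], "vowel"), 0.5,
               tolerance = 0.01)
  empty <- fake_token(c(numeric(round(0.6 * fs)),
                        sin(2 * pi * 500 * tt[1:(round(0.3 * fs))])), fs)
  expect_error(compute_hf_energy_proportion(empty[1, ], "consonant"), "empty")
})

# small synthetic outcome table with a known generative model
sim_table <- function(seed, b_exposure = 0, n_trials = 12,
                      b_snr = 0.22, b_prop = 1.0) {
  withr::with_seed(seed, {
    g <- tidyr::expand_grid(
      exposure = c("control", "exposed"), level_db = c(60, 75),
      snr_db = c(-12, -6, 0, 6, 12),
      token_id = paste0("t", 1:11), trial = seq_len(n_trials)
    )
    prop <- setNames(runif(11), paste0("t", 1:11))
    g$prop_hf <- prop[g$token_id]
    g$prop_hf_vowel <- g$prop_hf
    eta <- -0.3 + b_snr * g$snr_db + b_prop * g$prop_hf +
      b_exposure * (g$exposure == "exposed")
    g$correct <- rbinom(nrow(g), 1, plogis(eta))
    g
  })
}

test_that("the LRT loop matches explicit nested-model deviance differencing", {
  tab <- sim_table(31)
  fit <- fit_correctness_model(tab)
  expect_s3_class(fit, "correctness_fit")
  labels <- attr(terms(fit$formula), "term.labels")
  expect_setequal(tidy(fit)$term, labels)
  # oracle: for each tested term, explicitly fit the pair of nested models
  # (all terms not containing the term, with and without it) and difference
  # their deviances
  vars_of <- lapply(strsplit(labels, ":", fixed = TRUE), sort)
  for (tm in withr::with_seed(1, sample(labels, 5))) {
    vt <- sort(strsplit(tm, ":", fixed = TRUE)[[1]])
    base <- labels[!vapply(vars_of, function(v) all(vt %in% v), logical(1))]
    m0 <- glm(stats::reformulate(base, "correct"),
              data = fit$model$model, family = binomial())
    m1 <- glm(stats::reformulate(c(base, tm), "correct"),
              data = fit$model$model, family = binomial())
    want <- m0$deviance - m1$deviance
    expect_equal(tidy(fit)$chisq[tidy(fit)$term == tm], want,
                 tolerance = 1e-8)
  }
  # every term appears with a finite p-value and df >= 1
  expect_true(all(is.finite(tidy(fit)$p_value)))
  expect_true(all(tidy(fit)$df >= 1))
})

test_that("a strong SNR effect is detected and the exposure null is retained", {
  tab <- sim_table(32)
  fit <- fit_correctness_model(tab)
  lrt <- tidy(fit)
  expect_lt(lrt$p_value[lrt$term == "snr"], 1e-10)
  expect_gt(lrt$p_value[lrt$term == "exposure"], 0.001)
})

test_that("degenerate outcomes raise a separation error", {
  tab <- sim_table(33)
  tab$correct <- 1L
  expect_error(fit_correctness_model(tab), "separation")
})

test_that("clean rows are excluded unless requested", {
  tab <- sim_table(34)
  quiet <- tab[tab$snr_db == 12, ]
  quiet$snr_db <- Inf
  fit <- fit_correctness_model(dplyr::bind_rows(tab, quiet))
  expect_equal(fit$n, nrow(tab))
})

test_that("term exclusions and the vowel covariate are honoured", {
  tab <- sim_table(35)
  fit <- fit_correctness_model(tab, hf = "vowel",
                               exclude_terms = "exposure:level:snr:prop")
  expect_false("exposure:level:snr:prop" %in% tidy(fit)$term)
})

test_that("per-level fits drop level terms and Bonferroni-correct", {
  tab <- sim_table(36)
  lf <- fit_per_level_logistic(tab)
  expect_s3_class(lf, "level_fits")
  expect_setequal(unique(lf$level_db), c(60, 75))
  expect_false(any(grepl("level", lf$term)))
  expect_equal(lf$p_bonferroni, pmin(lf$p_value * 2, 1))
})

test_that("group comparisons cover the full battery", {
  withr::with_seed(37, {
    meta_c <- tibble::tibble(neuron_id = paste0("c", 1:40),
                             cf = exp(runif(40, log(250), log(8192))),
                             threshold = rnorm(40, 31, 6))
    meta_e <- meta_c
    meta_e$neuron_id <- paste0("e", 1:40)
    rates <- tidyr::expand_grid(arm = c("control", "exposed"),
                                level_db = c(60, 75), snr_db = c(0, Inf),
                                neuron_id = paste0("n", 1:40)) %>%
      dplyr::mutate(rate_hz = rgamma(dplyr::n(), 4, 0.2) +
                      10 * (level_db == 75))
  })
  rep <- suppressWarnings(compare_groups(rates, meta_c, meta_e))
  expect_setequal(
    unique(rep$test),
    c("fisher_cf", "wilcoxon_threshold", "kruskal_wallis_level",
      "friedman_exposure", "shapiro_wilk_rate")
  )
  # identical CF multisets give Fisher p = 1
  expect_equal(rep$p_value[rep$test == "fisher_cf"], 1)
  # identical threshold distributions: rank-sum far from significant
  expect_gt(rep$p_value[rep$test == "wilcoxon_threshold"], 0.9)
  # strong level effect on rates: Kruskal-Wallis detects it
  expect_lt(max(rep$p_value[rep$test == "kruskal_wallis_level"]), 0.01)
})

test_that("a 3-dB threshold shift is detected by the rank-sum test with power", {
  hits <- 0
  for (i in 1:60) {
    withr::with_seed(100 + i, {
      a <- rnorm(154, 31, 6)
      b <- rnorm(154, 28, 6)
    })
    p <- wilcox.test(a, b, correct = TRUE, exact = FALSE)$p.value
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / 60, 0.8)
})
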