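#' Proportion of segment energy above a cutoff frequency
#'
#' Extracts the requested segment of a token, optionally applies an outer/
#' middle-ear transfer function, and integrates the periodogram above and
#' below the cutoff. The ear filter defaults to identity; any magnitude
#' transfer function of frequency (Hz) can be supplied.
#'
#' @param token one row of a `vcv_tokens` tibble (or the full tibble, then a
#'   tibble of proportions is returned).
#' @param segment `"consonant"` (the C segment) or `"vowel"` (both V segments
#'   concatenated); `"V1"`, `"C"`, `"V2"` select single segments.
#' @param cutoff_hz cutoff frequency (default 2000).
#' @param ear_filter optional function(freq_hz) -> magnitude gain.
#' @return a proportion in \[0, 1\], or a tibble (`token_id`, `segment`,
#'   `prop_hf`) for a multi-row input.
#' @export
#' @examples
#' toks <- generate_token_set(cohort_config(seed = 1))
#' compute_hf_energy_proportion(toks[1, ], "consonant")
compute_hf_energy_proportion <- function(token, segment = "consonant",
                                         cutoff_hz = 2000, ear_filter = NULL) {
  stopifnot(is.data.frame(token))
  if (nrow(token) > 1) {
    props <- vapply(seq_len(nrow(token)), function(i) {
      tk <- token[i, ]
      attr(tk, "fs") <- attr(token, "fs")
      compute_hf_energy_proportion(tk, segment, cutoff_hz, ear_filter)
    }, numeric(1))
    return(tibble(token_id = token$token_id, segment = segment,
                  prop_hf = props))
  }
  fs <- attr(token, "fs")
  segs <- token$segments[[1]]
  w <- token$waveform[[1]]
  pick <- function(name) {
    r <- segs[segs$segment == name, ]
    w[(round(r$t0 * fs) + 1):round(r$t1 * fs)]
  }
  x <- switch(segment,
    consonant = , C = pick("C"),
    vowel = c(pick("V1"), pick("V2")),
    V1 = pick("V1"), V2 = pick("V2"),
    stop("unknown segment '", segment, "'")
  )
  if (length(x) == 0 || all(x == 0)) stop("empty segment")
  n <- length(x)
  P <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  P <- P[half]; f <- f[half]
  if (!is.null(ear_filter)) P <- P * ear_filter(f)^2
  sum(P[f > cutoff_hz]) / sum(P)
}

#' Trial-level outcome table
#'
#' One row per classification event across the whole experiment, joined with
#' the tokens' measured spectral covariates: the proportion of consonant
#' (and vowel) energy above the cutoff. This is the input to the regression
#' stage.
#'
#' @param clsf a `classification_set` from [classify_experiment()].
#' @param tokens the `vcv_tokens` used to generate the cohort.
#' @param cutoff_hz spectral cutoff for the covariates (default 2000).
#' @param ear_filter optional transfer function, see
#'   [compute_hf_energy_proportion()].
#' @return tibble: `exposure`, `level_db`, `snr_db`, `token_id`, `trial`,
#'   `correct`, `prop_hf`, `prop_hf_vowel`.
#' @export
trial_outcome_table <- function(clsf, tokens, cutoff_hz = 2000,
                                ear_filter = NULL) {
  stopifnot(inherits(clsf, "classification_set"))
  hf_c <- compute_hf_energy_proportion(tokens, "consonant", cutoff_hz, ear_filter)
  hf_v <- compute_hf_energy_proportion(tokens, "vowel", cutoff_hz, ear_filter)
  cov <- tibble(token_id = hf_c$token_id, prop_hf = hf_c$prop_hf,
                prop_hf_vowel = hf_v$prop_hf)
  purrr::pmap(clsf, function(arm, level_db, snr_db, overall_pc, result) {
    result$predictions %>%
      mutate(exposure = arm, level_db = level_db, snr_db = snr_db) %>%
      select("exposure", "level_db", "snr_db", "token_id", "trial", "correct")
  }) %>%
    bind_rows() %>%
    left_join(cov, by = "token_id")
}

# fit one binomial GLM and guard against separation
fit_binomial <- function(formula, data) {
  if (length(unique(data$correct)) < 2) {
    stop("perfect separation: the outcome is constant; ",
         "drop terms or conditions (all-correct/all-wrong table)")
  }
  fit <- suppressWarnings(glm(formula, data = data, family = binomial()))
  mu <- fitted(fit)
  if (all(mu > 1 - 1e-8 | mu < 1e-8)) {
    stop("perfect separation in the logistic fit; drop interaction terms ",
         "(see `exclude_terms`)")
  }
  fit
}

# marginality-respecting (type II) likelihood-ratio test per term: the term
# is added last to the model containing every term that does not contain it,
# and the deviances of the two nested fits are differenced. Main effects are
# thereby tested without their own interactions in the model (dropping a
# factor main effect from a full factorial fit only reparameterizes it and
# gives a zero-df comparison).
lrt_by_term <- function(full, data, terms_tested = NULL) {
  labels <- attr(terms(full), "term.labels")
  if (is.null(terms_tested)) terms_tested <- labels
  asgn <- attr(stats::model.matrix(full), "assign")
  cf <- summary(full)$coefficients
  vars_of <- lapply(strsplit(labels, ":", fixed = TRUE), sort)
  fit_sub <- function(labs) {
    f <- if (length(labs) == 0) correct ~ 1 else
      stats::reformulate(labs, response = "correct")
    suppressWarnings(glm(f, data = data, family = binomial()))
  }
  purrr::map(match(terms_tested, labels), function(i) {
    contains_i <- vapply(vars_of, function(v) all(vars_of[[i]] %in% v),
                         logical(1))
    base <- labels[!contains_i]
    reduced <- fit_sub(base)
    with_t <- fit_sub(c(base, labels[i]))
    chisq <- reduced$deviance - with_t$deviance
    df <- with_t$rank - reduced$rank
    cols <- which(asgn == i)
    cname <- colnames(stats::model.matrix(full))[cols]
    one_df <- length(cols) == 1 && !is.na(coef(full)[cname]) &&
      cname %in% rownames(cf)
    tibble(
      term = labels[i],
      estimate = if (one_df) unname(coef(full)[cname]) else NA_real_,
      z_wald = if (one_df) unname(cf[cname, "z value"]) else NA_real_,
      chisq = chisq, df = df,
      p_value = pchisq(chisq, df = df, lower.tail = FALSE)
    )
  }) %>% bind_rows()
}

#' Logistic regression of classification correctness
#'
#' Models per-trial correctness with exposure and level as categorical and
#' SNR and the high-frequency energy proportion as continuous explanatory
#' variables, with all interactions up to order 4. Each term's significance
#' is a marginality-respecting (type II) likelihood-ratio chi-square: the
#' term is added last to the model holding every term that does not contain
#' it, and the two fits' deviances are differenced. Wald z statistics
#' accompany single-degree-of-freedom terms.
#'
#' Clean (SNR = Inf) rows are excluded by default since SNR enters as a
#' continuous covariate; set `include_clean = TRUE` to keep them with a
#' numeric recoding of your choice already applied.
#'
#' @param table a [trial_outcome_table()].
#' @param hf which energy covariate to use: `"consonant"` (`prop_hf`) or
#'   `"vowel"` (`prop_hf_vowel`).
#' @param include_clean keep infinite-SNR rows (default FALSE).
#' @param exclude_terms character vector of term labels to drop (e.g.
#'   high-order interactions that cause perfect separation).
#' @param max_order maximum interaction order (default 4).
#' @param lrt_terms restrict the likelihood-ratio loop to these term labels
#'   (default: all terms); the full model is fitted either way.
#' @return a `correctness_fit`: the glm, the per-term LRT table, and metadata.
#'   Use [tidy()][generics::tidy()] / [glance()][generics::glance()].
#' @export
fit_correctness_model <- function(table, hf = c("consonant", "vowel"),
                                  include_clean = FALSE,
                                  exclude_terms = NULL, max_order = 4,
                                  lrt_terms = NULL) {
  hf <- match.arg(hf)
  d <- table
  if (!include_clean) d <- d %>% filter(is.finite(.data$snr_db))
  if (nrow(d) == 0) stop("no finite-SNR rows in the table")
  d <- d %>% mutate(
    exposure = factor(.data$exposure),
    level = factor(.data$level_db),
    snr = .data$snr_db,
    prop = if (hf == "consonant") .data$prop_hf else .data$prop_hf_vowel
  )
  vars <- c("exposure", "snr", "prop")
  if (length(unique(d$level)) > 1) vars <- c("exposure", "level", "snr", "prop")
  fml <- as.formula(paste(
    "correct ~ (", paste(vars, collapse = " + "), ")^", max_order))
  labels <- attr(terms(fml), "term.labels")
  labels <- setdiff(labels, exclude_terms)
  fml <- stats::reformulate(labels, response = "correct")
  full <- fit_binomial(fml, d)
  structure(list(
    model = full, lrt = lrt_by_term(full, d, lrt_terms), formula = fml,
    hf = hf, n = nrow(d)
  ), class = "correctness_fit")
}

#' @export
print.correctness_fit <- function(x, ...) {
  cat("<correctness_fit> ", x$n, " trials; ", nrow(x$lrt), " terms (",
      x$hf, " energy covariate)\n", sep = "")
  print(x$lrt, n = Inf)
  invisible(x)
}

#' Per-level logistic models with Bonferroni correction
#'
#' Fits [fit_correctness_model()] separately within each sound level (level
#' terms dropped) and Bonferroni-corrects the likelihood-ratio p-values
#' across the number of levels.
#'
#' @inheritParams fit_correctness_model
#' @return a `level_fits` tibble: one row per (level, term) with `estimate`,
#'   `z_wald`, `chisq`, `df`, `p_value`, `p_bonferroni`; the fits themselves
#'   are in the `fits` attribute.
#' @export
fit_per_level_logistic <- function(table, hf = c("consonant", "vowel"),
                                   include_clean = FALSE,
                                   exclude_terms = NULL, max_order = 3) {
  hf <- match.arg(hf)
  levels <- sort(unique(table$level_db))
  fits <- lapply(levels, function(lv) {
    fit_correctness_model(table %>% filter(.data$level_db == lv), hf = hf,
                          include_clean = include_clean,
                          exclude_terms = exclude_terms, max_order = max_order)
  })
  out <- purrr::map2(levels, fits, function(lv, f) {
    f$lrt %>% mutate(level_db = lv, .before = 1)
  }) %>%
    bind_rows() %>%
    mutate(p_bonferroni = pmin(.data$p_value * length(levels), 1),
           correction = "bonferroni")
  attr(out, "fits") <- fits
  class(out) <- c("level_fits", class(out))
  out
}

# octave bins spanning the CF range (250-8192 Hz by default)
octave_breaks <- function(f_range = c(250, 8192)) {
  2^seq(floor(log2(f_range[1])), ceiling(log2(f_range[2])), by = 1)
}

#' Non-parametric group comparisons
#'
#' The battery of distribution-level checks: CF distributions compared by
#' Fisher's exact test on octave-binned counts; response thresholds by the
#' Wilcoxon rank-sum test with continuity correction; spike rates across
#' levels (within arm) by the Kruskal-Wallis test; spike rates across
#' exposure arms (paired within matched neuron, per level) by the Friedman
#' test; normality of the rates screened by Shapiro-Wilk.
#'
#' @param rates a [neuron_rates()] tibble with both arms.
#' @param control_meta,exposed_meta neuron metadata tibbles (`neuron_id`,
#'   `cf`, `threshold`) for the two groups.
#' @param cf_breaks bin edges in Hz for the CF comparison (default octave
#'   bins over 250-8192 Hz). Bins empty in both groups are collapsed with a
#'   warning.
#' @return tibble: `test`, `subset`, `statistic`, `df`, `p_value`, `note`.
#' @export
compare_groups <- function(rates, control_meta, exposed_meta,
                           cf_breaks = octave_breaks()) {
  res <- list()
  # CF distributions: Fisher's exact test on binned counts
  br <- sort(unique(c(0, cf_breaks, Inf)))
  tab <- rbind(
    control = table(cut(control_meta$cf, br)),
    exposed = table(cut(exposed_meta$cf, br))
  )
  empty <- colSums(tab) == 0
  if (any(empty)) {
    warning(sum(empty), " empty CF bin(s) collapsed")
    tab <- tab[, !empty, drop = FALSE]
  }
  ft <- fisher.test(tab, workspace = 2e7)
  res$fisher <- tibble(test = "fisher_cf", subset = "all",
                       statistic = NA_real_, df = NA_real_,
                       p_value = ft$p.value,
                       note = paste(ncol(tab), "CF bins"))
  # thresholds: Wilcoxon rank-sum
  wt <- wilcox.test(control_meta$threshold, exposed_meta$threshold,
                    correct = TRUE, exact = FALSE)
  res$wilcox <- tibble(test = "wilcoxon_threshold", subset = "all",
                       statistic = unname(wt$statistic), df = NA_real_,
                       p_value = wt$p.value, note = "rank sum, continuity corrected")
  # rates across levels within each arm: Kruskal-Wallis (needs >= 2 levels)
  if (length(unique(rates$level_db)) > 1) {
    for (a in unique(rates$arm)) {
      sub <- rates %>% filter(.data$arm == a)
      kw <- kruskal.test(sub$rate_hz, factor(sub$level_db))
      res[[paste0("kw_", a)]] <- tibble(
        test = "kruskal_wallis_level", subset = a,
        statistic = unname(kw$statistic), df = unname(kw$parameter),
        p_value = kw$p.value, note = "rate ~ level")
    }
  }
  # rates across exposure, paired within neuron, per level: Friedman
  if (all(c("control", "exposed") %in% rates$arm)) {
    for (lv in unique(rates$level_db)) {
      sub <- rates %>%
        filter(.data$level_db == lv) %>%
        group_by(.data$arm, .data$neuron_id) %>%
        summarise(rate_hz = mean(.data$rate_hz), .groups = "drop")
      fr <- friedman.test(rate_hz ~ arm | neuron_id, data = sub)
      res[[paste0("fr_", lv)]] <- tibble(
        test = "friedman_exposure", subset = paste0(lv, " dB"),
        statistic = unname(fr$statistic), df = unname(fr$parameter),
        p_value = fr$p.value, note = "rate ~ exposure | neuron")
    }
  }
  # normality screen
  for (a in unique(rates$arm)) {
    x <- rates$rate_hz[rates$arm == a]
    if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
    if (length(unique(x)) > 1 && length(x) >= 3) {
      sw <- shapiro.test(x)
      res[[paste0("sw_", a)]] <- tibble(
        test = "shapiro_wilk_rate", subset = a,
        statistic = unname(sw$statistic), df = NA_real_,
        p_value = sw$p.value, note = "normality screen")
    }
  }
  bind_rows(res)
}
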