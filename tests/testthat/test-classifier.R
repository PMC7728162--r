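test_that("templates implement the trial-mean definition", {
  # one neuron, 2 bins, trials [[0,1],[1,1]] -> template [0.5, 1]
  cr <- make_cr(rbind(c(0, 1), c(1, 1)), "AMA", n_trials = 2, n_bins = 2)
  tpl <- build_templates(cr)
  expect_equal(unname(tpl$values["AMA", ]), c(0.5, 1))

  # T = 1: the template equals the single trial
  cr1 <- make_cr(matrix(c(1, 0, 1), 1), "AMA", n_trials = 1, n_bins = 3)
  expect_equal(unname(build_templates(cr1)$values["AMA", ]), c(1, 0, 1))

  # only clean responses may build templates
  cr_noisy <- make_cr(rbind(c(0, 1)), "AMA", n_trials = 1, n_bins = 2,
                      snr_db = 0)
  expect_error(build_templates(cr_noisy), "clean")
})

test_that("euclidean distance is the true metric", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  x <- runif(20)
  expect_equal(euclidean_distance(x, x), 0)
  expect_error(euclidean_distance(1:3, 1:4), "length mismatch")
  # symmetry and triangle inequality on random vectors
  withr::with_seed(8, {
    for (i in 1:20) {
      a <- rnorm(15); b <- rnorm(15); c <- rnorm(15)
      expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
      expect_lte(euclidean_distance(a, c),
                 euclidean_distance(a, b) + euclidean_distance(b, c) + 1e-12)
      expect_equal(euclidean_distance(a, b), bf_distance(a, b))
    }
  })
})

test_that("classification agrees with the brute-force oracle on 1000 instances", {
  for (i in 1:1000) {
    inst <- random_instance(i)
    tpl <- structure(list(values = inst$M, token_ids = inst$toks,
                          n_trials = 2, arm = "control", level_db = 60),
                     class = "vcv_templates")
    got <- suppressWarnings(classify_trial(inst$trial, tpl))
    expect_identical(got, bf_classify(inst$trial, inst$M))
  }
})

test_that("ties break to the lowest token index with a warning", {
  M <- rbind(a = c(1, 0), b = c(0, 1), c = c(5, 5))
  tpl <- structure(list(values = M, token_ids = rownames(M), n_trials = 2,
                        arm = "control", level_db = 60),
                   class = "vcv_templates")
  expect_warning(pred <- classify_trial(c(0.5, 0.5), tpl), "tie")
  expect_identical(pred, "a")
})

test_that("leave-one-out removes the tested trial from its own template", {
  withr::with_seed(10, {
    m <- matrix(rbinom(6 * 12, 1, 0.4), 6, 12)
  })
  cr <- make_cr(m, c("A", "B"), n_trials = 3, n_bins = 4)
  tpl <- build_templates(cr)
  # direct recomputation from the remaining 2 trials
  for (i in 1:3) {
    trial <- m[i, ]
    loo_direct <- colMeans(m[setdiff(1:3, i), , drop = FALSE])
    d_self <- euclidean_distance(trial, loo_direct)
    d_other <- euclidean_distance(trial, tpl$values["B", ])
    want <- if (d_self < d_other) "A" else "B"
    got <- classify_trial(trial, tpl, exclude_self = TRUE, true_token = "A")
    expect_identical(got, want)
  }
  # batch path agrees with per-trial path
  res <- classify_condition(cr, tpl, exclude_self = TRUE)
  per_trial <- vapply(seq_len(nrow(m)), function(i) {
    classify_trial(m[i, ], tpl, exclude_self = TRUE,
                   true_token = cr$rows$token_id[i])
  }, character(1))
  expect_identical(res$predictions$predicted, unname(per_trial))
})

test_that("trials identical to their templates classify perfectly", {
  withr::with_seed(11, {
    base <- matrix(runif(3 * 30), 3, 30,
                   dimnames = list(c("A", "B", "C"), NULL))
  })
  m <- base[rep(1:3, each = 4), ]
  cr <- make_cr(m, c("A", "B", "C"), n_trials = 4, n_bins = 10)
  res <- classify_condition(cr, build_templates(cr), exclude_self = FALSE)
  expect_equal(res$overall_pc, 100)
  expect_true(all(res$trial_pc$percent_correct == 100))
  expect_equal(unname(diag(res$confusion)), rep(4, 3))
})

test_that("confusion rows always sum to the trial count", {
  withr::with_seed(12, {
    m <- matrix(rbinom(8 * 20, 1, 0.3), 8, 20)
  })
  cr <- make_cr(m, c("A", "B"), n_trials = 4, n_bins = 10, snr_db = 0)
  clean <- make_cr(matrix(rbinom(8 * 20, 1, 0.3), 8, 20), c("A", "B"),
                   n_trials = 4, n_bins = 10, snr_db = Inf)
  res <- suppressWarnings(classify_condition(cr, build_templates(clean)))
  expect_equal(unname(rowSums(res$confusion)), rep(4, 2))
  expect_equal(res$overall_pc, mean(res$trial_pc$percent_correct))
})

test_that("shuffled labels decode at chance (~1/S)", {
  S <- 4; Tn <- 50; NB <- 40
  withr::with_seed(13, {
    # all tokens share one drive pattern: no information
    p <- runif(NB, 0.1, 0.4)
    m <- matrix(rbinom(S * Tn * NB, 1, rep(p, each = S * Tn)), S * Tn, NB)
  })
  toks <- LETTERS[1:S]
  clean <- make_cr(m, toks, n_trials = Tn, n_bins = 10, snr_db = Inf)
  noisy <- make_cr(
    withr::with_seed(14, matrix(rbinom(S * Tn * NB, 1,
                                       rep(p, each = S * Tn)), S * Tn, NB)),
    toks, n_trials = Tn, n_bins = 10, snr_db = 0)
  res <- suppressWarnings(classify_condition(noisy, build_templates(clean)))
  expect_lt(abs(res$overall_pc - 100 / S), 10) # Monte-Carlo tolerance
})

test_that("percent correct is invariant to neuron (feature-block) order", {
  withr::with_seed(15, {
    m <- matrix(rbinom(6 * 24, 1, 0.35), 6, 24)
  })
  cr <- make_cr(m, c("A", "B"), n_trials = 3, n_bins = 8)
  res1 <- suppressWarnings(
    classify_condition(cr, build_templates(cr), exclude_self = TRUE))
  # swap the two neurons' feature blocks everywhere
  perm <- c(9:16, 1:8, 17:24)
  cr2 <- make_cr(m[, perm], c("A", "B"), n_trials = 3, n_bins = 8)
  res2 <- suppressWarnings(
    classify_condition(cr2, build_templates(cr2), exclude_self = TRUE))
  expect_equal(res1$overall_pc, res2$overall_pc)
})

test_that("incomplete conditions are rejected", {
  m <- matrix(0, 3, 10)
  # token A has two trials, token B only one: unequal trial sets
  cr <- make_cr(m, c("A"), n_trials = 3, n_bins = 5)
  cr$rows <- tibble::tibble(token_id = c("A", "A", "B"), trial = c(1, 2, 1))
  tpl <- build_templates(make_cr(m[1:2, ], "A", 2, 5))
  tpl$token_ids <- c("A", "B")
  expect_error(classify_condition(cr, tpl), "incomplete")
  # a token entirely absent from the trials is also rejected
  cr2 <- make_cr(m[1:2, ], "A", n_trials = 2, n_bins = 5)
  expect_error(classify_condition(cr2, tpl), "incomplete")
})
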