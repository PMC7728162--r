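test_that("PSTH is the per-bin mean across trials", {
  expect_equal(compute_psth(rbind(c(0, 1), c(1, 1))), c(0.5, 1))
  expect_equal(compute_psth(matrix(0, 4, 3)), c(0, 0, 0))
  expect_error(compute_psth(matrix(0, 0, 3)), "empty")

  # 32 trials of Bernoulli(0.2): per-bin mean inside the binomial 99% band
  r <- sample_spikes(rep(0.2, 200), n_trials = 32, seed = 3)
  psth <- compute_psth(r)
  half <- qnorm(0.995) * sqrt(0.2 * 0.8 / 32)
  expect_gt(mean(abs(psth - 0.2) <= half), 0.97)
})

test_that("a PSTH regenerates itself through sampling (round trip)", {
  p <- matrix(runif(2 * 100, 0, 0.3), 2, 100,
              dimnames = list(c("a", "b"), NULL))
  r <- sample_spikes(p, n_trials = 8000, seed = 5)
  r$neuron_id <- c("a", "b")
  back <- compute_psth(r)
  expect_lt(max(abs(back - p)), 0.03)
})

test_that("neurograms are assembled in ascending CF order with stable ties", {
  psths <- matrix(1:6, 3, 2, dimnames = list(c("x", "y", "z"), NULL))
  meta <- tibble::tibble(neuron_id = c("x", "y", "z"),
                         cf = c(4000, 500, 1000))
  ng <- assemble_neurogram(psths, meta)
  expect_equal(ng$neuron_id, c("y", "z", "x"))
  expect_equal(ng$cf_order, c(500, 1000, 4000))
  # permutation: the multiset of rows is preserved
  expect_setequal(unname(split(ng$values, ng$neuron_id)),
                  unname(split(psths, rownames(psths))))

  meta$cf <- c(1000, 1000, 1000)
  ng2 <- assemble_neurogram(psths, meta)
  expect_equal(ng2$neuron_id, c("x", "y", "z")) # lexicographic tie-break

  meta$neuron_id <- c("x", "x", "z")
  expect_error(assemble_neurogram(psths, meta), "duplicate")
})

test_that("CF matching is greedy, nearest in log frequency, without reuse", {
  ctl <- tibble::tibble(neuron_id = paste0("c", 1:3), cf = c(500, 1000, 4000))
  exp_same <- tibble::tibble(neuron_id = paste0("e", 1:4),
                             cf = c(500, 1000, 4000, 250))
  m <- match_populations_by_cf(ctl, exp_same, seed = 1)
  expect_equal(nrow(m), 3)
  expect_equal(sum(m$distance), 0) # identical CFs -> exact bijection
  expect_false(anyDuplicated(m$exposed_id) > 0)

  one <- match_populations_by_cf(
    tibble::tibble(neuron_id = "c1", cf = 1000),
    tibble::tibble(neuron_id = paste0("e", 1:3), cf = c(500, 1100, 8000)),
    seed = 2
  )
  expect_equal(one$exposed_value, 1100) # nearest on the log axis

  expect_error(match_populations_by_cf(exp_same, ctl, seed = 1), "smaller")

  # deterministic given seed, including random tie-breaks
  big_c <- tibble::tibble(neuron_id = paste0("c", 1:20),
                          cf = rep(c(500, 2000), 10))
  big_e <- tibble::tibble(neuron_id = paste0("e", 1:40),
                          cf = rep(c(500, 2000), 20))
  m1 <- match_populations_by_cf(big_c, big_e, seed = 7)
  expect_identical(m1, match_populations_by_cf(big_c, big_e, seed = 7))
  expect_false(anyDuplicated(m1$exposed_id) > 0)
})

test_that("threshold matching reuses the same greedy scheme", {
  ctl <- tibble::tibble(neuron_id = "c1", threshold = 30)
  exp_m <- tibble::tibble(neuron_id = c("e1", "e2"), threshold = c(20, 33))
  m <- match_populations_by_cf(ctl, exp_m, seed = 1, by = "threshold")
  expect_equal(m$exposed_value, 33)
})

test_that("rate summaries report group differences in the expected direction", {
  # identical arms -> zero difference
  m <- matrix(rbinom(4 * 20, 1, 0.3), 4, 20)
  cr_c <- make_cr(m, "AMA", n_trials = 4, n_bins = 10,
                  arm = "control", snr_db = 0)
  cr_e <- make_cr(m, "AMA", n_trials = 4, n_bins = 10,
                  arm = "exposed", snr_db = 0)
  co <- structure(list(
    config = cohort_config(n_neurons = 2, n_trials = 4, seed = 1),
    responses = dplyr::bind_rows(
      tibble::tibble(arm = "control", level_db = 60, snr_db = 0,
                     data = list(cr_c)),
      tibble::tibble(arm = "exposed", level_db = 60, snr_db = 0,
                     data = list(cr_e))
    )
  ), class = "ic_cohort")
  smry <- mean_rate_summary(co)
  expect_equal(smry$diff_mean, 0)
  expect_equal(smry$ratio_mean, 1)

  # sub-knee drive transformed with gain 1.40 raises the exposed mean rate
  p <- matrix(runif(3 * 500, 0, 0.06), 3, 500)
  hp <- hhl_params(p_max = 0.127, gain = 1.40)
  rc <- sample_spikes(p, 64, seed = 2)$m
  re <- sample_spikes(apply_hhl_gain(p, hp), 64, seed = 3)$m
  expect_gt(sum(re) / sum(rc), 1.3)
})
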