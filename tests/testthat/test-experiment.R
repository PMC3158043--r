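test_that("Wilson intervals bracket the point estimate within [0, 100]", {
  for (k in c(0, 3, 10)) {
    ci <- stereocorr:::wilson_ci(k, 10)
    expect_true(ci[1] >= 0 && ci[2] <= 1)
    expect_true(ci[1] <= k / 10 + 1e-12 && ci[2] >= k / 10 - 1e-12)
  }
  cell <- stereocorr:::summarize_cell(
    list(frequency = 1, amplitude = 2, waveform = "sine"),
    c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(cell$percent_correct, 75)
  expect_true(cell$ci_lo <= 75 && cell$ci_hi >= 75 && cell$ci_hi <= 100)
})

test_that("trials run the full pipeline and are seed-deterministic", {
  cfg <- tiny_config()
  bank <- small_bank(config = cfg)
  cond <- list(frequency = 3.8, amplitude = 2.5, waveform = "sine")
  r1 <- run_trial(cond, bank, cfg, seed = 5)
  r2 <- run_trial(cond, bank, cfg, seed = 5)
  expect_identical(r1, r2)
  expect_type(r1, "logical")
  # amplitude far beyond every template still returns a boolean (totality)
  big <- list(frequency = 3.8, amplitude = 12.6, waveform = "square")
  expect_type(run_trial(big, bank, cfg, seed = 6), "logical")
})

test_that("experiments return tidy per-cell results, reproducibly", {
  cfg <- tiny_config()
  bank <- small_bank(config = cfg)
  res <- run_experiment(3.8, amplitudes = c(0.3, 2.5), waveforms = "sine",
                        trials = 6, config = cfg,
                        banks = list("3.8" = bank), seed = 2)
  expect_s3_class(res, "stereo_experiment")
  expect_equal(nrow(res), 2)
  expect_named(res, c("frequency", "amplitude", "waveform", "n_trials",
                      "n_correct", "percent_correct", "ci_lo", "ci_hi"))
  expect_true(all(res$ci_lo <= res$percent_correct &
                    res$percent_correct <= res$ci_hi))
  res2 <- run_experiment(3.8, amplitudes = c(0.3, 2.5), waveforms = "sine",
                         trials = 6, config = cfg,
                         banks = list("3.8" = bank), seed = 2)
  expect_identical(tidy(res), tidy(res2))         # bit-identical tables
  expect_error(run_experiment(1.3, amplitudes = 2.5, trials = 2,
                              config = cfg, banks = list("3.8" = bank)),
               "1.3")
  # peak performance is the max over amplitudes
  pk <- peak_performance(res)
  expect_equal(pk$peak_percent_correct, max(res$percent_correct))
})

test_that("upper depth limits interpolate, censor, and fit power laws", {
  mk <- function(frequency, amplitude, pc) {
    tibble::tibble(frequency = frequency, amplitude = amplitude,
                   waveform = "sine", n_trials = 100,
                   n_correct = round(pc), percent_correct = pc,
                   ci_lo = pc - 5, ci_hi = pc + 5)
  }
  # step from 100 to 0 between A = 4 and A = 8
  step <- dplyr::bind_rows(mk(1, 2, 100), mk(1, 4, 100), mk(1, 8, 0))
  lim <- upper_depth_limit(step)
  expect_gt(lim$limit, 4); expect_lt(lim$limit, 8)
  expect_false(lim$censored)
  # monotone in the criterion
  lim60 <- upper_depth_limit(step, criterion = 60)
  expect_gte(lim60$limit, lim$limit)
  # exact 1/f limits give slope -1 (pc crosses 80 at A = 10/f)
  grid <- tidyr::expand_grid(frequency = c(0.5, 1, 2, 4),
                             amplitude = c(1, 2, 4, 8, 16, 32))
  curves <- dplyr::bind_rows(purrr::pmap(grid, function(frequency, amplitude) {
    pc <- ifelse(amplitude <= 10 / frequency, 100, 0)
    mk(frequency, amplitude, pc)
  }))
  fit <- tidy(upper_depth_limit(curves))
  expect_equal(fit$loglog_slope, -1, tolerance = 0.01)
  # never dropping below criterion: censored, no numeric limit claimed
  flat <- dplyr::bind_rows(mk(1, 2, 100), mk(1, 8, 100))
  limf <- upper_depth_limit(flat)
  expect_true(limf$censored)
  expect_equal(limf$limit, 8)
  # never reaching criterion: NA
  low <- dplyr::bind_rows(mk(1, 2, 60), mk(1, 8, 55))
  expect_true(is.na(upper_depth_limit(low)$limit))
})

test_that("glance summaries aggregate the experiment", {
  cfg <- tiny_config()
  bank <- small_bank(config = cfg)
  res <- run_experiment(3.8, amplitudes = 2.5, waveforms = "sine",
                        trials = 4, config = cfg,
                        banks = list("3.8" = bank), seed = 8)
  g <- glance(res)
  expect_equal(g$n_cells, 1)
  expect_equal(g$n_trials, 4)
})
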