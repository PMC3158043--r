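test_that("bank condition grids have the canonical counts", {
  cond <- bank_conditions(3.8)
  expect_equal(sum(cond$type == "grating"), 432)     # 36 x 6 x 2
  expect_equal(sum(cond$type == "noise"), 12)        # 6 x 2
  cond2 <- bank_conditions(1.3, phases = 12, amplitudes = c(1, 2, 3))
  expect_equal(sum(cond2$type == "grating"), 72)
  expect_equal(sum(cond2$type == "noise"), 6)
  expect_error(bank_conditions(3.8, phases = 7), "divide")
  expect_error(bank_conditions(3.8, amplitudes = numeric(0)), "empty")
})

test_that("templates are ensemble statistics with reproducible seeds", {
  cfg <- tiny_config()
  cond <- bank_conditions(3.8, phases = 4, amplitudes = 2.5)[1, ]
  expect_error(build_template(cond, cfg, n = 1), "n must be")
  t1 <- build_template(cond, cfg, n = 4, seed = 9)
  t2 <- build_template(cond, cfg, n = 4, seed = 9)
  expect_identical(t1$mean, t2$mean)
  expect_identical(t1$sd, t2$sd)
  expect_true(all(t1$sd >= 0, na.rm = TRUE))
  expect_equal(dim(t1$mean), dim(t1$sd))
  expect_true(all(is.na(t1$mean) == is.na(t1$sd)))
  # zero-amplitude condition: mean-surface ridge at dx = 0
  cond0 <- cond; cond0$amplitude <- 0
  t0 <- build_template(cond0, cfg, n = 4, seed = 9)
  mc <- colMeans(t0$mean, na.rm = TRUE)
  expect_equal(t0$disparities[which.max(mc)], 0)
})

test_that("the SD of the template mean shrinks as 1/sqrt(n)", {
  # mean over n surfaces has SD ~ sigma/sqrt(n): estimate the sampling SD
  # of the mean surface at n and 4n from disjoint ensembles
  cfg <- tiny_config()
  cond <- bank_conditions(3.8, phases = 4, amplitudes = 2.5)[1, ]
  mean_at <- function(n, seed) build_template(cond, cfg, n = n, seed = seed)$mean
  ms_small <- lapply(1:6, function(s) mean_at(5, seed = 100 + s))
  ms_large <- lapply(1:6, function(s) mean_at(20, seed = 200 + s))
  spread <- function(ms) {
    arr <- simplify2array(ms)
    mean(apply(arr, c(1, 2), sd), na.rm = TRUE)
  }
  ratio <- spread(ms_small) / spread(ms_large)
  expect_gt(ratio, 1.5)          # ideal 2; Monte-Carlo slack
  expect_lt(ratio, 2.7)
})

test_that("sine templates shift by a half period under a 180-degree phase step", {
  cfg <- exp_config()
  freq <- 2.5                                 # half period = 20 rows exactly
  cond_a <- tibble::tibble(type = "grating", waveform = "sine",
                           frequency = freq, amplitude = 2.5, phase = 0,
                           template_id = 1L)
  cond_b <- cond_a; cond_b$phase <- 180
  ta <- build_template(cond_a, cfg, n = 12, seed = 4)
  # same id + seed -> same stereogram ensemble, only the phase differs
  tb <- build_template(cond_b, cfg, n = 12, seed = 4)
  half_px <- 60 / freq / 2 / 0.6              # half period in rows
  expect_equal(half_px, round(half_px))
  interior <- 60:140
  shifted <- tb$mean[interior + half_px, ]
  r <- stats::cor(as.numeric(ta$mean[interior, ]), as.numeric(shifted),
                  use = "complete.obs")
  expect_gt(r, 0.7)
})

test_that("noise templates carry no periodic structure", {
  cfg <- exp_config()
  freq <- 3.8
  period_px <- round(60 / freq / 0.6)
  mk <- function(type, waveform) {
    tibble::tibble(type = type, waveform = waveform, frequency = freq,
                   amplitude = 5.1, phase = ifelse(type == "noise", NA, 0),
                   template_id = ifelse(type == "noise", 7L, 8L))
  }
  autocorr_at_period <- function(tm) {
    # remove each detector column's mean first: noise templates are
    # y-homogeneous but structured across preferred disparity, and that
    # shared dx-profile would correlate any two rows
    dev <- sweep(tm$mean, 2, colMeans(tm$mean, na.rm = TRUE))
    interior <- 40:160
    v1 <- as.numeric(dev[interior, ])
    v2 <- as.numeric(dev[interior + period_px, ])
    stats::cor(v1, v2, use = "complete.obs")
  }
  tn <- build_template(mk("noise", "sine"), cfg, n = 15, seed = 6)
  tg <- build_template(mk("grating", "sine"), cfg, n = 15, seed = 6)
  expect_gt(autocorr_at_period(tg), 0.5)     # grating: strong periodicity
  expect_lt(abs(autocorr_at_period(tn)), 0.35)
})

test_that("banks assemble all conditions with matching grids", {
  bank <- small_bank()
  expect_s3_class(bank, "template_bank")
  expect_equal(length(bank$templates), nrow(bank$conditions))
  expect_equal(sum(bank$conditions$type == "grating"), 4 * 2 * 2)
  expect_equal(sum(bank$conditions$type == "noise"), 2 * 2)
  dims <- vapply(bank$templates, function(t) dim(t$mean), integer(2))
  expect_true(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]))
})
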