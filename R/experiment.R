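#' Run one simulated 2IFC trial
#'
#' Synthesizes one grating stereogram (random phase from the bank's phase
#' set) and one matched disparity-noise stereogram (fresh dot fields for
#' both), randomizes the interval order, runs the full encoding pipeline on
#' each interval, and applies the template-matching decision.
#'
#' @param condition List or one-row tibble with `frequency`, `amplitude`,
#'   `waveform`.
#' @param bank A [build_bank()] result for `condition$frequency` and the
#'   config's size/disparity relation.
#' @param config A [model_config()].
#' @param seed Integer seed; the trial is fully reproducible from it.
#' @return `TRUE` if the model picked the grating interval.
#' @export
run_trial <- function(condition, bank, config = model_config(), seed = 1L) {
  cond <- as.list(condition)
  phases <- unique(bank$conditions$phase[bank$conditions$type == "grating"])
  withr::with_seed(derive_seed(seed, 13L), {
    phase <- sample(phases, 1)
    grating_first <- runif(1) < 0.5
  })
  grating <- disparity_profile(cond$waveform, frequency = cond$frequency,
                               amplitude = cond$amplitude, phase = phase)
  noise <- disparity_profile("noise", amplitude = cond$amplitude,
                             noise_parent = cond$waveform)
  sg <- encode_stimulus(grating, config, derive_seed(seed, 7L))
  sn <- encode_stimulus(noise, config, derive_seed(seed, 11L))
  chosen <- withr::with_seed(derive_seed(seed, 17L), {
    if (grating_first) decide_interval(sg, sn, bank)
    else decide_interval(sn, sg, bank)
  })
  if (grating_first) chosen == 1L else chosen == 2L
}

#' Simulate the grating-detection psychometric experiment
#'
#' Runs `trials` two-interval trials for every (frequency, amplitude,
#' waveform) combination and returns percent correct with Wilson 95%
#' confidence intervals. Frequency is blocked (one template bank per
#' frequency, as in the psychophysics); amplitude, waveform and phase vary
#' trial by trial. Results are bit-identical under a fixed seed.
#'
#' @param frequencies Corrugation frequencies, cpd.
#' @param amplitudes Disparity amplitudes, arcmin; these are also the bank's
#'   amplitude set.
#' @param waveforms `"sine"`, `"square"` or both.
#' @param trials Trials per (frequency, amplitude, waveform) cell.
#' @param config A [model_config()]. For the correlator grid and
#'   size/disparity relation.
#' @param phases Bank phase count (36 in the full profile).
#' @param template_n Stereograms per template (100 in the full profile).
#' @param banks Optional prebuilt list of banks named by frequency
#'   (`as.character(frequency)`); missing frequencies are an error.
#' @param seed Master seed.
#' @return A tibble of class `stereo_experiment` with one row per cell:
#'   `frequency`, `amplitude`, `waveform`, `n_trials`, `n_correct`,
#'   `percent_correct`, `ci_lo`, `ci_hi`.
#' @export
run_experiment <- function(frequencies, amplitudes, waveforms = c("sine", "square"),
                           trials = 200, config = model_config(), phases = 36,
                           template_n = 100, banks = NULL, seed = 1L) {
  if (!is.null(banks)) {
    missing <- setdiff(as.character(frequencies), names(banks))
    if (length(missing))
      stop("no template bank for frequency ", paste(missing, collapse = ", "))
  }
  cells <- tidyr::expand_grid(frequency = frequencies, amplitude = amplitudes,
                              waveform = waveforms)
  results <- vector("list", nrow(cells))
  for (fi in seq_along(frequencies)) {
    f <- frequencies[fi]
    bank <- if (!is.null(banks)) banks[[as.character(f)]]
            else build_bank(f, config, phases = phases,
                            amplitudes = amplitudes, waveforms = waveforms,
                            n = template_n, seed = derive_seed(seed, 23L, fi))
    idx <- which(cells$frequency == f)
    for (ci in idx) {
      cond <- as.list(cells[ci, ])
      correct <- vapply(seq_len(trials), function(t)
        run_trial(cond, bank, config,
                  seed = derive_seed(seed, 29L + ci, t)), logical(1))
      results[[ci]] <- summarize_cell(cond, correct)
    }
  }
  out <- dplyr::bind_rows(results)
  class(out) <- c("stereo_experiment", class(out))
  attr(out, "seed") <- seed
  out
}

summarize_cell <- function(cond, correct) {
  n <- length(correct)
  k <- sum(correct)
  ci <- wilson_ci(k, n)
  tibble::tibble(frequency = cond$frequency, amplitude = cond$amplitude,
                 waveform = cond$waveform, n_trials = n, n_correct = k,
                 percent_correct = 100 * k / n,
                 ci_lo = 100 * ci[1], ci_hi = 100 * ci[2])
}

# Wilson score interval (no continuity correction), good small-n coverage.
# prop.test's chi-squared warning concerns its test statistic, not the
# score interval read off here.
wilson_ci <- function(k, n, conf = 0.95) {
  suppressWarnings(
    as.numeric(prop.test(k, n, correct = FALSE, conf.level = conf)$conf.int))
}

#' Peak performance per frequency
#'
#' Maximum percent correct over amplitudes, per frequency and waveform (the
#' stereoresolution summary curve).
#'
#' @param results A [run_experiment()] tibble.
#' @return A tibble with `frequency`, `waveform`, `peak_percent_correct`,
#'   `optimal_amplitude`.
#' @export
peak_performance <- function(results) {
  results |>
    dplyr::group_by(.data$frequency, .data$waveform) |>
    dplyr::slice_max(.data$percent_correct, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$frequency, .data$waveform,
                     peak_percent_correct = .data$percent_correct,
                     optimal_amplitude = .data$amplitude)
}

#' Upper depth limit versus frequency
#'
#' The upper depth limit at each frequency is the maximum disparity
#' amplitude for which performance exceeds the criterion (default 80%
#' correct), refined by linear interpolation in log-amplitude between the
#' largest amplitude above the criterion and the next tested amplitude
#' (the target relationship is a power law, so interpolation is done on the
#' log scale). Frequencies whose performance never falls below the
#' criterion within the tested range are censored (the classical
#' fixed-window model has no upper depth limit for square waves);
#' frequencies never above it yield `NA`. The log-log slope of limit versus
#' frequency is fit by least squares over the uncensored frequencies.
#'
#' @param results A [run_experiment()] tibble.
#' @param criterion Percent-correct criterion (default 80).
#' @return A tibble of class `depth_limit` with per-(frequency, waveform)
#'   rows: `limit` (arcmin), `censored`; the log-log fit per waveform is
#'   available via [tidy()] / [glance()].
#' @export
upper_depth_limit <- function(results, criterion = 80) {
  rows <- results |>
    dplyr::group_by(.data$frequency, .data$waveform) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$amplitude)
      above <- d$percent_correct > criterion
      if (!any(above))
        return(tibble::tibble(limit = NA_real_, censored = FALSE))
      i <- max(which(above))
      if (i == nrow(d))
        return(tibble::tibble(limit = d$amplitude[i], censored = TRUE))
      # log-linear interpolation to the criterion crossing
      a0 <- d$amplitude[i]; a1 <- d$amplitude[i + 1]
      p0 <- d$percent_correct[i]; p1 <- d$percent_correct[i + 1]
      la <- log(a0) + (criterion - p0) * (log(a1) - log(a0)) / (p1 - p0)
      tibble::tibble(limit = exp(la), censored = FALSE)
    }) |>
    dplyr::ungroup()
  fits <- rows |>
    dplyr::filter(!.data$censored, !is.na(.data$limit)) |>
    dplyr::group_by(.data$waveform) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) < 2) return(NULL)
      fit <- lm(log10(limit) ~ log10(frequency), data = d)
      tibble::tibble(waveform = key$waveform,
                     loglog_slope = unname(coef(fit)[2]),
                     loglog_intercept = unname(coef(fit)[1]),
                     n_frequencies = nrow(d))
    }) |>
    dplyr::bind_rows()
  structure(rows, class = c("depth_limit", class(rows)),
            criterion = criterion, fits = fits)
}

#' @describeIn upper_depth_limit per-waveform log-log fit coefficients.
#' @param x A `depth_limit` object.
#' @param ... Unused.
#' @export
tidy.depth_limit <- function(x, ...) attr(x, "fits")

#' @describeIn upper_depth_limit one-row summary (criterion, slope range).
#' @export
glance.depth_limit <- function(x, ...) {
  fits <- attr(x, "fits")
  tibble::tibble(criterion = attr(x, "criterion"),
                 n_limits = sum(!is.na(x$limit)),
                 n_censored = sum(x$censored),
                 mean_loglog_slope = mean(fits$loglog_slope))
}
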