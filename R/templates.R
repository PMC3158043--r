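#' Enumerate the conditions of a template bank
#'
#' The model observer's priors cover every stimulus it may be shown: all
#' combinations of phase, amplitude and waveform for gratings (with the
#' default 36 phases x 6 amplitudes x 2 waveforms = 432 grating templates
#' per frequency), plus one noise template per amplitude x parent waveform
#' (12 in total, independent of frequency and phase).
#'
#' @param frequency Corrugation frequency, cpd.
#' @param phases Number of equally spaced grating phases; must divide 360
#'   evenly (default 36, i.e. 10-degree steps).
#' @param amplitudes Disparity amplitudes in arcmin (default the six core
#'   values 0.3, 1.3, 2.5, 5.1, 7.6, 10.1).
#' @param waveforms Grating waveforms (default sine and square).
#' @return A tibble with columns `type` ("grating"/"noise"), `waveform`,
#'   `frequency`, `amplitude`, `phase` (NA for noise) and `template_id`.
#' @examples
#' dplyr::count(bank_conditions(3.8), type)
#' @export
bank_conditions <- function(frequency, phases = 36,
                            amplitudes = c(0.3, 1.3, 2.5, 5.1, 7.6, 10.1),
                            waveforms = c("sine", "square")) {
  stopifnot(frequency > 0, phases >= 1)
  if (360 %% phases != 0) stop("phases must divide 360 evenly")
  if (!length(amplitudes)) stop("empty amplitude list")
  gr <- tidyr::expand_grid(type = "grating", waveform = waveforms,
                           amplitude = amplitudes,
                           phase = seq(0, 360 - 360 / phases, by = 360 / phases))
  no <- tidyr::expand_grid(type = "noise", waveform = waveforms,
                           amplitude = amplitudes, phase = NA_real_)
  out <- dplyr::bind_rows(gr, no)
  out$frequency <- frequency
  out$template_id <- seq_len(nrow(out))
  dplyr::relocate(out, "template_id", "type", "waveform", "frequency",
                  "amplitude", "phase")
}

condition_profile <- function(cond) {
  if (cond$type == "noise") {
    disparity_profile("noise", amplitude = cond$amplitude,
                      noise_parent = cond$waveform)
  } else {
    disparity_profile(cond$waveform, frequency = cond$frequency,
                      amplitude = cond$amplitude, phase = cond$phase)
  }
}

#' Build one template from a Monte-Carlo stimulus ensemble
#'
#' A template is the elementwise mean and standard deviation of the
#' correlation surfaces of `n` independent full-pipeline simulations
#' (stimulus synthesis, optics, correlator) of one condition. Undefined
#' (edge-flagged) surface entries stay undefined in the template. The SD
#' surface is stored alongside the mean (the decision stage scores against
#' means only).
#'
#' @param condition A one-row tibble as produced by [bank_conditions()], or
#'   a list with the same fields.
#' @param config A [model_config()].
#' @param n Ensemble size (default 100); at least 2 (the SD is undefined
#'   otherwise).
#' @param seed Integer master seed; per-sample seeds are derived from it and
#'   the template id, so banks are reproducible and parallelizable.
#' @return A `template` object: list with `mean`, `sd`, `condition`, `n`,
#'   `disparities`, `y`.
#' @export
build_template <- function(condition, config = model_config(), n = 100,
                           seed = 1L) {
  if (n < 2) stop("n must be >= 2 (SD undefined otherwise)")
  cond <- as.list(condition)
  profile <- condition_profile(cond)
  id <- if (!is.null(cond$template_id)) cond$template_id else 0L
  acc <- NULL; acc2 <- NULL
  for (i in seq_len(n)) {
    s <- encode_stimulus(profile, config, derive_seed(seed, 1000L + id, i))
    if (is.null(acc)) {
      acc <- s$C; acc2 <- s$C^2
      dimn <- list(disparities = s$disparities, y = s$y)
    } else {
      acc <- acc + s$C; acc2 <- acc2 + s$C^2
    }
  }
  mu <- acc / n
  va <- pmax(acc2 / n - mu^2, 0)
  structure(list(mean = mu, sd = sqrt(va * n / (n - 1)), condition = cond,
                 n = n, disparities = dimn$disparities, y = dimn$y),
            class = "template")
}

#' Build the template bank for one frequency
#'
#' @inheritParams bank_conditions
#' @inheritParams build_template
#' @param n Stereograms per template (default 100; reduced, clearly labelled
#'   profiles are used for desk-scale runs).
#' @return A `template_bank`: list with `frequency`, `conditions` (tibble),
#'   `templates` (list of [build_template()] results, in `conditions`
#'   order), the build parameters, and precomputed matching matrices used
#'   by the decision stage.
#' @export
build_bank <- function(frequency, config = model_config(), phases = 36,
                       amplitudes = c(0.3, 1.3, 2.5, 5.1, 7.6, 10.1),
                       waveforms = c("sine", "square"), n = 100, seed = 1L) {
  conditions <- bank_conditions(frequency, phases, amplitudes, waveforms)
  templates <- purrr::map(seq_len(nrow(conditions)), function(i)
    build_template(conditions[i, ], config, n, seed))
  bank <- structure(
    list(frequency = frequency, conditions = conditions,
         templates = templates,
         build_config = list(phases = phases, amplitudes = amplitudes,
                             waveforms = waveforms, n = n, seed = seed)),
    class = "template_bank")
  bank$match <- bank_match_data(bank)
  bank
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf(
    "<template_bank> f = %g cpd: %d grating + %d noise templates (n = %d each)\n",
    x$frequency, sum(x$conditions$type == "grating"),
    sum(x$conditions$type == "noise"), x$build_config$n))
  invisible(x)
}

# Precompute centred, unit-norm template vectors on the shared defined-entry
# mask, for fast Pearson matching.
bank_match_data <- function(bank) {
  means <- purrr::map(bank$templates, "mean")
  mask <- Reduce(`&`, purrr::map(means, ~ !is.na(.x)))
  mat <- vapply(means, function(m) m[mask], numeric(sum(mask)))
  raw <- mat
  mat <- sweep(mat, 2, colMeans(mat))
  nrm <- sqrt(colSums(mat^2))
  if (any(nrm == 0)) stop("zero-variance template mean surface")
  list(mask = mask, unit = sweep(mat, 2, nrm, "/"), raw = raw,
       is_grating = bank$conditions$type == "grating")
}
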