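#' Describe a depth corrugation
#'
#' A disparity profile specifies how binocular disparity varies with vertical
#' position in the stimulus: a sinusoidal or square-wave disparity grating, or
#' a disparity-noise pattern in which each dot receives an independent draw
#' from the marginal disparity distribution of a parent grating (so that the
#' noise stimulus spans the same disparity range as the grating it is matched
#' to).
#'
#' @param waveform `"sine"`, `"square"` or `"noise"`.
#' @param frequency Corrugation frequency in cycles per degree (ignored for
#'   noise).
#' @param amplitude Disparity amplitude A in arcmin (peak disparity; the
#'   profile spans `[-A, A]`).
#' @param phase Phase in degrees, in `[0, 360)`.
#' @param noise_parent For `waveform = "noise"`, the parent waveform whose
#'   marginal disparity distribution is sampled (`"sine"` or `"square"`).
#' @return An object of class `disparity_profile`.
#' @examples
#' disparity_profile("sine", frequency = 3.8, amplitude = 7.6, phase = 90)
#' @export
disparity_profile <- function(waveform = c("sine", "square", "noise"),
                              frequency = NULL, amplitude, phase = 0,
                              noise_parent = NULL) {
  waveform <- match.arg(waveform)
  stopifnot(amplitude >= 0, phase >= 0, phase < 360)
  if (waveform == "noise") {
    if (is.null(noise_parent) || !noise_parent %in% c("sine", "square"))
      stop("a noise profile requires noise_parent = \"sine\" or \"square\"")
  } else {
    if (is.null(frequency) || frequency <= 0)
      stop("gratings require a positive frequency (cycles/deg)")
  }
  structure(
    list(waveform = waveform, frequency = frequency, amplitude = amplitude,
         phase = phase, noise_parent = noise_parent),
    class = "disparity_profile"
  )
}

#' @export
print.disparity_profile <- function(x, ...) {
  if (x$waveform == "noise") {
    cat(sprintf("<disparity_profile> noise (parent %s), A = %g arcmin\n",
                x$noise_parent, x$amplitude))
  } else {
    cat(sprintf("<disparity_profile> %s, f = %g cpd, A = %g arcmin, phase = %g deg\n",
                x$waveform, x$frequency, x$amplitude, x$phase))
  }
  invisible(x)
}

#' Evaluate a grating's disparity at a vertical position
#'
#' For a sine grating, `d(y) = A sin(2 pi f y + phase)`; for a square wave,
#' `d(y) = A sgn(sin(2 pi f y + phase))` with the tie-break `sgn(0) = +1`, so
#' the disparity at an exact edge belongs to the rising half-cycle.
#'
#' @param profile A [disparity_profile()] with waveform `"sine"` or
#'   `"square"`; a noise profile has no deterministic value and is an error.
#' @param y Vertical position(s) in degrees.
#' @return Disparity in arcmin, same length as `y`, bounded by the amplitude.
#' @examples
#' p <- disparity_profile("sine", 3.8, 7.6, phase = 90)
#' disparity_at(p, 0) # peak: 7.6
#' @export
disparity_at <- function(profile, y) {
  stopifnot(inherits(profile, "disparity_profile"))
  if (profile$waveform == "noise")
    stop("a noise profile has no deterministic disparity; use sample_noise_disparity()")
  s <- sin(2 * pi * profile$frequency * y + profile$phase * pi / 180)
  if (profile$waveform == "square") s <- ifelse(s >= 0, 1, -1)
  profile$amplitude * s
}

#' Draw disparities from a grating's marginal distribution
#'
#' Disparity-noise stimuli scatter the same disparities as the matched grating
#' at random across dots. A square parent has marginal `+/-A` with probability
#' 1/2 each; a sine parent has marginal `A sin(U)`, `U ~ Uniform[0, 2 pi)`
#' (the arcsine law on `[-A, A]`). Uses the current RNG state; seed the
#' stream with [withr::with_seed()] or `set.seed()` for reproducibility.
#'
#' @param parent `"sine"` or `"square"`.
#' @param amplitude Disparity amplitude A in arcmin (>= 0).
#' @param n Number of draws.
#' @return `n` disparities in arcmin, all in `[-A, A]`.
#' @export
sample_noise_disparity <- function(parent = c("sine", "square"), amplitude,
                                   n = 1) {
  parent <- match.arg(parent)
  stopifnot(amplitude >= 0, n >= 0)
  if (parent == "square") {
    amplitude * (2 * rbinom(n, 1, 0.5) - 1)
  } else {
    amplitude * sin(runif(n, 0, 2 * pi))
  }
}

#' Generate a random-dot field
#'
#' Dot positions are continuous (sub-pixel) uniform draws over the field; the
#' dot count is Poisson with mean `density * area`, and polarities are
#' independent fair draws of bright/dark on the mean-gray background.
#'
#' @param extent Field size `c(width, height)` in degrees (a scalar is
#'   recycled to a square field).
#' @param density Mean dot density in dots per square degree (> 0).
#' @param dot_diameter Dot diameter in arcmin.
#' @param seed Integer seed; identical seeds give identical fields.
#' @return A `dot_field`: a tibble with columns `x`, `y` (deg) and `polarity`
#'   (+1/-1), and attributes `extent`, `density`, `dot_diameter`, `seed`.
#' @examples
#' f <- generate_dot_field(c(1, 1), density = 120, seed = 1)
#' nrow(f)
#' @export
generate_dot_field <- function(extent = c(2, 2), density = 120,
                               dot_diameter = 1.2, seed = 1L) {
  if (length(extent) == 1) extent <- rep(extent, 2)
  if (any(extent <= 0)) stop("field extent must be positive")
  if (density <= 0) stop("dot density must be positive")
  if (dot_diameter <= 0) stop("dot_diameter must be positive")
  field <- withr::with_seed(seed, {
    n <- rpois(1, density * prod(extent))
    tibble::tibble(
      x = runif(n, 0, extent[1]),
      y = runif(n, 0, extent[2]),
      polarity = 2 * rbinom(n, 1, 0.5) - 1
    )
  })
  structure(field,
            class = c("dot_field", class(tibble::tibble())),
            extent = extent, density = density,
            dot_diameter = dot_diameter, seed = seed)
}

#' Stereo image pair container
#'
#' Left and right mean-zero luminance rasters with a common angular pixel
#' pitch. Rows index vertical position (top row at y = pitch/2), columns
#' horizontal position.
#'
#' @param left,right Numeric matrices of identical dimensions.
#' @param pitch Pixel pitch in arcmin per pixel.
#' @return An object of class `stereo_pair`.
#' @export
stereo_pair <- function(left, right, pitch) {
  stopifnot(is.matrix(left), is.matrix(right),
            all(dim(left) == dim(right)), pitch > 0)
  structure(list(left = left, right = right, pitch = pitch),
            class = "stereo_pair")
}

#' @export
print.stereo_pair <- function(x, ...) {
  cat(sprintf("<stereo_pair> %d x %d px, pitch %g arcmin/px (%.2f x %.2f deg)\n",
              nrow(x$left), ncol(x$left), x$pitch,
              ncol(x$left) * x$pitch / 60, nrow(x$left) * x$pitch / 60))
  invisible(x)
}

#' Render a random-dot stereogram of a depth corrugation
#'
#' Each dot is drawn at `(x - d/2, y)` in the left eye and `(x + d/2, y)` in
#' the right eye, where `d` is the profile disparity at the dot's vertical
#' position (gratings) or an independent draw from the parent marginal
#' (noise). Dots are rendered as anti-aliased discs: per-pixel disc coverage
#' is computed by sub-pixel sampling, so disparities well below one render
#' pixel remain representable after optical blur. Overlapping dots sum and
#' the raster is clipped to `clip_range`; dots falling partly outside the
#' raster are clipped silently at the border.
#'
#' @param dots A [generate_dot_field()] result.
#' @param profile A [disparity_profile()].
#' @param render_pitch Render resolution in arcmin/px (default 0.15).
#' @param seed Integer seed for the per-dot noise disparities (only used for
#'   noise profiles).
#' @param clip_range Luminance clipping range, default `c(-1, 1)`.
#' @return A [stereo_pair()] at `render_pitch`; background (mean gray) is 0.
#' @examples
#' f <- generate_dot_field(c(0.5, 0.5), 120, seed = 2)
#' p <- disparity_profile("sine", 3.8, 1.3)
#' rds <- render_stereogram(f, p, render_pitch = 0.3)
#' @export
render_stereogram <- function(dots, profile, render_pitch = 0.15, seed = 1L,
                              clip_range = c(-1, 1)) {
  stopifnot(inherits(dots, "dot_field"), inherits(profile, "disparity_profile"))
  d <- dot_disparities(dots, profile, seed)
  extent <- attr(dots, "extent")
  nx <- round(extent[1] * 60 / render_pitch)
  ny <- round(extent[2] * 60 / render_pitch)
  radius <- attr(dots, "dot_diameter") / 2
  x_min <- (dots$x * 60 - d / 2) / render_pitch   # px units, 0-based coords
  x_pls <- (dots$x * 60 + d / 2) / render_pitch
  y_px <- dots$y * 60 / render_pitch
  left <- render_discs_cpp(nx, ny, x_min, y_px, dots$polarity,
                           radius / render_pitch, 4L)
  right <- render_discs_cpp(nx, ny, x_pls, y_px, dots$polarity,
                            radius / render_pitch, 4L)
  left <- pmin(pmax(left, clip_range[1]), clip_range[2])
  right <- pmin(pmax(right, clip_range[1]), clip_range[2])
  stereo_pair(left, right, render_pitch)
}

# Per-dot disparity in arcmin for any profile type.
dot_disparities <- function(dots, profile, seed) {
  if (profile$waveform == "noise") {
    withr::with_seed(seed,
      sample_noise_disparity(profile$noise_parent, profile$amplitude,
                             n = nrow(dots)))
  } else {
    disparity_at(profile, dots$y)
  }
}
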