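#' Size/disparity relation of the correlator population
#'
#' Detectors tuned to larger disparities use larger correlation windows.
#' Three relations between window SD sigma (arcmin) and preferred disparity
#' dx (arcmin) are supported:
#' \describe{
#'   \item{constant}{`sigma = sigma0` — the classical fixed-window model
#'     (2 sigma = 6 arcmin window at the default).}
#'   \item{quadratic}{`sigma = sigma0 + quad_coef * dx^2` (default
#'     `3 + 0.032 dx^2`).}
#'   \item{linear}{`sigma = sigma0 + lin_slope * |dx|`.}
#' }
#' All relations are even in dx, non-decreasing in |dx|, and equal `sigma0`
#' at dx = 0. The default linear slope 0.24 is a package choice pinned so
#' that the linear and quadratic relations agree at dx = 7.6 arcmin.
#'
#' @param kind `"constant"`, `"quadratic"` or `"linear"`.
#' @param sigma0 Window SD at zero disparity, arcmin (default 3).
#' @param quad_coef Quadratic coefficient, 1/arcmin (default 0.032).
#' @param lin_slope Linear slope, arcmin per arcmin (default 0.24).
#' @return An object of class `size_disparity_relation`.
#' @examples
#' window_sigma(size_disparity_relation("quadratic"), 13) # 8.408
#' @export
size_disparity_relation <- function(kind = c("quadratic", "linear", "constant"),
                                    sigma0 = 3, quad_coef = 0.032,
                                    lin_slope = 0.24) {
  kind <- match.arg(kind)
  stopifnot(sigma0 > 0, quad_coef >= 0, lin_slope >= 0)
  structure(list(kind = kind, sigma0 = sigma0, quad_coef = quad_coef,
                 lin_slope = lin_slope),
            class = "size_disparity_relation")
}

#' Window SD for a preferred disparity
#'
#' @param rel A [size_disparity_relation()].
#' @param dx Preferred disparity (arcmin); vectorized.
#' @return Window SD sigma in arcmin.
#' @export
window_sigma <- function(rel, dx) {
  stopifnot(inherits(rel, "size_disparity_relation"))
  switch(rel$kind,
         constant = rep(rel$sigma0, length(dx)),
         quadratic = rel$sigma0 + rel$quad_coef * dx^2,
         linear = rel$sigma0 + rel$lin_slope * abs(dx))
}

#' Preferred-disparity grid of the correlator population
#'
#' @param range Disparity range `c(lo, hi)` in arcmin; the default
#'   `c(-13, 13)` is used for the core experiments, extended (up to +/- 140)
#'   for upper depth-limit runs at low corrugation frequencies.
#' @param step Grid step in arcmin; equals the working pixel pitch (0.6).
#' @return An object of class `correlator_grid` with a `disparities` vector.
#' @export
correlator_grid <- function(range = c(-13, 13), step = 0.6) {
  stopifnot(length(range) == 2, range[1] < range[2], step > 0)
  disparities <- seq(ceiling(range[1] / step), floor(range[2] / step)) * step
  if (!length(disparities)) stop("empty disparity grid")
  structure(list(disparities = disparities, step = step),
            class = "correlator_grid")
}

# Truncation half-width in pixels for the strict cut-off |offset| < 2 sigma.
trunc_halfwidth_px <- function(sigma, pitch) {
  as.integer(floor(2 * sigma / pitch - 1e-9))
}

#' Windowed normalized cross-correlation at one population point
#'
#' The left-eye window is centered at pixel `(x, y)`, the right-eye window at
#' `(x + dx/pitch, y)` (same vertical position in both eyes). Pixel values in
#' each window are multiplied by a 2-D Gaussian of SD `sigma`, truncated at
#' two standard deviations from the centre, and the Pearson correlation
#' coefficient of the two resulting value sets is returned: +1 for perfectly
#' correlated patches at the matching offset, -1 for anti-correlated
#' stimuli. A blank (zero-variance) window has no defined correlation and
#' yields `NA`.
#'
#' This is the direct reference implementation; [correlation_surface()]
#' computes the same quantity for the whole population with a fast separable
#' algorithm.
#'
#' @param pair A [stereo_pair()] at the working resolution.
#' @param x,y Left-window centre, in pixels (column, row; 1-based).
#' @param dx Preferred disparity in arcmin; must be a multiple of the pixel
#'   pitch.
#' @param sigma Window SD in arcmin.
#' @return Correlation in `[-1, 1]`, or `NA` for a blank window.
#' @export
windowed_correlation <- function(pair, x, y, dx, sigma) {
  stopifnot(inherits(pair, "stereo_pair"))
  p <- pair$pitch
  s <- dx / p
  if (abs(s - round(s)) > 1e-6)
    stop("dx must be a multiple of the pixel pitch")
  s <- as.integer(round(s))
  m <- trunc_halfwidth_px(sigma, p)
  nx <- ncol(pair$left); ny <- nrow(pair$left)
  if (x - m < 1 || x + m > nx || y - m < 1 || y + m > ny ||
      x + s - m < 1 || x + s + m > nx)
    stop("correlation window does not fit within the rasters")
  o <- (-m):m
  g <- exp(-o^2 * p^2 / (2 * sigma^2))
  w <- outer(g, g)  # rows = y offsets, cols = x offsets
  a <- w * pair$left[y + o, x + o, drop = FALSE]
  b <- w * pair$right[y + o, x + s + o, drop = FALSE]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Population response surface C(y, dx)
#'
#' Computes the windowed correlation for every vertical position (one row
#' per working pixel) and every preferred disparity on the grid, with the
#' window SD given by the size/disparity relation. Only one left-window
#' x-column is simulated (the model's left window is always at the same
#' horizontal position); it defaults to the raster's centre column.
#' Positions where the window does not fit inside the rasters are flagged
#' undefined (`NA`) rather than computed with a shrunken window, which would
#' silently change the size/disparity relation.
#'
#' @param pair A [stereo_pair()] at the working resolution.
#' @param grid A [correlator_grid()]; its step must equal the pixel pitch.
#' @param rel A [size_disparity_relation()].
#' @param x_col Left-window column (1-based); default centre column.
#' @return A `correlation_surface`: list with matrix `C` (rows = y, columns
#'   = preferred disparity), `y` (arcmin), `disparities` (arcmin), `pitch`,
#'   `x_col`.
#' @export
correlation_surface <- function(pair, grid = correlator_grid(),
                                rel = size_disparity_relation(),
                                x_col = NULL) {
  stopifnot(inherits(pair, "stereo_pair"), inherits(grid, "correlator_grid"),
            inherits(rel, "size_disparity_relation"))
  if (abs(grid$step - pair$pitch) > 1e-9)
    stop("grid step must equal the pixel pitch of the pair")
  if (is.null(x_col)) x_col <- (ncol(pair$left) + 1L) %/% 2L
  dx <- grid$disparities
  sig <- window_sigma(rel, dx)
  s_px <- as.integer(round(dx / pair$pitch))
  m_px <- trunc_halfwidth_px(sig, pair$pitch)
  C <- corr_surface_cpp(pair$left, pair$right, as.integer(x_col),
                        s_px, m_px, sig / pair$pitch)
  structure(
    list(C = C, y = (seq_len(nrow(C)) - 0.5) * pair$pitch,
         disparities = dx, pitch = pair$pitch, x_col = x_col),
    class = "correlation_surface"
  )
}

#' @export
print.correlation_surface <- function(x, ...) {
  cat(sprintf(
    "<correlation_surface> %d y-positions x %d disparities (%g..%g arcmin), %d undefined\n",
    nrow(x$C), ncol(x$C), min(x$disparities), max(x$disparities),
    sum(is.na(x$C))))
  invisible(x)
}

#' @describeIn correlation_surface long-format tibble (`y`, `dx`,
#'   `correlation`) of the defined entries.
#' @param x A `correlation_surface`.
#' @param ... Unused.
#' @export
as_tibble.correlation_surface <- function(x, ...) {
  out <- tibble::tibble(y = rep(x$y, times = length(x$disparities)),
                        dx = rep(x$disparities, each = length(x$y)),
                        correlation = as.numeric(x$C))
  dplyr::filter(out, !is.na(.data$correlation))
}

#' Range of stimulus disparities inside a correlation window
#'
#' The within-window disparity range (max minus min of the profile) is the
#' quantity that governs how strongly a detector's response is degraded by
#' depth variation inside its window: a detector centred on a grating peak
#' with half-width h sees a range `A (1 - cos(2 pi f h))`, one centred on a
#' zero crossing sees `2 A sin(2 pi f h)` (h converted to degrees). The
#' window extent here is the 1-SD contour of the Gaussian, i.e.
#' `halfwidth = sigma`.
#'
#' Computed exactly by enumerating the profile's interval extrema (interval
#' endpoints, interior stationary points of the sine, both sides of each
#' square-wave edge).
#'
#' @param profile A sine or square [disparity_profile()].
#' @param y_center Window centre, degrees.
#' @param halfwidth Window half-width in arcmin (the window SD sigma).
#' @return Disparity range in arcmin (>= 0).
#' @examples
#' p <- disparity_profile("sine", 3.8, 1.3, phase = 90) # peak at y = 0
#' disparity_range_in_window(p, 0, 3) # 0.82 arcmin
#' @export
disparity_range_in_window <- function(profile, y_center, halfwidth) {
  stopifnot(inherits(profile, "disparity_profile"),
            profile$waveform %in% c("sine", "square"), halfwidth >= 0)
  if (halfwidth == 0) return(0)
  h <- halfwidth / 60
  lo <- y_center - h
  hi <- y_center + h
  f <- profile$frequency
  phi <- profile$phase * pi / 180
  # candidate positions: endpoints plus interior critical points
  if (profile$waveform == "sine") {
    # stationary where 2 pi f y + phi = pi/2 + k pi
    k <- seq(ceiling((2 * pi * f * lo + phi - pi / 2) / pi),
             floor((2 * pi * f * hi + phi - pi / 2) / pi))
    crit <- (pi / 2 + k * pi - phi) / (2 * pi * f)
  } else {
    # value changes across each zero of sin(2 pi f y + phi): sample segment
    # midpoints between consecutive crossings
    k <- seq(ceiling((2 * pi * f * lo + phi) / pi),
             floor((2 * pi * f * hi + phi) / pi))
    cross <- (k * pi - phi) / (2 * pi * f)
    knots <- sort(unique(c(lo, cross, hi)))
    crit <- (knots[-1] + knots[-length(knots)]) / 2
  }
  ys <- c(lo, hi, crit[crit > lo & crit < hi])
  d <- disparity_at(profile, ys)
  max(d) - min(d)
}
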