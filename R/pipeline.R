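#' Bundle the model's stimulus and encoding parameters
#'
#' A `model_config` collects everything needed to turn a disparity profile
#' into a correlation surface: dot-field statistics, eye optics, the
#' size/disparity relation and the preferred-disparity grid.
#'
#' @param field_extent Stimulus extent `c(width, height)` in degrees. The
#'   default 2 x 2 deg shows at least two corrugation periods at the lowest
#'   core frequency; depth-limit runs use taller/wider fields (see
#'   [depth_limit_config()]).
#' @param density Dot density, dots per square degree.
#' @param dot_diameter Dot diameter, arcmin.
#' @param optics An [optics_config()].
#' @param relation A [size_disparity_relation()].
#' @param grid A [correlator_grid()].
#' @param stimulus_method `"kernel"` (default) renders dots directly on the
#'   working grid by splatting the composite dot-optics kernel — the
#'   closed-form composition of disc rendering, point-spread blur and block
#'   averaging; `"raster"` runs the explicit render/blur/downsample
#'   pipeline. The two agree to well under 1% RMS (see the package tests);
#'   the kernel path is used for Monte-Carlo ensembles because it is an
#'   order of magnitude faster.
#' @return An object of class `model_config`.
#' @export
model_config <- function(field_extent = c(2, 2), density = 120,
                         dot_diameter = 1.2, optics = optics_config(),
                         relation = size_disparity_relation(),
                         grid = correlator_grid(),
                         stimulus_method = c("kernel", "raster")) {
  if (length(field_extent) == 1) field_extent <- rep(field_extent, 2)
  stimulus_method <- match.arg(stimulus_method)
  if (abs(grid$step - optics$working_pitch) > 1e-9)
    stop("grid step must equal the optics working_pitch")
  structure(list(field_extent = field_extent, density = density,
                 dot_diameter = dot_diameter, optics = optics,
                 relation = relation, grid = grid,
                 stimulus_method = stimulus_method),
            class = "model_config")
}

#' Minimum field width for a disparity grid
#'
#' The correlator evaluates a single left-window column at the raster
#' centre; the field only needs to be wide enough that the largest window at
#' the largest preferred-disparity offset fits. Returns that width (deg)
#' with a small safety margin.
#'
#' @param grid A [correlator_grid()].
#' @param rel A [size_disparity_relation()].
#' @return Width in degrees.
#' @export
min_field_width <- function(grid, rel) {
  dmax <- max(abs(grid$disparities))
  smax <- max(window_sigma(rel, grid$disparities))
  2 * (2 * smax + dmax + 2) / 60
}

#' Model configuration for upper depth-limit runs
#'
#' Depth-limit simulations probe amplitudes far beyond the core +/- 13
#' arcmin grid, so the preferred-disparity grid is extended (up to +/- 140
#' arcmin for very low frequencies) and the field is made tall enough for
#' at least two corrugation periods at the lowest frequency and wide enough
#' for the largest window at the largest offset.
#'
#' @param frequency Lowest corrugation frequency to be run, cpd.
#' @param max_disparity Extended grid half-range, arcmin.
#' @param relation A [size_disparity_relation()].
#' @param ... Passed to [model_config()] (density, optics, ...).
#' @return A [model_config()].
#' @export
depth_limit_config <- function(frequency, max_disparity = 140,
                               relation = size_disparity_relation("linear"),
                               ...) {
  grid <- correlator_grid(c(-max_disparity, max_disparity))
  height <- max(2, 2 / frequency)
  width <- max(2, min_field_width(grid, relation))
  model_config(field_extent = c(width, height), relation = relation,
               grid = grid, ...)
}

#' Synthesize a preprocessed stimulus at the working resolution
#'
#' Generates a fresh random-dot field, applies the profile's disparities
#' (symmetric +/- d/2 split between the eyes) and returns the stereo pair
#' as seen by the correlator population, i.e. after eye optics, at the
#' working pitch. Fully reproducible from `seed`.
#'
#' @param profile A [disparity_profile()].
#' @param config A [model_config()].
#' @param seed Integer seed (drives both dot placement and, for noise
#'   profiles, the per-dot disparity draws).
#' @return A [stereo_pair()] at the working pitch.
#' @export
simulate_stimulus <- function(profile, config = model_config(), seed = 1L) {
  stopifnot(inherits(profile, "disparity_profile"),
            inherits(config, "model_config"))
  dots <- generate_dot_field(config$field_extent, config$density,
                             config$dot_diameter,
                             seed = derive_seed(seed, 101L))
  if (config$stimulus_method == "raster") {
    rds <- render_stereogram(dots, profile,
                             render_pitch = config$optics$render_pitch,
                             seed = derive_seed(seed, 102L))
    blur_and_scale(rds, config$optics)
  } else {
    d <- dot_disparities(dots, profile, seed = derive_seed(seed, 102L))
    kern <- composite_dot_kernel(config$dot_diameter, config$optics$psf_sd,
                                 config$optics$working_pitch)
    p <- config$optics$working_pitch
    nx <- round(config$field_extent[1] * 60 / p)
    ny <- round(config$field_extent[2] * 60 / p)
    left <- splat_kernel_cpp(nx, ny, (dots$x * 60 - d / 2) / p,
                             dots$y * 60 / p, dots$polarity,
                             kern$k, (kern$r[2] - kern$r[1]) / p)
    right <- splat_kernel_cpp(nx, ny, (dots$x * 60 + d / 2) / p,
                              dots$y * 60 / p, dots$polarity,
                              kern$k, (kern$r[2] - kern$r[1]) / p)
    stereo_pair(left, right, p)
  }
}

#' Full encoding pipeline: stimulus to correlation surface
#'
#' @inheritParams simulate_stimulus
#' @return A [correlation_surface()].
#' @export
encode_stimulus <- function(profile, config = model_config(), seed = 1L) {
  pair <- simulate_stimulus(profile, config, seed)
  correlation_surface(pair, config$grid, config$relation)
}
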