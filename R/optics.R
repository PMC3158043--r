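#' Eye-optics configuration
#'
#' The model preprocesses stimuli by blurring with the eye's point-spread
#' function and rescaling to the working resolution of the correlator
#' population (one working pixel = the 0.6-arcmin step of the preferred
#' disparity grid).
#'
#' @param psf_sd Standard deviation of the isotropic Gaussian point-spread
#'   function, in arcmin (default 2).
#' @param working_pitch Working resolution after rescaling, arcmin/px
#'   (default 0.6).
#' @param render_pitch Render resolution of the incoming stimulus, arcmin/px;
#'   must divide `working_pitch` evenly.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(psf_sd = 2, working_pitch = 0.6,
                          render_pitch = 0.15) {
  stopifnot(psf_sd > 0, working_pitch > 0, render_pitch > 0)
  ratio <- working_pitch / render_pitch
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("render_pitch must divide working_pitch evenly")
  structure(list(psf_sd = psf_sd, working_pitch = working_pitch,
                 render_pitch = render_pitch),
            class = "optics_config")
}

#' Blur and rescale a stereo pair to the working resolution
#'
#' Applies the identical operator to both eyes: isotropic Gaussian blur of SD
#' `psf_sd` (separable convolution, kernel truncated at 4 SD, zero-padded —
#' the background is mean gray = 0), followed by area-true block averaging
#' down to `working_pitch`. The operator is linear with DC gain 1.
#'
#' @param pair A [stereo_pair()] at `cfg$render_pitch`.
#' @param cfg An [optics_config()].
#' @return A [stereo_pair()] at `cfg$working_pitch`.
#' @export
blur_and_scale <- function(pair, cfg = optics_config()) {
  stopifnot(inherits(pair, "stereo_pair"), inherits(cfg, "optics_config"))
  if (abs(pair$pitch - cfg$render_pitch) > 1e-9)
    stop("pair pitch does not match cfg$render_pitch")
  factor <- round(cfg$working_pitch / cfg$render_pitch)
  if (nrow(pair$left) %% factor || ncol(pair$left) %% factor)
    stop("raster dimensions are not a multiple of the downsampling factor")
  sd_px <- cfg$psf_sd / cfg$render_pitch
  k <- gaussian_kernel(sd_px)
  left <- block_average_cpp(sepconv2_cpp(pair$left, k), factor)
  right <- block_average_cpp(sepconv2_cpp(pair$right, k), factor)
  stereo_pair(left, right, cfg$working_pitch)
}

# Normalized 1-D Gaussian kernel truncated at 4 SD (< 1e-4 mass lost).
gaussian_kernel <- function(sd_px) {
  m <- ceiling(4 * sd_px)
  k <- exp(-((-m):m)^2 / (2 * sd_px^2))
  k / sum(k)
}

#' Composite dot kernel: disc convolved with optics and pixel aperture
#'
#' Radial profile of a unit-luminance disc of the given diameter convolved
#' with the Gaussian point-spread function and the working-pixel box aperture
#' (the box is folded into the Gaussian SD as `pitch^2/12` per axis, an
#' approximation accurate to well under 1% of the SD for the default
#' geometry). Splatting this kernel at dot positions on the working grid is
#' analytically the render-blur-downsample pipeline evaluated in closed form,
#' up to the luminance clipping of overlapping same-polarity dots.
#'
#' @param dot_diameter Dot diameter, arcmin.
#' @param psf_sd Point-spread SD, arcmin.
#' @param working_pitch Working pixel pitch, arcmin.
#' @param dr Radial sample step of the returned profile, arcmin.
#' @return A list with `r` (radii, arcmin) and `k` (kernel values, luminance
#'   of a unit-contrast dot).
#' @keywords internal
composite_dot_kernel <- function(dot_diameter = 1.2, psf_sd = 2,
                                 working_pitch = 0.6, dr = 0.02) {
  key <- paste0("k_", dot_diameter, "_", psf_sd, "_", working_pitch, "_", dr)
  cached <- .stereocorr_cache[[key]]
  if (!is.null(cached)) return(cached)
  a <- dot_diameter / 2
  sig2 <- psf_sd^2 + working_pitch^2 / 12  # PSF + working pixel aperture
  rmax <- a + 5 * sqrt(sig2)
  r <- seq(0, rmax, by = dr)
  s <- seq(0, a, length.out = 256)
  ds <- s[2] - s[1]
  # K(r) = int_0^a (s/sig2) exp(-(r^2+s^2)/(2 sig2)) I0(r s / sig2) ds
  x <- outer(r, s) / sig2
  integrand <- exp(-(outer(r^2, s^2, "+")) / (2 * sig2)) *
    besselI(x, 0, expon.scaled = TRUE) * exp(x)
  integrand <- sweep(integrand, 2, s / sig2, "*")
  # trapezoid in s
  k <- as.numeric(integrand %*% rep(ds, length(s))) -
    0.5 * ds * (integrand[, 1] + integrand[, length(s)])
  out <- list(r = r, k = k)
  .stereocorr_cache[[key]] <- out
  out
}
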