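#' Gabor receptive-field parameters
#'
#' A linear subunit of a binocular energy unit: a Gaussian-windowed
#' sinusoid. The wavenumbers `kx`, `ky` (cycles/deg) jointly set the
#' preferred spatial frequency and orientation; the envelope is truncated
#' at the same two-standard-deviation box as the correlation window, so
#' that the summed energy bank lands on exactly the correlator's support.
#'
#' @param kx,ky Wavenumbers, cycles/deg.
#' @param phase Phase of the carrier, radians.
#' @param sigma Envelope SD, arcmin.
#' @param center Receptive-field centre `c(x, y)` in degrees.
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(kx, ky, phase = 0, sigma = 3, center = c(0, 0)) {
  stopifnot(sigma > 0, length(center) == 2)
  structure(list(kx = kx, ky = ky, phase = phase, sigma = sigma,
                 center = center),
            class = "gabor_params")
}

# Pixel-centre coordinates (deg) of a raster.
raster_coords <- function(mat, pitch) {
  list(x = (seq_len(ncol(mat)) - 0.5) * pitch / 60,
       y = (seq_len(nrow(mat)) - 0.5) * pitch / 60)
}

# Evaluate the Gabor on the raster grid (zero outside the truncation box).
gabor_field <- function(mat, pitch, params) {
  co <- raster_coords(mat, pitch)
  dx <- co$x - params$center[1]
  dy <- co$y - params$center[2]
  s <- params$sigma / 60
  wx <- exp(-dx^2 / (2 * s^2)) * (abs(dx) < 2 * s)
  wy <- exp(-dy^2 / (2 * s^2)) * (abs(dy) < 2 * s)
  ph <- 2 * pi * (outer(dy * params$ky, dx * params$kx, "+")) + params$phase
  outer(wy, wx) * cos(ph)
}

#' Inner product of an image with a Gabor subunit
#'
#' The linear response of one subunit: the sum over pixels of the image
#' times the (truncated) Gabor. Linear in the image.
#'
#' @param image Mean-zero luminance matrix.
#' @param pitch Pixel pitch, arcmin/px.
#' @param params A [gabor_params()].
#' @return A scalar.
#' @export
gabor_inner_product <- function(image, pitch, params) {
  sum(image * gabor_field(image, pitch, params))
}

#' Binocular energy-unit response and its exact decomposition
#'
#' A stereo energy unit with position disparity `dx` and the given phase
#' disparity: left and right receptive fields are identical Gabors with the
#' right centre shifted horizontally by `dx`. The squared sum of the
#' quadrature-pair subunit responses decomposes exactly as
#' `S = B + L + R`, with binocular cross term `B` and monocular energies
#' `L`, `R`.
#'
#' @param pair A [stereo_pair()].
#' @param left_params [gabor_params()] of the left receptive field.
#' @param dx Position disparity, arcmin.
#' @param phase_disparity Interocular phase difference, radians (default 0).
#' @return A list of class `energy_response` with `S`, `B`, `L`, `R`.
#' @export
energy_unit_response <- function(pair, left_params, dx, phase_disparity = 0) {
  stopifnot(inherits(pair, "stereo_pair"), inherits(left_params, "gabor_params"))
  right_params <- left_params
  right_params$center[1] <- right_params$center[1] + dx / 60
  right_params$phase <- right_params$phase + phase_disparity
  q <- function(p) { p$phase <- p$phase + pi / 2; p }
  sl1 <- gabor_inner_product(pair$left, pair$pitch, left_params)
  sl2 <- gabor_inner_product(pair$left, pair$pitch, q(left_params))
  sr1 <- gabor_inner_product(pair$right, pair$pitch, right_params)
  sr2 <- gabor_inner_product(pair$right, pair$pitch, q(right_params))
  B <- 2 * (sl1 * sr1 + sl2 * sr2)
  L <- sl1^2 + sl2^2
  R <- sr1^2 + sr2^2
  structure(list(S = (sl1 + sr1)^2 + (sl2 + sr2)^2, B = B, L = L, R = R),
            class = "energy_response")
}

#' Correlation from an integrated bank of energy units
#'
#' Sums the binocular and monocular terms of zero-phase-disparity energy
#' units over a quadrature bank of spatial frequencies (log-spaced radii,
#' trapezoid weights in log-frequency with the polar area element) and
#' orientations (uniform), and normalizes:
#' `C_int = B_int / sqrt(L_int * R_int)`, which lies in `[-1, 1]` (+1 when
#' the windowed patches are identical, -1 when anti-correlated). For dense
#' mean-zero random-dot stimuli this converges to the windowed correlation
#' at the same `(x, y, dx, sigma)`: integrating the binocular term over all
#' frequencies and orientations collapses the double sum over pixel pairs
#' onto matching pixels, leaving the product of the window-weighted patches
#' (plus a mean-luminance term that vanishes for mean-zero stimuli).
#'
#' The quadrature is convergence-checked: the bank density is doubled and
#' the run aborts if the result moves by more than `tol`.
#'
#' The zero-spatial-frequency "unit" — whose subunits simply sum the
#' windowed pixel values — is excluded from the bank by default (`dc_unit =
#' "exclude"`): no cortical cell is tuned to zero spatial frequency, and
#' removing it subtracts exactly the mean-luminance term of the derivation,
#' so the bank sum reproduces the covariance-normalized (Pearson)
#' correlation. With `dc_unit = "include"` the term is retained; the two
#' agree when the windowed mean luminance is negligible (windows holding
#' many independent image patches), which is the regime the analytic
#' derivation assumes.
#'
#' @param pair A [stereo_pair()] at the working resolution.
#' @param x,y Left-window centre, pixels (1-based).
#' @param dx Position disparity, arcmin (any multiple of the pitch).
#' @param sigma Envelope SD, arcmin.
#' @param n_freq,n_theta Radial and orientation quadrature counts of the
#'   base bank (the convergence check doubles both).
#' @param freq_range Radial frequency range in cycles/deg; the upper end
#'   defaults to 16 cpd, past the optics cutoff (the 2-arcmin PSF leaves
#'   under 1e-3 of amplitude beyond it).
#' @param tol Convergence tolerance on `C_int` under bank doubling.
#' @param dc_unit Whether the zero-frequency unit is part of the bank; see
#'   Details.
#' @return `C_int` (scalar) with attribute `convergence_delta`.
#' @export
integrated_correlation <- function(pair, x, y, dx, sigma,
                                   n_freq = 24, n_theta = 16,
                                   freq_range = c(0.25, 16), tol = 1e-3,
                                   dc_unit = c("exclude", "include")) {
  dc_unit <- match.arg(dc_unit)
  stopifnot(inherits(pair, "stereo_pair"))
  p <- pair$pitch
  s_px <- as.integer(round(dx / p))
  m <- trunc_halfwidth_px(sigma, p)
  nx <- ncol(pair$left); ny <- nrow(pair$left)
  if (x - m < 1 || x + m > nx || y - m < 1 || y + m > ny ||
      x + s_px - m < 1 || x + s_px + m > nx)
    stop("window does not fit within the rasters")
  o <- (-m):m
  g <- exp(-o^2 * p^2 / (2 * sigma^2))
  w <- outer(g, g)
  a <- as.numeric(w * pair$left[y + o, x + o, drop = FALSE])
  b <- as.numeric(w * pair$right[y + o, x + s_px + o, drop = FALSE])
  # coordinates relative to each window's own centre (deg)
  rel <- as.numeric(o) * p / 60
  X <- rep(rel, each = length(o))
  Y <- rep(rel, times = length(o))
  cint <- function(nf, nt) {
    lk <- seq(log(freq_range[1]), log(freq_range[2]), length.out = nf)
    k <- exp(lk)
    wk <- k^2 * (lk[2] - lk[1])            # polar area element k dk = k^2 dln k
    wk[c(1, nf)] <- wk[c(1, nf)] / 2       # trapezoid ends
    th <- seq(0, pi, length.out = nt + 1)[-(nt + 1)]
    kx <- as.numeric(outer(k, cos(th)))
    ky <- as.numeric(outer(k, sin(th)))
    wq <- rep(wk, times = nt) * (pi / nt)
    PH <- 2 * pi * (X %*% t(kx) + Y %*% t(ky))
    EL <- crossprod(cbind(a, b), exp(1i * PH))  # F_L, F_R per bank unit
    Bq <- 2 * Re(EL[1, ] * Conj(EL[2, ]))
    Lq <- Mod(EL[1, ])^2
    Rq <- Mod(EL[2, ])^2
    Bi <- sum(wq * Bq); Li <- sum(wq * Lq); Ri <- sum(wq * Rq)
    if (dc_unit == "exclude") {
      # The k = 0 unit's terms, on the half-plane measure scale
      # (full-plane integral of |F|^2 equals sum(a^2)/pixel-area).
      sdc <- 0.5 * (60 / p)^2 / length(a)
      Bi <- Bi - 2 * sum(a) * sum(b) * sdc
      Li <- Li - sum(a)^2 * sdc
      Ri <- Ri - sum(b)^2 * sdc
    }
    # B carries the quadrature-pair factor 2 (S = B + L + R); the
    # normalization divides it out so identical patches give exactly +1 and
    # the expression reduces to the Pearson form.
    Bi / (2 * sqrt(Li * Ri))
  }
  c1 <- cint(n_freq, n_theta)
  c2 <- cint(2 * n_freq, 2 * n_theta)
  if (abs(c2 - c1) > tol)
    stop(sprintf("energy-bank quadrature did not converge (delta = %.2g)",
                 abs(c2 - c1)))
  structure(c2, convergence_delta = abs(c2 - c1))
}
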