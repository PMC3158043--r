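#' Match quality between a correlation surface and a template set
#'
#' The quality of the match to a template set is the maximum, over
#' templates, of the Pearson correlation coefficient between the surface
#' and the template's mean surface, computed over all defined (y, dx)
#' entries with the means taken over that same entry set. Entries undefined
#' in either the surface or any template are excluded. Template/surface
#' pairings with zero variance are skipped; if every pairing is skipped, an
#' error is raised.
#'
#' @param surface A [correlation_surface()].
#' @param templates A list of `template` objects on the same grid (at least
#'   one).
#' @return A list with `M` (best match, in `[-1, 1]`) and `best_id` (index
#'   of the best template within `templates`).
#' @export
match_quality <- function(surface, templates) {
  stopifnot(inherits(surface, "correlation_surface"), length(templates) >= 1)
  means <- purrr::map(templates, "mean")
  if (!all(vapply(means, function(m) all(dim(m) == dim(surface$C)), TRUE)))
    stop("surface and template grids differ")
  mask <- Reduce(`&`, c(list(!is.na(surface$C)), purrr::map(means, ~ !is.na(.x))))
  v <- surface$C[mask]
  if (sd(v) == 0) stop("zero-variance surface")
  r <- vapply(means, function(m) {
    g <- m[mask]
    if (sd(g) == 0) return(NA_real_)
    stats::cor(v, g)
  }, numeric(1))
  if (all(is.na(r))) stop("all template pairings had zero variance")
  best <- which.max(r)
  list(M = r[best], best_id = best)
}

# Fast path: score one surface against a bank's precomputed matching data.
# Returns c(M_grating, M_noise). Falls back to per-surface masking if the
# surface has (rare) extra undefined entries inside the bank mask.
bank_score <- function(surface, bank) {
  md <- bank$match
  v <- surface$C[md$mask]
  if (anyNA(v)) {
    ok <- !is.na(v)
    mat <- md$raw[ok, , drop = FALSE]
    mat <- sweep(mat, 2, colMeans(mat))
    nrm <- sqrt(colSums(mat^2))
    v <- v[ok]
    vc <- v - mean(v)
    r <- as.numeric(crossprod(mat, vc)) / (nrm * sqrt(sum(vc^2)))
  } else {
    vc <- v - mean(v)
    r <- as.numeric(crossprod(md$unit, vc)) / sqrt(sum(vc^2))
  }
  c(M_grating = max(r[md$is_grating], na.rm = TRUE),
    M_noise = max(r[!md$is_grating], na.rm = TRUE))
}

#' Two-interval decision by template matching
#'
#' For each interval's correlation surface, computes the best match to the
#' grating templates and to the noise templates, and judges the grating to
#' be in the interval with the greater difference `M_grating - M_noise`.
#' An exact tie (possible only for bit-identical surfaces) is broken
#' uniformly at random using the current RNG state.
#'
#' @param surface_1,surface_2 [correlation_surface()]s of the two intervals,
#'   on the bank's grid.
#' @param bank A [build_bank()] result.
#' @return `1L` or `2L`: the interval judged to contain the grating.
#' @export
decide_interval <- function(surface_1, surface_2, bank) {
  stopifnot(inherits(bank, "template_bank"))
  s1 <- bank_score(surface_1, bank)
  s2 <- bank_score(surface_2, bank)
  d1 <- s1[["M_grating"]] - s1[["M_noise"]]
  d2 <- s2[["M_grating"]] - s2[["M_noise"]]
  if (d1 == d2) return(sample(1:2, 1))
  if (d1 > d2) 1L else 2L
}

#' Two-interval decision without knowing the corrugation frequency
#'
#' Variant of [decide_interval()] for a model observer that does not know
#' the grating frequency: the grating match is maximized across the banks
#' of every candidate frequency (noise templates are frequency-independent,
#' so their match is likewise pooled).
#'
#' @inheritParams decide_interval
#' @param banks A non-empty list of [build_bank()] results.
#' @return `1L` or `2L`.
#' @export
decide_interval_unknown_frequency <- function(surface_1, surface_2, banks) {
  if (!length(banks)) stop("empty bank list")
  sc <- function(surface) {
    s <- vapply(banks, function(b) bank_score(surface, b), numeric(2))
    max(s["M_grating", ]) - max(s["M_noise", ])
  }
  d1 <- sc(surface_1)
  d2 <- sc(surface_2)
  if (d1 == d2) return(sample(1:2, 1))
  if (d1 > d2) 1L else 2L
}
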