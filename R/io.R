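#' Write and read stimuli as 16-bit grayscale TIFF pairs
#'
#' Luminance in `[-1, 1]` is mapped linearly to the 16-bit range (mean gray
#' at mid-scale); a JSON sidecar records the pixel pitch, the disparity
#' profile and the seed, so a stimulus on disk is fully traceable.
#'
#' @param pair A [stereo_pair()].
#' @param basename Output path without extension; writes
#'   `<basename>_L.tif`, `<basename>_R.tif`, `<basename>.json`.
#' @param profile Optional [disparity_profile()] recorded in the sidecar.
#' @param seed Optional seed recorded in the sidecar.
#' @return `basename`, invisibly.
#' @export
write_stimulus <- function(pair, basename, profile = NULL, seed = NULL) {
  stopifnot(inherits(pair, "stereo_pair"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to write stimuli")
  enc <- function(m) (pmin(pmax(m, -1), 1) + 1) / 2
  tiff::writeTIFF(enc(pair$left), paste0(basename, "_L.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(enc(pair$right), paste0(basename, "_R.tif"),
                  bits.per.sample = 16)
  meta <- list(pitch_arcmin = pair$pitch,
               dim = dim(pair$left),
               profile = if (!is.null(profile)) unclass(profile),
               seed = seed)
  jsonlite::write_json(meta, paste0(basename, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(basename)
}

#' @rdname write_stimulus
#' @return For `read_stimulus`, a [stereo_pair()] with attribute `meta`.
#' @export
read_stimulus <- function(basename) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to read stimuli")
  meta <- jsonlite::read_json(paste0(basename, ".json"))
  dec <- function(f) {
    m <- tiff::readTIFF(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    2 * m - 1
  }
  pair <- stereo_pair(dec(paste0(basename, "_L.tif")),
                      dec(paste0(basename, "_R.tif")),
                      meta$pitch_arcmin)
  attr(pair, "meta") <- meta
  pair
}

#' Persist correlation surfaces and template banks
#'
#' Surfaces and banks are self-describing R objects; they are persisted
#' with R's native serialization.
#'
#' @param x A `correlation_surface` or `template_bank`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_object <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_model_object
#' @export
read_model_object <- function(path) readRDS(path)
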