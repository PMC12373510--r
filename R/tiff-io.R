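# Field images travel as multi-page 16-bit TIFFs (one page per channel) with
# a JSON companion file `<path>.json` carrying channel names and the
# pixel-size calibration, since the TIFF writer used here does not expose
# description/resolution tags. Intensities are stored as value/65535, which
# round-trips integer-valued data in [0, 65535] exactly.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a multichannel field as TIFF + JSON sidecar
#'
#' @param image A [multiplex_image()] with integer-valued intensities in
#'   \[0, 65535\].
#' @param path Output TIFF path; metadata goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @seealso [read_field_tiff()]
#' @export
write_field_tiff <- function(image, path) {
  stopifnot(inherits(image, "multiplex_image"))
  rng <- range(unlist(lapply(image$channels, range)))
  if (rng[1] < 0 || rng[2] > 65535) {
    abort("channel intensities must lie in [0, 65535] for 16-bit storage.")
  }
  pages <- lapply(image$channels, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(
      channels = names(image$channels),
      pixel_size_um = image$pixel_size_um,
      width_px = image$width_px,
      height_px = image$height_px
    ),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a multichannel field TIFF
#'
#' Reads all pages of a TIFF and restores channel names and calibration from
#' the JSON sidecar written by [write_field_tiff()]. Both can be overridden,
#' which also allows reading third-party TIFFs that carry no sidecar.
#'
#' @param path TIFF path.
#' @param channels Optional character vector of channel names (one per page).
#' @param pixel_size_um Optional calibration override (um per pixel).
#' @return A [multiplex_image()].
#' @export
read_field_tiff <- function(path, channels = NULL, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::fromJSON(sidecar_path(path))
  }
  channels <- channels %||% meta$channels
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(pixel_size_um)) {
    abort(paste0(
      "no pixel-size metadata found for '", path,
      "'; pass `pixel_size_um` (and `channels`) explicitly."
    ))
  }
  if (is.null(channels)) channels <- sprintf("channel_%d", seq_along(pages))
  if (length(channels) != length(pages)) {
    abort(sprintf("%d channel names supplied for %d TIFF pages.",
                  length(channels), length(pages)))
  }
  chans <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # tolerate grey stored with alpha
    round(p * 65535)
  })
  names(chans) <- channels
  multiplex_image(chans, pixel_size_um = pixel_size_um)
}
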