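#' Multichannel fluorescence field
#'
#' The unit of quantification: a set of named single-channel rasters acquired
#' over the same field, with a physical pixel-size calibration. Rasters are
#' numeric matrices indexed `[row, col]` = `[y + 1, x + 1]` with the origin at
#' the top-left and y increasing downward; pixel `(x, y)` (0-based) covers the
#' unit square `[x, x+1] x [y, y+1]` in pixel coordinates.
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions and non-negative intensities.
#' @param pixel_size_um Physical side length of one pixel, in micrometres.
#' @return An object of class `multiplex_image`.
#' @examples
#' img <- multiplex_image(list(DAPI = matrix(0, 4, 5)), pixel_size_um = 1)
#' img$width_px
#' @export
multiplex_image <- function(channels, pixel_size_um) {
  if (!is.list(channels) || length(channels) == 0) {
    abort("`channels` must be a non-empty named list of matrices.")
  }
  nms <- names(channels)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    abort("channel names must be present, non-empty and unique.")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), TRUE))) {
    abort("every channel must be a numeric matrix.")
  }
  if (length(unique(dims)) != 1L) {
    abort("all channels must share identical dimensions.")
  }
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  d <- dims[[1]]
  structure(
    list(
      channels = channels,
      pixel_size_um = as.numeric(pixel_size_um),
      width_px = d[2],
      height_px = d[1]
    ),
    class = "multiplex_image"
  )
}

#' @export
print.multiplex_image <- function(x, ...) {
  cat(sprintf(
    "<multiplex_image> %d x %d px @ %.6g um/px (%.4f um^2)\n",
    x$width_px, x$height_px, x$pixel_size_um,
    x$width_px * x$height_px * x$pixel_size_um^2
  ))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel raster
#'
#' @param image A [multiplex_image()].
#' @param channel Channel name.
#' @return The channel's numeric matrix.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "multiplex_image"))
  if (!channel %in% names(image$channels)) {
    abort(sprintf(
      "unknown channel '%s'; available channels: %s",
      channel, paste(names(image$channels), collapse = ", ")
    ))
  }
  image$channels[[channel]]
}

#' Physical area of a field
#'
#' @param image A [multiplex_image()].
#' @return Field area in um^2.
#' @export
field_area_um2 <- function(image) {
  stopifnot(inherits(image, "multiplex_image"))
  image$width_px * image$height_px * image$pixel_size_um^2
}

# ---- connected components --------------------------------------------------

#' Label connected components of a binary mask
#'
#' Components of `TRUE` pixels under 4- or 8-connectivity. Labelling is
#' delegated to an undirected graph over adjacent true pixels
#' (igraph::components); labels are dense integers in raster scan order of
#' each component's first pixel.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8: diagonal contacts join).
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  nc <- ncol(mask)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  # vertex ids 1..n in order of `idx` (which is sorted)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L)) # down, right
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- lapply(offs, function(o) {
    r2 <- row + o[1]
    c2 <- col + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[j]
    cbind(vid[idx[ok][keep]], vid[j[keep]])
  })
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)$membership
  # renumber so components appear in scan order
  lab[idx] <- match(comp, unique(comp))
  lab
}
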