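#' Global threshold specification for one channel
#'
#' Pixels are classified positive by comparing raw intensities against a
#' single global threshold, mirroring manual gating of stained channels.
#' The boundary semantics are explicit: `">="` (default, inclusive) or `">"`.
#'
#' @param channel Channel name.
#' @param threshold Numeric cutoff; required for `method = "manual"`,
#'   ignored (recomputed per image) for `method = "otsu"`.
#' @param comparison `">="` or `">"`.
#' @param method `"manual"` or `"otsu"`.
#' @return A `threshold_spec`.
#' @examples
#' threshold_spec("CD3", 400)
#' @export
threshold_spec <- function(channel, threshold = NULL,
                           comparison = c(">=", ">"),
                           method = c("manual", "otsu")) {
  comparison <- match.arg(comparison)
  method <- match.arg(method)
  stopifnot(is.character(channel), length(channel) == 1L)
  if (method == "manual") {
    if (!is_scalar_number(threshold)) {
      abort("manual thresholding requires an explicit numeric `threshold`.")
    }
  } else {
    threshold <- NULL
  }
  structure(
    list(channel = channel, threshold = threshold,
         comparison = comparison, method = method),
    class = "threshold_spec"
  )
}

#' Otsu's automatic global threshold
#'
#' Maximizes the between-class variance of a 256-bin intensity histogram.
#' Ties (flat plateaus of the criterion) are resolved by averaging the
#' maximizing cut positions, so a perfectly bimodal image thresholds midway
#' between its two modes.
#'
#' @param image A [multiplex_image()].
#' @param channel Channel name.
#' @return A single threshold value; classifying with `>=` places the upper
#'   class at or above it.
#' @export
auto_threshold <- function(image, channel) {
  ch <- get_channel(image, channel)
  lo <- min(ch); hi <- max(ch)
  if (lo == hi) {
    abort(sprintf("channel '%s' is constant (value %g); no classes to separate.",
                  channel, lo))
  }
  nbins <- 256L
  bin <- pmin(floor((ch - lo) / (hi - lo) * nbins), nbins - 1L)
  counts <- tabulate(bin + 1L, nbins)
  p <- counts / sum(counts)
  mids <- (seq_len(nbins) - 0.5)
  w0 <- cumsum(p)[-nbins]
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * w0 - mu[-nbins])^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which(sigma_b == max(sigma_b)) # cut after bin k
  cut <- mean(k) # bin boundary index; threshold at lower edge of bin k+1
  lo + cut / nbins * (hi - lo)
}

#' Classify marker-positive pixels by a global threshold
#'
#' @param image A [multiplex_image()].
#' @param spec A [threshold_spec()], or a named length-1 numeric (e.g.
#'   `c(CD3 = 400)`) treated as a manual `>=` threshold.
#' @return Logical matrix, `TRUE` where the comparison holds.
#' @examples
#' img <- multiplex_image(list(a = matrix(c(1, 5, 9, 9), 2)), 1)
#' global_threshold(img, c(a = 5))
#' @export
global_threshold <- function(image, spec) {
  if (is.numeric(spec) && length(spec) == 1L && !is.null(names(spec))) {
    spec <- threshold_spec(names(spec), unname(spec))
  }
  stopifnot(inherits(spec, "threshold_spec"))
  ch <- get_channel(image, spec$channel)
  thr <- if (spec$method == "otsu") {
    auto_threshold(image, spec$channel)
  } else {
    spec$threshold
  }
  if (spec$comparison == ">=") ch >= thr else ch > thr
}

#' Clean a binary mask
#'
#' Removes connected components whose area is below `min_object_area_um2`
#' and optionally fills fully enclosed holes. Idempotent; with
#' `fill_holes = FALSE` the output is a subset of the input.
#'
#' @param mask Logical matrix.
#' @param min_object_area_um2 Minimum component area to keep (um^2).
#' @param fill_holes Fill background components not touching the border.
#' @param pixel_size_um Pixel size (um).
#' @param connectivity Foreground connectivity (4 or 8; holes use the dual).
#' @return Logical matrix.
#' @export
clean_mask <- function(mask, min_object_area_um2 = 0, fill_holes = FALSE,
                       pixel_size_um = 1, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  out <- mask
  if (min_object_area_um2 > 0 && any(out)) {
    lab <- label_components(out, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes * pixel_size_um^2 < min_object_area_um2)
    if (length(drop)) out[lab %in% drop] <- FALSE
  }
  if (fill_holes && any(out)) {
    bg_conn <- if (connectivity == 8) 4 else 8
    lab <- label_components(!out, bg_conn)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    hole <- lab > 0L & !(lab %in% border)
    out[hole] <- TRUE
  }
  out
}
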