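#' Quantify one immunofluorescence field
#'
#' Runs the full measurement chain on a classified field: global thresholds
#' on the DAPI, T- and B-marker channels, aggregate detection on the T|B
#' union, nucleus counting per aggregate, focus calling (> `min_lymphocytes`
#' nuclei), focus score, aggregate area fraction and segregation scoring.
#'
#' When no gland annotation is supplied the whole field is taken as the
#' evaluated area (fixed-field convention); a gland polygon/region
#' annotation switches to whole-gland normalization.
#'
#' @param image A [multiplex_image()].
#' @param thresholds Named numeric vector of manual thresholds per channel
#'   (e.g. `c(DAPI = 2000, CD3 = 2000, B220 = 2000)`), a list of
#'   [threshold_spec()]s, or `NULL` for per-channel Otsu.
#' @param channels Named mapping of roles to channel names
#'   (`dapi`, `t`, `b`).
#' @param gland Optional gland annotation: polygon matrix or [region_set()].
#' @param min_aggregate_area_um2 Minimum aggregate union area (um^2).
#' @param min_lymphocytes Focus inclusion bound (exclusive; default 50).
#' @param index_threshold Segregation decision threshold (default 0.5).
#' @param nucleus_radius_um Nominal nucleus radius for counting (um).
#' @param count_method `"area_ratio"` or `"peaks"` (see [count_nuclei()]).
#' @param min_object_area_um2 Pre-cleaning of marker masks (um^2; 0 = none).
#' @return A `gland_metrics` object: list with `aggregates` (per-aggregate
#'   tibble) and scalar `gland_area_mm2`, `n_foci`, `focus_score`,
#'   `aggregate_area_fraction_pct`, `segregated_prevalence_pct`. Use
#'   [tidy()] for the aggregate table and [glance()] for the one-row
#'   summary.
#' @examples
#' f <- simulate_field(simulation_config(
#'   field_width_px = 300, field_height_px = 300,
#'   n_aggregates = 1, nuclei_per_aggregate = 60
#' ), seed = 2)
#' glance(quantify_field(f$image))
#' @export
quantify_field <- function(image,
                           thresholds = NULL,
                           channels = c(dapi = "DAPI", t = "CD3", b = "B220"),
                           gland = NULL,
                           min_aggregate_area_um2 = 200,
                           min_lymphocytes = 50,
                           index_threshold = 0.5,
                           nucleus_radius_um = 2.5,
                           count_method = c("area_ratio", "peaks"),
                           min_object_area_um2 = 0) {
  stopifnot(inherits(image, "multiplex_image"))
  count_method <- match.arg(count_method)
  px <- image$pixel_size_um

  get_mask <- function(ch) {
    spec <- if (is.null(thresholds)) {
      threshold_spec(ch, method = "otsu")
    } else if (is.numeric(thresholds)) {
      if (!ch %in% names(thresholds)) {
        abort(sprintf("no threshold supplied for channel '%s'.", ch))
      }
      threshold_spec(ch, thresholds[[ch]])
    } else {
      hit <- Filter(function(s) s$channel == ch, thresholds)
      if (length(hit) == 0) abort(sprintf("no threshold spec for '%s'.", ch))
      hit[[1]]
    }
    m <- global_threshold(image, spec)
    if (min_object_area_um2 > 0) {
      m <- clean_mask(m, min_object_area_um2, pixel_size_um = px)
    }
    m
  }
  mask_d <- get_mask(channels[["dapi"]])
  mask_t <- get_mask(channels[["t"]])
  mask_b <- get_mask(channels[["b"]])

  gland_mm2 <- if (is.null(gland)) {
    field_area_um2(image) / 1e6
  } else {
    gland_area_mm2(gland, px)
  }

  aggs <- detect_aggregates(mask_t, mask_b, px, min_aggregate_area_um2)
  dapi_ch <- get_channel(image, channels[["dapi"]])
  dapi_thr <- if (is.null(thresholds)) {
    auto_threshold(image, channels[["dapi"]])
  } else if (is.numeric(thresholds)) {
    thresholds[[channels[["dapi"]]]]
  } else {
    NULL
  }
  if (nrow(aggs) > 0) {
    aggs$nucleus_count <- vapply(aggs$pixels, function(idx) {
      count_nuclei(dapi_ch, idx, px, nucleus_radius_um,
                   method = count_method, dapi_threshold = dapi_thr)
    }, integer(1))
  } else {
    aggs$nucleus_count <- integer(0)
  }
  aggs <- segregation_classify(aggs, index_threshold)

  n_foci <- nrow(detect_foci(aggs, min_lymphocytes))
  total_aggregate_mm2 <- sum(aggs$union_area_um2) / 1e6
  structure(
    list(
      aggregates = aggs[, setdiff(names(aggs), "pixels")],
      gland_area_mm2 = gland_mm2,
      n_foci = n_foci,
      focus_score = focus_score(n_foci, gland_mm2),
      aggregate_area_fraction_pct =
        aggregate_area_fraction(total_aggregate_mm2, gland_mm2),
      segregated_prevalence_pct = segregated_prevalence_pct(aggs),
      params = list(
        min_aggregate_area_um2 = min_aggregate_area_um2,
        min_lymphocytes = min_lymphocytes,
        index_threshold = index_threshold,
        nucleus_radius_um = nucleus_radius_um,
        count_method = count_method
      )
    ),
    class = "gland_metrics"
  )
}

#' @export
print.gland_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<gland_metrics> gland %.4f mm^2 | %d aggregates | %d foci | ",
           "focus score %.3f | area fraction %.3f%% | segregated %.1f%%\n"),
    x$gland_area_mm2, nrow(x$aggregates), x$n_foci, x$focus_score,
    x$aggregate_area_fraction_pct, x$segregated_prevalence_pct
  ))
  invisible(x)
}

#' @method tidy gland_metrics
#' @export
tidy.gland_metrics <- function(x, ...) x$aggregates

#' @method glance gland_metrics
#' @export
glance.gland_metrics <- function(x, ...) {
  tibble(
    gland_area_mm2 = x$gland_area_mm2,
    n_aggregates = nrow(x$aggregates),
    n_foci = x$n_foci,
    focus_score = x$focus_score,
    aggregate_area_fraction_pct = x$aggregate_area_fraction_pct,
    t_area_um2 = sum(x$aggregates$t_area_um2),
    b_area_um2 = sum(x$aggregates$b_area_um2),
    intersection_area_um2 = sum(x$aggregates$intersection_area_um2),
    segregated_prevalence_pct = x$segregated_prevalence_pct
  )
}
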