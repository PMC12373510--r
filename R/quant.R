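# Histopathological measurements on classified masks: marker areas and
# intersections, lymphocytic aggregates (connected T-or-B regions), nucleus
# counts, inflammatory foci (> 50 lymphocytes), focus score, aggregate area
# fraction, and T/B segregation scoring.

#' Positive-marker area of a mask
#'
#' @param mask Logical matrix.
#' @param pixel_size_um Pixel size (um).
#' @return Area in um^2 (true-pixel count times pixel area).
#' @examples
#' marker_area(matrix(c(TRUE, TRUE, FALSE, FALSE), 2), pixel_size_um = 2) # 8
#' @export
marker_area <- function(mask, pixel_size_um) {
  stopifnot(is.matrix(mask), is.logical(mask))
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  sum(mask) * pixel_size_um^2
}

#' @rdname marker_area
#' @export
marker_area_mm2 <- function(mask, pixel_size_um) {
  marker_area(mask, pixel_size_um) / 1e6
}

#' Area where two markers intersect
#'
#' `mode = "raster"` measures the logical AND of the masks. `mode =
#' "polygon"` polygonizes both masks ([mask_to_regions()]) and measures the
#' geometric intersection of the two vector region sets by scanline clipping
#' of their unit-row coverage intervals. The two routes agree exactly because
#' polygonization traces pixel boundaries.
#'
#' @param maskA,maskB Logical matrices of identical dimensions.
#' @param pixel_size_um Pixel size (um).
#' @param mode `"raster"` (default) or `"polygon"`.
#' @return Intersection area in um^2.
#' @export
intersection_area <- function(maskA, maskB, pixel_size_um,
                              mode = c("raster", "polygon")) {
  mode <- match.arg(mode)
  if (!identical(dim(maskA), dim(maskB))) {
    abort("masks must share dimensions.")
  }
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  if (mode == "raster") {
    return(sum(maskA & maskB) * pixel_size_um^2)
  }
  ra <- mask_to_regions(maskA, pixel_size_um)
  rb <- mask_to_regions(maskB, pixel_size_um)
  polygon_overlap_px(ra, rb, nrow(maskA), ncol(maskA)) * pixel_size_um^2
}

# scanline intersection area (in px^2) of two region sets over an
# height x width pixel grid: per unit row strip, each set's coverage is a
# union of x-intervals cut at y = j + 0.5; overlap lengths are accumulated.
polygon_overlap_px <- function(rsA, rsB, height_px, width_px) {
  row_intervals <- function(rs, yc) {
    xs <- list()
    for (g in rs$regions$geometry) {
      rings <- unlist(g, recursive = FALSE)
      for (r in rings) {
        x <- r[, 1]; y <- r[, 2]
        xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
        lo <- pmin(y, yn); hi <- pmax(y, yn)
        hit <- which(lo <= yc & yc < hi)
        if (length(hit)) {
          xs[[length(xs) + 1L]] <-
            x[hit] + (yc - y[hit]) * (xn[hit] - x[hit]) / (yn[hit] - y[hit])
        }
      }
    }
    v <- sort(unlist(xs))
    if (length(v) == 0) return(NULL)
    matrix(v, ncol = 2, byrow = TRUE) # rows: [enter, exit]
  }
  total <- 0
  for (j in 0:(height_px - 1L)) {
    yc <- j + 0.5
    ia <- row_intervals(rsA, yc)
    ib <- row_intervals(rsB, yc)
    if (is.null(ia) || is.null(ib)) next
    for (a in seq_len(nrow(ia))) {
      lo <- pmax(ia[a, 1], ib[, 1])
      hi <- pmin(ia[a, 2], ib[, 2])
      total <- total + sum(pmax(hi - lo, 0))
    }
  }
  total
}

#' Detect lymphocytic aggregates from T and B marker masks
#'
#' Aggregates are connected components (default 8-connectivity) of the union
#' `maskT | maskB`; each carries its per-marker sub-areas clipped to the
#' component footprint.
#'
#' @param maskT,maskB Logical matrices (T- and B-marker positive pixels).
#' @param pixel_size_um Pixel size (um).
#' @param min_aggregate_area_um2 Components below this union area are
#'   dropped.
#' @param connectivity 4 or 8.
#' @return Tibble with one row per aggregate: `aggregate_id`, `pixels`
#'   (list-column of linear raster indices), `union_area_um2`,
#'   `t_area_um2`, `b_area_um2`, `intersection_area_um2`, `centroid_x_px`,
#'   `centroid_y_px`.
#' @export
detect_aggregates <- function(maskT, maskB, pixel_size_um,
                              min_aggregate_area_um2 = 0, connectivity = 8) {
  if (!identical(dim(maskT), dim(maskB))) abort("masks must share dimensions.")
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  u <- maskT | maskB
  lab <- label_components(u, connectivity)
  n <- max(lab)
  pa <- pixel_size_um^2
  rows <- list()
  nr <- nrow(u)
  for (i in seq_len(n)) {
    idx <- which(lab == i)
    area <- length(idx) * pa
    if (area < min_aggregate_area_um2) next
    rows[[length(rows) + 1L]] <- tibble(
      aggregate_id = length(rows) + 1L,
      pixels = list(idx),
      union_area_um2 = area,
      t_area_um2 = sum(maskT[idx]) * pa,
      b_area_um2 = sum(maskB[idx]) * pa,
      intersection_area_um2 = sum(maskT[idx] & maskB[idx]) * pa,
      centroid_x_px = mean((idx - 1L) %/% nr) + 0.5,
      centroid_y_px = mean((idx - 1L) %% nr) + 0.5
    )
  }
  if (length(rows) == 0) {
    return(tibble(
      aggregate_id = integer(), pixels = list(), union_area_um2 = numeric(),
      t_area_um2 = numeric(), b_area_um2 = numeric(),
      intersection_area_um2 = numeric(),
      centroid_x_px = numeric(), centroid_y_px = numeric()
    ))
  }
  dplyr::bind_rows(rows)
}

# separable Gaussian smoothing with edge replication
gaussian_smooth <- function(m, sigma) {
  k <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-k, k))^2 / (2 * sigma^2))
  w <- w / sum(w)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], k), v, rep(v[n], k))
    as.numeric(stats::filter(vp, w, sides = 2))[(k + 1):(k + n)]
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(m2, 1, pad_conv))
}

#' Count nuclei inside an aggregate footprint
#'
#' Two documented approximations of the lymphocyte count a pathologist would
#' make by eye:
#' \describe{
#'   \item{`area_ratio`}{DAPI-positive area inside the footprint divided by
#'     the nominal single-nucleus footprint
#'     ([nominal_nucleus_footprint_px()]), rounded. Exact when nuclei do not
#'     overlap.}
#'   \item{`peaks`}{Local maxima of the Gaussian-smoothed DAPI channel inside
#'     the footprint, kept greedily with a minimum separation of two nucleus
#'     radii. Robust in crowded fields but can merge abutting nuclei.}
#' }
#'
#' @param dapi Numeric matrix (DAPI channel).
#' @param footprint Logical matrix, or an integer vector of linear raster
#'   indices (as produced by [detect_aggregates()]).
#' @param pixel_size_um Pixel size (um).
#' @param nucleus_radius_um Nominal nucleus radius (um), > 0.
#' @param method `"area_ratio"` (default) or `"peaks"`.
#' @param dapi_threshold DAPI positivity cutoff; defaults to Otsu on the
#'   whole channel.
#' @return Integer nucleus count.
#' @export
count_nuclei <- function(dapi, footprint, pixel_size_um, nucleus_radius_um,
                         method = c("area_ratio", "peaks"),
                         dapi_threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(dapi), is.numeric(dapi))
  if (!is_scalar_number(nucleus_radius_um) || nucleus_radius_um <= 0) {
    abort("`nucleus_radius_um` must be positive.")
  }
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  fp <- if (is.logical(footprint)) which(footprint) else as.integer(footprint)
  if (length(fp) == 0) return(0L)
  if (any(fp < 1L | fp > length(dapi))) abort("footprint outside image bounds.")
  if (is.null(dapi_threshold)) {
    img <- multiplex_image(list(DAPI = dapi), pixel_size_um)
    dapi_threshold <- auto_threshold(img, "DAPI")
  }
  if (method == "area_ratio") {
    pos <- sum(dapi[fp] >= dapi_threshold)
    nominal <- nominal_nucleus_footprint_px(nucleus_radius_um, pixel_size_um)
    return(as.integer(round(pos / nominal)))
  }
  # peaks: smooth, find 8-neighbour local maxima, greedy min-separation
  r_px <- nucleus_radius_um / pixel_size_um
  sm <- gaussian_smooth(dapi, sigma = r_px / 2)
  nr <- nrow(sm); nc <- ncol(sm)
  inside <- matrix(FALSE, nr, nc)
  inside[fp] <- TRUE
  cand <- which(inside & sm >= dapi_threshold)
  if (length(cand) == 0) return(0L)
  ry <- (cand - 1L) %% nr + 1L
  rx <- (cand - 1L) %/% nr + 1L
  is_max <- vapply(seq_along(cand), function(i) {
    y <- ry[i]; x <- rx[i]
    y0 <- max(1L, y - 1L); y1 <- min(nr, y + 1L)
    x0 <- max(1L, x - 1L); x1 <- min(nc, x + 1L)
    sm[y, x] >= max(sm[y0:y1, x0:x1])
  }, logical(1))
  py <- ry[is_max]; px <- rx[is_max]; pv <- sm[cand[is_max]]
  o <- order(pv, decreasing = TRUE)
  py <- py[o]; px <- px[o]
  min_d2 <- (2 * r_px)^2
  kept_x <- numeric(0); kept_y <- numeric(0)
  for (i in seq_along(px)) {
    if (length(kept_x) == 0 ||
        min((kept_x - px[i])^2 + (kept_y - py[i])^2) >= min_d2) {
      kept_x <- c(kept_x, px[i]); kept_y <- c(kept_y, py[i])
    }
  }
  length(kept_x)
}

#' Filter aggregates down to inflammatory foci
#'
#' A focus is an aggregate with strictly more than `min_lymphocytes`
#' nuclei (the histological definition counts infiltrates of more than 50
#' lymphocytes, so a count of exactly 50 is excluded).
#'
#' @param aggregates Data frame with a `nucleus_count` column.
#' @param min_lymphocytes Exclusive lower bound (default 50).
#' @return The qualifying rows, as a tibble.
#' @export
detect_foci <- function(aggregates, min_lymphocytes = 50) {
  stopifnot(is.data.frame(aggregates), "nucleus_count" %in% names(aggregates))
  as_tibble(aggregates[aggregates$nucleus_count > min_lymphocytes, , drop = FALSE])
}

#' Focus score
#'
#' The clinical severity index: number of inflammatory foci per mm^2 of
#' gland, scaled to foci per 4 mm^2:
#' `focus_score = (n_foci / gland_area_mm2) * 4`.
#'
#' @param n_foci Number of foci (>= 0).
#' @param gland_area_mm2 Total gland area in mm^2 (> 0).
#' @return The focus score.
#' @examples
#' focus_score(3, 6) # 2
#' @export
focus_score <- function(n_foci, gland_area_mm2) {
  if (any(!is.finite(gland_area_mm2)) || any(gland_area_mm2 <= 0)) {
    abort("`gland_area_mm2` must be positive.")
  }
  if (any(n_foci < 0)) abort("`n_foci` must be non-negative.")
  n_foci / gland_area_mm2 * 4
}

#' Aggregate area fraction
#'
#' Percentage of the gland area occupied by inflammatory aggregates:
#' `100 * aggregate_area / gland_area`.
#'
#' @param total_aggregate_area_mm2 Summed aggregate area (mm^2).
#' @param gland_area_mm2 Gland area (mm^2, > 0).
#' @return Percentage in \[0, 100\].
#' @examples
#' aggregate_area_fraction(0.5, 2) # 25
#' @export
aggregate_area_fraction <- function(total_aggregate_area_mm2, gland_area_mm2) {
  if (any(!is.finite(gland_area_mm2)) || any(gland_area_mm2 <= 0)) {
    abort("`gland_area_mm2` must be positive.")
  }
  if (any(total_aggregate_area_mm2 < 0)) {
    abort("aggregate area must be non-negative.")
  }
  if (any(total_aggregate_area_mm2 > gland_area_mm2)) {
    abort("aggregate area exceeds gland area; inconsistent segmentation.")
  }
  100 * total_aggregate_area_mm2 / gland_area_mm2
}

#' Gland area from an annotation
#'
#' Accepts a semi-manual gland outline (simple polygon in pixel coordinates,
#' or a [region_set()] e.g. read from GeoJSON) or a gland mask.
#'
#' @param gland An n x 2 polygon matrix, a [region_set()], or a logical mask.
#' @param pixel_size_um Pixel size (um); ignored for a `region_set`, which
#'   carries its own.
#' @return Gland area in mm^2.
#' @export
gland_area_mm2 <- function(gland, pixel_size_um = NULL) {
  if (inherits(gland, "region_set")) {
    return(sum(gland$regions$area_um2) / 1e6)
  }
  if (is.matrix(gland) && is.logical(gland)) {
    stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
    return(sum(gland) * pixel_size_um^2 / 1e6)
  }
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  poly <- validate_simple_polygon(gland)
  polygon_area_px(poly) * pixel_size_um^2 / 1e6
}

#' Segregation index of one aggregate
#'
#' `1 - intersection / min(t_area, b_area)` when both marker areas are
#' positive; defined as 1 when exactly one marker area is 0 (fully discrete
#' compartments); undefined (`NA`) when both are 0.
#'
#' @param t_area_um2,b_area_um2,intersection_area_um2 Per-aggregate marker
#'   areas (vectorized).
#' @return Numeric vector in \[0, 1\], `NA` where undefined.
#' @export
segregation_index <- function(t_area_um2, b_area_um2, intersection_area_um2) {
  m <- pmin(t_area_um2, b_area_um2)
  out <- ifelse(t_area_um2 == 0 & b_area_um2 == 0, NA_real_,
                ifelse(m == 0, 1, 1 - intersection_area_um2 / m))
  pmin(pmax(out, 0), 1)
}

#' Classify aggregates as segregated
#'
#' Adds/overwrites `segregation_index` and `segregated` columns: segregated
#' when the index is at or above `index_threshold` (default 0.5). Aggregates
#' with both marker areas 0 get `NA` in both columns and are excluded from
#' the prevalence.
#'
#' @param aggregates Data frame with `t_area_um2`, `b_area_um2`,
#'   `intersection_area_um2`.
#' @param index_threshold Decision threshold on the index.
#' @return Tibble with the two columns added.
#' @seealso [segregated_prevalence_pct()]
#' @export
segregation_classify <- function(aggregates, index_threshold = 0.5) {
  stopifnot(is.data.frame(aggregates))
  idx <- segregation_index(aggregates$t_area_um2, aggregates$b_area_um2,
                           aggregates$intersection_area_um2)
  dplyr::mutate(as_tibble(aggregates),
                segregation_index = idx,
                segregated = idx >= index_threshold)
}

#' @rdname segregation_classify
#' @return `segregated_prevalence_pct()`: percentage of segregated
#'   aggregates among those with a defined index (`NA` if none defined).
#' @export
segregated_prevalence_pct <- function(aggregates) {
  s <- aggregates$segregated
  s <- s[!is.na(s)]
  if (length(s) == 0) return(NA_real_)
  100 * mean(s)
}

#' Per-field positive cell counts
#'
#' A cell is marker-positive when its nucleus position falls inside the
#' marker's positive mask. Reported per acquired field without gland
#' normalization.
#'
#' @param positions n x 2 matrix of nucleus positions in pixel coordinates
#'   (0-based, x then y).
#' @param maskA,maskB Logical marker masks of identical dimensions.
#' @return One-row tibble: `n_cells_markerA`, `n_cells_markerA_and_B`,
#'   `pct_double_positive` (`NA` when no A-positive cells).
#' @export
field_cell_counts <- function(positions, maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) abort("masks must share dimensions.")
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) {
    return(tibble(n_cells_markerA = 0L, n_cells_markerA_and_B = 0L,
                  pct_double_positive = NA_real_))
  }
  col <- floor(positions[, 1]) + 1L
  row <- floor(positions[, 2]) + 1L
  ok <- row >= 1L & row <= nrow(maskA) & col >= 1L & col <= ncol(maskA)
  ii <- cbind(row[ok], col[ok])
  a <- maskA[ii]
  ab <- a & maskB[ii]
  nA <- sum(a); nAB <- sum(ab)
  tibble(
    n_cells_markerA = nA,
    n_cells_markerA_and_B = nAB,
    pct_double_positive = if (nA > 0) 100 * nAB / nA else NA_real_
  )
}
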